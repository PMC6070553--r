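---
title: "Field-induced dispersion from quantum Drude oscillators: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-induced dispersion from quantum Drude oscillators: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdofid)
```

## The physical problem

Van der Waals dispersion forces arise from correlated quantum charge
fluctuations and are usually treated as independent of static external
fields.  A static point charge, however, polarizes the *excited* states of
the interacting fragments and thereby modifies the dispersion energy
itself.  This charge-odd part of the correlation energy — *field-induced
dispersion* (FID) — is absent from dispersion-corrected DFT, classical
force fields and MP2, yet can amount to a sizeable fraction of
intermolecular binding energies near ions, charged residues or electrode
surfaces.  `qdofid` evaluates the leading FID term analytically for
systems of atoms modelled as quantum Drude oscillators (QDOs), and ships a
brute-force perturbation-theory oracle for validating every ingredient.

## The quantum Drude oscillator model

Each atom's valence response is replaced by one isotropic 3D quantum
harmonic oscillator: a Drude quasiparticle of mass $\mu$ and charge $-q$
bound with frequency $\omega$ to a center carrying $+q$
(`qdo_params()`).  The multipole polarizabilities are analytic,

$$\alpha_l \;=\; \frac{q^2}{\mu\omega^2}\,\frac{(2l-1)!!}{l}
  \left(\frac{\hbar}{2\mu\omega}\right)^{l-1},$$

implemented in `alpha_l()`.  Only $\alpha_1$ survives the classical limit;
every higher multipole polarizability carries explicit powers of $\hbar$
(`classical_limit_alpha_l()` exposes $\hbar$ as a single switch).  The
triple $(\alpha_1, \alpha_2, \omega)$ is equivalent to $(\mu, \omega, q)$:
`make_sites()` inverts $\alpha_2/\alpha_1 = \tfrac{3}{2}\hbar/(2\mu\omega)$
for the mass and $\alpha_1 = q^2/\mu\omega^2$ for the charge.

Atoms in molecules are compressed relative to free atoms.  Following the
Tkatchenko–Scheffler picture, free-atom polarizabilities are rescaled by
the Hirshfeld volume ratio $v = V^{\mathrm{eff}}/V^{\mathrm{free}}$
computed externally by DFT: exponent 1 for $\alpha_1$ and exponent 2 for
$\alpha_2$ (`ts_scale()`).  The dipole exponent is the standard TS
convention; it is stated here as a convention because only the quadrupole
rule is fixed by the model's own scaling argument.  The default ratio is 1
(free-atom limit) because the package performs no electronic-structure
calculations.

## Multipole algebra

All angular algebra uses complex spherical harmonics in Racah
normalization, $C_{lm} = \sqrt{4\pi/(2l+1)}\,Y_{lm}$, with the
Condon–Shortley phase — one convention everywhere, tested everywhere.  The
two-center coupling between multipole components on sites A and B
separated by $\mathbf R$ is

$$T_{l_A m_A; l_B m_B}(\mathbf R) = (-1)^{l_A}
  \sqrt{\frac{(2l_A+2l_B+1)!}{(2l_A)!\,(2l_B)!}}
  \begin{pmatrix} l_A & l_B & l_A+l_B\\ m_A & m_B & -(m_A+m_B)\end{pmatrix}
  I_{l_A+l_B,-(m_A+m_B)}(\mathbf R),$$

with $I_{l,m}(\mathbf R) = C_{lm}(\hat{\mathbf R})/|\mathbf R|^{l+1}$ the
normalized irregular solid harmonic (`interaction_tensor()`,
`irregular_solid_harmonic()`, `wigner3j()`).  The normalization of
$I_{lm}$ is not uniquely fixed by the name "normalized"; the Racah choice
is adopted because it makes the dipole–dipole block reduce to the familiar
Cartesian $(\mathbf 1 - 3\hat z\hat z)/R^3$ tensor, and because with it
the multipole series reproduces direct Coulomb sums between neutral charge
distributions (both are asserted in the test suite).  The coupling of a
neutral QDO to an external charge $\delta$ at distance $\tilde R$ is
$-\delta\sum_{l\ge1}\sum_m Q_{lm}/\tilde R^{l+1}$ with the quantization
axis along the center-to-charge direction (`charge_coupling()`); the
monopole term cancels exactly for a neutral oscillator and is rejected.

Wigner 3j symbols are evaluated by the Racah single-sum formula in double
precision; factorials below $171!$ are exact to machine precision as
doubles, and the suite compares every symbol with $l \le 6$ exhaustively
against exact rational arithmetic (sympy) at $10^{-12}$.

## The FID energy

The leading FID term is third order in perturbation theory: one QDO is
quadrupole-polarized through the external charge while exchanging a
dipole–dipole fluctuation with its partner.  Per polarized site A,

$$E^A_{\mathrm{FID}} = -\frac{\delta}{2}\,
  \frac{\alpha_1^B\alpha_2^A\,\omega_A\omega_B}
       {(2\omega_A+\omega_B)(\omega_A+\omega_B)}\,
  \frac{1}{\tilde R_A^2}
  \sum_{m_A m_B} T_{2,-m_A;1,-m_B}\,T_{1,m_A;1,m_B}\sqrt{4-m_A^2},$$

and the pair total adds the mirror term with B polarized
(`fid_pair_polarized()`, `fid_pair_total()`).  The $m$-sum is evaluated in
a canonical pair frame with $z$ along $\mathbf R_{AB}$, because the
$\sqrt{4-m_A^2}$ weight is frame-specific; as printed the expression
depends on the charge position only through $|\tilde R_A|$.  For two
identical sites equidistant from the charge the frequency factor cancels
and the total collapses to the closed form

$$E_{\mathrm{FID}} = -3\,\delta\,\alpha_2\,\alpha_1\,
  \tilde R^{-2} R^{-7},$$

(`closed_form_symmetric()`); the $-3$ prefactor emerging from the 3j
machinery is an acceptance gate of the package.  A positive charge gives a
negative (binding) contribution and the energy is exactly antisymmetric in
$\delta$ — the basis of the diagnostic combination
$W = \tfrac12[E(-\delta) - E(+\delta)]$ (`antisymmetric_combination()`),
which strips charge-even electrostatic and induction content from total
binding-energy differences.

Systems (`fid_system()`, `compute_fid()`) are treated pairwise: the FID
total sums over all intermolecular atom pairs, and over external charges
by linear superposition, which is exact in the linear-response regime
since cross-charge terms are quadratic in the charges and therefore
charge-even — outside FID as defined.  Distances $\tilde R$ are measured
from each polarized atom's oscillation center, not from a molecular
center of mass.  Intramolecular pairs are excluded by default (they do not
contribute to intermolecular binding) but can be included for diagnostics.
A pairwise London comparator
$C_6 = \tfrac32\alpha_1^A\alpha_1^B\hbar\,\omega_A\omega_B/(\omega_A+\omega_B)$
(`london_pair_c6()`) puts FID magnitudes in context of the conventional
$-C_6/R^6$ dispersion.

## The perturbation-theory oracle

`rspt_energy()` evaluates orders 1–3 of Rayleigh–Schrödinger perturbation
theory for one to three QDOs plus point charges in a truncated
harmonic-oscillator product basis.  Design choices:

* The Coulomb couplings are represented by their multipole expansions
  (charge coupling to $l_{\max}$, default 3; inter-QDO coupling to
  combined order $l_A + l_B \le l_{\mathrm{sum}}$, default 3) — the same
  expansion in which the analytic formula lives, so the oracle isolates
  the same terms; bare $1/r$ matrix elements in an oscillator basis would
  converge far too slowly for desk-scale checks.
* All matrix elements are analytic: per-axis ladder matrices are taken
  large enough that truncation never clips an intermediate state, so the
  multipole operator blocks are exact on the retained states.  The
  spherical-basis route (`multipole_matrix_element()`, Laguerre radial
  integrals times Gaunt coefficients) is an independent code path used for
  cross-checks; numerical quadrature appears only inside tests.
* The isotropic oscillator ground state is unique for $\omega > 0$, so
  the second- and third-order sums never meet a vanishing denominator; an
  assertion guards this.
* A validity heuristic rejects geometries where any relevant distance is
  below five oscillator length scales, where the multipole expansion of
  the model itself breaks down.

The basis cutoff `n_max` counts oscillator quanta; states number
$(n_{\max}+1)(n_{\max}+2)(n_{\max}+3)/6$ per QDO.  Because the
perturbation operators are low-order polynomials in the coordinates, the
order-2 and order-3 sums saturate at small `n_max`; the suite uses 6–10,
where a two-QDO third-order evaluation takes well under a second.

Validation chain asserted by the tests: the charge couplings reproduce the
analytic static $\alpha_1,\alpha_2,\alpha_3$ responses of a single QDO to
$10^{-10}$; the dipole-truncated second order reproduces the London
$-C_6/R^6$ energy (identical and heteronuclear pairs) at machine
precision; the multipole series reproduces direct Coulomb sums; the
charge-odd third order is extracted by the antisymmetric combination
(`extract_fid_component()`), which is exact because charge-even orders
cancel identically.

## What the oracle shows about the analytic formula

With dipolar charge coupling ($l_{\max} = 1$, the channel with the
$\tilde R^{-2}$ signature of the analytic formula) the charge-odd third
order of the model Hamiltonian is, for the A-polarized term and measured
to $10^{-6}$ over random parameters and charge directions,

$$E^A_{\mathrm{odd}} = -\frac{\delta}{2}\,\alpha_1^B\alpha_2^A\,
  \frac{4\,\omega_B}{3\,(\omega_A+\omega_B)}\;
  q_A\cos\theta_A\,\frac{1}{\tilde R_A^2}\,\frac{18}{R^7},$$

where $\theta_A$ is the angle at A between the directions to its partner
and to the charge.  Relative to the analytic per-site formula this carries
(i) an extra factor $q_A$ — the bare third-order amplitude has three
perturbation legs on the polarized oscillator ($\propto q_A^3 q_B^2$) and
cannot be reduced to $\alpha_2^A\alpha_1^B \propto q_A^2q_B^2$, (ii) an
explicit dependence on the charge direction, absent from the analytic
expression, and (iii) a different frequency combination.  The package
treats the printed analytic formula as the authoritative definition of the
FID energy (it is the quantity validated against RPA reference data at
molecular scale) and reports the oracle relation as an open modelling
question rather than "fixing" either side: the corresponding
oracle-equivalence test is asserted at its stated 0.5% gate and fails,
with the measured law recorded in its own property test.  Users comparing
the two routes should expect, e.g., a ratio of $4q\cos\theta$-type between
them at equal frequencies.  A practical corollary of the in-model law is
that on the perpendicular bisector ($\cos\theta = R/2\tilde R$) the bare
third-order term scales as $\tilde R^{-3}R^{-6}$.

## Parameters, units and defaults

Internally everything is in Hartree atomic units ($\hbar = m_e = e = 1$);
geometry files and charge tables are read in ångström and elementary
charges, and reports default to meV (4 significant figures in printed
output, full precision in JSON).  The shipped element table
(`inst/extdata/qdo_params.tsv`) is deliberately minimal and editable: the
free-atom $\alpha_1$ values are standard reference polarizabilities, the
frequencies follow the homonuclear London closure
$\omega = 4C_6/3\alpha_1^2$ (a convention, flagged as such), the hydrogen
$\alpha_2$ is the exact hydrogen-atom value, and the C/N/O $\alpha_2$ are
synthetic model estimates supplied only so the package runs out of the
box.  Quantitative work should override them and supply per-atom Hirshfeld
ratios.

The fixture generator (`generate_fixture()`) encodes the probe conditions
the package is exercised under: the `collinear` preset realizes the
symmetric closed-form regime (identical sites, equal charge distances,
unit parameters by default — the $-3$ hartree unit case); the `bisector`
preset mirrors the molecular-scale probe layout of a charge held at 5 Å
from each oscillator while the separation is scanned over 4–8 Å (the
distance grid behind the $R^{-7}$ acceptance check); `random-dimer` draws
seeded random four-atom systems with polarizabilities of 2–12 bohr³ and
frequencies of 0.3–1.0 a.u. — the realistic range for light main-group
atoms — used by the exact-symmetry property tests.  The generator produces
idealized point-parameter systems; it does not emulate anisotropy,
many-body screening, overlap/exchange at short range, or geometry
relaxation, so passing tests demonstrate correctness of the implemented
model, not accuracy for real molecules.

## Numerical choices

* Selection rules (m-sums, triangle, parity) return exact zeros before
  any floating-point work, and axial tensor elements are evaluated on the
  rotated axis so the analytic m-sum contains only real arithmetic.
* Factorials are exact in double precision throughout the supported index
  range ($l_A + l_B \le 8$ guaranteed; overflow of the tensor prefactor
  would require $l_A + l_B > 15$).
* Degenerate inputs error early with typed messages (singular geometry,
  parse errors with line numbers, degenerate zero charges, non-disjoint
  fragments, coincident atom/charge positions at the $10^{-6}$ bohr
  level).
* The pipeline is deterministic: a fixed seed makes fixture generation
  reproducible and JSON reports byte-identical (no timestamps).

## Limitations

Pairwise additivity only (no many-body FID, no screening); the leading
dipole–quadrupole diagram only (higher-order polarization–dispersion
diagrams, which break exact charge-antisymmetry, are out of scope); point
charges only (no finite-dipole sources — within this implementation a
naive two-charge superposition does not reproduce the expected
finite-dipole scaling and is therefore not offered); no electrostatic or
induction terms, which must come from the user's force field or
electronic-structure method; no computation of Hirshfeld volumes.  For
real molecular dimers, deviations against infinite-order reference methods
of up to tens of percent are expected from the leading-order character of
the formula; no tolerance for real systems is asserted by this package.
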