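# qdofid — field-induced dispersion from quantum Drude oscillators

Van der Waals dispersion is usually treated as blind to static electric
fields, yet an external point charge — an ion in a binding pocket, a
charged residue, a protonated group — polarizes the *excited* states of
nearby molecules and thereby changes their mutual dispersion energy.
This charge-odd piece of the correlation energy, **field-induced
dispersion (FID)**, is missing from dispersion-corrected DFT, MP2 and
classical force fields.  `qdofid` computes it analytically for molecules
whose atoms are modelled as quantum Drude oscillators (QDOs), and is aimed
at force-field and vdW-method developers and at anyone estimating how much
an ion or charged group modulates non-covalent binding.

## The model in brief

Each atom is a quantum Drude oscillator with parameters (μ, ω, q) and
analytic multipole polarizabilities
α_l = (q²/μω²)·[(2l−1)!!/l]·(ħ/2μω)^(l−1).
The leading FID term is third-order: QDO A is quadrupole-polarized by the
external charge δ while exchanging a dipole–dipole fluctuation with QDO B,

    E_FID^A = −(δ/2) · α₁ᴮ α₂ᴬ ω_A ω_B / [(2ω_A+ω_B)(ω_A+ω_B)] · R̃_A⁻²
              · Σ_{m_A m_B} T_{2,−m_A;1,−m_B} T_{1,m_A;1,m_B} √(4−m_A²),

with T the complex spherical multipole interaction tensor (Wigner 3j ×
irregular solid harmonic) and R̃_A the distance from A to the charge.  The
pair total adds the mirror term with B polarized.  For identical sites
equidistant from the charge this collapses to the closed form

    E_FID = −3 δ α₂ α₁ / (R̃² R⁷),

so FID is linear in the charge (stabilizing for δ > 0, destabilizing for
δ < 0), falls off as R⁻⁷ with the interatomic distance — only one power
faster than London dispersion — and vanishes linearly with ħ (α₂ ∝ ħ): a
purely quantum effect.  Free-atom polarizabilities are rescaled by
DFT-derived Hirshfeld volume ratios in Tkatchenko–Scheffler fashion
(exponent 1 for α₁, exponent 2 for α₂).  A brute-force
Rayleigh–Schrödinger perturbation-theory oracle (orders 1–3 in a truncated
oscillator product basis) validates the tensor algebra, the
polarizabilities and the London limit, and probes the analytic formula
itself; see the methods vignette (`vignettes/field-induced-dispersion.Rmd`)
for what it confirms and what it leaves open.

## Worked example

Two hydrogen-like QDO sites 6 Å apart with a unit positive charge held
5 Å from each (the symmetric probe layout):

```r
library(qdofid)
fx  <- generate_fixture("bisector", seed = 1, R = 6, R_tilde = 5, delta = 1)
rep <- compute_fid(fx$system)
print(rep)
#> Field-induced dispersion report
#>   pair terms: 1   external charges: 1
#>   total E_FID: -0.002562 meV
#>   London dipole-dipole comparator: -0.08325 meV
```

The FID total is negative (a positive charge strengthens binding) and
about 3% of the London dipole–dipole energy for this weakly polarizable
pair; for polarizable molecular dimers at realistic ion distances the
reported analytic FID can reach tens of meV, e.g. a 47.4 meV FID energy
against a 134.6 meV total binding energy:

```r
binding_fraction(47.4, 134.6)
#> [1] 35.21545      # percent of the binding energy
```

Scanning the separation at fixed charge distance shows the R⁻⁷ law:

```r
fid_distance_scan(c(4, 5.7, 8), R_tilde = 5)
#>   R_angstrom     E_hartree         E_meV
#> 1        4.0 -2.383260e-08 -6.485182e-04
#> 2        5.7 -1.997411e-09 -5.435232e-05
#> 3        8.0 -1.861922e-10 -5.066548e-06
```

Real geometries enter through standard files: `read_xyz()` +
`read_charges()` + `load_fid_system()`, with per-element parameters from
an editable table (`read_param_table()`).  A thin command-line interface
(`inst/scripts/fid`) exposes the same functionality
(`fid compute`, `fid scan`, `fid oracle`, `fid tensors`, `fid cbs`,
`fid fixtures`).

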