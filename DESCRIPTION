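Package: qdofid
Title: Field-Induced Dispersion Energies from Quantum Drude Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analytic evaluation of field-induced dispersion (FID), the part
    of the intermolecular van der Waals correlation energy created or
    modified by an external static point charge.  Atoms are modelled as
    quantum Drude oscillators (QDOs); the leading dipole-quadrupole FID
    term, linear in the external charge and scaling as R^-7 with the
    inter-oscillator distance, is assembled from complex spherical
    multipole interaction tensors built on Wigner 3j symbols and irregular
    solid harmonics.  Includes Tkatchenko-Scheffler-like rescaling of
    free-atom polarizabilities by Hirshfeld volume ratios, a pairwise
    London C6 comparator, XYZ/charge-table input, and a brute-force
    Rayleigh-Schrodinger perturbation-theory oracle (orders 1-3) in a
    truncated harmonic-oscillator product basis that validates every
    analytic formula.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
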