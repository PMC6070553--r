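# Hartree atomic units are used internally throughout (hbar = m_e = e = 1,
# lengths in bohr, energies in hartree).  All user-facing I/O is in angstrom,
# elementary charges and (by default) meV.  Planck's constant enters only
# through hbar_au()/the hbar_scale arguments, so the classical limit is a
# single switch.

#' Physical conversion constants of the internal unit system
#'
#' Returns the conversion constants between internal Hartree atomic units
#' (bohr, hartree, hbar = 1, elementary charge = 1) and the external units
#' used for input and reporting.
#'
#' @return Named list with elements `bohr_per_angstrom`, `angstrom_per_bohr`,
#'   `ev_per_hartree`, `mev_per_hartree`, `kcalmol_per_hartree` and `hbar`
#'   (the value of hbar in internal units, identically 1).
#' @export
#' @examples
#' au_units()$angstrom_per_bohr
au_units <- function() {
  list(
    angstrom_per_bohr   = 0.529177210903,
    bohr_per_angstrom   = 1 / 0.529177210903,
    ev_per_hartree      = 27.211386245988,
    mev_per_hartree     = 27211.386245988,
    kcalmol_per_hartree = 627.5094740631,
    hbar                = 1
  )
}

#' hbar in internal units
#'
#' @return 1 (Hartree atomic units).
#' @export
hbar_au <- function() au_units()$hbar

.energy_units <- c("hartree", "eV", "meV", "kcal/mol")

.energy_factor <- function(unit) {
  u <- au_units()
  switch(match.arg(unit, .energy_units),
    "hartree"  = 1,
    "eV"       = u$ev_per_hartree,
    "meV"      = u$mev_per_hartree,
    "kcal/mol" = u$kcalmol_per_hartree
  )
}

#' Convert energies between supported units
#'
#' @param x Numeric energy value(s).
#' @param from,to One of `"hartree"`, `"eV"`, `"meV"`, `"kcal/mol"`.
#' @return Converted numeric value(s).
#' @export
#' @examples
#' convert_energy(1, "hartree", "meV")
convert_energy <- function(x, from = "hartree", to = "meV") {
  x / .energy_factor(from) * .energy_factor(to)
}

#' Convert lengths between bohr and angstrom
#'
#' @param x Numeric length value(s).
#' @param from,to Either `"bohr"` or `"angstrom"`.
#' @return Converted numeric value(s).
#' @export
convert_length <- function(x, from = "angstrom", to = "bohr") {
  from <- match.arg(from, c("bohr", "angstrom"))
  to <- match.arg(to, c("bohr", "angstrom"))
  u <- au_units()
  bohr <- if (from == "bohr") x else x * u$bohr_per_angstrom
  if (to == "bohr") bohr else bohr * u$angstrom_per_bohr
}
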