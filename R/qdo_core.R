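# QDO parameters, analytic multipole polarizabilities and
# Tkatchenko-Scheffler-like environmental rescaling.

#' Quantum Drude oscillator parameters
#'
#' A QDO replaces the valence electronic response of an atom by a single
#' quantum harmonic oscillator: a Drude quasiparticle of mass `mu` bound to
#' the oscillation center with angular frequency `omega`.  The quasiparticle
#' carries charge `-q` and the center `+q`, so the oscillator is neutral but
#' polarizable.  All parameters are in Hartree atomic units.
#'
#' @param mu Oscillator (Drude quasiparticle) mass, must be positive.
#' @param omega Oscillator angular frequency, must be positive.
#' @param q Drude charge magnitude (stored positive), must be positive.
#' @return Object of class `qdo_params`.
#' @export
#' @examples
#' p <- qdo_params(mu = 1, omega = 0.5, q = 1)
#' alpha_l(p, 1)  # dipole polarizability q^2 / (mu omega^2)
qdo_params <- function(mu, omega, q) {
  for (nm in c("mu", "omega", "q")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid parameter: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(list(mu = mu, omega = omega, q = q), class = "qdo_params")
}

#' @export
print.qdo_params <- function(x, ...) {
  cat(sprintf("QDO parameters (a.u.): mu = %g, omega = %g, q = %g\n",
              x$mu, x$omega, x$q))
  cat(sprintf("  alpha_1 = %g bohr^3, alpha_2 = %g bohr^5\n",
              alpha_l(x, 1), alpha_l(x, 2)))
  invisible(x)
}

.double_factorial_odd <- function(l) {
  # (2l - 1)!! for integer l >= 1
  prod(seq(1, 2 * l - 1, by = 2))
}

#' Analytic multipole polarizability of a QDO
#'
#' The static multipole polarizability of order `l` of an isotropic QDO has
#' the closed form
#' \deqn{\alpha_l = \frac{q^2}{\mu\omega^2}\,\frac{(2l-1)!!}{l}
#'       \left(\frac{\hbar}{2\mu\omega}\right)^{l-1},}
#' in atomic units (bohr^(2l+1)).  For `l = 1` this reduces to the familiar
#' \eqn{q^2/\mu\omega^2}; all higher orders carry explicit powers of hbar
#' and are therefore genuinely quantum.
#'
#' @param params A [qdo_params()] object.
#' @param l Multipole order, integer >= 1 (1 = dipole, 2 = quadrupole, ...).
#' @param hbar_scale Scale factor multiplying hbar; see
#'   [classical_limit_alpha_l()].
#' @return Polarizability in atomic units (bohr^(2l+1)).
#' @export
#' @examples
#' p <- qdo_params(1, 1, 1)
#' alpha_l(p, 2)  # 0.75 bohr^5
alpha_l <- function(params, l, hbar_scale = 1) {
  stopifnot(inherits(params, "qdo_params"))
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l != round(l)) {
    stop("invalid multipole order: l must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(hbar_scale) || length(hbar_scale) != 1L || hbar_scale < 0) {
    stop("invalid parameter: hbar_scale must be a nonnegative number",
         call. = FALSE)
  }
  hb <- hbar_au() * hbar_scale
  with(params,
       (q^2 / (mu * omega^2)) * (.double_factorial_odd(l) / l) *
         (hb / (2 * mu * omega))^(l - 1))
}

#' Multipole polarizability with a scaled hbar (classical limit probe)
#'
#' Evaluates [alpha_l()] with hbar replaced by `hbar_scale * hbar`.  For
#' `l >= 2` the polarizability is proportional to `hbar^(l-1)` and vanishes
#' as `hbar_scale -> 0`; the dipole polarizability (`l = 1`) is classical
#' and unaffected.  Because the quadrupole polarizability enters the
#' field-induced dispersion energy linearly, FID is a purely quantum effect
#' that switches off linearly in this limit.
#'
#' @inheritParams alpha_l
#' @param hbar_scale Nonnegative scale factor for hbar.
#' @return Polarizability in atomic units.
#' @export
classical_limit_alpha_l <- function(params, l, hbar_scale) {
  alpha_l(params, l, hbar_scale = hbar_scale)
}

#' Tkatchenko-Scheffler-like rescaling of a free-atom polarizability
#'
#' Rescales a free-atom polarizability by the Hirshfeld volume ratio
#' `V_eff / V_free` of the atom in its molecular environment: exponent 1 for
#' the dipole polarizability (the usual TS rule) and exponent 2 for the
#' quadrupole polarizability.  Higher orders are not defined.
#'
#' @param alpha_free Free-atom polarizability (>= 0, atomic units).
#' @param hirshfeld_ratio Dimensionless Hirshfeld volume ratio (> 0).
#' @param l Multipole order, 1 or 2.
#' @return Effective polarizability `alpha_free * hirshfeld_ratio^l`.
#' @export
#' @examples
#' ts_scale(10, 0.8, l = 2)  # 6.4
ts_scale <- function(alpha_free, hirshfeld_ratio, l) {
  if (!is.numeric(alpha_free) || alpha_free < 0) {
    stop("invalid parameter: alpha_free must be >= 0", call. = FALSE)
  }
  if (!is.numeric(hirshfeld_ratio) || hirshfeld_ratio <= 0) {
    stop("invalid parameter: hirshfeld_ratio must be > 0", call. = FALSE)
  }
  if (!(length(l) == 1L && l %in% c(1, 2))) {
    stop("unsupported order: TS scaling is defined for l = 1 or 2 only",
         call. = FALSE)
  }
  alpha_free * hirshfeld_ratio^l
}

#' Recover QDO parameters from a dipole polarizability
#'
#' Inverts `alpha_1 = q^2 / (mu omega^2)` for the Drude charge given the
#' oscillator mass and frequency.
#'
#' @param alpha1 Dipole polarizability (bohr^3), positive.
#' @param omega Oscillator frequency (a.u.), positive.
#' @param mu Oscillator mass (a.u.), positive.
#' @return A [qdo_params()] object with `q = sqrt(alpha1 * mu * omega^2)`.
#' @export
params_from_alpha <- function(alpha1, omega, mu) {
  for (nm in c("alpha1", "omega", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid parameter: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  qdo_params(mu = mu, omega = omega, q = sqrt(alpha1 * mu * omega^2))
}

#' QDO frequency from dipole polarizability and C6
#'
#' Standard QDO parameter closure for an atom whose homonuclear London
#' coefficient is known: for two identical oscillators
#' `C6 = (3/4) hbar omega alpha1^2`, hence
#' `omega = 4 C6 / (3 alpha1^2)` (a convention, flagged as such).
#'
#' @param alpha1 Dipole polarizability (bohr^3).
#' @param c6 Homonuclear C6 coefficient (hartree bohr^6).
#' @return Frequency omega in atomic units.
#' @export
omega_from_alpha_c6 <- function(alpha1, c6) {
  if (alpha1 <= 0 || c6 <= 0) {
    stop("invalid parameter: alpha1 and c6 must be positive", call. = FALSE)
  }
  4 * c6 / (3 * hbar_au() * alpha1^2)
}

#' An atomic site carrying QDO parameters and polarizabilities
#'
#' Bundles an element label, a Cartesian position, a Hirshfeld volume ratio
#' and the per-atom response parameters.  When a [qdo_params()] object is
#' supplied, the dipole and quadrupole polarizabilities are derived from it
#' via [alpha_l()] and then environment-scaled via [ts_scale()]; they may
#' also be given directly (in which case `params` is optional but required
#' for anything that needs frequencies, i.e. heteronuclear FID terms,
#' London C6 and the perturbation-theory oracle).
#'
#' @param element Chemical symbol (informational label).
#' @param position Numeric length-3 Cartesian position.
#' @param hirshfeld_ratio Hirshfeld volume ratio `V_eff / V_free` (> 0,
#'   default 1 = free-atom limit).
#' @param params Optional [qdo_params()].
#' @param alpha1,alpha2 Optional explicit polarizabilities (atomic units,
#'   already environment-scaled if given).  Default: derived from `params`.
#' @param pos_unit Unit of `position`: `"angstrom"` (default) or `"bohr"`.
#'   Stored internally in bohr.
#' @return Object of class `atom_site`.
#' @export
#' @examples
#' atom_site("H", c(0, 0, 0), params = qdo_params(1, 0.5, 1))
atom_site <- function(element, position, hirshfeld_ratio = 1, params = NULL,
                      alpha1 = NULL, alpha2 = NULL, pos_unit = "angstrom") {
  if (!is.numeric(position) || length(position) != 3L ||
      any(!is.finite(position))) {
    stop("position must be a finite numeric vector of length 3", call. = FALSE)
  }
  if (!is.numeric(hirshfeld_ratio) || hirshfeld_ratio <= 0) {
    stop("invalid parameter: hirshfeld_ratio must be > 0", call. = FALSE)
  }
  if (!is.null(params)) stopifnot(inherits(params, "qdo_params"))
  if (is.null(alpha1)) {
    if (is.null(params)) {
      stop("parameterization error: supply either `params` or `alpha1`",
           call. = FALSE)
    }
    alpha1 <- ts_scale(alpha_l(params, 1), hirshfeld_ratio, 1)
  }
  if (is.null(alpha2)) {
    alpha2 <- if (is.null(params)) {
      NA_real_
    } else {
      ts_scale(alpha_l(params, 2), hirshfeld_ratio, 2)
    }
  }
  if (alpha1 <= 0) stop("alpha1 must be > 0", call. = FALSE)
  if (!is.na(alpha2) && alpha2 < 0) stop("alpha2 must be >= 0", call. = FALSE)
  structure(
    list(element = as.character(element),
         position = convert_length(as.numeric(position), pos_unit, "bohr"),
         hirshfeld_ratio = hirshfeld_ratio,
         params = params,
         alpha1 = alpha1,
         alpha2 = alpha2),
    class = "atom_site"
  )
}

#' @export
print.atom_site <- function(x, ...) {
  cat(sprintf(
    "<atom_site> %s at (%.4f, %.4f, %.4f) bohr; alpha1 = %g, alpha2 = %s, V ratio = %g\n",
    x$element, x$position[1], x$position[2], x$position[3],
    x$alpha1, format(x$alpha2), x$hirshfeld_ratio))
  invisible(x)
}
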