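# Complex spherical multipole algebra: Wigner 3j symbols, Racah-normalized
# spherical harmonics C_lm (Condon-Shortley phase), irregular solid
# harmonics, the two-center multipole interaction tensor and the
# charge-multipole coupling coefficient.  One convention is used everywhere:
# complex harmonics, Condon-Shortley phase, Racah normalization
# C_lm = sqrt(4 pi / (2l + 1)) Y_lm.

#' Wigner 3j symbol
#'
#' Evaluates the Wigner 3j symbol for integer angular momenta by the Racah
#' single-sum formula.  Selection rules (m-sum and triangle inequality)
#' return an exact 0; projection indices exceeding their angular momentum
#' (`|m_i| > l_i`) are an error, distinct from a legitimate zero.
#'
#' @param l1,l2,l3 Nonnegative integer angular momenta.
#' @param m1,m2,m3 Integer projections with `|m_i| <= l_i`.
#' @return The 3j value as a double.
#' @export
#' @examples
#' wigner3j(1, 1, 2, 1, 1, -2)  # sqrt(5)/5
wigner3j <- function(l1, l2, l3, m1, m2, m3) {
  ls <- c(l1, l2, l3); ms <- c(m1, m2, m3)
  if (any(ls != round(ls)) || any(ms != round(ms)) || any(ls < 0)) {
    stop("invalid index: l must be nonnegative integers, m integers",
         call. = FALSE)
  }
  if (any(abs(ms) > ls)) {
    stop("invalid index: |m_i| > l_i", call. = FALSE)
  }
  if (m1 + m2 + m3 != 0) return(0)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) return(0)
  # Racah formula; factorials as doubles (exact to ~1e-15 relative, no
  # overflow below 170!)
  f <- factorial
  delta <- sqrt(f(l1 + l2 - l3) * f(l1 - l2 + l3) * f(-l1 + l2 + l3) /
                  f(l1 + l2 + l3 + 1))
  pre <- (-1)^(l1 - l2 - m3) * delta *
    sqrt(f(l1 + m1) * f(l1 - m1) * f(l2 + m2) * f(l2 - m2) *
           f(l3 + m3) * f(l3 - m3))
  tmin <- max(0, l2 - l3 - m1, l1 - l3 + m2)
  tmax <- min(l1 + l2 - l3, l1 - m1, l2 + m2)
  if (tmax < tmin) return(0)
  s <- 0
  for (t in tmin:tmax) {
    s <- s + (-1)^t /
      (f(t) * f(l3 - l2 + t + m1) * f(l3 - l1 + t - m2) *
         f(l1 + l2 - l3 - t) * f(l1 - t - m1) * f(l2 - t + m2))
  }
  pre * s
}

# Associated Legendre P_l^m(x) for 0 <= m <= l, Condon-Shortley phase
# included, by the standard stable upward recursion in l.
.assoc_legendre <- function(l, m, x) {
  pmm <- if (m == 0) 1 else {
    (-1)^m * .double_factorial_odd(m) * (1 - x^2)^(m / 2)
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    p <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- p
  }
  pmmp1
}

# Racah-normalized complex spherical harmonic C_lm evaluated at the
# direction of Cartesian vector r (need not be normalized).
.c_lm <- function(l, m, r) {
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("singular geometry: |R| = 0", call. = FALSE)
  if (m < 0) {
    return((-1)^(-m) * Conj(.c_lm(l, -m, r)))
  }
  ct <- r[3] / rn
  ct <- max(-1, min(1, ct))
  phi <- atan2(r[2], r[1])
  norm <- sqrt(factorial(l - m) / factorial(l + m))
  norm * .assoc_legendre(l, m, ct) * exp(1i * m * phi)
}

#' Normalized irregular solid harmonic
#'
#' \eqn{I_{l,m}(R) = \sqrt{4\pi/(2l+1)}\, Y_{l,m}(\hat R) / |R|^{l+1}}
#' with the Condon-Shortley phase convention (Racah normalization).  For
#' `R` along +z, `I_{l,0} = |R|^{-(l+1)}` and all `m != 0` components
#' vanish.  This is the decaying (long-range) solid-harmonic solution that
#' enters the multipole interaction tensor.
#'
#' @param l Integer order >= 0.
#' @param m Integer component, `|m| <= l`.
#' @param R Cartesian vector (length 3), `|R| > 0`, in bohr.
#' @return Complex scalar with dimension length^-(l+1).
#' @export
#' @examples
#' irregular_solid_harmonic(2, 0, c(0, 0, 2))  # 1/8
irregular_solid_harmonic <- function(l, m, R) {
  if (l != round(l) || l < 0 || m != round(m) || abs(m) > l) {
    stop("invalid index: require integer l >= 0 and |m| <= l", call. = FALSE)
  }
  rn <- sqrt(sum(R^2))
  if (rn == 0) stop("singular geometry: |R| = 0", call. = FALSE)
  .c_lm(l, m, R) / rn^(l + 1)
}

# Scalar value of the interaction tensor (internal fast path).
.it_value <- function(l_A, m_A, l_B, m_B, R) {
  L <- l_A + l_B
  pref <- (-1)^l_A *
    sqrt(factorial(2 * L + 1) / (factorial(2 * l_A) * factorial(2 * l_B)))
  w <- wigner3j(l_A, l_B, L, m_A, m_B, -(m_A + m_B))
  if (w == 0) return(0 + 0i)
  pref * w * irregular_solid_harmonic(L, -(m_A + m_B), R)
}

#' Two-center multipole interaction tensor
#'
#' The coefficient coupling multipole component (l_A, m_A) on center A to
#' (l_B, m_B) on center B separated by the vector `R` (from A to B):
#' \deqn{T_{l_A m_A; l_B m_B}(R) = (-1)^{l_A}
#'   \sqrt{\frac{(2l_A + 2l_B + 1)!}{(2l_A)!\,(2l_B)!}}
#'   \begin{pmatrix} l_A & l_B & l_A + l_B\\ m_A & m_B & -(m_A+m_B)
#'   \end{pmatrix} I_{l_A+l_B,\,-(m_A+m_B)}(R).}
#' Its magnitude decays as \eqn{|R|^{-(l_A+l_B+1)}}; for `R` along z only
#' components with `m_A + m_B = 0` survive.  With this normalization the
#' dipole-dipole block reduces to the standard Cartesian tensor
#' (e.g. \eqn{T_{1,0;1,0}(R\hat z) = -2/R^3}).
#'
#' @param l_A,m_A,l_B,m_B Integer multipole indices, `|m| <= l`.
#' @param R Cartesian separation vector from center A to center B (bohr).
#' @return Object of class `interaction_tensor`: a list with the indices,
#'   `separation`, and the complex `value` (atomic units).
#' @export
#' @examples
#' interaction_tensor(1, 0, 1, 0, c(0, 0, 3))$value  # -2/27
interaction_tensor <- function(l_A, m_A, l_B, m_B, R) {
  if (any(c(l_A, l_B) != round(c(l_A, l_B))) || l_A < 0 || l_B < 0 ||
      abs(m_A) > l_A || abs(m_B) > l_B) {
    stop("invalid index: require integer l >= 0 and |m| <= l", call. = FALSE)
  }
  structure(
    list(l_A = l_A, m_A = m_A, l_B = l_B, m_B = m_B,
         separation = as.numeric(R),
         value = .it_value(l_A, m_A, l_B, m_B, R)),
    class = "interaction_tensor"
  )
}

#' @export
print.interaction_tensor <- function(x, ...) {
  cat(sprintf("T_{%d,%d;%d,%d}(R = [%g, %g, %g] bohr) = %s\n",
              x$l_A, x$m_A, x$l_B, x$m_B,
              x$separation[1], x$separation[2], x$separation[3],
              format(x$value, digits = 10)))
  invisible(x)
}

#' Charge-multipole coupling coefficient
#'
#' Coefficient multiplying the multipole operator `Q_lm` in the interaction
#' of a neutral QDO with an external point charge `delta` at distance
#' `R_tilde`, in the compact form
#' \eqn{H = -\delta \sum_{l\ge1}\sum_m Q_{lm} / \tilde R^{l+1}}
#' (quantization axis along the center-to-charge direction).  The monopole
#' term `l = 0` is identically compensated for a neutral oscillator and is
#' not supported.
#'
#' @param l Integer multipole order >= 1.
#' @param m Integer component, `|m| <= l`.
#' @param delta Signed external charge (elementary charges).
#' @param R_tilde Distance from the oscillation center to the charge (bohr).
#' @return Object of class `charge_coupling` with fields `l`, `m`,
#'   `coefficient` (= `-delta / R_tilde^(l+1)`), `source_charge`, `distance`.
#' @export
#' @examples
#' charge_coupling(2, 0, delta = 1, R_tilde = 2)$coefficient  # -1/8
charge_coupling <- function(l, m, delta, R_tilde) {
  if (l != round(l) || l < 1) {
    stop("unsupported order: charge coupling requires integer l >= 1",
         call. = FALSE)
  }
  if (m != round(m) || abs(m) > l) {
    stop("invalid index: |m| > l", call. = FALSE)
  }
  if (R_tilde <= 0) stop("singular geometry: R_tilde must be > 0",
                         call. = FALSE)
  structure(
    list(l = l, m = m,
         coefficient = -delta / R_tilde^(l + 1),
         source_charge = delta,
         distance = R_tilde),
    class = "charge_coupling"
  )
}
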