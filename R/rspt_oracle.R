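# Brute-force Rayleigh-Schrodinger perturbation theory (orders 1-3) for
# coupled QDOs plus external point charges, in a truncated 3D
# harmonic-oscillator product basis.  The Coulomb couplings are represented
# through their multipole expansions (charge coupling truncated at l <=
# l_max, inter-QDO coupling at l_A + l_B <= l_sum), matching the expansion
# the analytic FID formula is derived in.  All matrix elements are analytic
# (ladder operators / Gaunt coefficients); numerical quadrature exists only
# as a test oracle.

#' Truncated 3D harmonic-oscillator basis
#'
#' Enumerates the eigenstates of one isotropic 3D harmonic oscillator with
#' at most `n_max` total quanta, in the Cartesian labeling
#' `(n_x, n_y, n_z)`.  This spans the same space as the spherical
#' `(n, l, m)` labeling with `2n + l <= n_max`; the state count is
#' `(n_max + 1)(n_max + 2)(n_max + 3) / 6`.
#'
#' @param n_max Maximum number of quanta (integer >= 0).
#' @return Data frame with columns `nx`, `ny`, `nz`, `quanta`.
#' @export
oscillator_basis <- function(n_max) {
  stopifnot(n_max == round(n_max), n_max >= 0)
  g <- expand.grid(nx = 0:n_max, ny = 0:n_max, nz = 0:n_max)
  g <- g[g$nx + g$ny + g$nz <= n_max, , drop = FALSE]
  g$quanta <- g$nx + g$ny + g$nz
  g <- g[order(g$quanta, g$nx, g$ny, g$nz), ]
  rownames(g) <- NULL
  g
}

# Monomial expansions of the Racah-normalized regular solid harmonics
# r^l C_lm(rhat) for l = 1..3, m = 0..l, as lists of (a, b, c, coef)
# meaning coef * x^a y^b z^c.  m < 0 follows from
# r^l C_{l,-m} = (-1)^m Conj(r^l C_{l,m}) (real Cartesian basis).
.solid_harmonic_monomials <- local({
  s <- sqrt
  tab <- list(
    "1,0" = list(c(0, 0, 1, 1)),
    "1,1" = list(c(1, 0, 0, -1 / s(2)), c(0, 1, 0, -1i / s(2))),
    "2,0" = list(c(0, 0, 2, 1), c(2, 0, 0, -0.5), c(0, 2, 0, -0.5)),
    "2,1" = list(c(1, 0, 1, -s(1.5)), c(0, 1, 1, -1i * s(1.5))),
    "2,2" = list(c(2, 0, 0, s(3 / 8)), c(0, 2, 0, -s(3 / 8)),
                 c(1, 1, 0, 1i * s(3 / 2))),
    "3,0" = list(c(0, 0, 3, 1), c(2, 0, 1, -1.5), c(0, 2, 1, -1.5)),
    "3,1" = list(c(1, 0, 2, -s(3)), c(3, 0, 0, s(3) / 4),
                 c(1, 2, 0, s(3) / 4), c(0, 1, 2, -1i * s(3)),
                 c(2, 1, 0, 1i * s(3) / 4), c(0, 3, 0, 1i * s(3) / 4)),
    "3,2" = list(c(2, 0, 1, s(30) / 4), c(0, 2, 1, -s(30) / 4),
                 c(1, 1, 1, 1i * s(30) / 2)),
    "3,3" = list(c(3, 0, 0, -s(5) / 4), c(1, 2, 0, 3 * s(5) / 4),
                 c(2, 1, 0, -3i * s(5) / 4), c(0, 3, 0, 1i * s(5) / 4))
  )
  function(l, m) {
    if (l < 1 || l > 3 || abs(m) > l) {
      stop("solid-harmonic monomials tabulated for 1 <= l <= 3 only",
           call. = FALSE)
    }
    mono <- tab[[paste(l, abs(m), sep = ",")]]
    if (m < 0) {
      mono <- lapply(mono, function(t) c(t[1:3], (-1)^m * Conj(t[4])))
    }
    mono
  }
})

# One-axis position matrix <n'|x|n> (quanta 0..dim-1) for oscillator
# length scale lam = sqrt(hbar / (2 mu omega)).
.ladder_x <- function(dim, lam) {
  m <- matrix(0, dim, dim)
  for (n in 0:(dim - 2)) {
    m[n + 1, n + 2] <- sqrt(n + 1)   # <n|x|n+1>
    m[n + 2, n + 1] <- sqrt(n + 1)   # <n+1|x|n>
  }
  lam * m
}

# Multipole operator matrix Q_lm = q r^l C_lm in the truncated Cartesian
# product basis `basis` (rows of oscillator_basis()).  Exact: per-axis
# matrices are taken large enough that truncation never clips an
# intermediate state.
.qdo_multipole_matrix <- function(l, m, basis, params, hbar = 1) {
  lam <- sqrt(hbar / (2 * params$mu * params$omega))
  dim1 <- max(basis$quanta) + l + 1
  X <- .ladder_x(dim1, lam)
  pow <- vector("list", l + 1)
  pow[[1]] <- diag(dim1)
  for (p in seq_len(l)) pow[[p + 1]] <- pow[[p]] %*% X
  ix <- basis$nx + 1L; iy <- basis$ny + 1L; iz <- basis$nz + 1L
  S <- nrow(basis)
  Q <- matrix(0 + 0i, S, S)
  for (t in .solid_harmonic_monomials(l, m)) {
    a <- Re(t[1]); b <- Re(t[2]); cc <- Re(t[3]); coef <- t[4]
    Q <- Q + coef * (pow[[a + 1]][ix, ix] *
                       pow[[b + 1]][iy, iy] *
                       pow[[cc + 1]][iz, iz])
  }
  params$q * Q
}

# ---- spherical-basis closed-form matrix elements -------------------------

# Radial integral <n1 l1 | r^L | n2 l2> for the 3D isotropic HO with
# nu = mu omega / (2 hbar), via the finite Laguerre expansion; all Gamma
# functions of half-integer arguments.
.ho_radial_integral <- function(n1, l1, n2, l2, L, nu) {
  norm <- function(n, l) {
    sqrt(2 * (2 * nu)^(l + 1.5) * factorial(n) / gamma(n + l + 1.5))
  }
  lag_coef <- function(n, alpha, k) {
    (-1)^k * gamma(n + alpha + 1) /
      (gamma(alpha + k + 1) * factorial(n - k) * factorial(k))
  }
  s <- (l1 + l2 + L + 1) / 2
  acc <- 0
  for (k1 in 0:n1) {
    a1 <- lag_coef(n1, l1 + 0.5, k1)
    for (k2 in 0:n2) {
      a2 <- lag_coef(n2, l2 + 0.5, k2)
      acc <- acc + a1 * a2 * gamma(s + k1 + k2 + 1)
    }
  }
  norm(n1, l1) * norm(n2, l2) * (2 * nu)^(-(l1 + l2 + L + 3) / 2) / 2 * acc
}

#' Multipole matrix element between spherical oscillator states
#'
#' Closed-form matrix element `<n1 l1 m1 | Q_lm | n2 l2 m2>` of the
#' spherical multipole operator `Q_lm = q r^l C_lm(rhat)` of the Drude
#' displacement between eigenstates of one isotropic 3D harmonic
#' oscillator, labeled by radial quantum number `n` and angular momentum
#' `(l, m)`.  The angular factor is a Gaunt coefficient (two Wigner 3j
#' symbols), the radial factor a finite Laguerre sum; angular selection
#' rules (`m1 = m + m2`, triangle rule, parity `(-1)^l`) give exact zeros.
#'
#' The sign convention is such that the coupling of the oscillator to an
#' external point charge `delta` along the quantization axis is
#' `H = -delta sum_l Q_l0 / R_tilde^(l+1)`; see [charge_coupling()].
#'
#' @param state_i,state_j Numeric vectors `c(n, l, m)` (bra and ket).
#' @param l,m Multipole operator indices, `l >= 1`, `|m| <= l`.
#' @param params [qdo_params()] of the oscillator.
#' @param hbar_scale Optional scale of hbar (classical-limit probe).
#' @return Complex scalar (real for this phase convention), atomic units.
#' @export
#' @examples
#' p <- qdo_params(1, 1, 1)
#' # ground to first z-excited state, dipole operator:
#' multipole_matrix_element(c(0, 0, 0), c(0, 1, 0), 1, 0, p)
multipole_matrix_element <- function(state_i, state_j, l, m, params,
                                     hbar_scale = 1) {
  stopifnot(inherits(params, "qdo_params"))
  chk <- function(s) {
    if (length(s) != 3L || any(s != round(s)) || s[1] < 0 || s[2] < 0 ||
        abs(s[3]) > s[2]) {
      stop("invalid state: need c(n, l, m) with n, l >= 0 and |m| <= l",
           call. = FALSE)
    }
  }
  chk(state_i); chk(state_j)
  if (l != round(l) || l < 1 || abs(m) > l) {
    stop("invalid index: operator requires l >= 1 and |m| <= l",
         call. = FALSE)
  }
  n1 <- state_i[1]; l1 <- state_i[2]; m1 <- state_i[3]
  n2 <- state_j[1]; l2 <- state_j[2]; m2 <- state_j[3]
  if (m1 != m + m2) return(0 + 0i)
  if (l1 < abs(l2 - l) || l1 > l2 + l) return(0 + 0i)
  if ((l1 + l + l2) %% 2 != 0) return(0 + 0i)  # parity
  ang <- (-1)^m1 * sqrt((2 * l1 + 1) * (2 * l2 + 1)) *
    wigner3j(l1, l, l2, 0, 0, 0) * wigner3j(l1, l, l2, -m1, m, m2)
  nu <- params$mu * params$omega / (2 * hbar_au() * hbar_scale)
  rad <- .ho_radial_integral(n1, l1, n2, l2, l, nu)
  params$q * ang * rad + 0i
}

# ---- product-space machinery ---------------------------------------------

# Apply a one-site operator O (S x S) to site `i` of the product-state
# array u (dims = rep(S, n_sites)).
.apply_site <- function(u, O, i, dims) {
  n <- length(dims)
  if (n == 1L) return(as.vector(O %*% u))
  perm <- c(i, setdiff(seq_len(n), i))
  up <- aperm(array(u, dims), perm)
  res <- O %*% matrix(up, nrow = dims[i])
  res <- array(res, dims[perm])
  as.vector(aperm(res, order(perm)))
}

# Assemble the perturbation H' = sum_i H_i + sum_{i<j} H_ij for a list of
# sites and a charge table (bohr / elementary charges), as a list of
# one-site and two-site terms acting on the truncated product basis.
.build_perturbation <- function(sites, charges, basis, l_max, l_sum,
                                hbar = 1) {
  nsite <- length(sites)
  S <- nrow(basis)
  # per-site multipole operator cache, keys "l,m"
  ops <- lapply(sites, function(s) {
    o <- list()
    for (l in 1:max(l_max, l_sum - 1)) {
      for (m in -l:l) {
        o[[paste(l, m, sep = ",")]] <-
          .qdo_multipole_matrix(l, m, basis, s$params, hbar = hbar)
      }
    }
    o
  })
  # one-site charge couplings:
  # H_i = -sum_j delta_j sum_{l<=l_max, m} Conj(C_lm(u_ij)) Q^i_lm / Rt^(l+1)
  one_site <- vector("list", nsite)
  for (i in seq_len(nsite)) {
    H <- matrix(0 + 0i, S, S)
    if (nrow(charges) > 0) {
      for (j in seq_len(nrow(charges))) {
        cp <- as.numeric(charges[j, c("x", "y", "z")])
        d <- cp - sites[[i]]$position
        rt <- sqrt(sum(d^2))
        for (l in 1:l_max) {
          for (m in -l:l) {
            coef <- -charges$q[j] * Conj(.c_lm(l, m, d)) / rt^(l + 1)
            if (coef != 0) H <- H + coef * ops[[i]][[paste(l, m, sep = ",")]]
          }
        }
      }
    }
    one_site[[i]] <- H
  }
  # two-site multipole couplings:
  # H_ij = sum_{l+l' <= l_sum} sum_{m m'} T_{lm;l'm'}(R_ij) Q^i_lm Q^j_l'm'
  two_site <- list()
  if (nsite >= 2) {
    for (i in seq_len(nsite - 1)) {
      for (j in (i + 1):nsite) {
        R <- sites[[j]]$position - sites[[i]]$position
        for (l in 1:(l_sum - 1)) {
          for (lp in 1:(l_sum - l)) {
            for (m in -l:l) {
              for (mp in -lp:lp) {
                tv <- .it_value(l, m, lp, mp, R)
                if (tv == 0) next
                two_site[[length(two_site) + 1L]] <- list(
                  i = i, j = j, coef = tv,
                  Qi = ops[[i]][[paste(l, m, sep = ",")]],
                  Qj = ops[[j]][[paste(lp, mp, sep = ",")]])
              }
            }
          }
        }
      }
    }
  }
  list(one_site = one_site, two_site = two_site, ops = ops)
}

.apply_perturbation <- function(u, pert, dims) {
  out <- 0 + 0i * u
  for (i in seq_along(pert$one_site)) {
    if (any(pert$one_site[[i]] != 0)) {
      out <- out + .apply_site(u, pert$one_site[[i]], i, dims)
    }
  }
  for (t in pert$two_site) {
    out <- out + t$coef * .apply_site(.apply_site(u, t$Qj, t$j, dims),
                                      t$Qi, t$i, dims)
  }
  out
}

#' Rayleigh-Schrodinger perturbation energy for a QDO + charge system
#'
#' Numerically evaluates the perturbation series of the coupled-QDO +
#' point-charge Hamiltonian through third order in a truncated
#' harmonic-oscillator product basis.  The perturbation is
#' `H' = sum_i H_i + sum_{i<j} H_ij`, with the charge couplings expanded in
#' multipoles up to `l_max` and the inter-QDO coupling up to combined order
#' `l_sum` — the same expansion in which the analytic FID formula is
#' derived, so this routine is the independent oracle for it.  Orders:
#' \deqn{E^{(1)} = \langle 0|H'|0\rangle,\quad
#'   E^{(2)} = \sum_{k\ne0} \frac{|\langle 0|H'|k\rangle|^2}{E^{(0)}-E^{(k)}},}
#' \deqn{E^{(3)} = \sum_{k,m\ne0}
#'   \frac{\langle0|H'|m\rangle\langle m|H'|k\rangle\langle k|H'|0\rangle}
#'        {(E^{(0)}-E^{(k)})(E^{(0)}-E^{(m)})}
#'   - \langle0|H'|0\rangle \sum_{m\ne0}
#'   \frac{|\langle0|H'|m\rangle|^2}{(E^{(0)}-E^{(m)})^2}.}
#' With charges absent, `order = 2` with dipole-only coupling reproduces
#' London dispersion; `order = 3` with one charge contains the FID term as
#' its charge-odd part (see [extract_fid_component()]).
#'
#' @param system A [fid_system()] with at most 3 atoms in total; every site
#'   must carry QDO parameters.
#' @param order Perturbation order, 1, 2 or 3; the value returned is the
#'   order-`order` term (not the cumulative sum).
#' @param n_max Basis cutoff: maximum oscillator quanta per QDO.
#' @param l_max Multipole truncation of the charge coupling (>= 1).
#' @param l_sum Maximum combined multipole order `l_A + l_B` of the
#'   inter-QDO coupling (>= 2).
#' @param check_separation Enforce the validity heuristic that every
#'   relevant distance exceeds 5 oscillator length scales (default `TRUE`).
#' @return Energy term in hartree.
#' @export
rspt_energy <- function(system, order, n_max = 8, l_max = 3, l_sum = 3,
                        check_separation = TRUE) {
  stopifnot(inherits(system, "fid_system"))
  if (!(order %in% 1:3)) stop("order must be 1, 2 or 3", call. = FALSE)
  if (l_max < 1 || l_sum < 2) {
    stop("explicit truncation error: need l_max >= 1 and l_sum >= 2",
         call. = FALSE)
  }
  if (n_max < l_sum) {
    stop("explicit truncation error: basis cutoff n_max = ", n_max,
         " too small for the requested multipole truncation", call. = FALSE)
  }
  sites <- c(system$fragment_A, system$fragment_B)
  if (length(sites) > 3L) {
    stop("the perturbation-theory oracle supports at most 3 QDOs",
         call. = FALSE)
  }
  if (any(vapply(sites, function(s) is.null(s$params), logical(1)))) {
    stop("parameterization error: every site needs QDO parameters",
         call. = FALSE)
  }
  if (check_separation) {
    len <- vapply(sites, function(s)
      sqrt(hbar_au() / (s$params$mu * s$params$omega)), numeric(1))
    for (i in seq_along(sites)) {
      for (j in seq_along(sites)) {
        if (j <= i) next
        d <- sqrt(sum((sites[[i]]$position - sites[[j]]$position)^2))
        if (d < 5 * max(len[i], len[j])) {
          stop("geometry too tight for the perturbative oracle: ",
               "inter-QDO distance below 5 oscillator lengths",
               call. = FALSE)
        }
      }
      if (nrow(system$charges) > 0) {
        for (jc in seq_len(nrow(system$charges))) {
          cp <- as.numeric(system$charges[jc, c("x", "y", "z")])
          d <- sqrt(sum((sites[[i]]$position - cp)^2))
          if (d < 5 * len[i]) {
            stop("geometry too tight for the perturbative oracle: ",
                 "charge distance below 5 oscillator lengths", call. = FALSE)
          }
        }
      }
    }
  }
  basis <- oscillator_basis(n_max)
  S <- nrow(basis)
  nsite <- length(sites)
  dims <- rep(S, nsite)
  pert <- .build_perturbation(sites, system$charges, basis, l_max, l_sum)
  # excitation energies per product state: E_k - E_0 = hbar sum_i omega_i N_i
  ex <- 0
  for (i in seq_len(nsite)) {
    e_i <- hbar_au() * sites[[i]]$params$omega * basis$quanta
    before <- prod(dims[seq_len(i - 1)])   # empty product = 1
    after <- prod(dims[-seq_len(i)])
    ex <- ex + rep(rep(e_i, each = before), times = after)
  }
  ground <- which(ex == 0)
  stopifnot(length(ground) == 1L)  # unique ground state for positive omega
  e0 <- rep(0 + 0i, prod(dims)); e0[ground] <- 1
  v <- .apply_perturbation(e0, pert, dims)
  E1 <- Re(v[ground])
  if (order == 1L) return(E1)
  denom <- -ex           # E^(0) - E^(k)
  u2 <- v / denom
  u2[ground] <- 0
  E2 <- Re(sum(Conj(v) * u2))
  if (order == 2L) return(E2)
  Hu <- .apply_perturbation(u2, pert, dims)
  E3 <- Re(sum(Conj(u2) * Hu)) -
    E1 * Re(sum((Conj(v) * v)[-ground] / denom[-ground]^2))
  E3
}

#' Charge-odd part of the third-order energy (the FID component)
#'
#' Given two third-order perturbation energies computed with the external
#' charge(s) at `+delta` and `-delta` (all else identical), returns the
#' charge-odd combination `(E3_plus - E3_minus) / 2`, which at leading
#' multipole order is the field-induced dispersion term evaluated at
#' `+delta`.
#'
#' @param E3_plus Third-order energy at `+delta`.
#' @param E3_minus Third-order energy at `-delta`.
#' @return Energy, same units as the inputs.
#' @export
extract_fid_component <- function(E3_plus, E3_minus) {
  (E3_plus - E3_minus) / 2
}
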