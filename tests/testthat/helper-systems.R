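# Shared builders for test systems (all in atomic units unless noted).

# identical-site pair: alpha1, alpha2 and omega free; mass follows from
# alpha2/alpha1 = (3/2) hbar / (2 mu omega)
sym_site <- function(position, alpha1 = 1, alpha2 = 0.75, omega = 1,
                     element = "X1") {
  mu <- 3 * alpha1 / (4 * alpha2 * omega)
  atom_site(element, position, params = params_from_alpha(alpha1, omega, mu),
            pos_unit = "bohr")
}

# collinear pair on z with a single on-axis charge below site A
collinear_system <- function(R = 12, R_tilde = 20, delta = 1, alpha1 = 1,
                             alpha2 = 0.75, omega = 1) {
  sA <- sym_site(c(0, 0, 0), alpha1, alpha2, omega)
  sB <- sym_site(c(0, 0, R), alpha1, alpha2, omega)
  fid_system(list(sA), list(sB),
             data.frame(x = 0, y = 0, z = -R_tilde, q = delta),
             charge_unit = "bohr")
}

# random small two-fragment system with params on every site
random_system <- function(seed, n_charges = 1) {
  set.seed(seed)
  rs <- function(center) {
    atom_site("X", center + stats::runif(3, -0.5, 0.5),
              params = qdo_params(stats::runif(1, 0.5, 2),
                                  stats::runif(1, 0.4, 1.2),
                                  stats::runif(1, 0.5, 1.5)),
              pos_unit = "bohr")
  }
  fragA <- list(rs(c(0, 0, 0)), rs(c(3, 0, 0)))
  fragB <- list(rs(c(0, 0, 10)), rs(c(3, 0, 10)))
  charges <- data.frame(x = stats::runif(n_charges, -3, 6),
                        y = stats::runif(n_charges, 8, 14),
                        z = stats::runif(n_charges, 2, 8),
                        q = sample(c(-2, -1, 1, 2), n_charges,
                                   replace = TRUE))
  fid_system(fragA, fragB, charges, charge_unit = "bohr")
}

# exact Wigner 3j reference values from sympy (exact rational/surd
# arithmetic), computed in one python call for all valid index sets with
# l1, l2, l3 <= lmax
sympy_wigner3j_table <- function(lmax) {
  script <- sprintf(
    "from sympy.physics.wigner import wigner_3j\nimport itertools\nL = %d\nfor l1 in range(L+1):\n    for l2 in range(L+1):\n        for l3 in range(abs(l1-l2), min(L, l1+l2)+1):\n            for m1 in range(-l1, l1+1):\n                for m2 in range(-l2, l2+1):\n                    m3 = -(m1+m2)\n                    if abs(m3) > l3: continue\n                    v = wigner_3j(l1,l2,l3,m1,m2,m3)\n                    print(l1,l2,l3,m1,m2,m3,v.evalf(17))\n",
    lmax)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- system2("python", f, stdout = TRUE)
  tab <- utils::read.table(text = out,
                           col.names = c("l1", "l2", "l3", "m1", "m2",
                                         "m3", "value"))
  tab
}
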