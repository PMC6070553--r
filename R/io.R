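# File I/O, parameter tables, fixture generation and the basis-set
# extrapolation helper.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U")

.title_case_element <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

#' Read a molecular geometry in XYZ format
#'
#' Standard XYZ: first line the atom count, second line a comment, then one
#' `element x y z` line per atom, coordinates in angstrom.  Extra per-line
#' columns are ignored with a warning.  Parse errors report the offending
#' line number.
#'
#' @param path Path to the XYZ file.
#' @return Data frame with columns `element`, `x`, `y`, `z` (angstrom), in
#'   input order.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("parse error at line 1: empty XYZ file",
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("parse error at line 1: atom count expected", call. = FALSE)
  }
  if (length(lines) < n + 2L) {
    stop("parse error at line ", length(lines) + 1L,
         ": expected ", n, " atom lines, file ends early", call. = FALSE)
  }
  out <- vector("list", n)
  warned_extra <- FALSE
  for (i in seq_len(n)) {
    lineno <- i + 2L
    tok <- strsplit(trimws(lines[lineno]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop("parse error at line ", lineno, ": need `element x y z`",
           call. = FALSE)
    }
    if (length(tok) > 4L && !warned_extra) {
      warning("extra columns beyond `element x y z` ignored (line ",
              lineno, ")")
      warned_extra <- TRUE
    }
    el <- .title_case_element(tok[1])
    if (!(el %in% .element_symbols)) {
      stop("parse error at line ", lineno, ": unknown element '", tok[1],
           "'", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("parse error at line ", lineno, ": non-numeric coordinate",
           call. = FALSE)
    }
    out[[i]] <- data.frame(element = el, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  do.call(rbind, out)
}

#' Read external point charges from a delimited table
#'
#' Rows `x y z q` (positions in angstrom, charge in elementary charges),
#' `#` comment lines allowed.  Zero-magnitude charges are rejected; an
#' empty file yields an empty table with a warning (plain dispersion run).
#'
#' @param path Path to the charge table.
#' @return Data frame with columns `x`, `y`, `z`, `q` (angstrom, e).
#' @export
read_charges <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      col.names = c("x", "y", "z", "q")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          q = numeric(0)))
      }
      stop("parse error in charge table '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (nrow(raw) == 0L) {
    warning("empty charge table: plain dispersion run (no FID)")
    return(raw)
  }
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    stop("parse error in charge table '", path, "': non-numeric entry",
         call. = FALSE)
  }
  if (any(raw$q == 0)) {
    stop("degenerate charge: zero-magnitude row in '", path, "'",
         call. = FALSE)
  }
  raw
}

#' Read a QDO parameter table
#'
#' Delimited text with a header line `element alpha1_free alpha2_free
#' omega`: free-atom dipole polarizability (bohr^3), free-atom quadrupole
#' polarizability (bohr^5) and QDO frequency (a.u.) per element; `#`
#' comments allowed.  The package ships an editable illustrative table for
#' H, C, N and O (see `system.file("extdata", "qdo_params.tsv", package =
#' "qdofid")`); users supply their own values where accuracy matters.
#'
#' @param path Path to the table; default the shipped table.
#' @return Data frame with columns `element`, `alpha1_free`, `alpha2_free`,
#'   `omega`.
#' @export
read_param_table <- function(path = system.file("extdata", "qdo_params.tsv",
                                                package = "qdofid")) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("element", "alpha1_free", "alpha2_free", "omega")
  if (!all(need %in% names(tab))) {
    stop("parse error in parameter table: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab$element <- .title_case_element(tab$element)
  tab
}

#' Build atom sites from a geometry and a parameter table
#'
#' Looks up each element's free-atom polarizabilities and frequency,
#' applies the Tkatchenko-Scheffler-like Hirshfeld scaling, and derives
#' the per-atom QDO parameters: `mu` from the quadrupole/dipole ratio
#' (`alpha2/alpha1 = (3/2) hbar / (2 mu omega)`), `q` from `alpha1`.
#'
#' @param geometry Data frame `element, x, y, z` (angstrom), e.g. from
#'   [read_xyz()].
#' @param params Parameter table from [read_param_table()].
#' @param hirshfeld Hirshfeld volume ratios: a single number or one per
#'   atom (default 1, free-atom limit).
#' @return List of [atom_site()] objects.
#' @export
make_sites <- function(geometry, params = read_param_table(),
                       hirshfeld = 1) {
  n <- nrow(geometry)
  hirshfeld <- rep_len(hirshfeld, n)
  lapply(seq_len(n), function(i) {
    el <- geometry$element[i]
    row <- params[params$element == el, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop("parameterization error: element '", el,
           "' missing from the parameter table", call. = FALSE)
    }
    a1f <- row$alpha1_free[1]; a2f <- row$alpha2_free[1]
    omega <- row$omega[1]
    mu <- 3 * a1f * hbar_au() / (4 * a2f * omega)
    atom_site(el, as.numeric(geometry[i, c("x", "y", "z")]),
              hirshfeld_ratio = hirshfeld[i],
              params = params_from_alpha(a1f, omega, mu),
              pos_unit = "angstrom")
  })
}

# Identical sites for a symmetric pair: given alpha1, alpha2, omega, the
# mass follows from alpha2/alpha1 = (3/2) hbar / (2 mu omega).
.symmetric_site <- function(position, alpha1, alpha2, omega = 1,
                            element = "X1", pos_unit = "bohr") {
  mu <- 3 * alpha1 * hbar_au() / (4 * alpha2 * omega)
  atom_site(element, position, params = params_from_alpha(alpha1, omega, mu),
            pos_unit = pos_unit)
}

#' Generate a deterministic test system
#'
#' Builds small two-QDO + one-charge systems with known properties:
#' \describe{
#'   \item{`collinear`}{Two identical QDOs on the z axis a distance `R`
#'     apart, the charge on the perpendicular bisector so that both charge
#'     distances equal `R_tilde` — the symmetric regime in which the
#'     closed-form FID expression holds exactly; the manifest records it.}
#'   \item{`bisector`}{Same layout at molecular scale: distances given in
#'     angstrom (defaults `R_tilde` = 5 A, `R` = 6 A), sites
#'     parameterized from the shipped table (element `H`).  Suitable for
#'     distance scans.}
#'   \item{`random-dimer`}{Seeded random two-atom fragments and one random
#'     external charge; reproducible for a fixed seed.}
#' }
#'
#' @param preset One of `"collinear"`, `"bisector"`, `"random-dimer"`.
#' @param seed Integer seed (used by `random-dimer`; kept for determinism
#'   everywhere).
#' @param alpha1,alpha2 Site polarizabilities in a.u. (collinear preset).
#' @param delta External charge (elementary charges).
#' @param R Inter-oscillator distance: bohr for `collinear`, angstrom for
#'   `bisector`.
#' @param R_tilde Charge distance: bohr for `collinear`, angstrom for
#'   `bisector`.
#' @param omega Oscillator frequency (a.u., `collinear` preset).
#' @return List with elements `system` (a [fid_system()]) and `manifest`
#'   (preset parameters plus, where the closed form applies,
#'   `expected_fid_hartree`).
#' @export
#' @examples
#' fx <- generate_fixture("collinear", seed = 1, alpha1 = 1, alpha2 = 1,
#'                        delta = 1, R = 1, R_tilde = 1)
#' fx$manifest$expected_fid_hartree  # -3
generate_fixture <- function(preset = c("collinear", "bisector",
                                        "random-dimer"),
                             seed = 1, alpha1 = 1, alpha2 = 1, delta = 1,
                             R = 1, R_tilde = 1, omega = 1) {
  preset <- match.arg(preset)
  set.seed(seed)
  if (preset == "collinear") {
    if (R_tilde < R / 2) {
      stop("R_tilde must be at least R/2 to place an equidistant charge",
           call. = FALSE)
    }
    h <- sqrt(R_tilde^2 - (R / 2)^2)
    sA <- .symmetric_site(c(0, 0, -R / 2), alpha1, alpha2, omega)
    sB <- .symmetric_site(c(0, 0, +R / 2), alpha1, alpha2, omega)
    charges <- data.frame(x = h, y = 0, z = 0, q = delta)
    sys <- fid_system(list(sA), list(sB), charges, charge_unit = "bohr")
    manifest <- list(
      preset = preset, seed = seed, alpha1 = alpha1, alpha2 = alpha2,
      delta = delta, R_bohr = R, R_tilde_bohr = R_tilde,
      expected_fid_hartree =
        closed_form_symmetric(alpha1, alpha2, delta, R_tilde, R))
    return(list(system = sys, manifest = manifest))
  }
  if (preset == "bisector") {
    R_b <- convert_length(R, "angstrom", "bohr")
    Rt_b <- convert_length(R_tilde, "angstrom", "bohr")
    if (Rt_b < R_b / 2) {
      stop("R_tilde must be at least R/2 to place an equidistant charge",
           call. = FALSE)
    }
    tab <- read_param_table()
    geom <- data.frame(element = c("H", "H"), x = 0, y = 0,
                       z = c(-R / 2, R / 2))
    sites <- make_sites(geom, tab)
    h <- sqrt(R_tilde^2 - (R / 2)^2)
    charges <- data.frame(x = h, y = 0, z = 0, q = delta)
    sys <- fid_system(sites[1], sites[2], charges,
                      charge_unit = "angstrom")
    a1 <- sites[[1]]$alpha1; a2 <- sites[[1]]$alpha2
    manifest <- list(
      preset = preset, seed = seed, delta = delta,
      R_angstrom = R, R_tilde_angstrom = R_tilde,
      alpha1 = a1, alpha2 = a2,
      expected_fid_hartree =
        closed_form_symmetric(a1, a2, delta, Rt_b, R_b))
    return(list(system = sys, manifest = manifest))
  }
  # random-dimer: two fragments of 2 atoms in separated boxes, one charge
  rand_site <- function(center) {
    a1 <- stats::runif(1, 2, 12)
    w <- stats::runif(1, 0.3, 1.0)
    mu <- stats::runif(1, 0.5, 2)
    atom_site("X", center + stats::runif(3, -0.8, 0.8),
              params = params_from_alpha(a1, w, mu), pos_unit = "bohr")
  }
  fragA <- list(rand_site(c(0, 0, 0)), rand_site(c(2.5, 0, 0)))
  fragB <- list(rand_site(c(0, 0, 9)), rand_site(c(2.5, 0, 9)))
  cp <- c(stats::runif(1, -2, 4), stats::runif(1, 6, 10),
          stats::runif(1, 3, 6))
  charges <- data.frame(x = cp[1], y = cp[2], z = cp[3],
                        q = sample(c(-2, -1, 1, 2), 1))
  sys <- fid_system(fragA, fragB, charges, charge_unit = "bohr")
  list(system = sys,
       manifest = list(preset = preset, seed = seed,
                       expected_fid_hartree = NULL))
}

#' Pair FID energy on a grid of inter-oscillator distances
#'
#' Evaluates the total pair FID energy through the full tensor machinery
#' for two identical QDOs at a fixed common charge distance, over a grid of
#' separations — the setup used to verify the `R^-7` distance power law.
#'
#' @param R_values Inter-oscillator distances (angstrom).
#' @param R_tilde Common distance from each QDO to the charge (angstrom).
#' @param alpha1,alpha2 Site polarizabilities (a.u.).
#' @param delta External charge (elementary charges).
#' @param omega Oscillator frequency (a.u.).
#' @return Data frame with columns `R_angstrom`, `E_hartree`, `E_meV`.
#' @export
fid_distance_scan <- function(R_values, R_tilde, alpha1 = 1, alpha2 = 1,
                              delta = 1, omega = 1) {
  Rt_b <- convert_length(R_tilde, "angstrom", "bohr")
  E <- vapply(R_values, function(R_ang) {
    R_b <- convert_length(R_ang, "angstrom", "bohr")
    sA <- .symmetric_site(c(0, 0, 0), alpha1, alpha2, omega)
    sB <- .symmetric_site(c(0, 0, R_b), alpha1, alpha2, omega)
    fid_pair_total(sA, sB, delta, Rt_b, Rt_b, c(0, 0, R_b))
  }, numeric(1))
  data.frame(R_angstrom = R_values, E_hartree = E,
             E_meV = convert_energy(E, "hartree", "meV"))
}

#' Two-point complete-basis-set extrapolation
#'
#' Cubic two-point extrapolation of correlation energies computed in
#' basis sets of cardinal numbers `n1` and `n2`:
#' \deqn{E(\infty) = \frac{E(n_1) n_1^3 - E(n_2) n_2^3}{n_1^3 - n_2^3}.}
#' Provided so externally computed reference energies can be extrapolated
#' before comparison with analytic FID values.
#'
#' @param E1,E2 Energies at cardinal numbers `n1`, `n2`.
#' @param n1,n2 Distinct integer cardinal numbers, both >= 2.
#' @return Extrapolated energy.
#' @export
#' @examples
#' cbs_extrapolate(-1.000, 4, -1.010, 5)
cbs_extrapolate <- function(E1, n1, E2, n2) {
  if (n1 == n2) stop("n1 and n2 must differ", call. = FALSE)
  if (n1 < 2 || n2 < 2 || n1 != round(n1) || n2 != round(n2)) {
    stop("cardinal numbers must be integers >= 2", call. = FALSE)
  }
  (E1 * n1^3 - E2 * n2^3) / (n1^3 - n2^3)
}

#' Write a FID report as JSON
#'
#' Machine-readable report: totals, per-pair terms, unit declarations and
#' an input digest.  Deterministic (no timestamps), so identical inputs
#' produce byte-identical files.
#'
#' @param report A `fid_report` from [compute_fid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fid_report <- function(report, path) {
  stopifnot(inherits(report, "fid_report"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(report$terms, tmp, version = 2)
  digest <- unname(tools::md5sum(tmp))
  doc <- list(
    units = report$units,
    frame = report$meta$frame,
    total_fid = report$total,
    total_fid_hartree = report$total_hartree,
    london_total = report$london_total,
    n_charges = report$meta$n_charges,
    include_intra = report$meta$include_intra,
    terms = report$terms,
    input_digest = digest
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration for the command-line interface.  Recognized
#' keys: `geometry` (XYZ path), `fragment_a`, `fragment_b` (1-based
#' inclusive index ranges, e.g. `[1, 5]`), `charges` (charge-table path),
#' `params` (parameter-table path), `hirshfeld` (scalar or per-atom list),
#' `units`, `include_intra`, `output`, `seed`.
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(hirshfeld = 1, units = "meV", include_intra = FALSE,
                   seed = 1, output = NULL, charges = NULL, params = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  for (k in c("fragment_a", "fragment_b")) {
    r <- cfg[[k]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || any(r < 1)) {
      stop("config error: '", k, "' must be a 1-based inclusive range ",
           "[first, last]", call. = FALSE)
    }
  }
  if (length(intersect(seq(cfg$fragment_a[1], cfg$fragment_a[2]),
                       seq(cfg$fragment_b[1], cfg$fragment_b[2])))) {
    stop("config error: fragment ranges overlap", call. = FALSE)
  }
  cfg
}

#' Assemble a FID system from input files
#'
#' @param geometry_path XYZ geometry file (angstrom).
#' @param fragment_a,fragment_b 1-based inclusive atom index ranges
#'   `c(first, last)`.
#' @param charges_path Optional charge-table path.
#' @param params_path Optional parameter-table path (default: shipped
#'   table).
#' @param hirshfeld Hirshfeld ratios, scalar or per-atom.
#' @return A [fid_system()].
#' @export
load_fid_system <- function(geometry_path, fragment_a, fragment_b,
                            charges_path = NULL, params_path = NULL,
                            hirshfeld = 1) {
  geom <- read_xyz(geometry_path)
  n <- nrow(geom)
  ia <- seq(fragment_a[1], fragment_a[2])
  ib <- seq(fragment_b[1], fragment_b[2])
  if (any(c(ia, ib) > n)) {
    stop("fragment range refers to atoms beyond the geometry (", n,
         " atoms)", call. = FALSE)
  }
  tab <- if (is.null(params_path)) read_param_table() else
    read_param_table(params_path)
  sites <- make_sites(geom, tab, hirshfeld = hirshfeld)
  charges <- if (is.null(charges_path)) NULL else read_charges(charges_path)
  if (!is.null(charges) && nrow(charges) == 0L) charges <- NULL
  fid_system(sites[ia], sites[ib], charges, charge_unit = "angstrom")
}
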