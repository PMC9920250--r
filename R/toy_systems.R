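# Analytic toy potentials with exactly known free-energy surfaces,
# packaged molecular fixtures (alanine dipeptide, remdesivir, synthetic
# dimers), and a Metropolis reference sampler.  These are first-class
# study systems: the toy landscapes play the role of the molecular
# Ramachandran surfaces at desk scale, with closed-form answers.

#' 1-D periodic double well
#'
#' `V(s) = barrier cos^2(s) + (asymmetry/2) sin(s)` on `(-pi, pi]`:
#' wells exactly at -pi/2 and +pi/2 separated by barriers near 0 and pi,
#' with a potential-energy difference of exactly `asymmetry` between the
#' wells.  For one CV the exact free energy equals the potential up to a
#' constant; the exact basin free-energy difference is computed by
#' quadrature, not from the well depths.
#'
#' @param barrier Barrier scale in kJ/mol (`> 0`, default 10).
#' @param asymmetry Well asymmetry in kJ/mol (default 5).
#' @return A `toy_potential` with `energy`, `gradient`, `exact_fes(bins)`
#'   and `exact_basin_df(T, halfwidth)`.
#' @export
double_well_1d <- function(barrier = 10, asymmetry = 5) {
  if (barrier <= 0) stop("double_well_1d: barrier must be positive")
  energy <- function(s) barrier * cos(s)^2 + asymmetry / 2 * sin(s)
  gradient <- function(s) -barrier * sin(2 * s) + asymmetry / 2 * cos(s)
  structure(list(
    dimension = 1L, periodic = TRUE,
    energy = energy, gradient = gradient,
    exact_fes = function(bins = 100) {
      s <- grid_centers(bins)
      fes_grid(energy(s), "phi", kind = "free_energy")
    },
    exact_basin_df = function(T = 300, halfwidth = 0.8, n_quad = 10000) {
      # Boltzmann integral over [-pi/2 +/- hw] vs [pi/2 +/- hw]
      z <- function(center) {
        s <- seq(center - halfwidth, center + halfwidth,
                 length.out = n_quad)
        sum(exp(-energy(s) / (KB_KJMOL * T))) * (s[2] - s[1])
      }
      -KB_KJMOL * T * log(z(-pi / 2) / z(pi / 2))
    },
    params = list(barrier = barrier, asymmetry = asymmetry)),
    class = "toy_potential")
}

#' 2-D periodic double-well landscape
#'
#' Ramachandran-like periodic surface
#' `V(phi, psi) = a cos^2(phi) + b cos^2(psi) + c cos(phi - psi)
#'  + (t1/2) sin(phi) + (t2/2) cos(psi)`.
#' The defaults give two dominant wells and saddle regions between them;
#' the mixed sine/cosine tilts leave the surface with no exact discrete
#' symmetry, so its minima are isolated.
#'
#' @param a,b Well depths along each CV (kJ/mol).
#' @param c Coupling amplitude (kJ/mol; 0 makes the surface separable).
#' @param t1,t2 Tilts along each CV (kJ/mol).
#' @return A `toy_potential` with `energy(s)`, `gradient(s)` (s a length-2
#'   vector) and `exact_fes(bins)`.
#' @export
double_well_2d <- function(a = 10, b = 8, c = 2, t1 = 4, t2 = 3) {
  energy <- function(s) {
    a * cos(s[1])^2 + b * cos(s[2])^2 + c * cos(s[1] - s[2]) +
      t1 / 2 * sin(s[1]) + t2 / 2 * cos(s[2])
  }
  gradient <- function(s) {
    c(-a * sin(2 * s[1]) - c * sin(s[1] - s[2]) + t1 / 2 * cos(s[1]),
      -b * sin(2 * s[2]) + c * sin(s[1] - s[2]) - t2 / 2 * sin(s[2]))
  }
  structure(list(
    dimension = 2L, periodic = TRUE,
    energy = energy, gradient = gradient,
    exact_fes = function(bins = 100) {
      s1 <- grid_centers(bins); s2 <- grid_centers(bins)
      v <- outer(s1, s2, function(x, y)
        a * cos(x)^2 + b * cos(y)^2 + c * cos(x - y) +
          t1 / 2 * sin(x) + t2 / 2 * cos(y))
      fes_grid(v, c("phi", "psi"), kind = "free_energy")
    },
    params = list(a = a, b = b, c = c, t1 = t1, t2 = t2)),
    class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("toy_potential: %d-D periodic, params %s\n", x$dimension,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' MD potential contract for a toy landscape
#'
#' Wraps a `toy_potential` so the MD and metadynamics drivers can run
#' CV-space walkers on it (coordinates = CVs, unit masses).
#'
#' @param tp A `toy_potential`.
#' @return A potential contract (`energy`, `forces`).
#' @export
toy_md_potential <- function(tp) {
  make_potential(energy = function(x) tp$energy(x),
                 forces = function(x) -tp$gradient(x))
}

#' Load a packaged molecular fixture
#'
#' `"adp"` is a 22-atom alanine dipeptide conformer, `"remdesivir"` a
#' 77-atom remdesivir conformer (both generated, plain-text XYZ, with
#' documented phi/psi dihedral quadruples); `"dimers"` supplies the
#' two- and three-atom synthetic-element systems used with the synthetic
#' Slater-Koster tables.
#'
#' @param name `"adp"`, `"remdesivir"` or `"dimers"`.
#' @return For molecules: list with `name`, `symbols`, `coords`,
#'   `atom_count`, `cv_indices` (list of two quadruples).  For
#'   `"dimers"`: list of `atomic_system` objects.
#' @export
load_fixture <- function(name = c("adp", "remdesivir", "dimers")) {
  name <- match.arg(name)
  if (name == "dimers") {
    d <- 2.5 * BOHR_ANGSTROM
    return(list(
      name = "dimers",
      xx = atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(0, 0, d))),
      xy = atomic_system(c("X", "Y"), rbind(c(0, 0, 0), c(0, 0, d))),
      zz = atomic_system(c("Z", "Z"), rbind(c(0, 0, 0), c(0, 0, 1.4))),
      # bent closed-shell triatomic: 6 valence electrons, finite
      # HOMO-LUMO gap at zero smearing
      zxx = atomic_system(c("Z", "X", "X"),
                          rbind(c(0, 0, 0), c(0, 0, 1.1),
                                c(1.0, 0, -0.5)))))
  }
  path <- system.file("extdata", paste0(name, ".xyz"), package = "qmetad")
  if (path == "") path <- file.path("inst", "extdata", paste0(name, ".xyz"))
  xyz <- read_xyz(path)
  cv_indices <- if (name == "adp") {
    # backbone: CH3-C(=O)-N-CA(-CH3)-C(=O)-N-CH3
    list(phi = c(2, 4, 5, 7), psi = c(4, 5, 7, 9))
  } else {
    # phosphoramidate scaffold torsions: about P-N and P-O(ester)
    list(phi = c(10, 12, 13, 15), psi = c(12, 13, 15, 16))
  }
  list(name = name, symbols = xyz$symbols, coords = xyz$coords,
       atom_count = length(xyz$symbols), cv_indices = cv_indices)
}

#' Metropolis reference sampler on a toy potential
#'
#' Independent Boltzmann-distribution oracle: random-walk Metropolis with
#' periodically wrapped Gaussian proposals.
#'
#' @param tp A `toy_potential`.
#' @param T Temperature in Kelvin.
#' @param n Number of samples.
#' @param seed Seed.
#' @param step Proposal standard deviation in radians (default 0.5).
#' @param burn Burn-in samples discarded (default 1000).
#' @return n x dimension matrix of CV samples in (-pi, pi].
#' @export
reference_boltzmann_sample <- function(tp, T, n, seed = 1, step = 0.5,
                                       burn = 1000) {
  if (n <= 0) stop("reference_boltzmann_sample: n must be positive")
  kT <- KB_KJMOL * T
  d <- tp$dimension
  with_seed(seed, {
    total <- n + burn
    prop <- matrix(stats::rnorm(total * d, sd = step), total, d)
    us <- stats::runif(total)
    x <- rep(0, d)
    ex <- tp$energy(x)
    out <- matrix(0, n, d)
    for (i in seq_len(total)) {
      y <- wrap_angle(x + prop[i, ])
      ey <- tp$energy(y)
      if (us[i] < exp((ex - ey) / kT)) { x <- y; ex <- ey }
      if (i > burn) out[i - burn, ] <- x
    }
    out
  })
}
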