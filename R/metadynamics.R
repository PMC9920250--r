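# Well-tempered metadynamics: collective variables (torsions and
# CV-space identities), Gaussian hill deposition with well-tempered
# damping, bias potential/forces, the sampling driver, and
# PLUMED-dialect HILLS / COLVAR text files.
#
# Bias model: V_B(s, t) = sum over hills deposited before t of
#   h exp(-sum_i d_i^2 / (2 sigma_i^2)),
# d_i the minimum-image periodic displacement of CV i, and deposited
# heights h = W0 exp(-V_B / (kB T gamma)) ("paper" convention) or
# W0 exp(-V_B / (kB T (gamma - 1))) ("standard" convention).

#' Torsion (dihedral) collective variable
#'
#' @param indices Four distinct 1-based atom indices.
#' @param name CV name used in HILLS/COLVAR headers.
#' @return A `cv` object with `value(coords)` and `grad(coords)` in the
#'   IUPAC sign convention (cis = 0, trans = pi), periodic on (-pi, pi].
#' @export
cv_dihedral <- function(indices, name = "phi") {
  indices <- as.integer(indices)
  if (length(indices) != 4 || anyDuplicated(indices))
    stop("cv_dihedral: need 4 distinct atom indices")
  structure(list(
    name = name, periodic = TRUE, indices = indices, kind = "dihedral",
    value = function(coords) dihedral_value(coords, indices),
    grad = function(coords) dihedral_gradient(coords, indices)),
    class = "cv")
}

#' Identity collective variable (CV-space walkers)
#'
#' For toy potentials whose MD coordinates already are the collective
#' variables: CV k is the (periodically wrapped) k-th coordinate.
#'
#' @param k Component index.
#' @param name CV name.
#' @return A `cv` object.
#' @export
cv_identity <- function(k = 1, name = paste0("cv", k)) {
  structure(list(
    name = name, periodic = TRUE, indices = k, kind = "identity",
    value = function(coords) wrap_angle(coords[k]),
    grad = function(coords) { g <- coords * 0; g[k] <- 1; g }),
    class = "cv")
}

#' Dihedral angle of four atoms
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param indices Four 1-based atom indices.
#' @return Angle in radians on (-pi, pi], IUPAC convention.
#' @export
dihedral_value <- function(coords, indices) {
  p <- coords[indices, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  check_collinear(n1, n2, b1, b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_collinear <- function(n1, n2, b1, b2, b3) {
  scale2 <- max(sum(b1^2), sum(b2^2), sum(b3^2))
  if (sum(n1^2) < 1e-16 * scale2^2 || sum(n2^2) < 1e-16 * scale2^2)
    stop("dihedral: three consecutive atoms are (nearly) collinear")
  invisible(TRUE)
}

#' Analytic gradient of a dihedral angle
#'
#' @param coords n x 3 coordinates.
#' @param indices Four atom indices.
#' @return n x 3 gradient matrix (1/Angstrom); rows of atoms not in the
#'   quadruple are zero, and the four gradient rows sum to the zero
#'   vector (translational invariance).
#' @export
dihedral_gradient <- function(coords, indices) {
  p <- coords[indices, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  check_collinear(n1, n2, b1, b2, b3)
  nb2 <- sqrt(sum(b2^2))
  g1 <- -nb2 / sum(n1^2) * n1
  g4 <- nb2 / sum(n2^2) * n2
  f12 <- sum(b1 * b2) / sum(b2^2)
  f32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + f12) * g1 + f32 * g4
  g3 <- f12 * g1 - (1 + f32) * g4
  G <- matrix(0, nrow(coords), 3)
  G[indices[1], ] <- g1; G[indices[2], ] <- g2
  G[indices[3], ] <- g3; G[indices[4], ] <- g4
  G
}

#' Create an empty bias state
#'
#' @param cvs List of `cv` objects.
#' @param W0 Initial hill height in kJ/mol (default 1.2).
#' @param sigma Per-CV hill widths in radians (default 0.35, recycled).
#' @param pace Steps between deposits (default 500).
#' @param biasf Bias factor gamma (`> 1`, default 10).
#' @param T Temperature in Kelvin (default 300).
#' @param wt_convention `"paper"` (damping exponent divided by gamma) or
#'   `"standard"` (divided by gamma - 1).
#' @return A `bias_state` with an empty hill list.
#' @export
bias_state <- function(cvs, W0 = 1.2, sigma = 0.35, pace = 500L,
                       biasf = 10, T = 300,
                       wt_convention = c("paper", "standard")) {
  wt_convention <- match.arg(wt_convention)
  if (biasf <= 1) stop("bias_state: bias factor must be > 1")
  if (any(sigma <= 0)) stop("bias_state: sigma must be positive")
  if (W0 < 0) stop("bias_state: W0 must be >= 0")
  k <- length(cvs)
  structure(list(cvs = cvs, W0 = W0,
                 sigma = rep(sigma, length.out = k),
                 pace = as.integer(pace), biasf = biasf, T = T,
                 wt_convention = wt_convention,
                 hill_time = numeric(0),
                 hill_center = matrix(0, 0, k),
                 hill_height = numeric(0)),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("bias_state: %d hills over %d CV(s) [%s], W0 %.3g kJ/mol, sigma %s rad, gamma %.3g, %s convention\n",
              length(x$hill_height), length(x$cvs),
              paste(vapply(x$cvs, `[[`, "", "name"), collapse = ","),
              x$W0, paste(signif(x$sigma, 3), collapse = ","), x$biasf,
              x$wt_convention))
  invisible(x)
}

#' Metadynamics bias potential at a CV point
#'
#' @param bias A `bias_state`.
#' @param s CV point (radians).
#' @param t Only hills with deposition time `< t` contribute
#'   (default all).
#' @return Bias energy in kJ/mol.
#' @export
bias_potential <- function(bias, s, t = Inf) {
  sel <- bias$hill_time < t
  if (!any(sel)) return(0)
  d <- wrap_angle(sweep(bias$hill_center[sel, , drop = FALSE], 2, s, "-"))
  sum(bias$hill_height[sel] *
        exp(-colSums(t(d^2) / (2 * bias$sigma^2))))
}

# dV_B/ds at a CV point (kJ/mol per radian, one component per CV)
bias_cv_gradient <- function(bias, s, t = Inf) {
  sel <- bias$hill_time < t
  k <- length(bias$sigma)
  if (!any(sel)) return(numeric(k))
  d <- wrap_angle(-sweep(bias$hill_center[sel, , drop = FALSE], 2, s, "-"))
  g <- bias$hill_height[sel] * exp(-colSums(t(d^2) / (2 * bias$sigma^2)))
  -drop(crossprod(d, g)) / bias$sigma^2
}

#' Deposit one well-tempered hill
#'
#' Height `W0 exp(-beta V_B(s)/gamma)` under the `"paper"` convention or
#' `W0 exp(-beta V_B(s)/(gamma - 1))` under `"standard"`.
#'
#' @param bias A `bias_state`.
#' @param s_now Current CV values.
#' @param t Deposition time in fs.
#' @return Updated `bias_state` with the hill appended; the new hill's
#'   height is in `attr(, "last_height")`.
#' @export
deposit_hill <- function(bias, s_now, t) {
  vb <- bias_potential(bias, s_now, t = Inf)
  denom <- if (bias$wt_convention == "paper") bias$biasf else bias$biasf - 1
  h <- bias$W0 * exp(-vb / (KB_KJMOL * bias$T * denom))
  bias$hill_time <- c(bias$hill_time, t)
  bias$hill_center <- rbind(bias$hill_center, s_now)
  bias$hill_height <- c(bias$hill_height, h)
  attr(bias, "last_height") <- h
  bias
}

#' Bias forces on the atoms
#'
#' Chain rule through the CVs:
#' `F_i = -sum_cv dV_B/ds_cv * ds_cv/dr_i`.
#'
#' @param bias A `bias_state`.
#' @param coords MD coordinates (matrix or vector, matching the CVs).
#' @param t Hill-time cutoff (default all hills).
#' @return Force array with the shape of `coords`, kJ/mol/Angstrom
#'   (kJ/mol/rad for identity CVs).
#' @export
bias_forces <- function(bias, coords, t = Inf) {
  s <- vapply(bias$cvs, function(cv) cv$value(coords), 0)
  dv <- bias_cv_gradient(bias, s, t)
  F <- coords * 0
  for (j in seq_along(bias$cvs))
    F <- F - dv[j] * bias$cvs[[j]]$grad(coords)
  F
}

#' Run well-tempered metadynamics
#'
#' Thermostatted (Nose-Hoover) MD in which the total force is the
#' potential force plus the metadynamics bias force; one hill is
#' deposited at the instantaneous CV values every `pace` completed steps,
#' and a COLVAR record (time, CVs, potential energy) is taken every
#' `stride` steps.  Bit-reproducible for a fixed seed.
#'
#' @param potential Potential contract (kJ/mol, kJ/mol/Angstrom).
#' @param cvs List of `cv` objects.
#' @param coords0 Initial coordinates.
#' @param masses Masses in amu.
#' @param steps Number of MD steps.
#' @param dt Time step in fs (default 1.0).
#' @param T Temperature in Kelvin (default 300).
#' @param tau Thermostat coupling time in fs (default 50).
#' @param seed Velocity seed.
#' @param W0,sigma,pace,biasf,wt_convention Hill parameters, see
#'   [bias_state()].
#' @param stride COLVAR sampling stride (default 10).
#' @param equil_steps Unbiased NVT equilibration steps run first
#'   (default 0).
#' @return List with `colvar` (data.frame time/CVs/ene), `bias` (the
#'   final `bias_state`), and `state` (final `md_state`).
#' @export
run_wtmetad <- function(potential, cvs, coords0, masses, steps,
                        dt = 1.0, T = 300, tau = 50, seed = 1,
                        W0 = 1.2, sigma = 0.35, pace = 500L, biasf = 10,
                        wt_convention = c("paper", "standard"),
                        stride = 10L, equil_steps = 0L) {
  wt_convention <- match.arg(wt_convention)
  bias <- bias_state(cvs, W0 = W0, sigma = sigma, pace = pace,
                     biasf = biasf, T = T, wt_convention = wt_convention)
  all_identity <- !is.matrix(coords0) &&
    all(vapply(cvs, function(cv) identical(cv$kind, "identity"), TRUE))
  if (all_identity) {
    return(run_wtmetad_cv(potential, cvs, coords0, masses, steps, dt, T,
                          tau, seed, bias, stride, equil_steps))
  }
  shape <- if (is.matrix(coords0)) "matrix" else "vector"
  v0 <- initialize_velocities(masses, T, seed, shape)
  state <- md_state(coords0, v0, masses, potential)
  biased <- list(
    energy = function(x) potential$energy(x) + local_bias_energy(x),
    forces = function(x) potential$forces(x) + local_bias_forces(x))
  # closures see the current bias through this environment
  local_bias_energy <- function(x) {
    s <- vapply(bias$cvs, function(cv) cv$value(x), 0)
    bias_potential(bias, s)
  }
  local_bias_forces <- function(x) bias_forces(bias, x)
  for (k in seq_len(equil_steps))
    state <- nose_hoover_step(state, potential, dt, T, tau)
  state$time <- 0
  n_samp <- if (steps == 0) 0 else steps %/% stride
  k_cv <- length(cvs)
  colvar <- matrix(NA_real_, n_samp, 2 + k_cv)
  isamp <- 0
  for (k in seq_len(steps)) {
    state <- nose_hoover_step(state, biased, dt, T, tau)
    if (k %% bias$pace == 0) {
      s_now <- vapply(bias$cvs, function(cv) cv$value(state$coords), 0)
      bias <- deposit_hill(bias, s_now, t = state$time)
    }
    if (k %% stride == 0) {
      isamp <- isamp + 1
      s_now <- vapply(bias$cvs, function(cv) cv$value(state$coords), 0)
      colvar[isamp, ] <- c(state$time, s_now, potential$energy(state$coords))
    }
  }
  colvar <- as.data.frame(colvar[seq_len(isamp), , drop = FALSE])
  names(colvar) <- c("time", vapply(cvs, `[[`, "", "name"), "ene")
  list(colvar = colvar, bias = bias, state = state)
}

# Specialized inner loop for CV-space walkers (vector coordinates,
# identity CVs): same Nose-Hoover splitting and bias math as the generic
# path, inlined without the md_state bookkeeping for speed.
run_wtmetad_cv <- function(potential, cvs, coords0, masses, steps, dt, T,
                           tau, seed, bias, stride, equil_steps) {
  d <- length(coords0)
  v <- initialize_velocities(masses, T, seed, "vector")
  x <- as.numeric(coords0)
  m <- rep(masses, length.out = d)
  nf <- d
  kT <- KB_KJMOL * T
  Q <- nf * kT * tau^2
  conv <- AMU_A2_FS2_KJMOL
  mconv <- m * conv
  xi <- 0; eta <- 0
  sig2 <- 2 * bias$sigma^2
  denom_wt <- if (bias$wt_convention == "paper") bias$biasf else bias$biasf - 1
  nmax <- steps %/% bias$pace
  h_center <- matrix(0, nmax, d)
  h_height <- numeric(nmax)
  h_time <- numeric(nmax)
  nh <- 0
  f_pot <- potential$forces(x)
  f_bias <- numeric(d)
  bias_grad <- function(s) {
    if (nh == 0) return(numeric(d))
    dd <- wrap_angle(matrix(s, nh, d, byrow = TRUE) -
                       h_center[seq_len(nh), , drop = FALSE])
    g <- h_height[seq_len(nh)] * exp(-colSums(t(dd^2) / sig2))
    -drop(crossprod(dd, g)) / bias$sigma^2
  }
  bias_pot_at <- function(s) {
    if (nh == 0) return(0)
    dd <- wrap_angle(matrix(s, nh, d, byrow = TRUE) -
                       h_center[seq_len(nh), , drop = FALSE])
    sum(h_height[seq_len(nh)] * exp(-colSums(t(dd^2) / sig2)))
  }
  for (k in seq_len(equil_steps)) {
    # unbiased NH equilibration (same splitting)
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    v <- v * exp(-0.5 * dt * xi); eta <- eta + 0.5 * dt * xi
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    vh <- v + 0.5 * dt * f_pot / mconv
    x <- x + dt * vh
    f_pot <- potential$forces(x)
    v <- vh + 0.5 * dt * f_pot / mconv
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    v <- v * exp(-0.5 * dt * xi); eta <- eta + 0.5 * dt * xi
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
  }
  time <- 0
  n_samp <- if (steps == 0) 0 else steps %/% stride
  colvar <- matrix(NA_real_, n_samp, 2 + d)
  isamp <- 0
  f_tot <- f_pot + f_bias
  for (k in seq_len(steps)) {
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    v <- v * exp(-0.5 * dt * xi); eta <- eta + 0.5 * dt * xi
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    vh <- v + 0.5 * dt * f_tot / mconv
    x <- x + dt * vh
    f_pot <- potential$forces(x)
    f_bias <- -bias_grad(wrap_angle(x))
    f_tot <- f_pot + f_bias
    v <- vh + 0.5 * dt * f_tot / mconv
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    v <- v * exp(-0.5 * dt * xi); eta <- eta + 0.5 * dt * xi
    ke <- 0.5 * sum(mconv * v^2)
    xi <- xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    time <- time + dt
    if (k %% bias$pace == 0) {
      s_now <- wrap_angle(x)
      vb <- bias_pot_at(s_now)
      nh <- nh + 1
      h_center[nh, ] <- s_now
      h_height[nh] <- bias$W0 * exp(-vb / (kT * denom_wt))
      h_time[nh] <- time
      # the new hill enters the dynamics at the next force evaluation,
      # matching the generic driver's update order
    }
    if (k %% stride == 0) {
      isamp <- isamp + 1
      colvar[isamp, ] <- c(time, wrap_angle(x), potential$energy(x))
    }
  }
  bias$hill_time <- h_time[seq_len(nh)]
  bias$hill_center <- h_center[seq_len(nh), , drop = FALSE]
  bias$hill_height <- h_height[seq_len(nh)]
  colvar <- as.data.frame(colvar[seq_len(isamp), , drop = FALSE])
  names(colvar) <- c("time", vapply(cvs, `[[`, "", "name"), "ene")
  state <- md_state(x, v, masses, potential, time = time)
  state$thermostat_xi <- xi
  state$thermostat_eta <- eta
  list(colvar = colvar, bias = bias, state = state)
}

# ---- HILLS / COLVAR dialect --------------------------------------------

#' Write a HILLS file
#'
#' PLUMED dialect: header
#' `#! FIELDS time <cv...> <sigma_cv...> height biasf`, one row per hill.
#' Time is converted to ps in the file for community-tool compatibility.
#'
#' @param bias A `bias_state`.
#' @param path Output path.
#' @param extra_header Optional comment lines written after the FIELDS
#'   line (each prefixed `#!`).
#' @export
write_hills <- function(bias, path, extra_header = character(0)) {
  nm <- vapply(bias$cvs, `[[`, "", "name")
  hdr <- paste("#! FIELDS time", paste(nm, collapse = " "),
               paste(paste0("sigma_", nm), collapse = " "), "height biasf")
  n <- length(bias$hill_height)
  rows <- character(n)
  for (i in seq_len(n)) {
    rows[i] <- paste(sprintf("%.15g",
                             c(bias$hill_time[i] / 1000,
                               bias$hill_center[i, ],
                               bias$sigma, bias$hill_height[i],
                               bias$biasf)), collapse = " ")
  }
  writeLines(c(hdr, if (length(extra_header)) paste("#!", extra_header),
               rows), path)
  invisible(path)
}

#' Read a HILLS file
#'
#' Accepts files written by [write_hills()] or by the reference community
#' tools for torsional CVs (time in ps, converted to fs on read).
#'
#' @param path HILLS file path.
#' @param T Temperature in Kelvin attached to the returned state
#'   (default 300).
#' @param wt_convention Convention tag attached to the returned state.
#' @return A `bias_state` whose CVs are identity placeholders named from
#'   the header.
#' @export
read_hills <- function(path, T = 300, wt_convention = "paper") {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#!\\s*FIELDS", lines[1]))
    stop("read_hills: missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS\\s*", "", lines[1])),
                     "\\s+")[[1]]
  is_sigma <- grepl("^sigma_", fields)
  cv_names <- setdiff(fields[!is_sigma], c("time", "height", "biasf"))
  k <- length(cv_names)
  if (k == 0 || sum(is_sigma) != k)
    stop("read_hills: inconsistent FIELDS header")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  cvs <- lapply(seq_len(k), function(j) cv_identity(j, cv_names[j]))
  if (!length(body)) {
    return(bias_state(cvs, sigma = 0.35, T = T,
                      wt_convention = wt_convention))
  }
  vals <- lapply(body, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  ncols <- length(fields)
  bad <- which(vapply(vals, function(v) length(v) != ncols || anyNA(v), TRUE))
  if (length(bad))
    stop("read_hills: row ", bad[1], " has inconsistent column count")
  m <- do.call(rbind, vals)
  colnames(m) <- fields
  if (length(unique(m[, "biasf"])) > 1)
    stop("read_hills: mixed bias factors in one file are not supported")
  biasf <- unname(m[1, "biasf"])
  bias <- bias_state(cvs, W0 = max(m[, "height"]),
                     sigma = as.numeric(m[1, paste0("sigma_", cv_names)]),
                     biasf = biasf, T = T, wt_convention = wt_convention)
  bias$hill_time <- m[, "time"] * 1000   # ps -> fs
  bias$hill_center <- m[, cv_names, drop = FALSE]
  dimnames(bias$hill_center) <- NULL
  bias$hill_height <- m[, "height"]
  bias
}

#' Write a COLVAR file
#'
#' Header `#! FIELDS time <cv...> ene`; time in ps, energy in kJ/mol.
#'
#' @param colvar Data frame from [run_wtmetad()] (time fs, CV columns,
#'   `ene`).
#' @param path Output path.
#' @param extra_header Optional `#!` comment lines.
#' @export
write_colvar <- function(colvar, path, extra_header = character(0)) {
  nm <- setdiff(names(colvar), c("time", "ene"))
  hdr <- paste("#! FIELDS time", paste(nm, collapse = " "), "ene")
  m <- as.matrix(colvar[, c("time", nm, "ene")])
  m[, 1] <- m[, 1] / 1000
  rows <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, if (length(extra_header)) paste("#!", extra_header),
               rows), path)
  invisible(path)
}

#' Read a COLVAR file
#'
#' @param path COLVAR file path.
#' @return Data frame with `time` (fs), CV columns and `ene` (kJ/mol).
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#!\\s*FIELDS", lines[1]))
    stop("read_colvar: missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS\\s*", "", lines[1])),
                     "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  df <- as.data.frame(m)
  names(df) <- fields
  df$time <- df$time * 1000   # ps -> fs
  df
}
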