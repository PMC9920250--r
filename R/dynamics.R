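# NVT molecular dynamics over any potential implementing the
# energy+forces contract: a `potential` is a list with functions
# `energy(coords)` (kJ/mol) and `forces(coords)` (kJ/mol/Angstrom, same
# shape as coords).  Coordinates may be an n x 3 matrix (molecular
# systems, masses per atom) or a plain numeric vector (collective
# variable walkers, masses per component).  Units: Angstrom, fs, amu,
# kJ/mol, Kelvin.

make_potential <- function(energy, forces) {
  list(energy = energy, forces = forces)
}

# per-component mass expansion matching the coordinate shape
expand_masses <- function(coords, masses) {
  if (is.matrix(coords)) {
    if (length(masses) == 1) masses <- rep(masses, nrow(coords))
    matrix(rep(masses, ncol(coords)), nrow(coords), ncol(coords))
  } else {
    if (length(masses) == 1) masses <- rep(masses, length(coords))
    masses
  }
}

kinetic_energy <- function(velocities, m_exp) {
  0.5 * sum(m_exp * velocities^2) * AMU_A2_FS2_KJMOL
}

instantaneous_temperature <- function(velocities, m_exp, n_dof) {
  2 * kinetic_energy(velocities, m_exp) / (n_dof * KB_KJMOL)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian draw at temperature `T`, center-of-mass momentum removed (for
#' matrix-shaped coordinates), then rescaled so the instantaneous
#' temperature equals `T` exactly.
#'
#' @param masses Masses in amu (per atom for matrix coordinates, per
#'   component for vector coordinates).
#' @param T Target temperature in Kelvin (`>= 0`).
#' @param seed Integer seed.
#' @param shape `"matrix"` (n x 3) or `"vector"`.
#' @param n_dof Number of degrees of freedom used for the rescale
#'   (default: all components minus 3 for matrix shape with > 1 atom,
#'   all components otherwise).
#' @return Velocities in Angstrom/fs with the requested shape.
#' @export
initialize_velocities <- function(masses, T, seed = 1,
                                  shape = c("matrix", "vector"),
                                  n_dof = NULL) {
  shape <- match.arg(shape)
  if (T < 0) stop("initialize_velocities: T must be >= 0")
  n <- length(masses)
  if (shape == "matrix") {
    v <- matrix(0, n, 3)
    if (is.null(n_dof)) n_dof <- if (n > 1) 3 * n - 3 else 3
  } else {
    v <- numeric(n)
    if (is.null(n_dof)) n_dof <- n
  }
  if (T == 0) return(v)
  sigma <- sqrt(KB_KJMOL * T / (masses * AMU_A2_FS2_KJMOL))  # A/fs
  raw <- with_seed(seed, stats::rnorm(length(v)))
  if (shape == "matrix") {
    v[] <- raw * sigma   # column recycling: sigma per atom
    ptot <- colSums(v * masses)
    v <- v - matrix(ptot / sum(masses), n, 3, byrow = TRUE)
  } else {
    v <- raw * sigma
  }
  m_exp <- expand_masses(v, masses)
  t_inst <- instantaneous_temperature(v, m_exp, n_dof)
  if (t_inst > 0) v <- v * sqrt(T / t_inst)
  v
}

#' Construct an MD state
#'
#' @param coords Coordinates (Angstrom), matrix or vector.
#' @param velocities Velocities (Angstrom/fs), same shape.
#' @param masses Masses (amu).
#' @param potential Potential contract (list with `energy`, `forces`).
#' @param time Current time in fs.
#' @param n_dof Degrees of freedom for temperature bookkeeping.
#' @return An `md_state` list.
#' @export
md_state <- function(coords, velocities, masses, potential, time = 0,
                     n_dof = NULL) {
  m_exp <- expand_masses(coords, masses)
  if (any(masses <= 0)) stop("md_state: masses must be positive")
  if (is.null(n_dof))
    n_dof <- if (is.matrix(coords) && nrow(coords) > 1)
      length(coords) - 3 else length(coords)
  structure(list(coords = coords, velocities = velocities, masses = masses,
                 m_exp = m_exp, time = time, n_dof = n_dof,
                 thermostat_xi = 0, thermostat_eta = 0,
                 forces = potential$forces(coords),
                 potential_energy = potential$energy(coords),
                 kinetic_energy = kinetic_energy(velocities, m_exp)),
            class = "md_state")
}

#' One velocity-Verlet step
#'
#' Standard symplectic kick-drift-kick update (no thermostat).
#'
#' @param state An `md_state`.
#' @param potential Potential contract.
#' @param dt Time step in fs (`> 0`).
#' @return Updated `md_state`.
#' @export
velocity_verlet_step <- function(state, potential, dt) {
  if (dt <= 0) stop("velocity_verlet_step: dt must be positive")
  if (any(!is.finite(state$forces)))
    stop("velocity_verlet_step: non-finite forces")
  acc <- state$forces / (state$m_exp * AMU_A2_FS2_KJMOL)  # A/fs^2
  v_half <- state$velocities + 0.5 * dt * acc
  x_new <- state$coords + dt * v_half
  f_new <- potential$forces(x_new)
  acc_new <- f_new / (state$m_exp * AMU_A2_FS2_KJMOL)
  v_new <- v_half + 0.5 * dt * acc_new
  state$coords <- x_new
  state$velocities <- v_new
  state$forces <- f_new
  state$time <- state$time + dt
  state$potential_energy <- potential$energy(x_new)
  state$kinetic_energy <- kinetic_energy(v_new, state$m_exp)
  state
}

#' One Nose-Hoover NVT step
#'
#' Single Nose-Hoover thermostat with coupling mass
#' `Q = N_f k_B T tau^2`, in a velocity-Verlet-compatible splitting:
#' half thermostat, half kick, drift, force, half kick, half thermostat.
#' The extended-system conserved quantity is available through
#' [nose_hoover_conserved()].
#'
#' @param state An `md_state`.
#' @param potential Potential contract.
#' @param dt Time step in fs.
#' @param T_target Target temperature in Kelvin (default 300).
#' @param tau Thermostat coupling time in fs (default 50).
#' @return Updated `md_state`.
#' @export
nose_hoover_step <- function(state, potential, dt, T_target = 300,
                             tau = 50) {
  if (tau <= 0) stop("nose_hoover_step: tau must be positive")
  if (any(!is.finite(unlist(state[c("coords", "velocities")]))))
    stop("nose_hoover_step: non-finite state")
  nf <- state$n_dof
  kT <- KB_KJMOL * T_target
  Q <- nf * kT * tau^2             # kJ/mol * fs^2
  half_thermostat <- function(st) {
    ke <- kinetic_energy(st$velocities, st$m_exp)
    st$thermostat_xi <- st$thermostat_xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    scale <- exp(-0.5 * dt * st$thermostat_xi)
    st$velocities <- st$velocities * scale
    st$thermostat_eta <- st$thermostat_eta + 0.5 * dt * st$thermostat_xi
    ke <- kinetic_energy(st$velocities, st$m_exp)
    st$thermostat_xi <- st$thermostat_xi + 0.25 * dt * (2 * ke - nf * kT) / Q
    st
  }
  state <- half_thermostat(state)
  acc <- state$forces / (state$m_exp * AMU_A2_FS2_KJMOL)
  v_half <- state$velocities + 0.5 * dt * acc
  x_new <- state$coords + dt * v_half
  f_new <- potential$forces(x_new)
  acc_new <- f_new / (state$m_exp * AMU_A2_FS2_KJMOL)
  state$velocities <- v_half + 0.5 * dt * acc_new
  state$coords <- x_new
  state$forces <- f_new
  state <- half_thermostat(state)
  state$time <- state$time + dt
  state$potential_energy <- potential$energy(x_new)
  state$kinetic_energy <- kinetic_energy(state$velocities, state$m_exp)
  state
}

#' Extended-system conserved quantity of the Nose-Hoover dynamics
#'
#' `E_pot + E_kin + Q xi^2 / 2 + N_f k_B T eta`, constant along the
#' thermostatted trajectory up to integration error.
#'
#' @param state An `md_state`.
#' @param T_target,tau Thermostat parameters used in the run.
#' @return Conserved energy in kJ/mol.
#' @export
nose_hoover_conserved <- function(state, T_target = 300, tau = 50) {
  nf <- state$n_dof
  kT <- KB_KJMOL * T_target
  Q <- nf * kT * tau^2
  state$potential_energy + state$kinetic_energy +
    0.5 * Q * state$thermostat_xi^2 + nf * kT * state$thermostat_eta
}

#' Run NVT (or NVE) molecular dynamics
#'
#' Thermostatted trajectory with observer sampling every `stride` steps.
#' Deterministic for a fixed seed.
#'
#' @param potential Potential contract.
#' @param coords0 Initial coordinates.
#' @param masses Masses in amu.
#' @param steps Number of MD steps (`>= 0`).
#' @param dt Time step in fs (default 1.0).
#' @param T Temperature in Kelvin (default 300).
#' @param seed Seed for the initial velocity draw.
#' @param tau Nose-Hoover coupling time in fs (default 50).
#' @param thermostat `"nose-hoover"` or `"none"` (NVE).
#' @param stride Observer sampling stride in steps (default 10).
#' @param observer Optional `function(state)` returning a numeric vector
#'   recorded at every sampled step.
#' @param velocities0 Optional explicit initial velocities.
#' @return List with `record` (data.frame: time, pe, ke, T_inst,
#'   conserved, observer columns) and `state` (final `md_state`).
#' @export
run_nvt <- function(potential, coords0, masses, steps, dt = 1.0, T = 300,
                    seed = 1, tau = 50, thermostat = c("nose-hoover", "none"),
                    stride = 10, observer = NULL, velocities0 = NULL) {
  thermostat <- match.arg(thermostat)
  if (steps < 0) stop("run_nvt: steps must be >= 0")
  shape <- if (is.matrix(coords0)) "matrix" else "vector"
  if (is.null(velocities0))
    velocities0 <- initialize_velocities(masses, T, seed, shape)
  state <- md_state(coords0, velocities0, masses, potential)
  n_samp <- if (steps == 0) 0 else steps %/% stride
  obs0 <- if (is.null(observer)) NULL else observer(state)
  ncol_obs <- length(obs0)
  rec <- matrix(NA_real_, n_samp, 5 + ncol_obs)
  isamp <- 0
  for (k in seq_len(steps)) {
    state <- if (thermostat == "nose-hoover")
      nose_hoover_step(state, potential, dt, T, tau)
    else velocity_verlet_step(state, potential, dt)
    if (k %% stride == 0) {
      isamp <- isamp + 1
      cons <- if (thermostat == "nose-hoover")
        nose_hoover_conserved(state, T, tau)
      else state$potential_energy + state$kinetic_energy
      row <- c(state$time, state$potential_energy, state$kinetic_energy,
               instantaneous_temperature(state$velocities, state$m_exp,
                                         state$n_dof), cons)
      if (!is.null(observer)) row <- c(row, observer(state))
      rec[isamp, ] <- row
    }
  }
  rec <- as.data.frame(rec[seq_len(isamp), , drop = FALSE])
  names(rec) <- c("time", "pe", "ke", "T_inst", "conserved",
                  if (ncol_obs) paste0("obs", seq_len(ncol_obs)))
  list(record = rec, state = state)
}
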