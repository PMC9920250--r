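# DFTB3 engine: assembly of the non-self-consistent Hamiltonian H0 and
# overlap S from Slater-Koster tables, the second/third-order charge
# kernels gamma and Gamma, the self-consistent-charge (SCC) loop, total
# energy components, a pairwise damped-C6 dispersion hook, finite
# difference forces, and geometry relaxation.
#
# Energy model (all in Hartree):
#   E = E_BS + E_gamma + E_Gamma + E_rep (+ E_disp)
#   E_BS    = sum_i f_i <psi_i|H0|psi_i>
#   E_gamma = 1/2 sum_AB dq_A dq_B gamma_AB
#   E_Gamma = 1/3 sum_AB dq_A^2 dq_B Gamma_AB
#   E_rep   = 1/2 sum_{A != B} V_rep(r_AB)
# with dq_A = q_A - q0_A the Mulliken net charge in the electron-count
# convention (positive dq = electron excess).

sk_pair_key <- function(a, b) paste(a, b, sep = "-")

get_sk_table <- function(tables, a, b) {
  t <- tables[[sk_pair_key(a, b)]]
  if (is.null(t)) stop("missing SK table for pair ", a, "-", b)
  t
}

#' Assemble H0 and S matrices from Slater-Koster tables
#'
#' Diagonal elements are the free-atom on-site energies (unit diagonal for
#' S); same-atom off-diagonal blocks are zero; inter-atomic blocks come
#' from Slater-Koster rotation of the tabulated (ss sigma, sp sigma,
#' pp sigma, pp pi) channels using direction cosines.
#'
#' @param system An `atomic_system`.
#' @param tables Named list of `sk_table` objects covering all ordered
#'   element pairs of the system.
#' @return List with symmetric matrices `H0` and `S` (Hartree /
#'   dimensionless) over the atomic-orbital basis, plus `basis_atom`
#'   mapping each orbital to its atom index.
#' @export
build_h0_s <- function(system, tables) {
  n_at <- length(system$symbols)
  norb_at <- n_orbitals(system)
  nbas <- sum(norb_at)
  off <- cumsum(c(0, norb_at))[seq_len(n_at)]
  basis_atom <- rep(seq_len(n_at), norb_at)
  H0 <- matrix(0, nbas, nbas)
  S <- diag(nbas)
  for (A in seq_len(n_at)) {
    key <- sk_pair_key(system$symbols[A], system$symbols[A])
    tabAA <- tables[[key]]
    if (is.null(tabAA)) stop("missing SK table for pair ",
                             system$symbols[A], "-", system$symbols[A])
    o <- tabAA$onsite
    idx <- off[A] + seq_len(norb_at[A])
    H0[idx[1], idx[1]] <- o$eps_s
    if (norb_at[A] == 4) for (k in 2:4) H0[idx[k], idx[k]] <- o$eps_p
  }
  if (n_at > 1) {
    for (A in seq_len(n_at - 1)) for (B in seq((A + 1), n_at)) {
      rvec <- (system$coords[B, ] - system$coords[A, ]) / BOHR_ANGSTROM
      r <- sqrt(sum(rvec^2))
      tabAB <- get_sk_table(tables, system$symbols[A], system$symbols[B])
      tabBA <- get_sk_table(tables, system$symbols[B], system$symbols[A])
      for (w in c("H", "S")) {
        blk <- sk_pair_block(tabAB, tabBA, r, rvec / r,
                             norb_at[A], norb_at[B], w)
        ia <- off[A] + seq_len(norb_at[A])
        ib <- off[B] + seq_len(norb_at[B])
        if (w == "H") {
          H0[ia, ib] <- blk; H0[ib, ia] <- t(blk)
        } else {
          S[ia, ib] <- blk; S[ib, ia] <- t(blk)
        }
      }
    }
  }
  list(H0 = H0, S = S, basis_atom = basis_atom)
}

# Slater-Koster rotation of one inter-atomic block.  Orbital order per
# atom: s (, px, py, pz).  l is the unit vector from atom A to atom B.
# sp_sigma(A,B) tabulates <s_A|..|p_B>; <p_A|..|s_B> uses the (B,A) table
# with a sign flip from the direction reversal.
sk_pair_block <- function(tabAB, tabBA, r, l, na, nb, which) {
  ss <- sk_interpolate(tabAB, r, "ss_sigma", which)
  blk <- matrix(0, na, nb)
  blk[1, 1] <- ss
  if (nb == 4) {
    sp <- sk_interpolate(tabAB, r, "sp_sigma", which)
    blk[1, 2:4] <- l * sp
  }
  if (na == 4) {
    spBA <- sk_interpolate(tabBA, r, "sp_sigma", which)
    blk[2:4, 1] <- -l * spBA
  }
  if (na == 4 && nb == 4) {
    pps <- sk_interpolate(tabAB, r, "pp_sigma", which)
    ppp <- sk_interpolate(tabAB, r, "pp_pi", which)
    ll <- outer(l, l)
    blk[2:4, 2:4] <- ll * pps + (diag(3) - ll) * ppp
  }
  blk
}

#' Second-order charge-interaction kernel gamma
#'
#' The DFTB3 exponential-damped Coulomb interpolation with decay
#' `tau = 16 U / 5`: equal to the Hubbard parameter at zero distance and
#' to `1/r` asymptotically.  An optional hydrogen-pair short-range damping
#' exponent `zeta` multiplies the short-range part by
#' `exp(-((U_A + U_B)/2)^zeta r^2)`.
#'
#' @param r Distance in Bohr (`>= 0`).
#' @param Ua,Ub Hubbard parameters in Hartree (`> 0`).
#' @param zeta Optional damping exponent (used for pairs involving
#'   hydrogen when enabled; default `NULL` = no damping).
#' @return Kernel value in Hartree.
#' @export
gamma_h <- function(r, Ua, Ub, zeta = NULL) {
  if (Ua <= 0 || Ub <= 0) stop("gamma_h: Hubbard parameters must be positive")
  ta <- 3.2 * Ua; tb <- 3.2 * Ub
  if (r < 1e-10) {
    return(ta * tb * (ta^2 + 3 * ta * tb + tb^2) / (2 * (ta + tb)^3))
  }
  if (abs(ta - tb) < 1e-8 * max(ta, tb)) {
    t <- (ta + tb) / 2
    S <- exp(-t * r) * (1 / r + 11 * t / 16 + 3 * t^2 * r / 16 +
                          t^3 * r^2 / 48)
  } else {
    term <- function(p, q) {
      exp(-p * r) * (q^4 * p / (2 * (p^2 - q^2)^2) -
                       (q^6 - 3 * q^4 * p^2) / ((p^2 - q^2)^3 * r))
    }
    S <- term(ta, tb) + term(tb, ta)
  }
  if (!is.null(zeta)) S <- S * exp(-((Ua + Ub) / 2)^zeta * r^2)
  1 / r - S
}

# Third-order kernel Gamma_AB = d gamma_AB / d q_A, chained through the
# Hubbard derivative Ud_A = dU_A/dq_A.  For A == B this is Ud_A exactly
# (gamma_AA = U_A); off-site the U_A-derivative of the closed form is
# evaluated by a 4-point central difference.  The step must be large
# enough (1e-2 relative) that the perturbed evaluations stay clear of
# the ill-conditioned near-equal-tau regime of the unequal-parameter
# closed form; the 4-point truncation error is then ~1e-8 relative.
gamma_dU <- function(r, Ua, Ub, zeta = NULL) {
  h <- 1e-2 * Ua
  (-gamma_h(r, Ua + 2 * h, Ub, zeta) + 8 * gamma_h(r, Ua + h, Ub, zeta) -
     8 * gamma_h(r, Ua - h, Ub, zeta) + gamma_h(r, Ua - 2 * h, Ub, zeta)) /
    (12 * h)
}

#' Charge model for the SCC loop
#'
#' Collects per-atom Hubbard parameters and Hubbard derivatives (from the
#' homonuclear SK tables unless overridden), the SCC mixing and
#' convergence controls, and optional switches: `third_order` (on by
#' default), `h_damping` zeta exponent, Fermi `smear_kT` (Hartree), and a
#' dispersion hook (`disp = list(c6, d)` in Ha Bohr^6 / Bohr).
#'
#' @param system An `atomic_system`.
#' @param tables SK table set.
#' @param U,Ud Optional per-atom overrides (Hartree, Hartree/e).
#' @param third_order Include the third-order Gamma terms (default TRUE).
#' @param zeta Hydrogen-pair damping exponent or NULL (default).
#' @param smear_kT Fermi smearing width in Hartree (0 = Aufbau filling).
#' @param mix Linear-mixing coefficient alpha (default 0.2).
#' @param disp Optional dispersion spec `list(c6 = matrix, d = scalar)`.
#' @return A `charge_model` list.
#' @export
charge_model <- function(system, tables, U = NULL, Ud = NULL,
                         third_order = TRUE, zeta = NULL, smear_kT = 0,
                         mix = 0.2, disp = NULL) {
  n <- length(system$symbols)
  if (is.null(U) || is.null(Ud)) {
    Ut <- numeric(n); Udt <- numeric(n)
    for (i in seq_len(n)) {
      o <- get_sk_table(tables, system$symbols[i], system$symbols[i])$onsite
      Ut[i] <- o$U_s
      Udt[i] <- o$Ud
    }
    if (is.null(U)) U <- Ut
    if (is.null(Ud)) Ud <- Udt
  }
  if (any(U <= 0)) stop("charge_model: U must be positive")
  structure(list(U = U, Ud = Ud, third_order = third_order, zeta = zeta,
                 smear_kT = smear_kT, mix = mix, disp = disp),
            class = "charge_model")
}

# n x n kernel matrices over atoms
charge_kernels <- function(system, model) {
  n <- length(system$symbols)
  d_bohr <- as.matrix(stats::dist(system$coords)) / BOHR_ANGSTROM
  G <- matrix(0, n, n)
  DG <- matrix(0, n, n)
  for (A in seq_len(n)) for (B in seq_len(n)) {
    zeta <- if (!is.null(model$zeta) &&
                (system$symbols[A] == "H" || system$symbols[B] == "H") &&
                A != B) model$zeta else NULL
    if (A == B) {
      G[A, B] <- model$U[A]
      DG[A, B] <- model$Ud[A]
    } else {
      G[A, B] <- gamma_h(d_bohr[A, B], model$U[A], model$U[B], zeta)
      DG[A, B] <- gamma_dU(d_bohr[A, B], model$U[A], model$U[B], zeta) *
        model$Ud[A]
    }
  }
  if (!model$third_order) DG[] <- 0
  list(gamma = G, Gamma = DG)
}

#' Build the charge-dependent SCC Hamiltonian
#'
#' Adds the second- and third-order charge shift to H0:
#' `H = H0 + S * (eps_A + eps_B)` over atom blocks, with the per-atom
#' potential
#' `eps_A = sum_xi dq_xi (gamma_A,xi / 2 + dq_A Gamma_A,xi / 3 +
#'  dq_xi Gamma_xi,A / 6)`.
#' With all `dq = 0` the result equals H0 exactly.
#'
#' @param H0,S Matrices from [build_h0_s()].
#' @param dq Per-atom net Mulliken charges (e, electron-count sign).
#' @param kernels List with `gamma` and `Gamma` atom matrices (Hartree).
#' @param basis_atom Orbital-to-atom map.
#' @return Symmetric Hamiltonian matrix H (Hartree).
#' @export
build_scc_hamiltonian <- function(H0, S, dq, kernels, basis_atom) {
  n_at <- nrow(kernels$gamma)
  if (length(dq) != n_at) stop("build_scc_hamiltonian: dq length mismatch")
  eps <- drop(kernels$gamma %*% dq) / 2 +
    dq * drop(kernels$Gamma %*% dq) / 3 +
    drop(t(kernels$Gamma) %*% (dq^2)) / 6
  shift <- eps[basis_atom]
  H <- H0 + S * outer(shift, rep(1, length(shift))) +
    S * outer(rep(1, length(shift)), shift)
  # the two outer() terms add eps_A + eps_B elementwise
  (H + t(H)) / 2
}

#' Mulliken population analysis
#'
#' `q_A = sum_{mu in A} (P S)_{mu,mu}` with density matrix
#' `P = C f C'`; net charges are `dq_A = q_A - q0_A`.
#'
#' @param vectors MO coefficient matrix (columns).
#' @param occupations Per-orbital fillings (sum = electron count).
#' @param S Overlap matrix.
#' @param basis_atom Orbital-to-atom map.
#' @param ref_occ Per-atom reference occupations.
#' @return List with `q` (populations) and `dq` (net charges).
#' @export
mulliken_charges <- function(vectors, occupations, S, basis_atom, ref_occ) {
  P <- vectors %*% (t(vectors) * occupations)
  pop_orb <- rowSums(P * S)   # diag(P %*% S)
  q <- as.numeric(tapply(pop_orb, basis_atom, sum))
  list(q = q, dq = q - ref_occ)
}

# zero-temperature Aufbau or Fermi-smeared occupations
fill_occupations <- function(values, electrons, smear_kT = 0) {
  n <- length(values)
  if (smear_kT <= 0) {
    if (abs(electrons - round(electrons)) > 1e-9 ||
        as.integer(round(electrons)) %% 2L != 0L)
      stop("fill_occupations: odd electron count needs Fermi smearing")
    nocc <- as.integer(round(electrons)) %/% 2L
    occ <- c(rep(2, nocc), rep(0, n - nocc))
    if (nocc >= 1 && nocc < n &&
        values[nocc + 1] - values[nocc] < 1e-10)
      stop("fill_occupations: degenerate HOMO at zero temperature; ",
           "enable Fermi smearing (smear_kT > 0)")
    return(occ)
  }
  fermi <- function(mu) 2 / (1 + exp((values - mu) / smear_kT))
  lo <- min(values) - 50 * smear_kT; hi <- max(values) + 50 * smear_kT
  for (i in 1:200) {
    mu <- (lo + hi) / 2
    if (sum(fermi(mu)) < electrons) lo <- mu else hi <- mu
  }
  fermi((lo + hi) / 2)
}

#' Self-consistent-charge iteration
#'
#' Fixed-point loop: build the charge-dependent Hamiltonian, solve the
#' generalized eigenproblem, fill orbitals (Aufbau, 2 electrons per
#' spatial orbital, or Fermi smearing), recompute Mulliken charges, and
#' linearly mix `dq_new = (1 - alpha) dq_old + alpha dq_out` until
#' `max|d dq| < tol`.
#'
#' @param system An `atomic_system`.
#' @param tables SK table set.
#' @param model A `charge_model`.
#' @param tol Charge convergence tolerance in e (default 1e-8).
#' @param max_iter Iteration cap (default 200); non-convergence flags the
#'   state instead of raising an error.
#' @param dq_init Initial charge guess (default all zero).
#' @return An `scc_state`: matrices, charges, orbitals, occupations,
#'   energy components (Hartree), iteration count and convergence flag.
#' @export
scc_iterate <- function(system, tables, model = charge_model(system, tables),
                        tol = 1e-8, max_iter = 200, dq_init = NULL) {
  hs <- build_h0_s(system, tables)
  kern <- charge_kernels(system, model)
  n_at <- length(system$symbols)
  dq <- if (is.null(dq_init)) numeric(n_at) else dq_init
  converged <- FALSE
  n_iter <- 0
  orbitals <- NULL; occ <- NULL
  if (max_iter < 1) {
    # unconverged by construction: report the initial guess
    H <- build_scc_hamiltonian(hs$H0, hs$S, dq, kern, hs$basis_atom)
    orbitals <- solve_generalized(H, hs$S)
    occ <- fill_occupations(orbitals$values, system$electrons, model$smear_kT)
  }
  for (it in seq_len(max_iter)) {
    n_iter <- it
    H <- build_scc_hamiltonian(hs$H0, hs$S, dq, kern, hs$basis_atom)
    orbitals <- solve_generalized(H, hs$S)
    occ <- fill_occupations(orbitals$values, system$electrons, model$smear_kT)
    mul <- mulliken_charges(orbitals$vectors, occ, hs$S, hs$basis_atom,
                            system$ref_occ)
    delta <- max(abs(mul$dq - dq))
    if (delta < tol) {
      dq <- mul$dq
      converged <- TRUE
      break
    }
    dq <- (1 - model$mix) * dq + model$mix * mul$dq
  }
  state <- structure(list(H0 = hs$H0, S = hs$S,
                          H = build_scc_hamiltonian(hs$H0, hs$S, dq, kern,
                                                    hs$basis_atom),
                          basis_atom = hs$basis_atom, kernels = kern,
                          dq = dq, orbitals = orbitals, occupations = occ,
                          n_iter = n_iter, converged = converged),
                     class = "scc_state")
  state$energy_components <- total_energy(state, system, tables, model)
  state
}

#' @export
print.scc_state <- function(x, ...) {
  e <- x$energy_components
  cat(sprintf("scc_state: %s in %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  E_total %.10f Ha (BS %.6f, gamma %.6f, Gamma %.6f, rep %.6f, disp %.6f)\n",
              e["E_total"], e["E_BS"], e["E_gamma"], e["E_Gamma"],
              e["E_rep"], e["E_disp"]))
  cat("  dq:", paste(sprintf("%+.5f", x$dq), collapse = " "), "\n")
  invisible(x)
}

#' Total DFTB3 energy components
#'
#' Recomputes all energy components from a (converged or flagged) SCC
#' state: band-structure, second-order gamma, third-order Gamma,
#' repulsive, and dispersion terms.
#'
#' @param state An `scc_state`.
#' @param system,tables,model As in [scc_iterate()].
#' @return Named numeric vector of energy components in Hartree.
#' @export
total_energy <- function(state, system, tables, model) {
  V <- state$orbitals$vectors
  f <- state$occupations
  E_BS <- sum(f * colSums(V * (state$H0 %*% V)))
  dq <- state$dq
  E_gamma <- 0.5 * sum(outer(dq, dq) * state$kernels$gamma)
  E_Gamma <- sum(outer(dq^2, dq) * state$kernels$Gamma) / 3
  E_rep <- 0
  n_at <- length(system$symbols)
  if (n_at > 1) {
    d_bohr <- as.matrix(stats::dist(system$coords)) / BOHR_ANGSTROM
    for (A in seq_len(n_at - 1)) for (B in seq((A + 1), n_at)) {
      tab <- get_sk_table(tables, system$symbols[A], system$symbols[B])
      E_rep <- E_rep + sk_repulsive_energy(tab, d_bohr[A, B])
    }
  }
  E_disp <- dispersion_energy(system, model$disp)
  c(E_BS = E_BS, E_gamma = E_gamma, E_Gamma = E_Gamma, E_rep = E_rep,
    E_disp = E_disp,
    E_total = E_BS + E_gamma + E_Gamma + E_rep + E_disp)
}

#' Damped pairwise dispersion energy
#'
#' Generic damped-C6 hook with user-supplied coefficients:
#' `E = -sum_{A<B} c6_AB / (r^6 + d^6)` (constant Becke-Johnson-style
#' damping length `d`).  Returns 0 when no coefficients are supplied.
#'
#' @param system An `atomic_system`.
#' @param disp `NULL` or `list(c6 = symmetric n x n matrix in Ha Bohr^6,
#'   d = damping length in Bohr)`.
#' @return Dispersion energy in Hartree.
#' @export
dispersion_energy <- function(system, disp = NULL) {
  if (is.null(disp)) return(0)
  c6 <- disp$c6
  if (any(c6 < 0)) stop("dispersion_energy: c6 coefficients must be >= 0")
  if (max(abs(c6 - t(c6))) > 1e-12 * max(abs(c6), 1))
    stop("dispersion_energy: c6 must be symmetric")
  n <- length(system$symbols)
  if (n < 2) return(0)
  d_bohr <- as.matrix(stats::dist(system$coords)) / BOHR_ANGSTROM
  e <- 0
  for (A in seq_len(n - 1)) for (B in seq((A + 1), n))
    e <- e - c6[A, B] / (d_bohr[A, B]^6 + disp$d^6)
  e
}

#' Total energy of a geometry (convenience wrapper)
#'
#' Runs the SCC loop for the given coordinates and returns the total
#' energy; errors if the loop does not converge.
#'
#' @param system An `atomic_system` (its coordinates may be overridden).
#' @param tables,model As in [scc_iterate()].
#' @param coords Optional replacement n x 3 coordinates (Angstrom).
#' @param dq_init Optional warm-start charges.
#' @param tol SCC charge tolerance in e; note that for systems with a
#'   slowly contracting charge mode the energy error can exceed the
#'   charge residual, so reproducibility checks at the 1e-9 Ha level
#'   should tighten this.
#' @param max_iter SCC iteration cap.
#' @return List with `energy` (Hartree) and `state`.
#' @export
dftb_energy <- function(system, tables, model = charge_model(system, tables),
                        coords = NULL, dq_init = NULL, tol = 1e-8,
                        max_iter = 200) {
  if (!is.null(coords)) system$coords <- as.matrix(coords)
  st <- scc_iterate(system, tables, model, tol = tol, max_iter = max_iter,
                    dq_init = dq_init)
  if (!st$converged) stop("dftb_energy: SCC did not converge")
  list(energy = unname(st$energy_components["E_total"]), state = st)
}

#' Finite-difference forces
#'
#' Central differences of the total SCC energy with respect to each
#' Cartesian coordinate.  Returned in Hartree/Bohr.
#'
#' @param system,tables,model As in [scc_iterate()].
#' @param step Displacement step in Bohr (default 1e-3).
#' @return n x 3 matrix of forces (Hartree/Bohr).
#' @export
dftb_forces <- function(system, tables, model = charge_model(system, tables),
                        step = 1e-3) {
  ref <- dftb_energy(system, tables, model)
  dq0 <- ref$state$dq
  step_ang <- step * BOHR_ANGSTROM
  n <- length(system$symbols)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    cp <- system$coords; cp[i, k] <- cp[i, k] + step_ang
    cm <- system$coords; cm[i, k] <- cm[i, k] - step_ang
    ep <- dftb_energy(system, tables, model, coords = cp, dq_init = dq0)$energy
    em <- dftb_energy(system, tables, model, coords = cm, dq_init = dq0)$energy
    F[i, k] <- -(ep - em) / (2 * step)
  }
  F
}

#' Relax a geometry by steepest descent
#'
#' Steepest descent with backtracking line search until the largest
#' per-atom force norm drops below `fmax`; accepted steps never increase
#' the energy.
#'
#' @param system,tables,model As in [scc_iterate()].
#' @param fmax Convergence threshold in eV/Angstrom (default 0.04).
#' @param max_steps Accepted-step cap (default 500).
#' @param step0 Initial step scale in Angstrom^2/eV-ish units (internally
#'   scaled; default 0.5).
#' @return The relaxed `atomic_system` with attributes `energy` (Ha),
#'   `n_steps` and `fmax_final` (eV/Angstrom).
#' @export
dftb_relax <- function(system, tables, model = charge_model(system, tables),
                       fmax = 0.04, max_steps = 500, step0 = 0.5) {
  if (fmax <= 0) stop("dftb_relax: fmax must be positive")
  fmax_ha <- fmax / HARTREE_EV * BOHR_ANGSTROM   # eV/A -> Ha/Bohr
  e_cur <- dftb_energy(system, tables, model)$energy
  accepted <- 0
  repeat {
    F <- dftb_forces(system, tables, model)     # Ha/Bohr
    fnorm <- sqrt(rowSums(F^2))
    if (max(fnorm) < fmax_ha) break
    if (accepted >= max_steps)
      stop("dftb_relax: iteration cap exceeded (", max_steps, " steps)")
    # displacement in Angstrom along the force
    alpha <- step0
    repeat {
      trial <- system$coords + alpha * F * BOHR_ANGSTROM
      e_try <- tryCatch(dftb_energy(system, tables, model, coords = trial)$energy,
                        error = function(e) Inf)
      if (e_try <= e_cur) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (e_try > e_cur) break   # no descent direction at resolution limit
    system$coords <- trial
    e_cur <- e_try
    accepted <- accepted + 1
  }
  attr(system, "energy") <- e_cur
  attr(system, "n_steps") <- accepted
  attr(system, "fmax_final") <- max(sqrt(rowSums(
    dftb_forces(system, tables, model)^2))) * HARTREE_EV / BOHR_ANGSTROM
  system
}
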