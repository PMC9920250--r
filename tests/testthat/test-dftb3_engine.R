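# DFTB3 engine: H0/S assembly, charge kernels, Mulliken analysis, SCC
# fixed points, energy components, dispersion, forces and relaxation.

test_that("H0/S closed forms: single atom, far pair, aligned s dimer", {
  tabs <- sk_fix()
  # single s,p atom
  sysz <- atomic_system("Z", matrix(c(0, 0, 0), 1))
  hs <- build_h0_s(sysz, tabs)
  o <- tabs[["Z-Z"]]$onsite
  expect_equal(hs$H0, diag(c(o$eps_s, rep(o$eps_p, 3))))
  expect_equal(hs$S, diag(4))
  # two atoms beyond all cutoffs
  far <- atomic_system(c("X", "X"),
                       rbind(c(0, 0, 0), c(0, 0, 20 * 0.529177210903)))
  hsf <- build_h0_s(far, tabs)
  expect_equal(hsf$H0, diag(rep(tabs[["X-X"]]$onsite$eps_s, 2)))
  expect_equal(hsf$S, diag(2))
  # s-only dimer on the z-axis: off-diagonal = tabulated channel
  d <- 2.5
  dim2 <- atomic_system(c("X", "X"),
                        rbind(c(0, 0, 0), c(0, 0, d * 0.529177210903)))
  hs2 <- build_h0_s(dim2, tabs)
  expect_equal(hs2$H0[1, 2],
               sk_interpolate(tabs[["X-X"]], d, "ss_sigma", "H"),
               tolerance = 1e-12)
  expect_equal(hs2$S[1, 2],
               sk_interpolate(tabs[["X-X"]], d, "ss_sigma", "S"),
               tolerance = 1e-12)
  expect_lt(max(abs(hs2$H0 - t(hs2$H0))), 1e-14)
})

test_that("basis bookkeeping: matrix dimension equals summed orbital counts", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  expect_equal(nrow(build_h0_s(dm$xx, tabs)$H0), 2)   # 2 s-only atoms
  expect_equal(nrow(build_h0_s(dm$zz, tabs)$H0), 8)   # 2 s,p atoms
  expect_equal(nrow(build_h0_s(dm$zxx, tabs)$H0), 6)  # 4 + 1 + 1
})

test_that("gamma kernel: on-site limit, Coulomb asymptote, symmetry, smoothness", {
  expect_equal(gamma_h(0, 0.4, 0.4), 0.4, tolerance = 1e-12)
  expect_equal(gamma_h(0, 0.35, 0.25),
               local({
                 ta <- 3.2 * 0.35; tb <- 3.2 * 0.25
                 ta * tb * (ta^2 + 3 * ta * tb + tb^2) / (2 * (ta + tb)^3)
               }), tolerance = 1e-12)
  r <- 55
  expect_equal(gamma_h(r, 0.4, 0.3), 1 / r, tolerance = 1e-6)
  expect_equal(gamma_h(3.1, 0.4, 0.3), gamma_h(3.1, 0.3, 0.4))
  # equal-U branch joins the unequal-U branch continuously
  expect_equal(gamma_h(2.5, 0.4, 0.4), gamma_h(2.5, 0.4, 0.4 + 1e-9),
               tolerance = 1e-6)
  expect_error(gamma_h(1, -0.1, 0.4), "positive")
})

test_that("SCC Hamiltonian: zero charges give H0; second-order shift matches hand evaluation", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  hs <- build_h0_s(dm$xy, tabs)
  model <- charge_model(dm$xy, tabs, third_order = FALSE)
  kern <- qmetad:::charge_kernels(dm$xy, model)
  H <- build_scc_hamiltonian(hs$H0, hs$S, c(0, 0), kern, hs$basis_atom)
  expect_identical(H, hs$H0)
  # 2-atom second-order shift: S_mu_nu/2 * sum_xi dq_xi (g_Axi + g_Bxi)
  dq <- c(0.3, -0.3)
  H2 <- build_scc_hamiltonian(hs$H0, hs$S, dq, kern, hs$basis_atom)
  g <- kern$gamma
  shiftAB <- 0.5 * (dq[1] * (g[1, 1] + g[2, 1]) + dq[2] * (g[1, 2] + g[2, 2]))
  expect_equal(H2[1, 2] - hs$H0[1, 2], hs$S[1, 2] * shiftAB,
               tolerance = 1e-12)
  # linearity at second order: flipping all charges flips the shift
  H3 <- build_scc_hamiltonian(hs$H0, hs$S, -dq, kern, hs$basis_atom)
  expect_equal(H3 - hs$H0, -(H2 - hs$H0), tolerance = 1e-12)
})

test_that("Mulliken charges: symmetric dimer, isolated atom, 2-level closed form", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  st <- scc_iterate(dm$xx, tabs)
  expect_equal(st$dq, c(0, 0), tolerance = 1e-10)
  atom <- atomic_system("Z", matrix(0, 1, 3))
  sta <- scc_iterate(atom, tabs, charge_model(atom, tabs, smear_kT = 0.01))
  expect_equal(sta$dq, 0, tolerance = 1e-9)
  # polar s-only heterodimer with s = 0, solved by hand:
  # H = [[e1, t], [t, e2]], ground state c = (cos a, sin a)
  e1 <- -0.6; e2 <- -0.4; t <- -0.2
  H <- rbind(c(e1, t), c(t, e2))
  ev <- eigen(H, symmetric = TRUE)
  c0 <- ev$vectors[, which.min(ev$values)]
  q_hand <- 2 * c0^2
  mul <- mulliken_charges(ev$vectors[, order(ev$values), drop = FALSE],
                          c(2, 0), diag(2), c(1, 2), c(1, 1))
  expect_equal(mul$q, q_hand, tolerance = 1e-12)
  expect_equal(sum(mul$q), 2, tolerance = 1e-12)
})

test_that("SCC loop: fixed point, mixing independence, max_iter = 0 flag", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  st <- scc_iterate(dm$xx, tabs)
  expect_true(st$converged)
  expect_lte(st$n_iter, 2)
  st1 <- scc_iterate(dm$xy, tabs, charge_model(dm$xy, tabs, mix = 0.1),
                     max_iter = 500)
  st2 <- scc_iterate(dm$xy, tabs, charge_model(dm$xy, tabs, mix = 0.3),
                     max_iter = 500)
  expect_true(st1$converged && st2$converged)
  expect_equal(st1$dq, st2$dq, tolerance = 1e-7)
  st0 <- scc_iterate(dm$xy, tabs, max_iter = 0)
  expect_false(st0$converged)
  expect_equal(st0$dq, c(0, 0))
})

test_that("charge conservation holds at every SCC iteration", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  hs <- build_h0_s(dm$xy, tabs)
  model <- charge_model(dm$xy, tabs)
  kern <- qmetad:::charge_kernels(dm$xy, model)
  dq <- c(0, 0)
  for (it in 1:5) {
    H <- build_scc_hamiltonian(hs$H0, hs$S, dq, kern, hs$basis_atom)
    orb <- solve_generalized(H, hs$S)
    occ <- qmetad:::fill_occupations(orb$values, dm$xy$electrons)
    mul <- mulliken_charges(orb$vectors, occ, hs$S, hs$basis_atom,
                            dm$xy$ref_occ)
    expect_equal(sum(mul$q), dm$xy$electrons, tolerance = 1e-10)
    dq <- 0.8 * dq + 0.2 * mul$dq
  }
})

test_that("energy components: closed forms and recompute consistency", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  st <- scc_iterate(dm$xx, tabs)
  e <- st$energy_components
  # homonuclear: charge terms vanish
  expect_equal(unname(e["E_gamma"]), 0, tolerance = 1e-12)
  expect_equal(unname(e["E_Gamma"]), 0, tolerance = 1e-12)
  # s-only dimer: E_BS = 2 (eps + t)/(1 + s)
  d <- 2.5
  eps <- tabs[["X-X"]]$onsite$eps_s
  t <- sk_interpolate(tabs[["X-X"]], d, "ss_sigma", "H")
  s <- sk_interpolate(tabs[["X-X"]], d, "ss_sigma", "S")
  expect_equal(unname(e["E_BS"]), 2 * (eps + t) / (1 + s),
               tolerance = 1e-12)
  # component sum identity and reproducibility from the converged state
  expect_equal(unname(e["E_total"]),
               unname(sum(e[c("E_BS", "E_gamma", "E_Gamma", "E_rep",
                              "E_disp")])), tolerance = 1e-12)
  model <- charge_model(dm$xx, tabs)
  expect_equal(total_energy(st, dm$xx, tabs, model), e, tolerance = 1e-12)
  # far pair: no repulsion
  far <- atomic_system(c("X", "X"),
                       rbind(c(0, 0, 0), c(0, 0, 10 * 0.529177210903)))
  expect_equal(unname(scc_iterate(far, tabs)$energy_components["E_rep"]), 0)
})

test_that("second-order mode: Gamma terms vanish for any charges", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  model2 <- charge_model(dm$xy, tabs, third_order = FALSE)
  st <- scc_iterate(dm$xy, tabs, model2, max_iter = 500)
  expect_equal(unname(st$energy_components["E_Gamma"]), 0)
})

test_that("rigid rotations and translations leave the energy invariant", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  # the charge loop is tightened beyond its default here: for systems
  # with a slowly contracting charge mode the energy error exceeds the
  # charge residual, and this check is about the rotation code, not the
  # SCC stopping rule
  for (nm in c("xy", "zxx")) {
    sys <- dm[[nm]]
    model <- charge_model(sys, tabs)
    e0 <- dftb_energy(sys, tabs, model, tol = 1e-12, max_iter = 2000)$energy
    set.seed(20)
    for (k in 1:5) {
      th <- runif(3, 0, 2 * pi)
      Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                  c(0, sin(th[1]), cos(th[1])))
      Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                  c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
      cc <- sys$coords %*% t(Rz %*% Rx) +
        matrix(runif(3, -1, 1), nrow(sys$coords), 3, byrow = TRUE)
      e1 <- dftb_energy(sys, tabs, model, coords = cc, tol = 1e-12,
                        max_iter = 2000)$energy
      expect_lt(abs(e1 - e0), 1e-9)
    }
  }
})

test_that("dispersion hook: zero default, closed forms, validation", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  expect_identical(dispersion_energy(dm$xx, NULL), 0)
  r_ang <- dm$xx$coords[2, 3]
  r <- r_ang / 0.529177210903
  c6 <- matrix(c(0, 2, 2, 0), 2)
  # at r = d: -c6/(2 d^6)
  e <- dispersion_energy(dm$xx, list(c6 = c6, d = r))
  expect_equal(e, -2 / (2 * r^6), tolerance = 1e-12)
  # r >> d asymptote within 1%
  e2 <- dispersion_energy(dm$xx, list(c6 = c6, d = r / 10))
  expect_equal(e2, -2 / r^6, tolerance = 0.01)
  expect_error(dispersion_energy(dm$xx, list(c6 = -c6, d = 1)), "c6")
})

test_that("forces: translation invariance, outward push inside repulsion, minimum", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  F1 <- dftb_forces(dm$xx, tabs)
  expect_lt(max(abs(colSums(F1))), 1e-6)
  shifted <- dm$xx
  shifted$coords <- shifted$coords + matrix(c(1, -2, 0.5), 2, 3, byrow = TRUE)
  F2 <- dftb_forces(shifted, tabs)
  expect_equal(F1, F2, tolerance = 1e-8)
  # compressed dimer: forces point outward along the bond (z) axis
  comp <- atomic_system(c("X", "X"),
                        rbind(c(0, 0, 0), c(0, 0, 1.2 * 0.529177210903)))
  Fc <- dftb_forces(comp, tabs)
  expect_lt(Fc[1, 3], 0)
  expect_gt(Fc[2, 3], 0)
  # golden-section scan oracle for the X-X bond minimum
  ebond <- function(d_ang) dftb_energy(dm$xx, tabs,
    coords = rbind(c(0, 0, 0), c(0, 0, d_ang)))$energy
  d_min <- stats::optimize(ebond, c(0.6, 2.2), tol = 1e-8)$minimum
  atmin <- atomic_system(c("X", "X"), rbind(c(0, 0, 0), c(0, 0, d_min)))
  Fm <- dftb_forces(atmin, tabs)
  expect_lt(max(sqrt(rowSums(Fm^2))), 1e-5)
})

test_that("relaxation reaches the scan minimum and honors fmax validation", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  expect_error(dftb_relax(dm$xx, tabs, fmax = 0), "fmax")
  ebond <- function(d_ang) dftb_energy(dm$xx, tabs,
    coords = rbind(c(0, 0, 0), c(0, 0, d_ang)))$energy
  d_min <- stats::optimize(ebond, c(0.6, 2.2), tol = 1e-8)$minimum
  stretched <- atomic_system(c("X", "X"),
                             rbind(c(0, 0, 0), c(0, 0, d_min + 0.25)))
  rel <- dftb_relax(stretched, tabs, fmax = 0.005)
  d_rel <- abs(rel$coords[2, 3] - rel$coords[1, 3])
  expect_lt(abs(d_rel - d_min), 0.01)
  # already-relaxed input: zero accepted steps
  rel2 <- dftb_relax(rel, tabs, fmax = 0.04)
  expect_equal(attr(rel2, "n_steps"), 0)
  expect_equal(rel2$coords, rel$coords)
})

test_that("degenerate HOMO without smearing raises an advisory error", {
  tabs <- sk_fix()
  dm <- dimer_fix()
  expect_error(scc_iterate(dm$zz, tabs), "smearing")
  st <- scc_iterate(dm$zz, tabs, charge_model(dm$zz, tabs, smear_kT = 0.01))
  expect_true(st$converged)
})
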