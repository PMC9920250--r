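# FES reconstruction and decomposition: sum-hills algebra, projection,
# basin differences, internal-energy/entropy surfaces, smoothing,
# minima, NEB.

make_bias_with_hills <- function(centers, heights, sigma = 0.35,
                                 biasf = 10, k = NCOL(centers)) {
  cvs <- lapply(seq_len(k), function(j)
    cv_identity(j, c("phi", "psi")[j]))
  b <- bias_state(cvs, sigma = sigma, biasf = biasf)
  b$hill_time <- seq_len(NROW(centers)) * 500
  b$hill_center <- matrix(centers, ncol = k)
  b$hill_height <- heights
  b
}

test_that("sum_hills: flat zero for no hills, single-hill depth, linearity", {
  b0 <- make_bias_with_hills(matrix(0, 0, 1), numeric(0), k = 1)
  g0 <- sum_hills(b0, bins = 50)
  expect_true(all(g0$values == 0))
  b1 <- make_bias_with_hills(matrix(0.5, 1, 1), 1.2, k = 1)
  g1 <- sum_hills(b1, bins = 360, shift = FALSE)
  # F = -gamma/(gamma-1) V_B: depth of -F at the center = 10/9 * height
  # (bin centers don't hit 0.5 exactly; compare at the nearest center)
  i <- which.min(abs(g1$centers[[1]] - 0.5))
  vb <- bias_potential(b1, g1$centers[[1]][i])
  expect_equal(g1$values[i], -10 / 9 * vb, tolerance = 1e-12)
  b2 <- b1; b2$hill_height <- 2 * b1$hill_height
  g2 <- sum_hills(b2, bins = 360, shift = FALSE)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
  # mixed bias factors in a hills file are rejected at read time
  mixed <- withr::local_tempfile()
  writeLines(c("#! FIELDS time phi sigma_phi height biasf",
               "0.5 0.1 0.35 1.2 10", "1.0 0.3 0.35 1.1 8"), mixed)
  expect_error(read_hills(mixed), "bias factor")
})

test_that("well-tempered estimator identity holds at every bin center", {
  set.seed(21)
  b <- make_bias_with_hills(matrix(runif(40, -pi, pi), 20, 2),
                            runif(20, 0.2, 1.2), sigma = c(0.35, 0.5))
  f <- sum_hills(b, bins = 40, shift = FALSE)
  for (i in c(1, 7, 23)) for (j in c(2, 19, 40)) {
    s <- c(f$centers[[1]][i], f$centers[[2]][j])
    expect_equal(-(b$biasf - 1) / b$biasf * f$values[i, j],
                 bias_potential(b, s), tolerance = 1e-10)
  }
})

test_that("fes_time_series: checkpoint subsets and convergence diagnostic", {
  set.seed(22)
  b <- make_bias_with_hills(matrix(runif(30, -pi, pi), 30, 1),
                            runif(30, 0.2, 1.2), k = 1)
  ts <- fes_time_series(b, c(250, 5000, 30 * 500), bins = 60)
  expect_true(all(ts$surfaces[[1]]$values == 0))   # before the first hill
  full <- sum_hills(b, bins = 60, shift = FALSE)
  expect_equal(ts$surfaces[[3]]$values, full$values, tolerance = 1e-12)
  expect_length(ts$offset_corrected_diff, 2)
  expect_error(fes_time_series(b, c(2, 1)), "ascending")
})

test_that("project_1d: separable surfaces and flat surfaces", {
  bins <- 80
  s <- qmetad:::grid_centers(bins)
  fx <- 3 * cos(s)^2
  gy <- 5 * sin(s / 1)^2
  v <- outer(fx, gy, "+")
  fes <- fes_grid(v, c("phi", "psi"), shift = FALSE)
  p1 <- project_1d(fes, 1, T = 300)
  expect_equal(as.numeric(p1$values), fx - min(fx), tolerance = 1e-9)
  flat <- fes_grid(matrix(2, 40, 40), c("phi", "psi"), shift = FALSE)
  pf <- project_1d(flat, 2)
  expect_true(all(abs(pf$values) < 1e-12))
  # double-well projection vs direct 1-D Boltzmann integral oracle
  kT <- 0.008314462618 * 300
  vv <- outer(10 * cos(s)^2 + 2.5 * sin(s), 4 * sin(s)^2, "+")
  f2 <- fes_grid(vv, c("phi", "psi"), shift = FALSE)
  p2 <- project_1d(f2, 1, T = 300)
  oracle <- -kT * log(rowSums(exp(-vv / kT)) * (2 * pi / bins))
  oracle <- oracle - min(oracle)
  expect_equal(as.numeric(p2$values), oracle, tolerance = 1e-6)
})

test_that("basin differences: symmetry zero, designed value, antisymmetry", {
  bins <- 400
  s <- qmetad:::grid_centers(bins)
  f_sym <- fes_grid(10 * cos(s)^2, "phi")
  expect_equal(basin_free_energy_difference(f_sym, c(-2.3, -0.8),
                                            c(0.8, 2.3)), 0,
               tolerance = 1e-10)
  # designed 1-D double well with dF = 5 kJ/mol between harmonic basins:
  # equal curvature wells at -/+ pi/2 offset by exactly 5
  kT <- 0.008314462618 * 300
  wellA <- 40 * (s + pi / 2)^2
  wellB <- 40 * (s - pi / 2)^2 + 5
  v <- pmin(wellA, wellB)
  fdes <- fes_grid(v, "phi", shift = FALSE)
  dfv <- basin_free_energy_difference(fdes, c(-pi / 2 - 0.7, -pi / 2 + 0.7),
                                      c(pi / 2 - 0.7, pi / 2 + 0.7))
  expect_equal(dfv, -5, tolerance = 0.01)
  dfr <- basin_free_energy_difference(fdes, c(pi / 2 - 0.7, pi / 2 + 0.7),
                                      c(-pi / 2 - 0.7, -pi / 2 + 0.7))
  expect_equal(dfr, -dfv, tolerance = 1e-12)
  expect_error(basin_free_energy_difference(fdes, c(-1, 1), c(0, 2)),
               "overlap")
})

test_that("internal-energy surface: means, masking, equipartition", {
  # frames alternating U in {0, 2} within one bin -> mean 1
  cvr <- data.frame(time = 1:10, phi = rep(0.01, 10),
                    ene = rep(c(0, 2), 5))
  g <- internal_energy_surface(cvr, "phi", bins = 10, min_count = 5)
  ibin <- qmetad:::bin_index(0.01, 10)
  expect_equal(g$values[ibin], 1 - 1 + 0)  # single unmasked bin -> shift to 0
  expect_true(all(g$mask[-ibin]))
  # constant energy -> flat zero after shift
  cvc <- data.frame(time = 1:200, phi = runif(200, -pi, pi), ene = 7)
  gc <- internal_energy_surface(cvc, "phi", bins = 10, min_count = 1)
  expect_true(all(gc$values[!gc$mask] == 0))
  expect_error(internal_energy_surface(cvr[0, ], "phi"), "no records")
  # equipartition on a 2-D (weakly coupled) harmonic toy: <U> ~ kB T.
  # The small quartic coupling breaks the integrability that makes a
  # single Nose-Hoover thermostat non-ergodic on pure harmonic systems,
  # and the weak thermostat coupling (tau = 100 fs) keeps the
  # configurational distribution canonical.
  harm2 <- make_potential(
    energy = function(x) 0.5 * 50 * sum(x^2) + 10 * x[1]^2 * x[2]^2,
    forces = function(x) -50 * x - 20 * c(x[1] * x[2]^2, x[1]^2 * x[2]))
  res <- run_nvt(harm2, c(0, 0), c(1, 1), steps = 100000, dt = 1, T = 300,
                 seed = 13, tau = 100, stride = 10)
  expect_lt(abs(mean(res$record$pe) / (0.008314462618 * 300) - 1), 0.05)
})

test_that("entropy surface: identity, arithmetic, mask propagation", {
  v <- matrix(c(1, 2, 0, 3), 2, 2)
  fes <- fes_grid(v, c("phi", "psi"), shift = FALSE)
  pes_same <- fes_grid(v, c("phi", "psi"), kind = "internal_energy",
                       shift = FALSE)
  ts0 <- entropy_surface(fes, pes_same)
  expect_true(all(ts0$values == 0))
  zero <- fes_grid(matrix(0, 2, 2), c("phi", "psi"), shift = FALSE)
  pes3 <- fes_grid(matrix(3, 2, 2), c("phi", "psi"),
                   kind = "internal_energy", shift = FALSE)
  expect_true(all(entropy_surface(zero, pes3)$values == 3))
  msk <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  pesm <- fes_grid(v, c("phi", "psi"), kind = "internal_energy",
                   mask = msk, shift = FALSE)
  tsm <- entropy_surface(fes, pesm)
  expect_identical(tsm$mask, msk)
  # decomposition identity on unmasked bins
  expect_true(all(abs((fes$values - pesm$values + tsm$values)[!msk])
                  < 1e-12))
  expect_error(entropy_surface(fes, fes_grid(matrix(0, 3, 3),
                                             c("phi", "psi"),
                                             shift = FALSE)), "mismatch")
})

test_that("gaussian smoothing: identity cases and mass conservation", {
  set.seed(23)
  g <- fes_grid(matrix(runif(400), 20, 20), c("phi", "psi"), shift = FALSE)
  expect_identical(gaussian_smooth(g, 0), g)
  const <- fes_grid(matrix(4, 20, 20), c("phi", "psi"), shift = FALSE)
  expect_equal(gaussian_smooth(const, 2)$values, const$values,
               tolerance = 1e-10)
  spike <- matrix(0, 21, 21); spike[11, 11] <- 5
  gs <- gaussian_smooth(fes_grid(spike, c("phi", "psi"), shift = FALSE), 1)
  expect_equal(sum(gs$values), 5, tolerance = 1e-10)
  expect_equal(mean(gaussian_smooth(g, 1.5)$values), mean(g$values),
               tolerance = 1e-10)
})

test_that("find_minima: constructed single well, flat surface, symmetric wells", {
  bins <- 100
  s <- qmetad:::grid_centers(bins)
  single <- fes_grid(outer(10 * (1 - exp(-((s - 0.5)^2) / 0.5)),
                           10 * (1 - exp(-((s + 1)^2) / 0.5)), "+"),
                     c("phi", "psi"), shift = FALSE)
  m1 <- find_minima(single, depth_cut = 1)
  expect_equal(nrow(m1), 1)
  expect_lt(abs(m1$phi[1] - 0.5), 2 * pi / bins * 1.5)
  expect_lt(abs(m1$psi[1] + 1), 2 * pi / bins * 1.5)
  flat <- fes_grid(matrix(1, 30, 30), c("phi", "psi"), shift = FALSE)
  expect_equal(nrow(find_minima(flat)), 0)
  twow <- fes_grid(outer(10 * cos(s)^2, 3 * sin(s)^2, "+"),
                   c("phi", "psi"), shift = FALSE)
  m2 <- find_minima(twow, depth_cut = 1)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$value[1], m2$value[2], tolerance = 1e-9)
})

test_that("NEB: degenerate endpoints, symmetric well, known saddle height", {
  bins <- 100
  s <- qmetad:::grid_centers(bins)
  # separable surface: 12 cos^2(phi) + 5 sin^2(psi)
  # minima at (-pi/2, 0) and (pi/2, 0); MEP along psi = 0 crosses the
  # saddle at phi = 0 with height exactly 12
  v <- outer(12 * cos(s)^2, 5 * sin(s)^2, "+")
  grid <- fes_grid(v, c("phi", "psi"), shift = FALSE)
  p0 <- neb_path(grid, c(0.3, 0.2), c(0.3, 0.2))
  expect_equal(p0$barrier, 0)
  # symmetric endpoints around a single well: path relaxes through it
  well <- fes_grid(outer(3 * s^2, 3 * s^2, "+"), c("phi", "psi"),
                   shift = FALSE)
  psym <- neb_path(well, c(-0.8, 0), c(0.8, 0), n_images = 16)
  expect_lt(psym$barrier, 1e-3 + max(psym$energies[1], 0))
  pth <- neb_path(grid, c(-pi / 2, 0), c(pi / 2, 0), n_images = 32)
  expect_lt(abs(pth$barrier - 12), 0.5)
  # barrier invariant under start/end reversal
  rev <- neb_path(grid, c(pi / 2, 0), c(-pi / 2, 0), n_images = 32)
  expect_lt(abs(rev$barrier - pth$barrier), 1e-6)
})

test_that("FES grid files round trip", {
  set.seed(24)
  g <- fes_grid(matrix(runif(100), 10, 10), c("phi", "psi"), shift = FALSE)
  path <- withr::local_tempfile()
  write_fes_grid(g, path)
  g2 <- read_fes_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$cv_names, g$cv_names)
})
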