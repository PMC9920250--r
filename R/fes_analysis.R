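# Free-energy-surface analysis: hill summation into an FES (the
# well-tempered estimator F = -gamma/(gamma-1) V_B), convergence
# checkpoints, 1-D Boltzmann projection, basin free-energy differences,
# grid-local internal-energy averaging, the entropy decomposition
# T dS = dU - dA, periodic Gaussian smoothing, minima detection, and
# nudged-elastic-band transition paths on gridded surfaces.
#
# All grids are bin-centered over the periodic CV domain (-pi, pi]^k and
# carry kJ/mol values shifted so the (unmasked) minimum is zero.

#' Construct an FES grid container
#'
#' @param values k-dimensional array of bin-center values (kJ/mol).
#' @param cv_names CV names, one per dimension.
#' @param bins Bins per dimension.
#' @param kind `"free_energy"`, `"internal_energy"` or `"entropy_term"`.
#' @param mask Optional logical array: TRUE marks bins with no data.
#' @param shift Shift unmasked values so their minimum is zero
#'   (default TRUE; entropy grids are stored unshifted).
#' @return An `fes_grid`.
#' @export
fes_grid <- function(values, cv_names, bins = dim(as.array(values)),
                     kind = "free_energy", mask = NULL, shift = TRUE) {
  values <- as.array(values)
  if (is.null(dim(values))) dim(values) <- length(values)
  if (!is.null(mask) && !identical(dim(as.array(mask)), dim(values)))
    stop("fes_grid: mask shape mismatch")
  if (shift) {
    keep <- if (is.null(mask)) TRUE else !mask
    values <- values - min(values[keep])
  }
  centers <- lapply(dim(values), function(b) grid_centers(b))
  structure(list(values = values, cv_names = cv_names,
                 bins = dim(values), centers = centers,
                 kind = kind, mask = mask,
                 offset_convention = if (shift) "min-zero" else "none"),
            class = "fes_grid")
}

grid_centers <- function(bins) {
  edges <- seq(-pi, pi, length.out = bins + 1)
  (edges[-1] + edges[-(bins + 1)]) / 2
}

#' @export
print.fes_grid <- function(x, ...) {
  rng <- range(if (is.null(x$mask)) x$values else x$values[!x$mask])
  cat(sprintf("fes_grid (%s): %s bins over (-pi,pi]^%d [%s], range %.3f..%.3f kJ/mol\n",
              x$kind, paste(x$bins, collapse = "x"), length(x$bins),
              paste(x$cv_names, collapse = ","), rng[1], rng[2]))
  invisible(x)
}

#' Plot a 2-D FES grid
#'
#' Filled-contour rendering with CV axes in radians.
#'
#' @param x An `fes_grid` with two dimensions.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.fes_grid <- function(x, ...) {
  if (length(x$bins) != 2) stop("plot.fes_grid: 2-D grids only")
  graphics::filled.contour(x$centers[[1]], x$centers[[2]], x$values,
                           xlab = x$cv_names[1], ylab = x$cv_names[2], ...)
}

# evaluate the summed bias on all bin centers (pre-shift, kJ/mol)
bias_on_grid <- function(bias, bins, t = Inf) {
  k <- ncol(bias$hill_center)
  sel <- bias$hill_time < t
  centers <- lapply(rep(bins, length.out = k), grid_centers)
  if (k == 1) {
    v <- numeric(length(centers[[1]]))
    if (any(sel)) {
      d <- wrap_angle(outer(centers[[1]], bias$hill_center[sel, 1], "-"))
      v <- drop(exp(-d^2 / (2 * bias$sigma[1]^2)) %*% bias$hill_height[sel])
    }
    array(v, dim = length(v))
  } else if (k == 2) {
    n1 <- length(centers[[1]]); n2 <- length(centers[[2]])
    v <- matrix(0, n1, n2)
    if (any(sel)) {
      e1 <- exp(-wrap_angle(outer(centers[[1]], bias$hill_center[sel, 1],
                                  "-"))^2 / (2 * bias$sigma[1]^2))
      e2 <- exp(-wrap_angle(outer(centers[[2]], bias$hill_center[sel, 2],
                                  "-"))^2 / (2 * bias$sigma[2]^2))
      v <- e1 %*% (t(e2) * bias$hill_height[sel])
    }
    v
  } else stop("bias_on_grid: only 1 or 2 CVs supported")
}

#' Sum hills into a free-energy surface
#'
#' Evaluates the total bias at every bin center and applies the
#' well-tempered estimator `F = -gamma/(gamma-1) V_B`, shifted to a zero
#' minimum.
#'
#' @param bias A `bias_state` (all hills must share one bias factor).
#' @param bins Bins per CV (default 100).
#' @param shift Min-zero shift (default TRUE; the pre-shift surface is
#'   returned when FALSE, as needed for the estimator identity).
#' @return An `fes_grid` of kind `"free_energy"`.
#' @export
sum_hills <- function(bias, bins = 100, shift = TRUE) {
  g <- bias$biasf
  vb <- bias_on_grid(bias, bins)
  f <- -g / (g - 1) * vb
  fes_grid(f, vapply(bias$cvs, `[[`, "", "name"), kind = "free_energy",
           shift = shift)
}

#' Free-energy surfaces at a series of time checkpoints
#'
#' Each checkpoint surface uses only hills deposited up to that time.
#' The convergence diagnostic between consecutive checkpoints is the
#' offset-corrected maximum difference
#' `max |F_a - F_b - median(F_a - F_b)|`.
#'
#' @param bias A `bias_state`.
#' @param checkpoint_times Ascending times in fs.
#' @param bins Bins per CV.
#' @return List with `surfaces` (one `fes_grid` per checkpoint, unshifted)
#'   and `offset_corrected_diff` (length `length(checkpoint_times) - 1`).
#' @export
fes_time_series <- function(bias, checkpoint_times, bins = 100) {
  if (is.unsorted(checkpoint_times))
    stop("fes_time_series: checkpoint times must be ascending")
  g <- bias$biasf
  nm <- vapply(bias$cvs, `[[`, "", "name")
  surfaces <- lapply(checkpoint_times, function(tc) {
    vb <- bias_on_grid(bias, bins, t = tc + 1e-9)
    fes_grid(-g / (g - 1) * vb, nm, kind = "free_energy", shift = FALSE)
  })
  dd <- numeric(max(length(surfaces) - 1, 0))
  for (i in seq_along(dd)) {
    dif <- surfaces[[i + 1]]$values - surfaces[[i]]$values
    dd[i] <- max(abs(dif - stats::median(dif)))
  }
  list(surfaces = surfaces, offset_corrected_diff = dd)
}

#' Boltzmann projection of a 2-D FES onto one CV
#'
#' `F1(s1) = -kB T log sum_s2 exp(-F(s1,s2)/kB T) ds2`, min-zero
#' shifted.
#'
#' @param fes A 2-D `fes_grid`.
#' @param cv_index Dimension to keep (1 or 2).
#' @param T Temperature in Kelvin (default 300).
#' @return A 1-D `fes_grid`.
#' @export
project_1d <- function(fes, cv_index = 1, T = 300) {
  if (length(fes$bins) != 2) stop("project_1d: need a 2-D grid")
  kT <- KB_KJMOL * T
  other <- 3 - cv_index
  ds <- 2 * pi / fes$bins[other]
  w <- exp(-fes$values / kT)
  z <- apply(w, cv_index, sum) * ds
  fes_grid(-kT * log(z), fes$cv_names[cv_index], kind = "free_energy")
}

#' Basin free-energy difference on a 1-D FES
#'
#' Boltzmann-weighted basin populations:
#' `dF = -kB T log(Z_A / Z_B)` with
#' `Z = sum_bins exp(-F/kB T) ds` over each interval.
#'
#' @param fes1d A 1-D `fes_grid`.
#' @param basinA,basinB Disjoint intervals `c(lo, hi)` in radians
#'   (wrapping intervals with `lo > hi` are supported).
#' @param T Temperature in Kelvin.
#' @return Free-energy difference `F_A - F_B` in kJ/mol.
#' @export
basin_free_energy_difference <- function(fes1d, basinA, basinB, T = 300) {
  if (length(fes1d$bins) != 1)
    stop("basin_free_energy_difference: need a 1-D grid")
  s <- fes1d$centers[[1]]
  in_int <- function(b) {
    if (b[1] <= b[2]) s >= b[1] & s <= b[2] else s >= b[1] | s <= b[2]
  }
  selA <- in_int(basinA); selB <- in_int(basinB)
  if (any(selA & selB))
    stop("basin_free_energy_difference: basins overlap")
  if (!any(selA) || !any(selB))
    stop("basin_free_energy_difference: empty basin interval")
  kT <- KB_KJMOL * T
  ds <- 2 * pi / fes1d$bins[1]
  zA <- sum(exp(-fes1d$values[selA] / kT)) * ds
  zB <- sum(exp(-fes1d$values[selB] / kT)) * ds
  -kT * log(zA / zB)
}

#' Grid-local average internal energy
#'
#' Bins COLVAR frames on the CV grid and averages the instantaneous
#' potential energy per bin; bins with fewer than `min_count` frames are
#' masked, and unmasked values are shifted min-zero (giving dU).
#'
#' @param colvar Data frame with CV columns and `ene` (kJ/mol).
#' @param cv_names CV column names to bin on (default: all non-time,
#'   non-ene columns).
#' @param bins Bins per CV (default 100).
#' @param min_count Minimum frames per bin (default 5).
#' @return An `fes_grid` of kind `"internal_energy"` with a mask.
#' @export
internal_energy_surface <- function(colvar, cv_names = NULL, bins = 100,
                                    min_count = 5) {
  if (!nrow(colvar)) stop("internal_energy_surface: no records")
  if (is.null(cv_names))
    cv_names <- setdiff(names(colvar), c("time", "ene"))
  k <- length(cv_names)
  bins <- rep(bins, length.out = k)
  idx <- sapply(seq_len(k), function(j) {
    b <- bin_index(colvar[[cv_names[j]]], bins[j])
    b
  })
  idx <- matrix(idx, ncol = k)
  lin <- idx[, 1]
  if (k > 1) for (j in 2:k) lin <- lin + (idx[, j] - 1) * prod(bins[1:(j - 1)])
  sums <- counts <- array(0, dim = bins)
  tb <- tapply(colvar$ene, lin, sum)
  tc <- tapply(colvar$ene, lin, length)
  sums[as.integer(names(tb))] <- tb
  counts[as.integer(names(tc))] <- tc
  mask <- counts < min_count
  if (all(mask)) stop("internal_energy_surface: all bins masked")
  vals <- array(0, dim = bins)
  vals[!mask] <- sums[!mask] / counts[!mask]
  vals[!mask] <- vals[!mask] - min(vals[!mask])
  fes_grid(vals, cv_names, kind = "internal_energy", mask = mask,
           shift = FALSE)
}

bin_index <- function(x, bins) {
  x <- wrap_angle(x)
  i <- floor((x + pi) / (2 * pi) * bins) + 1
  pmin(pmax(i, 1), bins)
}

#' Entropy term from the free-energy / internal-energy decomposition
#'
#' `T dS = dU - dA` bin-wise (the decomposition
#' `dA = dU - T dS` rearranged); masked dU bins propagate to the
#' output.
#'
#' @param fes dA grid (`"free_energy"`).
#' @param pes dU grid (`"internal_energy"`).
#' @param T Temperature in Kelvin (bookkeeping only; the subtraction is
#'   bin-wise).
#' @return An `fes_grid` of kind `"entropy_term"` with values `T dS`
#'   (kJ/mol, unshifted).
#' @export
entropy_surface <- function(fes, pes, T = 300) {
  if (!identical(fes$bins, pes$bins) ||
      !identical(fes$cv_names, pes$cv_names))
    stop("entropy_surface: grid mismatch")
  vals <- pes$values - fes$values
  mask <- pes$mask
  if (!is.null(mask)) vals[mask] <- 0
  out <- fes_grid(vals, fes$cv_names, kind = "entropy_term", mask = mask,
                  shift = FALSE)
  attr(out, "T") <- T
  out
}

#' Periodic Gaussian smoothing of a grid
#'
#' Wrapped (circular) Gaussian convolution, separable per dimension;
#' `sigma_bins = 0` returns the grid unchanged.  The grid mean is
#' preserved.  Intended for presentation only - quantitative analyses
#' (basin differences, NEB) operate on unsmoothed grids.
#'
#' @param grid An `fes_grid` (no mask).
#' @param sigma_bins Kernel width in bins (`>= 0`).
#' @return Smoothed `fes_grid`.
#' @export
gaussian_smooth <- function(grid, sigma_bins) {
  if (sigma_bins < 0) stop("gaussian_smooth: sigma_bins must be >= 0")
  if (sigma_bins == 0) return(grid)
  if (!is.null(grid$mask) && any(grid$mask))
    stop("gaussian_smooth: masked grids are not smoothed")
  v <- grid$values
  for (d in seq_along(grid$bins)) {
    n <- grid$bins[d]
    off <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    kern <- exp(-off^2 / (2 * sigma_bins^2))
    kern <- kern / sum(kern)
    kf <- stats::fft(kern)
    if (length(grid$bins) == 1) {
      v <- Re(stats::fft(stats::fft(v) * kf, inverse = TRUE)) / n
    } else {
      v <- apply(v, setdiff(seq_along(grid$bins), d), function(col)
        Re(stats::fft(stats::fft(col) * kf, inverse = TRUE)) / n)
      if (d == 2) v <- t(v)
    }
  }
  out <- grid
  out$values <- array(v, dim = grid$bins)
  out
}

#' Locate local minima of a 2-D grid
#'
#' A bin is a minimum when it is lower than its 8 periodic neighbors and
#' lies more than `depth_cut` below the grid median.  Plateau ties break
#' by lexicographic bin index.
#'
#' @param grid A 2-D `fes_grid`.
#' @param depth_cut Minimum depth below the median in kJ/mol
#'   (default 1).
#' @return Data frame with CV coordinates and values, sorted by value.
#' @export
find_minima <- function(grid, depth_cut = 1) {
  if (length(grid$bins) != 2) stop("find_minima: 2-D grids only")
  v <- grid$values
  n1 <- grid$bins[1]; n2 <- grid$bins[2]
  med <- stats::median(v)
  lower_than_all <- matrix(TRUE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- v[(seq_len(n1) - 1 + di) %% n1 + 1,
                 (seq_len(n2) - 1 + dj) %% n2 + 1]
    lower_than_all <- lower_than_all & (v < shifted)
  }
  sel <- which(lower_than_all & (v < med - depth_cut), arr.ind = TRUE)
  if (!nrow(sel))
    return(data.frame(cv1 = numeric(0), cv2 = numeric(0),
                      value = numeric(0)))
  out <- data.frame(cv1 = grid$centers[[1]][sel[, 1]],
                    cv2 = grid$centers[[2]][sel[, 2]],
                    value = v[sel])
  names(out)[1:2] <- grid$cv_names
  out[order(out$value, sel[, 1], sel[, 2]), , drop = FALSE]
}

# periodic bilinear interpolation of a 2-D grid and its gradient
grid_interp2 <- function(grid, p) {
  n1 <- grid$bins[1]; n2 <- grid$bins[2]
  h1 <- 2 * pi / n1; h2 <- 2 * pi / n2
  # continuous bin coordinate: center i at -pi + (i - 1/2) h
  u <- (wrap_angle(p[1]) + pi) / h1 - 0.5
  w <- (wrap_angle(p[2]) + pi) / h2 - 0.5
  i0 <- floor(u); j0 <- floor(w)
  fu <- u - i0; fw <- w - j0
  ii <- c(i0, i0 + 1) %% n1 + 1
  jj <- c(j0, j0 + 1) %% n2 + 1
  q <- grid$values[ii, jj]
  val <- (1 - fu) * (1 - fw) * q[1, 1] + fu * (1 - fw) * q[2, 1] +
    (1 - fu) * fw * q[1, 2] + fu * fw * q[2, 2]
  gx <- ((1 - fw) * (q[2, 1] - q[1, 1]) + fw * (q[2, 2] - q[1, 2])) / h1
  gy <- ((1 - fu) * (q[1, 2] - q[1, 1]) + fu * (q[2, 2] - q[2, 1])) / h2
  list(value = val, grad = c(gx, gy))
}

#' Nudged-elastic-band path on a gridded surface
#'
#' Images are initialized on the minimum-image straight segment between
#' the endpoints; each iteration keeps the surface-gradient component
#' perpendicular to the local tangent (normalized central difference)
#' plus a tangential spring force, and takes a fixed gradient-descent
#' step.  Endpoints stay fixed.
#'
#' @param grid A 2-D `fes_grid`.
#' @param start,end CV endpoints (radians).
#' @param n_images Number of images including endpoints (default 32,
#'   `>= 3`).
#' @param spring_k Spring constant in kJ/mol/rad^2 (default 10).
#' @param max_iter Iteration cap (default 5000).
#' @param step Descent step in rad per (kJ/mol/rad) (default 0.01).
#' @param tol Convergence threshold on the max image displacement in rad
#'   (default 1e-5).
#' @return A `path_result`: `images` (n x 2), `energies`, `barrier`
#'   (max energy minus first-image energy), `converged`.
#' @export
neb_path <- function(grid, start, end, n_images = 32, spring_k = 10,
                     max_iter = 5000, step = 0.01, tol = 1e-5) {
  if (length(grid$bins) != 2) stop("neb_path: 2-D grids only")
  if (n_images < 3) stop("neb_path: need at least 3 images")
  start <- wrap_angle(start); end <- wrap_angle(end)
  if (max(abs(wrap_angle(end - start))) < 1e-12) {
    e0 <- grid_interp2(grid, start)$value
    return(structure(list(images = rbind(start, end),
                          energies = c(e0, e0), barrier = 0,
                          converged = TRUE), class = "path_result"))
  }
  dvec <- wrap_angle(end - start)
  tgrid <- seq(0, 1, length.out = n_images)
  imgs <- t(vapply(tgrid, function(a) start + a * dvec, numeric(2)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    new <- imgs
    for (i in 2:(n_images - 1)) {
      prev <- wrap_angle(imgs[i - 1, ] - imgs[i, ])
      nxt <- wrap_angle(imgs[i + 1, ] - imgs[i, ])
      tau <- wrap_angle(imgs[i + 1, ] - imgs[i - 1, ])
      nt <- sqrt(sum(tau^2))
      tau <- if (nt > 0) tau / nt else c(1, 0)
      gi <- grid_interp2(grid, imgs[i, ])
      g_perp <- gi$grad - sum(gi$grad * tau) * tau
      f_spring <- spring_k * (sqrt(sum(nxt^2)) - sqrt(sum(prev^2))) * tau
      new[i, ] <- wrap_angle(imgs[i, ] + step * (-g_perp + f_spring))
    }
    disp <- max(abs(wrap_angle(new - imgs)))
    imgs <- new
    if (disp < tol) { converged <- TRUE; break }
  }
  energies <- vapply(seq_len(n_images),
                     function(i) grid_interp2(grid, imgs[i, ])$value, 0)
  structure(list(images = imgs, energies = energies,
                 barrier = max(energies) - energies[1],
                 converged = converged), class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("path_result: %d images, barrier %.3f kJ/mol%s\n",
              nrow(x$images), x$barrier,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# ---- FES grid text files -----------------------------------------------

#' Write an FES grid file
#'
#' Plain text, `#! FIELDS <cv...> free` header then one row per bin
#' center (2-D grids in column-major bin order, compatible with
#' community fes.dat layouts for two CVs).
#'
#' @param grid An `fes_grid` (1-D or 2-D, no mask).
#' @param path Output path.
#' @param extra_header Optional `#!` comment lines.
#' @export
write_fes_grid <- function(grid, path, extra_header = character(0)) {
  nm <- grid$cv_names
  hdr <- paste("#! FIELDS", paste(nm, collapse = " "), "free")
  if (length(grid$bins) == 1) {
    m <- cbind(grid$centers[[1]], grid$values)
  } else {
    cc <- expand.grid(grid$centers[[1]], grid$centers[[2]])
    m <- cbind(cc[[1]], cc[[2]], as.vector(grid$values))
  }
  rows <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, if (length(extra_header)) paste("#!", extra_header),
               rows), path)
  invisible(path)
}

#' Read an FES grid file written by [write_fes_grid()]
#'
#' @param path File path.
#' @return An `fes_grid` (values are taken as-is, no re-shift).
#' @export
read_fes_grid <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#!\\s*FIELDS", lines[1]))
    stop("read_fes_grid: missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS\\s*", "", lines[1])),
                     "\\s+")[[1]]
  nm <- setdiff(fields, "free")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  k <- length(nm)
  if (k == 1) {
    fes_grid(m[, 2], nm, kind = "free_energy", shift = FALSE)
  } else {
    n1 <- length(unique(m[, 1])); n2 <- length(unique(m[, 2]))
    fes_grid(array(m[, 3], dim = c(n1, n2)), nm, kind = "free_energy",
             shift = FALSE)
  }
}
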