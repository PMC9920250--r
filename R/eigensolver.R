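# Generalized symmetric-definite eigensolver:
#   A x = lambda B x
# via Cholesky reduction to a standard problem, Householder
# tridiagonalization, and a from-scratch divide-and-conquer solver for the
# symmetric tridiagonal eigenproblem (rank-one tear, secular equation with
# safeguarded bisection, deflation of negligible couplings and of nearly
# equal eigenvalues by Givens rotation).  Base cases are solved by
# implicit-shift QL.  All routines are dense, real, CPU-only.

#' Reduce a generalized symmetric-definite pencil to standard form
#'
#' Factorizes `B = L L'` and forms `C = L^-1 A L^-T`, which has the same
#' eigenvalues as the pencil `(A, B)`.
#'
#' @param A Real symmetric matrix.
#' @param B Real symmetric positive-definite matrix of the same dimension.
#' @return List with `C` (symmetric standard-form matrix) and `L`
#'   (lower-triangular Cholesky factor of `B`).
#' @export
cholesky_reduce <- function(A, B) {
  check_pencil(A, B)
  R <- tryCatch(chol(B), error = function(e) {
    m <- regmatches(conditionMessage(e),
                    regexpr("[0-9]+", conditionMessage(e)))
    stop("cholesky_reduce: B is not positive definite (leading minor of order ",
         if (length(m)) m else "?", " is not positive)", call. = FALSE)
  })
  L <- t(R)
  # C = L^-1 A L^-T by two triangular solves
  tmp <- forwardsolve(L, A)
  C <- t(forwardsolve(L, t(tmp)))
  C <- (C + t(C)) / 2
  list(C = C, L = L)
}

check_pencil <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B) || nrow(A) != ncol(A) ||
      any(dim(A) != dim(B)))
    stop("pencil: A and B must be square matrices of equal dimension")
  nrmA <- max(abs(A))
  if (nrmA > 0 && max(abs(A - t(A))) > 1e-12 * nrmA)
    stop("pencil: A is not symmetric")
  nrmB <- max(abs(B))
  if (max(abs(B - t(B))) > 1e-12 * nrmB)
    stop("pencil: B is not symmetric")
  invisible(TRUE)
}

#' Householder tridiagonalization of a symmetric matrix
#'
#' Reduces a symmetric matrix to tridiagonal form `T = Q' C Q` with an
#' accumulated orthogonal `Q`.  Reflector signs are chosen to avoid
#' cancellation and the off-diagonal is normalized to be non-negative.
#'
#' @param C Real symmetric matrix.
#' @return List with `diag` (length n), `offdiag` (length n-1, all
#'   `>= 0`), and `Q` (orthogonal, `Q' C Q` tridiagonal).
#' @export
tridiagonalize <- function(C) {
  n <- nrow(C)
  if (n == 0) stop("tridiagonalize: empty matrix")
  nrm <- max(abs(C))
  if (nrm > 0 && max(abs(C - t(C))) > 1e-10 * nrm)
    stop("tridiagonalize: matrix is not symmetric")
  A <- (C + t(C)) / 2
  Q <- diag(n)
  if (n > 2) {
    for (k in seq_len(n - 2)) {
      x <- A[(k + 1):n, k]
      alpha <- -sign2(x[1]) * sqrt(sum(x^2))
      if (abs(alpha) < .Machine$double.xmin) next
      v <- x
      v[1] <- v[1] - alpha
      vn2 <- sum(v^2)
      if (vn2 < .Machine$double.xmin) next
      idx <- (k + 1):n
      # similarity update of trailing block: A <- H A H, H = I - 2 v v'/v'v
      w <- drop(A[idx, idx] %*% v) * (2 / vn2)
      kap <- sum(w * v) / vn2
      A[idx, idx] <- A[idx, idx] - outer(v, w) - outer(w, v) +
        2 * kap * outer(v, v)
      A[idx, k] <- c(alpha, rep(0, n - k - 1))
      A[k, idx] <- A[idx, k]
      # accumulate Q <- Q H
      qv <- Q[, idx] %*% v
      Q[, idx] <- Q[, idx] - (2 / vn2) * qv %*% t(v)
    }
  }
  d <- diag(A)
  e <- if (n > 1) A[cbind(2:n, 1:(n - 1))] else numeric(0)
  # normalize off-diagonals to beta >= 0 by a diagonal sign similarity
  if (n > 1) {
    s <- cumprod(c(1, sign2(e)))
    e <- abs(e)
    Q <- Q * rep(s, each = n)
  }
  list(diag = d, offdiag = e, Q = Q)
}

sign2 <- function(x) ifelse(x >= 0, 1, -1)

# ---- implicit-shift QL with eigenvectors (base-case solver) -------------

# Classic tql2-style algorithm on (d, e); returns values ascending and the
# orthogonal eigenvector matrix of the tridiagonal matrix.
ql_implicit <- function(d, e, max_sweeps = 50) {
  n <- length(d)
  z <- diag(n)
  if (n == 1) return(list(values = d, vectors = z))
  e <- c(e, 0)
  for (l in seq_len(n)) {
    iter <- 0
    repeat {
      m <- l
      while (m < n) {
        dd <- abs(d[m]) + abs(d[m + 1])
        if (abs(e[m]) <= .Machine$double.eps * dd) break
        m <- m + 1
      }
      if (m == l) break
      iter <- iter + 1
      if (iter > max_sweeps) stop("ql_implicit: too many iterations")
      g <- (d[l + 1] - d[l]) / (2 * e[l])
      r <- hypot2(g, 1)
      g <- d[m] - d[l] + e[l] / (g + sign2(g) * r)
      s <- 1; cth <- 1; p <- 0
      for (i in seq(m - 1, l)) {
        f <- s * e[i]; b <- cth * e[i]
        r <- hypot2(f, g)
        e[i + 1] <- r
        if (r == 0) { d[i + 1] <- d[i + 1] - p; e[m] <- 0; break }
        s <- f / r; cth <- g / r
        g <- d[i + 1] - p
        r <- (d[i] - g) * s + 2 * cth * b
        p <- s * r
        d[i + 1] <- g + p
        g <- cth * r - b
        # eigenvector rotation
        zi <- z[, i]; zi1 <- z[, i + 1]
        z[, i + 1] <- s * zi + cth * zi1
        z[, i] <- cth * zi - s * zi1
      }
      if (r == 0 && (m - 1) >= l) next
      d[l] <- d[l] - p
      e[l] <- g
      e[m] <- 0
    }
  }
  ord <- order(d)
  list(values = d[ord], vectors = z[, ord, drop = FALSE])
}

hypot2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  hi <- pmax(a, b); lo <- pmin(a, b)
  ifelse(hi == 0, 0, hi * sqrt(1 + (lo / hi)^2))
}

# ---- secular equation ---------------------------------------------------

# Roots of f(lam) = 1 + rho * sum(z^2 / (d - lam)) for sorted d, rho > 0.
# One root per open interval (d_i, d_{i+1}) and one in
# (d_n, d_n + rho * sum(z^2)).  Each root is computed by safeguarded
# bisection in the shifted variable mu = lam - sigma, where sigma is the
# closer of the two bracketing poles: this keeps the differences
# d_j - lam accurate even when the root almost touches a pole, which is
# what the eigenvector formula needs.  Returns the roots and the stable
# difference matrix delta[j, i] = d_j - lam_i.
secular_roots <- function(d, z, rho) {
  n <- length(d)
  z2 <- z^2
  roots <- numeric(n)
  delta <- matrix(0, n, n)
  for (i in seq_len(n)) {
    gap <- if (i < n) d[i + 1] - d[i] else rho * sum(z2)
    # decide which half of the bracket holds the root
    d0_lo <- d - d[i]
    g_mid <- 1 + rho * sum(z2 / (d0_lo - gap / 2))
    if (is.finite(g_mid) && g_mid > 0) {
      sigma_idx <- i; lo <- 0; hi <- gap / 2; d0 <- d0_lo
    } else if (i < n) {
      sigma_idx <- i + 1; d0 <- d - d[i + 1]; lo <- -gap / 2; hi <- 0
    } else {
      sigma_idx <- i; lo <- gap / 2; hi <- gap; d0 <- d0_lo
    }
    g <- function(mu) 1 + rho * sum(z2 / (d0 - mu))
    # invariant: g(lo+) < 0 (pole side below root), g(hi-) > 0
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break
      gm <- g(mid)
      if (!is.finite(gm) || gm < 0) lo <- mid else hi <- mid
      if ((hi - lo) <= .Machine$double.eps * max(abs(lo), abs(hi), 1e-300))
        break
    }
    mu <- (lo + hi) / 2
    roots[i] <- d[sigma_idx] + mu
    delta[, i] <- d0 - mu
  }
  list(roots = roots, delta = delta)
}

#' Divide-and-conquer eigensolver for a symmetric tridiagonal matrix
#'
#' Computes the full spectrum and eigenvectors of the tridiagonal matrix
#' with the given diagonal and off-diagonal.  The matrix is torn at
#' `m = floor(n/2)` into two half-size blocks plus a rank-one coupling;
#' the halves are solved recursively (closed form for `n <= 2`,
#' implicit-shift QL below `base_size`) and merged through the rank-one
#' secular equation.  Couplings with `|z_i| <= tol * ||T||` and eigenvalue
#' gaps `<= tol * ||T||` are deflated.
#'
#' @param diag Length-n diagonal.
#' @param offdiag Length-(n-1) off-diagonal.
#' @param base_size Sub-problem size at or below which QL is used
#'   (default 32).
#' @param tol Relative deflation tolerance (default 1e-14).
#' @return An `eigen_result`: list with ascending `values`, orthonormal
#'   column `vectors`, and `basis = "standard"`.
#' @export
dc_eigen <- function(diag, offdiag, base_size = 32, tol = 1e-14) {
  n <- length(diag)
  if (n == 0) stop("dc_eigen: empty matrix")
  if (length(offdiag) != max(n - 1, 0))
    stop("dc_eigen: offdiag must have length n - 1")
  if (any(!is.finite(c(diag, offdiag))))
    stop("dc_eigen: non-finite entries")
  nrmT <- max(abs(diag), abs(offdiag), 0)
  res <- dc_rec(diag, offdiag, base_size, tol, nrmT)
  # stabilization: re-orthogonalize by modified Gram-Schmidt if residuals
  # degraded (can happen after heavy deflation)
  r <- tridiag_residual(diag, offdiag, res$values, res$vectors)
  if (nrmT > 0 && r > 1e-8 * nrmT) {
    res$vectors <- mgs_orthonormalize(res$vectors)
  }
  structure(list(values = res$values, vectors = res$vectors,
                 basis = "standard"), class = "eigen_result")
}

dc_rec <- function(d, e, base_size, tol, nrmT) {
  n <- length(d)
  if (n == 1) return(list(values = d, vectors = matrix(1, 1, 1)))
  if (n == 2) {
    # closed form for [[a, b], [b, c]]
    a <- d[1]; cc <- d[2]; b <- e[1]
    if (b == 0) {
      ord <- order(d)
      return(list(values = d[ord], vectors = diag(2)[, ord, drop = FALSE]))
    }
    tr <- (a + cc) / 2
    disc <- sqrt(((a - cc) / 2)^2 + b^2)
    l1 <- tr - disc; l2 <- tr + disc
    v1 <- c(b, l1 - a); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(-v1[2], v1[1])
    return(list(values = c(l1, l2), vectors = cbind(v1, v2)))
  }
  if (n <= base_size) return(ql_implicit(d, e))
  if (max(abs(e)) <= tol * max(nrmT, .Machine$double.xmin)) {
    ord <- order(d)
    return(list(values = d[ord], vectors = diag(n)[, ord, drop = FALSE]))
  }
  m <- n %/% 2
  beta <- e[m]
  if (abs(beta) <= tol * max(nrmT, .Machine$double.xmin)) {
    left <- dc_rec(d[1:m], e[seq_len(m - 1)], base_size, tol, nrmT)
    right <- dc_rec(d[(m + 1):n], e[seq(m + 1, length.out = n - m - 1)],
                    base_size, tol, nrmT)
    vals <- c(left$values, right$values)
    vecs <- matrix(0, n, n)
    vecs[1:m, 1:m] <- left$vectors
    vecs[(m + 1):n, (m + 1):n] <- right$vectors
    ord <- order(vals)
    return(list(values = vals[ord], vectors = vecs[, ord, drop = FALSE]))
  }
  # rank-one tear: T = blockdiag(T1', T2') + c u u', u = (e_m ; s e_1),
  # c = |beta| > 0, s = sign(beta)
  s <- sign2(beta)
  cpos <- abs(beta)
  d1 <- d[1:m]; d1[m] <- d1[m] - cpos
  d2 <- d[(m + 1):n]; d2[1] <- d2[1] - cpos * s * s
  left <- dc_rec(d1, e[seq_len(m - 1)], base_size, tol, nrmT)
  right <- dc_rec(d2, e[seq(m + 1, length.out = n - m - 1)], base_size, tol, nrmT)
  # z in the eigenbasis of blockdiag(T1', T2')
  z <- c(left$vectors[m, ], s * right$vectors[1, ])
  dd <- c(left$values, right$values)
  ord <- order(dd)
  dd <- dd[ord]; z <- z[ord]
  merged <- rank_one_update(dd, z, cpos, tol, nrmT)
  # back-transform vectors into the tridiagonal basis
  Qblk <- matrix(0, n, n)
  Qblk[1:m, 1:m] <- left$vectors
  Qblk[(m + 1):n, (m + 1):n] <- right$vectors
  Qblk <- Qblk[, ord, drop = FALSE]
  list(values = merged$values, vectors = Qblk %*% merged$vectors)
}

# Eigen-decomposition of diag(d) + rho z z' (d ascending, rho > 0) with
# deflation; returns values ascending and vectors in the d-basis.
rank_one_update <- function(d, z, rho, tol, nrmT) {
  n <- length(d)
  scale <- max(nrmT, rho * sum(z^2), .Machine$double.xmin)
  rot <- list()  # Givens rotations applied during deflation
  keep <- rep(TRUE, n)
  # deflate nearly equal neighbors: rotate the coupling of the later one
  # into the earlier one (error O(gap) <= tol * scale)
  i <- 1
  while (i < n) {
    j <- i + 1
    if (keep[i] && keep[j] && abs(d[j] - d[i]) <= tol * scale &&
        abs(z[i]) > 0 && abs(z[j]) > 0) {
      r <- hypot2(z[i], z[j])
      cth <- z[i] / r; sth <- z[j] / r
      z[i] <- r; z[j] <- 0
      rot[[length(rot) + 1]] <- c(i, j, cth, sth)
    }
    i <- i + 1
  }
  deflated <- abs(z) <= tol * scale
  act <- which(!deflated)
  vals <- numeric(n)
  vecs <- matrix(0, n, n)
  if (length(act) == 0) {
    vals <- d
    vecs <- diag(n)
  } else {
    sec <- secular_roots(d[act], z[act], rho)
    vals[act] <- sec$roots
    vals[deflated] <- d[deflated]
    for (k in seq_along(act)) {
      w <- numeric(n)
      w[act] <- z[act] / sec$delta[, k]
      nw <- sqrt(sum(w^2))
      if (!is.finite(nw) || nw == 0) { w[act[k]] <- 1; nw <- 1 }
      vecs[, act[k]] <- w / nw
    }
    for (k in which(deflated)) vecs[k, k] <- 1
  }
  # undo deflation rotations on the vectors
  for (g in rev(rot)) {
    i <- g[1]; j <- g[2]; cth <- g[3]; sth <- g[4]
    vi <- vecs[i, ]; vj <- vecs[j, ]
    vecs[i, ] <- cth * vi - sth * vj
    vecs[j, ] <- sth * vi + cth * vj
  }
  ord <- order(vals)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

tridiag_residual <- function(d, e, values, vectors) {
  n <- length(d)
  TV <- vectors * d
  if (n > 1) {
    TV[1:(n - 1), ] <- TV[1:(n - 1), ] + vectors[2:n, , drop = FALSE] * e
    TV[2:n, ] <- TV[2:n, ] + vectors[1:(n - 1), , drop = FALSE] * e
  }
  R <- TV - vectors %*% diag(values, n)
  max(sqrt(colSums(R^2)))
}

mgs_orthonormalize <- function(V) {
  n <- ncol(V)
  for (j in seq_len(n)) {
    v <- V[, j]
    if (j > 1) {
      for (i in seq_len(j - 1)) v <- v - sum(V[, i] * v) * V[, i]
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) V[, j] <- v / nv
  }
  V
}

#' Solve the generalized symmetric-definite eigenproblem
#'
#' Composes [cholesky_reduce()], [tridiagonalize()] and [dc_eigen()], then
#' back-transforms eigenvectors to the original basis, where they are
#' B-orthonormal (`X' B X = I`).
#'
#' @param A Real symmetric matrix.
#' @param B Real symmetric positive-definite matrix (default identity).
#' @param base_size,tol Passed to [dc_eigen()].
#' @return An `eigen_result` with `basis = "generalized"` (or
#'   `"standard"` when `B` is the identity).
#' @export
solve_generalized <- function(A, B = diag(nrow(A)), base_size = 32,
                              tol = 1e-14) {
  red <- cholesky_reduce(A, B)
  td <- tridiagonalize(red$C)
  ev <- dc_eigen(td$diag, td$offdiag, base_size = base_size, tol = tol)
  Y <- td$Q %*% ev$vectors
  X <- backsolve(t(red$L), Y)
  structure(list(values = ev$values, vectors = X, basis = "generalized"),
            class = "eigen_result")
}

#' @export
print.eigen_result <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("eigen_result: %d eigenpairs (%s basis)\n", n, x$basis))
  show <- utils::head(x$values, 8)
  cat("  values:", paste(sprintf("%.6g", show), collapse = " "),
      if (n > 8) "...\n" else "\n")
  invisible(x)
}
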