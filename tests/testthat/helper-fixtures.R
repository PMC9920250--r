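# Shared fixtures: synthetic SK tables and small systems, built once per
# test session.

sk_fix <- local({
  tabs <- NULL
  function() {
    if (is.null(tabs)) tabs <<- make_synthetic_sk(c("X", "Y", "Z"), seed = 1)
    tabs
  }
})

dimer_fix <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- load_fixture("dimers")
    d
  }
})

# dense tridiagonal matrix from (diag, offdiag)
tridiag_dense <- function(d, e) {
  n <- length(d)
  T <- diag(d, n)
  if (n > 1) {
    T[cbind(2:n, 1:(n - 1))] <- e
    T[cbind(1:(n - 1), 2:n)] <- e
  }
  T
}

# random SPD matrix
rand_spd <- function(n, jitter = 0.5) {
  M <- matrix(stats::rnorm(n * n), n)
  S <- crossprod(M) + diag(n) * jitter
  (S + t(S)) / 2
}

rand_sym <- function(n) {
  M <- matrix(stats::rnorm(n * n), n)
  (M + t(M)) / 2
}

# independent dense oracle for the generalized problem: inline Cholesky
# reduction + base eigen (LAPACK), no qmetad code paths
dense_generalized_oracle <- function(A, B) {
  R <- chol(B)
  Ri <- backsolve(R, diag(nrow(A)))
  C <- t(Ri) %*% A %*% Ri
  sort(eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
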