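# Independent oracles and small fixture builders shared across tests.

# Projected-gradient solver for the bound-constrained quadratic program
#   min 1/2 v'Qv - b'v   s.t. |v_i| <= vc
# Deliberately independent of the Growth Transform machinery.
pg_qp_oracle <- function(Q, b, vc = 1, tol = 1e-12, maxit = 2e5) {
  v <- numeric(length(b))
  eta <- 1 / (2 * norm(Q, "2"))
  for (i in seq_len(maxit)) {
    vn <- pmin(vc, pmax(-vc, v - eta * (drop(Q %*% v) - b)))
    if (max(abs(vn - v)) < tol) break
    v <- vn
  }
  vn
}

# Rank-revealing pseudo-inverse via spectral decomposition of a symmetric
# matrix (oracle for remap_weights on singular symmetric W).
spectral_pinv <- function(W, tol = 1e-10) {
  e <- eigen(W, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Seeded random symmetric coupling matrix.
random_symmetric_Q <- function(M, sd = 0.5) {
  Q <- matrix(stats::rnorm(M * M, sd = sd), M)
  (Q + t(Q)) / 2
}

# Seeded random positive-definite coupling matrix with bounded conditioning.
random_pd_Q <- function(M) {
  A <- matrix(stats::rnorm(M * M), M)
  crossprod(A) / M + 0.3 * diag(M)
}

uncoupled_net <- function(Q0 = 1, I_psi = 1, C = NULL, lam = NULL) {
  gt_network(matrix(Q0), I_psi = I_psi, C = C, lam = lam)
}
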