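# Independent oracles used across tests.  These deliberately avoid the
# package's own computational paths.

# Monte-Carlo propagation of a Gaussian belief through one model step,
# with batch-based standard errors (honest for non-Gaussian outputs).
mc_propagate <- function(belief, mats, Q, n = 2e5, n_batch = 20,
                         sp = sigmoid_params()) {
  L <- t(chol(belief$cov + 1e-18 * diag(13)))
  nb <- n %/% n_batch
  means <- array(0, c(n_batch, 13))
  covs <- array(0, c(n_batch, 13, 13))
  Lq <- t(chol(Q + 1e-30 * diag(13)))
  for (b in seq_len(n_batch)) {
    Xi <- belief$mean + L %*% matrix(stats::rnorm(nb * 13), 13, nb)
    G <- matrix(0, 4, nb)
    for (j in 1:4) {
      v <- as.numeric(mats$Cs[j, ] %*% Xi)
      G[j, ] <- Xi[mats$ia[j], ] *
        0.5 * (1 + erf_scalar((v - sp$v0) / sp$varsigma))
    }
    Y <- mats$A %*% Xi + mats$Bs %*% G +
      Lq %*% matrix(stats::rnorm(nb * 13), 13, nb)
    means[b, ] <- rowMeans(Y)
    covs[b, , ] <- stats::cov(t(Y))
  }
  list(
    mean = apply(means, 2, mean),
    mean_se = apply(means, 2, stats::sd) / sqrt(n_batch),
    cov = apply(covs, c(2, 3), mean),
    cov_se = apply(covs, c(2, 3), stats::sd) / sqrt(n_batch)
  )
}

# plain erf, independent of the package's helper
erf_scalar <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Textbook linear Kalman filter (reference implementation for the
# linear-limit equivalence check).
textbook_kf <- function(y, A, H, Q, R, mu0, P0) {
  n <- length(y)
  nx <- length(mu0)
  M <- matrix(0, n, nx)
  mu <- mu0
  P <- P0
  for (t in seq_len(n)) {
    mu <- A %*% mu
    P <- A %*% P %*% t(A) + Q
    S <- as.numeric(H %*% P %*% t(H)) + R
    K <- P %*% t(H) / S
    mu <- mu + K %*% (y[t] - H %*% mu)
    P <- P - K %*% H %*% P
    M[t, ] <- mu
  }
  M
}

# Matrix-form simulation of the neural mass model (the loop route lives in
# compiled code; this is the independent A/B/C route).
simulate_via_matrices <- function(theta_mat, sp, fs, znoise, x0 = numeric(8)) {
  mats <- build_matrices(theta_mat[1, ], sp, dt = 1 / fs)
  n <- nrow(theta_mat)
  X <- matrix(0, n, 8)
  yv <- numeric(n)
  xi <- c(x0, theta_mat[1, ])
  for (t in seq_len(n)) {
    xi[9:13] <- theta_mat[t, ]
    X[t, ] <- xi[1:8]
    yv[t] <- as.numeric(mats$H %*% xi)
    phi_vec <- numeric(13)
    act <- as.numeric(mats$C %*% xi)
    for (j in 1:4) {
      iz <- 2 * j
      phi_vec[iz] <- xi[mats$ia[j]] *
        0.5 * (1 + erf_scalar((act[iz] - sp$v0) / sp$varsigma))
    }
    xi <- as.numeric(mats$A %*% xi + mats$B %*% phi_vec)
    xi[c(2, 4, 6, 8)] <- xi[c(2, 4, 6, 8)] + znoise[t, ]
  }
  list(states = X, observation = yv)
}

# catalog used by several seizure-stats tests
make_bimodal_durations <- function(n_per = 100, meanlog = c(2.5, 4.5),
                                   sdlog = 0.3, seed = 1) {
  set.seed(seed)
  exp(c(rnorm(n_per, meanlog[1], sdlog), rnorm(n_per, meanlog[2], sdlog)))
}

# minimal trajectory-like object accepted by baseline_normalize etc.
fake_estimate <- function(time, theta) list(time = time, theta = theta)
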