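test_that("Gaussian sigmoid mean: degenerate, symmetric and shrinking", {
  sp <- sigmoid_params()
  m <- seq(-0.01, 0.02, length.out = 13)
  expect_equal(gaussian_sigmoid_mean(m, 0, sp), erf_sigmoid(m, sp),
               tolerance = 1e-14)
  expect_equal(gaussian_sigmoid_mean(sp$v0, c(0, 1e-6, 1e-4), sp),
               rep(0.5, 3))
  # shrinks toward 1/2 with growing variance
  s2 <- c(0, 1e-6, 1e-5, 1e-4)
  vals <- gaussian_sigmoid_mean(0.009, s2, sp)
  expect_true(all(diff(abs(vals - 0.5)) < 0))
  # closed form at the documented point
  expect_equal(gaussian_sigmoid_mean(0.009, 9e-6, sp),
               0.5 * (1 + erf_scalar(0.003 / sqrt(2.7e-5))),
               tolerance = 1e-12)
  expect_error(gaussian_sigmoid_mean(0, -1, sp))
})

test_that("Gaussian sigmoid slope: degenerate limit and closed form", {
  sp <- sigmoid_params()
  # at s2 = 0 equals phi'(m); at m = v0 equals 1/(varsigma sqrt(pi))
  m <- seq(-0.01, 0.02, length.out = 7)
  expect_equal(gaussian_sigmoid_slope_mean(m, 0, sp),
               erf_sigmoid_slope(m, sp), tolerance = 1e-12)
  expect_equal(gaussian_sigmoid_slope_mean(sp$v0, 0, sp),
               1 / (0.003 * sqrt(pi)), tolerance = 1e-12)
  expect_lt(gaussian_sigmoid_slope_mean(sp$v0, 1e4, sp), 1e-2)
  expect_true(all(gaussian_sigmoid_slope_mean(m, 1e-5, sp) > 0))
})

test_that("sigmoid moments match Monte-Carlo on a coarse grid", {
  sp <- sigmoid_params()
  set.seed(42)
  n <- 2e5
  for (m in c(0, 0.006, 0.012)) {
    for (s in c(1e-3, 5e-3)) {
      v <- rnorm(n, m, s)
      ph <- erf_sigmoid(v, sp)
      z1 <- abs(gaussian_sigmoid_mean(m, s^2, sp) - mean(ph)) /
        (sd(ph) / sqrt(n))
      dph <- erf_sigmoid_slope(v, sp)
      z2 <- abs(gaussian_sigmoid_slope_mean(m, s^2, sp) - mean(dph)) /
        (sd(dph) / sqrt(n))
      expect_lt(z1, 4)
      expect_lt(z2, 4)
    }
  }
})

test_that("prediction reduces to the linear Kalman form without coupling", {
  # all gains zero with zero parameter uncertainty: model is linear
  mats <- build_matrices(dt = 1 / 400)
  set.seed(1)
  A0 <- matrix(rnorm(169), 13)
  P <- crossprod(A0) * 1e-6
  P[9:13, ] <- 0
  P[, 9:13] <- 0
  mu <- c(rnorm(8, 0, 3e-3), rep(0, 5))
  bel <- gaussian_belief(mu, P)
  Q <- diag(rep(1e-9, 13))
  pred <- adf_predict(bel, mats, Q)
  expect_equal(pred$mean, as.numeric(mats$A %*% mu), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pred$cov, mats$A %*% P %*% t(mats$A) + Q, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-covariance belief predicts one deterministic model step", {
  mats <- build_matrices(dt = 1 / 400)
  sp <- sigmoid_params()
  th <- ref_params()
  x0 <- c(rep(2e-3, 8))
  bel <- gaussian_belief(c(x0, th), matrix(0, 13, 13))
  Q <- diag(rep(1e-10, 13))
  pred <- adf_predict(bel, mats, Q)
  step <- simulate_nmm(matrix(th, 2, 5, byrow = TRUE), sp, fs = 400,
                       x0 = x0)
  expect_equal(pred$mean[1:8], step$states[2, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(pred$cov - Q)), 1e-16)
})

test_that("prediction matches Monte-Carlo propagation on random beliefs", {
  # a fast, low-n version of the moment-oracle contract (the full 20-belief
  # 1e6-sample suite runs in the acceptance tests)
  mats <- build_matrices(dt = 1 / 400)
  th <- ref_params()
  set.seed(7)
  for (rep in 1:3) {
    mu <- c(rnorm(8, 0, 0.005), th * (1 + rnorm(5, 0, 0.2)))
    A0 <- matrix(rnorm(169), 13)
    P <- crossprod(A0) * 1e-6
    D <- diag(c(rep(1, 8), abs(th) * 30))
    P <- D %*% P %*% D
    bel <- gaussian_belief(mu, P)
    Q <- diag(rep(1e-8, 13))
    pred <- adf_predict(bel, mats, Q)
    mc <- mc_propagate(bel, mats, Q, n = 1e5)
    expect_lt(max(abs(pred$mean - mc$mean) / mc$mean_se), 5)
    expect_lt(max(abs(pred$cov - mc$cov) / mc$cov_se), 5)
  }
})

test_that("update reproduces scalar Kalman arithmetic and sanity limits", {
  H <- matrix(c(1, rep(0, 12)), 1, 13)
  P <- diag(13)
  prior <- gaussian_belief(rep(0, 13), P)
  up <- adf_update(prior, y = 2, H = H, R = 1)
  expect_equal(up$belief$mean[1], 1, ignore_attr = TRUE)
  expect_equal(up$belief$cov[1, 1], 0.5)
  expect_equal(up$innovation, 2)
  # effectively infinite noise: posterior ~ prior
  up2 <- adf_update(prior, y = 2, H = H, R = 1e12)
  expect_lt(max(abs(up2$belief$mean)), 1e-10)
  expect_equal(up2$belief$cov, P, tolerance = 1e-10)
  # information never increases variance
  set.seed(2)
  A0 <- matrix(rnorm(169), 13)
  P2 <- crossprod(A0)
  pr <- gaussian_belief(rnorm(13), P2)
  up3 <- adf_update(pr, 0.3, matrix(rnorm(13), 1, 13), 0.5)
  expect_true(all(diag(up3$belief$cov) <= diag(P2) + 1e-12))
})

test_that("initialization estimates R from baseline and honors overrides", {
  set.seed(11)
  fs <- 400
  base <- rnorm(1e4, sd = 2e-3)
  cfg <- filter_config(r_obs = 1.23e-6)
  init <- adf_initialize(base, fs, cfg)
  expect_equal(init$R, 1.23e-6)
  expect_true(all(init$belief$mean[1:8] == 0))
  expect_equal(init$belief$mean[9:13], cfg$theta0, ignore_attr = TRUE)
  expect_equal(init$belief$cov, diag(diag(init$belief$cov)))
  # white-noise baseline, high-pass disabled: R ~ sample variance
  cfg2 <- filter_config(r_highpass_hz = NULL)
  init2 <- adf_initialize(base, fs, cfg2)
  expect_lt(abs(init2$R - 4e-6) / 4e-6, 0.10)
  # white-noise baseline with the spectral high-pass proxy
  init3 <- adf_initialize(base, fs, filter_config())
  expect_lt(abs(init3$R - 4e-6) / 4e-6, 0.25)
  expect_error(adf_initialize(rep(1, 100), fs, cfg2))
})

test_that("filter equals an independent textbook KF in the linear limit", {
  fs <- 400
  n <- 2000  # the full 1e4-sample check runs in the acceptance tests
  cfg <- filter_config(theta0 = rep(0, 5), p0_param = 0, q_param_rel = 0,
                       p0_state = 1e-6, q_state_sd = 1, r_obs = 1e-6)
  mats <- build_matrices(cfg$theta0, cfg$sp, dt = 1 / fs)
  set.seed(4)
  y <- rnorm(n, sd = 1e-3)
  init <- adf_initialize(y, fs, cfg)
  est <- run_filter(y, fs, cfg, init = init)
  ref <- textbook_kf(y, mats$A, mats$H, init$Q, init$R,
                     init$belief$mean, init$belief$cov)
  expect_true(est$valid)
  expect_lt(max(abs(est$mean - ref)), 1e-10)
})

test_that("a NaN observation invalidates the trajectory from that sample", {
  set.seed(9)
  y <- rnorm(500, sd = 1e-3)
  y[301] <- NaN
  cfg <- filter_config(r_obs = 1e-6)
  est <- run_filter(y, 400, cfg)
  expect_false(est$valid)
  expect_equal(est$diagnostics$first_bad, 301)
  expect_true(all(is.finite(est$mean[1:300, ])))
  expect_true(all(is.na(est$mean[301:500, ])))
})

test_that("posterior covariance stays symmetric and PSD along a run", {
  th <- ref_params()
  sim <- simulate_nmm(th, fs = 400, duration = 4, process_noise_sd = 0.05,
                      obs_noise_sd = 3e-4, seed = 21)
  cfg <- filter_config(r_obs = 9e-8, q_state_sd = 0.05 / 3e-4)
  est <- run_filter(sim$observation, 400, cfg)
  expect_true(est$valid)
  expect_true(all(est$var >= 0, na.rm = TRUE))
  Pf <- est$diagnostics$final_cov
  expect_lt(max(abs(Pf - t(Pf))), 1e-10)
  expect_gt(min(eigen(Pf, symmetric = TRUE, only.values = TRUE)$values),
            -1e-12 * sum(diag(Pf)))
})

test_that("innovations are white on matched-model data", {
  th <- ref_params()
  pn <- 0.05; on <- 3e-4
  sim <- simulate_nmm(th, fs = 400, duration = 25, process_noise_sd = pn,
                      obs_noise_sd = on, seed = 31)
  cfg <- filter_config(theta0 = th, r_obs = on^2, q_state_sd = pn / on)
  est <- run_filter(sim$observation, 400, cfg)
  innov <- est$diagnostics$innovation
  rho1 <- cor(innov[-1], innov[-length(innov)])
  expect_lt(abs(rho1), 0.1)
})

test_that("known constant parameters are recovered on matched data", {
  th <- ref_params()
  pn <- 0.05; on <- 3e-4
  sim <- simulate_nmm(th, fs = 400, duration = 120, process_noise_sd = pn,
                      obs_noise_sd = on, seed = 2)
  cfg <- filter_config(theta0 = th * c(1, 0.8, 1.2, 0.9, 1.1),
                       r_obs = on^2, q_state_sd = pn / on)
  est <- run_filter(sim$observation, 400, cfg)
  expect_true(est$valid)
  n <- nrow(est$mean)
  fin <- colMeans(est$mean[(2 * n / 3):n, 9:13])
  # smoke-level bound for a single seed; the strict 10%-on-9-of-10-seeds
  # contract runs in the acceptance tests
  expect_true(all(abs(fin - th) / th < 0.15))
})

test_that("forward reconstruction reproduces a noise-free simulation", {
  th <- ref_params()
  sim <- simulate_nmm(th, fs = 400, duration = 6)
  est <- list(valid = TRUE, fs = 400,
              mean = cbind(sim$states, sim$params_used))
  class(est) <- "sp_estimate"
  rec <- reconstruct_forward(est)
  expect_gt(cor(rec$observation, sim$observation), 0.99)
  rec2 <- reconstruct_forward(est)
  expect_identical(rec$observation, rec2$observation)
  # constant sub-threshold parameters: bounded, non-oscillatory output
  quiet <- simulate_nmm(connectivity_params(0.001, 0.1, 0.1, 0.1, 0.1),
                        fs = 400, duration = 4)
  tail_obs <- quiet$observation[801:1600]
  expect_lt(diff(range(tail_obs)), 1e-6)
  est$valid <- FALSE
  expect_error(reconstruct_forward(est))
})
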