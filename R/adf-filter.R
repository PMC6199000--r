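# Assumed-density (Kalman) filter for joint state + connectivity estimation.
#
# The belief over the augmented state xi = [x; theta] is kept Gaussian.
# Prediction pushes it through xi' = A xi + B g(xi) + w with g_j =
# theta_j * phi(v_j), using exact Gaussian moments for E[g] and Cov(xi, g)
# (Stein's identity through the erf sigmoid) and Gauss-Hermite quadrature
# for the 4x4 Cov(g) block; the update is a standard linear Kalman step in
# Joseph form.

#' Gaussian expectation of the erf sigmoid
#'
#' E\[phi(V)\] for V ~ N(m, s2) in closed form:
#' (1 + erf((m - v0) / sqrt(varsigma^2 + 2 s2))) / 2.  Reduces to
#' [erf_sigmoid()] at `s2 = 0` and shrinks toward 1/2 as `s2` grows.
#'
#' @param m Mean membrane potential(s), volts.
#' @param s2 Variance(s), volts^2 (>= 0).
#' @param sp [sigmoid_params()].
#' @return Expected firing-rate fraction(s) in (0, 1).
#' @export
gaussian_sigmoid_mean <- function(m, s2, sp = sigmoid_params()) {
  stopifnot(all(s2 >= 0))
  n <- max(length(m), length(s2))
  .cpp_gauss_sig_mean(rep_len(as.numeric(m), n), rep_len(as.numeric(s2), n),
                      sp$v0, sp$varsigma)
}

#' Gaussian expectation of the sigmoid derivative
#'
#' E\[phi'(V)\] for V ~ N(m, s2):
#' exp(-(m - v0)^2 / (varsigma^2 + 2 s2)) / sqrt(pi (varsigma^2 + 2 s2)).
#'
#' @inheritParams gaussian_sigmoid_mean
#' @return Expected slope(s), 1/volt; positive, tending to 0 for large `s2`.
#' @export
gaussian_sigmoid_slope_mean <- function(m, s2, sp = sigmoid_params()) {
  stopifnot(all(s2 >= 0))
  n <- max(length(m), length(s2))
  .cpp_gauss_sig_slope(rep_len(as.numeric(m), n), rep_len(as.numeric(s2), n),
                       sp$v0, sp$varsigma)
}

#' Gauss-Hermite nodes and weights (probabilist-normalized)
#'
#' Golub-Welsch nodes for the physicists' weight exp(-x^2), with weights
#' pre-divided by sqrt(pi) so that E\[f(Z)\] for Z ~ N(0,1) is
#' sum(w * f(sqrt(2) * x)).
#'
#' @param order Number of nodes (default 9).
#' @return List with `x`, `w` (weights summing to 1).
#' @export
gauss_hermite <- function(order = 9) {
  stopifnot(order >= 1)
  if (order == 1) return(list(x = 0, w = 1))
  i <- seq_len(order - 1)
  J <- matrix(0, order, order)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ord])^2)
}

#' Gaussian belief over the augmented state
#'
#' @param mean Length-13 mean vector (8 states then 5 parameters).
#' @param cov 13x13 covariance; symmetrized on construction.
#' @return List of class `sp_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  stopifnot(length(mean) == 13, all(dim(cov) == c(13, 13)))
  cov <- 0.5 * (cov + t(cov))
  structure(list(mean = stats::setNames(as.numeric(mean), xi_names()),
                 cov = cov), class = "sp_belief")
}

#' One assumed-density prediction step
#'
#' Propagates a Gaussian belief through the augmented model, returning the
#' a-priori belief.  Means and cross-covariances of the nonlinear terms are
#' exact; the nonlinear-nonlinear covariance block uses Gauss-Hermite
#' quadrature of the configured order.
#'
#' @param belief [gaussian_belief()].
#' @param mats [build_matrices()] output.
#' @param Q 13x13 process-noise covariance.
#' @param gh_order Quadrature order for the one-dimensional integrals that
#'   remain after the semi-analytic reduction (default 31).
#' @param gh_order_wide Order used instead when an integral's outer
#'   standard deviation exceeds the sigmoid slope scale (the integrand is
#'   then close to a step times a quadratic and needs far more nodes;
#'   default 201).  Wide beliefs occur at initialization, so the extra
#'   cost is paid only on early samples.
#' @return A-priori `sp_belief`.
#' @export
adf_predict <- function(belief, mats, Q, gh_order = 31,
                        gh_order_wide = 201) {
  gh <- gauss_hermite(gh_order)
  gh2 <- gauss_hermite(max(gh_order_wide, gh_order))
  out <- .cpp_adf_predict(belief$mean, belief$cov, mats$A, mats$Bs, mats$Cs,
                          mats$ia - 1L, Q, mats$sp$v0, mats$sp$varsigma,
                          gh$x, gh$w, gh2$x, gh2$w)
  gaussian_belief(out$mean, out$cov)
}

#' Linear Kalman measurement update
#'
#' Standard update against a scalar observation with row matrix `H` and
#' noise variance `R`; the posterior covariance uses the Joseph form
#' (algebraically identical to (I - KH)P, numerically stabler).
#'
#' @param prior `sp_belief`.
#' @param y Observed sample, volts.
#' @param H 1x13 observation row.
#' @param R Observation-noise variance (> 0).
#' @return List `belief` (posterior), `innovation`, `gain`.
#' @export
adf_update <- function(prior, y, H, R) {
  stopifnot(R > 0)
  P <- prior$cov
  Ht <- t(H)
  s <- as.numeric(H %*% P %*% Ht) + R
  if (!is.finite(s) || s <= 0) stop("innovation variance <= 0: filter unstable")
  K <- (P %*% Ht) / s
  e <- as.numeric(y - H %*% prior$mean)
  mu <- prior$mean + as.numeric(K) * e
  IKH <- diag(13) - K %*% H
  P2 <- IKH %*% P %*% t(IKH) + R * (K %*% t(K))
  list(belief = gaussian_belief(mu, P2), innovation = e,
       gain = as.numeric(K))
}

#' Filter configuration
#'
#' All tunables of the estimator with their defaults.  Process noise is
#' applied to the z-states and (as a random walk) to the parameters.  The
#' z-state scale is a multiple of the observation-noise SD (the filter's
#' freedom scales with the recording's noise floor); the parameter
#' random-walk SD is relative to each parameter's nominal magnitude, so
#' all five parameters drift at comparable fractional rates despite
#' spanning three orders of magnitude.  `r_obs` overrides the baseline
#' estimate of the observation-noise variance when non-NULL.
#'
#' @param theta0 Nominal parameter initialization (default [ref_params()]).
#' @param p0_state Initial variance of each membrane-potential state, V^2.
#' @param p0_param Initial parameter variances: length 5 or scalar; default
#'   (0.3 * theta0)^2, floored at `p0_param_min`.
#' @param p0_param_min Floor for the initial parameter variance.
#' @param q_state_sd Per-step z-state process noise SD, as a multiple of
#'   sqrt(R).
#' @param q_param_rel Per-step parameter random-walk SD, as a fraction of
#'   each parameter's `|theta0|`.
#' @param r_obs Optional fixed observation-noise variance, V^2.
#' @param r_highpass_hz Cutoff of the high-pass used to estimate R from a
#'   baseline segment; `NULL` disables the high-pass (plain variance).
#' @param gh_order Gauss-Hermite order for the prediction's remaining 1-D
#'   integrals.
#' @param gh_order_wide Order used when a belief is wider than the sigmoid
#'   slope scale (see [adf_predict()]).
#' @param sp [sigmoid_params()].
#' @return List of class `sp_filter_config`.
#' @export
filter_config <- function(theta0 = ref_params(),
                          p0_state = 1e-4,
                          p0_param = NULL,
                          p0_param_min = 1e-6,
                          q_state_sd = 150,
                          q_param_rel = 3e-3,
                          r_obs = NULL,
                          r_highpass_hz = 100,
                          gh_order = 31,
                          gh_order_wide = 201,
                          sp = sigmoid_params()) {
  if (is.null(p0_param)) p0_param <- pmax((0.3 * theta0)^2, p0_param_min)
  p0_param <- rep_len(p0_param, 5)
  structure(as.list(environment()), class = "sp_filter_config")
}

#' Initialize the filter from a pre-seizure baseline
#'
#' State means start at zero, parameter means at the configured nominal
#' values; the initial covariance is diagonal.  The observation-noise
#' variance R is estimated as the variance of the baseline signal after a
#' high-pass (a proxy for the white-noise floor, rescaled by the retained
#' bandwidth fraction), unless overridden in the config.  Process noise Q
#' is diagonal with separate state and parameter scales tied to sqrt(R).
#'
#' @param baseline Numeric vector of baseline samples (one channel).
#' @param fs Sampling rate, Hz.
#' @param config [filter_config()].
#' @return List `belief` (initial `sp_belief`), `Q` (13x13), `R` (scalar).
#' @export
adf_initialize <- function(baseline, fs, config = filter_config()) {
  stopifnot(length(baseline) > 1)
  if (stats::var(baseline) == 0) {
    stop("baseline segment is constant; cannot estimate observation noise")
  }
  R <- config$r_obs
  if (is.null(R)) {
    hp <- config$r_highpass_hz
    if (is.null(hp)) {
      R <- stats::var(baseline)
    } else {
      ny <- fs / 2
      stopifnot(hp < ny)
      bf <- signal::butter(2, hp / ny, type = "high")
      res <- signal::filtfilt(bf, baseline - mean(baseline))
      R <- stats::var(res) * ny / (ny - hp)
    }
  }
  stopifnot(R > 0)
  mu <- c(numeric(8), config$theta0)
  P0 <- diag(c(rep(config$p0_state, 8), config$p0_param))
  sd_obs <- sqrt(R)
  qz <- (config$q_state_sd * sd_obs)^2
  qp <- (config$q_param_rel * pmax(abs(config$theta0), 1e-8))^2
  qdiag <- numeric(13)
  qdiag[synapse_set()$iz] <- qz
  qdiag[9:13] <- qp
  list(belief = gaussian_belief(mu, P0), Q = diag(qdiag), R = R)
}

#' Run the assumed-density filter over one channel
#'
#' Applies predict + update at every sample ("no loss of temporal
#' resolution").  The trajectory is marked invalid from the first sample at
#' which the estimate becomes non-finite, the innovation variance is
#' non-positive, or the covariance cannot be repaired to PSD by a single
#' jitter; invalid trajectories are excluded downstream.
#'
#' @param y Numeric observation vector (one channel), volts.
#' @param fs Sampling rate, Hz.
#' @param config [filter_config()].
#' @param init Optional output of [adf_initialize()]; if `NULL`, the first
#'   `baseline_s` seconds of `y` are used as the baseline.
#' @param baseline_s Seconds of leading data used for initialization when
#'   `init` is NULL (default 30, capped at the segment length).
#' @param t0 Time of the first sample (seconds, e.g. relative to onset).
#' @param store_gain Keep the per-sample Kalman gain (memory-heavy).
#' @return List of class `sp_estimate`: `time`, `mean` (n x 13), `var`
#'   (n x 13), `diagnostics` (innovation, mse, first_bad, optional gain),
#'   `valid`, `fs`, `R`, `Q`, `config`.
#' @export
run_filter <- function(y, fs, config = filter_config(), init = NULL,
                       baseline_s = 30, t0 = 0, store_gain = FALSE) {
  stopifnot(length(y) > 0, fs > 0)
  if (is.null(init)) {
    nb <- max(2L, min(length(y), round(baseline_s * fs)))
    base <- y[seq_len(nb)]
    base <- base[is.finite(base)]
    if (length(base) < 2) stop("too few finite baseline samples")
    init <- adf_initialize(base, fs, config)
  }
  mats <- build_matrices(config$theta0, config$sp, dt = 1 / fs)
  gh <- gauss_hermite(config$gh_order)
  gh2 <- gauss_hermite(max(config$gh_order_wide %||% 201, config$gh_order))
  out <- .cpp_run_filter(as.numeric(y), mats$A, mats$Bs, mats$Cs,
                         mats$ia - 1L, init$Q, mats$H, init$R,
                         init$belief$mean, init$belief$cov,
                         config$sp$v0, config$sp$varsigma, gh$x, gh$w,
                         gh2$x, gh2$w, store_gain)
  colnames(out$mean) <- colnames(out$var) <- xi_names()
  diagnostics <- list(innovation = as.numeric(out$innovation),
                      mse = out$mse, first_bad = out$first_bad,
                      final_cov = out$final_cov)
  if (store_gain) diagnostics$gain <- out$gain
  structure(list(
    time = t0 + (seq_along(y) - 1) / fs,
    mean = out$mean, var = out$var,
    diagnostics = diagnostics,
    valid = out$first_bad == 0,
    fs = fs, R = init$R, Q = init$Q, config = config
  ), class = "sp_estimate")
}

#' @export
print.sp_estimate <- function(x, ...) {
  cat(sprintf("<sp_estimate> %d samples at %g Hz; valid: %s; mse: %.3g\n",
              length(x$time), x$fs, x$valid,
              if (is.na(x$diagnostics$mse)) NA else x$diagnostics$mse))
  invisible(x)
}

#' Extract the parameter trajectory from an estimate
#'
#' @param est `sp_estimate`.
#' @return n x 5 matrix of posterior parameter means.
#' @export
theta_trajectory <- function(est) est$mean[, 9:13, drop = FALSE]

#' Deterministic forward reconstruction from estimated parameters
#'
#' Re-simulates the neural mass model driven by the filtered time-varying
#' parameter estimates, with no process or observation noise.  Used to
#' check that the estimated effective connectivity reproduces the recorded
#' seizure.
#'
#' @param est A valid `sp_estimate`.
#' @param sp [sigmoid_params()].
#' @param x0 Initial state (default: the filter's first state estimate).
#' @return `sp_simulation`.
#' @export
reconstruct_forward <- function(est, sp = sigmoid_params(), x0 = NULL) {
  if (!isTRUE(est$valid)) stop("cannot reconstruct from an invalid estimate")
  if (is.null(x0)) x0 <- est$mean[1, 1:8]
  simulate_nmm(theta = theta_trajectory(est), sp = sp, fs = est$fs, x0 = x0)
}

#' Write an estimate as tidy CSV
#'
#' Columns: `time_s`, 13 posterior means, 13 posterior variances.
#'
#' @param est `sp_estimate`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(est, path) {
  m <- est$mean; v <- est$var
  colnames(m) <- paste0("mean_", xi_names())
  colnames(v) <- paste0("var_", xi_names())
  utils::write.csv(data.frame(time_s = est$time, m, v, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
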