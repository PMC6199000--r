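#' @useDynLib seizurepath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Augmented-state layout (13 entries), fixed throughout the package:
#   1 v_ep  2 z_ep  3 v_ip  4 z_ip  5 v_pe  6 z_pe  7 v_pi  8 z_pi
#   9 u    10 a_ep 11 a_ip 12 a_pe 13 a_pi
# Synapse labels are pre->post: e->p, i->p, p->e, p->i.

#' Names of the five estimated connectivity parameters
#'
#' Order is fixed: external input `u`, then the four lumped connectivity
#' gains in pre->post labels (`alpha_ep` = excitatory-to-pyramidal,
#' `alpha_ip` = inhibitory-to-pyramidal, `alpha_pe`, `alpha_pi`).
#'
#' @return Character vector of length 5.
#' @export
theta_names <- function() c("u", "alpha_ep", "alpha_ip", "alpha_pe", "alpha_pi")

state_names <- function() {
  c("v_ep", "z_ep", "v_ip", "z_ip", "v_pe", "z_pe", "v_pi", "z_pi")
}

xi_names <- function() c(state_names(), theta_names())

#' Firing-rate sigmoid parameters
#'
#' The population firing-rate nonlinearity is an erf sigmoid with threshold
#' `v0` and slope scale `varsigma`.  Defaults are the standard values
#' v0 = 6 mV and varsigma = 3 mV, expressed in the requested unit
#' convention (internal computations are unit-homogeneous, so either
#' convention may be used throughout as long as it is used consistently).
#'
#' @param v0 Firing threshold (volts by default).
#' @param varsigma Sigmoid slope scale; must be positive.
#' @param units `"V"` (default) or `"mV"`; scales the defaults only.
#' @return List with elements `v0`, `varsigma`, `units`.
#' @export
sigmoid_params <- function(v0 = NULL, varsigma = NULL, units = c("V", "mV")) {
  units <- match.arg(units)
  sc <- if (units == "mV") 1e3 else 1
  if (is.null(v0)) v0 <- 0.006 * sc
  if (is.null(varsigma)) varsigma <- 0.0030 * sc
  stopifnot(is.finite(v0), is.finite(varsigma), varsigma > 0)
  list(v0 = v0, varsigma = varsigma, units = units)
}

#' Erf firing-rate sigmoid
#'
#' phi(v) = (1 + erf((v - v0)/varsigma)) / 2, the fraction of the
#' population's maximum firing rate at mean membrane potential `v`.
#'
#' @param v Membrane potential(s), same units as `sp`.
#' @param sp A [sigmoid_params()] list.
#' @return Values in (0, 1); 0.5 exactly at `v = v0`.
#' @export
erf_sigmoid <- function(v, sp = sigmoid_params()) {
  0.5 * (1 + erf((v - sp$v0) / sp$varsigma))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Derivative of the erf sigmoid
#' @inheritParams erf_sigmoid
#' @return phi'(v), units 1/volt.
#' @export
erf_sigmoid_slope <- function(v, sp = sigmoid_params()) {
  exp(-((v - sp$v0) / sp$varsigma)^2) / (sp$varsigma * sqrt(pi))
}

#' The four synapses of the three-population model
#'
#' Pyramidal (p), excitatory interneuron (e) and inhibitory interneuron (i)
#' populations are connected by four synapses.  Time constants follow the
#' standard Jansen-Rit values: 10 ms for the excitatory kernels and 20 ms
#' for the slower inhibitory kernel (i->p).  `sign` is -1 only for the
#' inhibitory-presynaptic synapse; the sign is carried in the observation
#' and potential-assembly rows so that all gains alpha stay non-negative by
#' convention.
#'
#' @return data.frame with columns `pre`, `post`, `tau` (seconds), `sign`,
#'   and the state/parameter indices `iv`, `iz`, `ia` into the augmented
#'   state vector.
#' @export
synapse_set <- function() {
  data.frame(
    pre = c("e", "i", "p", "p"),
    post = c("p", "p", "e", "i"),
    tau = c(0.010, 0.020, 0.010, 0.010),
    sign = c(1L, -1L, 1L, 1L),
    iv = c(1L, 3L, 5L, 7L),
    iz = c(2L, 4L, 6L, 8L),
    ia = c(10L, 11L, 12L, 13L),
    stringsAsFactors = FALSE
  )
}

#' Connectivity parameter vector
#'
#' Assembles the theta vector [u, alpha_ep, alpha_ip, alpha_pe, alpha_pi].
#' `u` is the external (non-local) input to the pyramidal population in
#' volts; the alphas are lumped connectivity gains (synaptic gain x
#' connection count x maximum firing rate) and are non-negative by
#' convention (inhibition's sign lives in the model structure).
#'
#' @param u External input, volts.
#' @param alpha_ep,alpha_ip,alpha_pe,alpha_pi Lumped gains.
#' @return Named numeric vector of length 5.
#' @export
connectivity_params <- function(u, alpha_ep, alpha_ip, alpha_pe, alpha_pi) {
  th <- c(u, alpha_ep, alpha_ip, alpha_pe, alpha_pi)
  stopifnot(all(is.finite(th)), all(th[-1] >= 0))
  stats::setNames(th, theta_names())
}

#' Reference oscillatory parameter set
#'
#' A documented baseline producing bounded, oscillatory pyramidal output
#' under the erf sigmoid, derived by lumping the classic Jansen-Rit
#' constants (He = 3.25 mV, Hi = 22 mV, C = 135, maximum rate 5/s) into the
#' gain convention used here (alpha_mn = H_pre * C_mn * rate_max, steady
#' state v = alpha * tau * phi).  The external input u is set inside the
#' oscillatory regime of the model.
#'
#' @return Named theta vector (see [connectivity_params()]).
#' @export
ref_params <- function() {
  C1 <- 135; C2 <- 0.8 * C1; C3 <- 0.25 * C1; C4 <- 0.25 * C1
  He <- 0.00325; Hi <- 0.022; r <- 5
  connectivity_params(
    u = 0.0055,
    alpha_ep = He * C2 * r,
    alpha_ip = Hi * C4 * r,
    alpha_pe = He * C1 * r,
    alpha_pi = He * C3 * r
  )
}

#' Pyramidal membrane potential
#'
#' v_p = v_ep - v_ip + u: the excitatory-to-pyramidal PSP minus the
#' inhibitory-to-pyramidal PSP plus the external input.  This combination
#' is also what the electrode observes.
#'
#' @param state Numeric vector of the 8 synaptic states (or a full
#'   13-entry augmented state, in which case `u` defaults to its entry).
#' @param u External input, volts.
#' @return Scalar potential, volts.
#' @export
pyramidal_potential <- function(state, u = NULL) {
  if (length(state) >= 13 && is.null(u)) u <- state[9]
  if (is.null(u)) u <- 0
  unname(state[1] - state[3] + u)
}

#' Discrete-time system matrices of the augmented model
#'
#' Builds the 13x13 matrices of the discretized augmented model
#' xi_t = A xi_{t-1} + B phi_vec(C xi_{t-1}) + w.  Each second-order
#' synaptic kernel is critically damped with a repeated eigenvalue -1/tau,
#' so its zero-order-hold discretization is available in closed form: with
#' E = exp(-dt/tau) the homogeneous block is
#' \[\[E(1+dt/tau), E dt\], \[-E dt/tau^2, E(1-dt/tau)\]\] and the held
#' nonlinear drive alpha*phi enters the v- and z-rows with weights
#' tau*(1 - E*(1+dt/tau)) and dt*E/tau respectively (the explicit-Euler
#' weights 0 and dt/tau are their first-order limits; the exact form is
#' used because at 400 Hz forward Euler audibly detunes the model's limit
#' cycle).  The parameter block of A is the identity (random-walk
#' parameters).  The active rows of C form each synapse's presynaptic
#' membrane potential (for pyramidal-presynaptic synapses this is
#' v_ep - v_ip + u, carrying the inhibitory minus sign).  H is the
#' observation row selecting the pyramidal potential.
#'
#' @param theta Named theta vector (only used for validation; the matrices
#'   themselves do not depend on theta, which enters through the nonlinear
#'   vector).
#' @param sp [sigmoid_params()].
#' @param dt Time step, seconds (> 0).
#' @return List with `A`, `B`, `C` (13x13), `H` (1x13), `Bs` (13x4 compact
#'   routing), `Cs` (4x13 active rows), `ia` (theta index per synapse),
#'   `dt`, `sp`, `syn`.
#' @export
build_matrices <- function(theta = ref_params(), sp = sigmoid_params(),
                           dt = 1 / 400) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  stopifnot(length(theta) == 5, all(is.finite(theta)))
  syn <- synapse_set()
  n <- 13L
  A <- diag(n)
  B <- matrix(0, n, n)
  C <- matrix(0, n, n)
  Bs <- matrix(0, n, 4)
  Cs <- matrix(0, 4, n)
  vp_row <- numeric(n)
  vp_row[c(1, 3, 9)] <- c(1, -1, 1)  # v_ep - v_ip + u
  for (j in seq_len(4)) {
    iv <- syn$iv[j]; iz <- syn$iz[j]; tau <- syn$tau[j]
    E <- exp(-dt / tau)
    A[iv, iv] <- E * (1 + dt / tau)
    A[iv, iz] <- E * dt
    A[iz, iv] <- -E * dt / tau^2
    A[iz, iz] <- E * (1 - dt / tau)
    bv <- tau * (1 - E * (1 + dt / tau))
    bz <- dt * E / tau
    B[iv, iz] <- bv
    B[iz, iz] <- bz
    Bs[iv, j] <- bv
    Bs[iz, j] <- bz
    crow <- numeric(n)
    if (syn$pre[j] == "e") crow[5] <- 1          # v_e = v_pe
    if (syn$pre[j] == "i") crow[7] <- 1          # v_i = v_pi
    if (syn$pre[j] == "p") crow <- vp_row        # v_p
    C[iz, ] <- crow
    Cs[j, ] <- crow
  }
  H <- matrix(vp_row, 1, n)
  dimnames(A) <- dimnames(B) <- dimnames(C) <- list(xi_names(), xi_names())
  colnames(H) <- xi_names()
  list(A = A, B = B, C = C, H = H, Bs = Bs, Cs = Cs,
       ia = syn$ia, dt = dt, sp = sp, syn = syn)
}

#' Simulate the neural mass model
#'
#' Integrates the model with explicit Euler steps at `1/fs`, driven by a
#' fixed or time-varying parameter vector.  Process noise (if any) is added
#' to the z-states only (the v-states are exact integrals of z); the
#' observation is the pyramidal potential plus white observation noise.
#' With both noise SDs zero the trajectory is deterministic; identical
#' seeds give identical output.
#'
#' @param theta A named theta vector, or an (n x 5) matrix giving theta at
#'   every sample.
#' @param sp [sigmoid_params()].
#' @param fs Sampling rate, Hz.
#' @param duration Seconds (ignored when `theta` is a matrix).
#' @param process_noise_sd SD of per-step noise on each z-state
#'   (volts/second units of z).
#' @param obs_noise_sd SD of observation noise, volts.
#' @param seed Optional integer seed.
#' @param x0 Initial 8-entry state (default zeros).
#' @return List of class `sp_simulation` with `time`, `states` (n x 8),
#'   `observation` (noisy), `observation_clean`, `params_used` (n x 5),
#'   `fs`, `seed`.
#' @export
simulate_nmm <- function(theta = ref_params(), sp = sigmoid_params(),
                         fs = 400, duration = NULL,
                         process_noise_sd = 0, obs_noise_sd = 0,
                         seed = NULL, x0 = numeric(8)) {
  stopifnot(fs > 0, process_noise_sd >= 0, obs_noise_sd >= 0)
  if (is.matrix(theta)) {
    n <- nrow(theta)
    stopifnot(ncol(theta) == 5)
  } else {
    stopifnot(length(theta) == 5, !is.null(duration), duration > 0)
    n <- round(duration * fs)
    theta <- matrix(theta, n, 5, byrow = TRUE)
  }
  stopifnot(all(is.finite(theta)))
  if (!is.null(seed)) set.seed(seed)
  zn <- if (process_noise_sd > 0) {
    matrix(stats::rnorm(n * 4, sd = process_noise_sd), n, 4)
  } else matrix(0, n, 4)
  on <- if (obs_noise_sd > 0) stats::rnorm(n, sd = obs_noise_sd) else numeric(n)
  out <- .cpp_simulate(theta, 1 / fs, sp$v0, sp$varsigma, zn,
                       as.numeric(x0), synapse_set()$tau)
  out$observation <- as.numeric(out$observation)
  colnames(out$states) <- state_names()
  colnames(theta) <- theta_names()
  structure(list(
    time = (seq_len(n) - 1) / fs,
    states = out$states,
    observation = out$observation + on,
    observation_clean = out$observation,
    params_used = theta,
    fs = fs,
    seed = seed
  ), class = "sp_simulation")
}

#' @export
print.sp_simulation <- function(x, ...) {
  cat(sprintf("<sp_simulation> %d samples at %g Hz (%.1f s)\n",
              length(x$time), x$fs, length(x$time) / x$fs))
  invisible(x)
}

#' Write / read a simulation as tidy CSV plus JSON sidecar
#'
#' Columns: `time_s`, the 8 states, `observation`, then the 5 parameters.
#' Metadata (fs, seed, units) goes to `<path>.json`.
#'
#' @param sim An `sp_simulation`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  df <- data.frame(time_s = sim$time, sim$states,
                   observation = sim$observation, sim$params_used,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = sim$fs, seed = sim$seed, units = "V")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
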