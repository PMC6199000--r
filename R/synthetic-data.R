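# Ground-truth seizure catalogs and model-based ECoG.
#
# The generator emulates the statistical structure reported for chronic
# focal-epilepsy recordings: per-patient catalogs of >= 20 seizures with
# unimodal or bimodal log-duration distributions, stereotyped ictal
# parameter motifs on the in-going pyramidal connections (decrease,
# increase, or decrease-then-increase), identical onset epochs for long and
# short seizures, and an optional duration-linked divergence confined to
# the pre-offset epoch.

#' Ictal parameter motif specification
#'
#' A motif is a piecewise-smooth (cosine-ramped) multiplicative excursion
#' applied to the affected parameters during the ictal period, expressed in
#' percent of baseline.  `decrease_then_increase` dips by `amplitude` and
#' then overshoots baseline by `overshoot` during the final
#' `offset_epoch_s` seconds.
#'
#' @param motif One of `"decrease"`, `"increase"`,
#'   `"decrease_then_increase"`.
#' @param params Affected parameters (default: the in-going pyramidal
#'   connections and input, `u`, `alpha_ep`, `alpha_ip`).
#' @param amplitude Excursion amplitude, percent of baseline (> 0).
#' @param overshoot Overshoot amplitude for the final epoch, percent
#'   (decrease_then_increase only).
#' @param onset_ramp_s,offset_ramp_s Cosine ramp durations, seconds.
#' @param offset_epoch_s Length of the final (offset) epoch, seconds.
#' @return List of class `sp_motif`.
#' @export
motif_spec <- function(motif = c("decrease_then_increase", "decrease",
                                 "increase"),
                       params = c("u", "alpha_ep", "alpha_ip"),
                       amplitude = 30, overshoot = 30,
                       onset_ramp_s = 2, offset_ramp_s = 2,
                       offset_epoch_s = 8) {
  motif <- match.arg(motif)
  stopifnot(amplitude >= 0, overshoot >= 0, onset_ramp_s > 0,
            offset_ramp_s > 0, offset_epoch_s > 0,
            all(params %in% theta_names()))
  structure(list(motif = motif, params = params, amplitude = amplitude,
                 overshoot = overshoot, onset_ramp_s = onset_ramp_s,
                 offset_ramp_s = offset_ramp_s,
                 offset_epoch_s = offset_epoch_s), class = "sp_motif")
}

# cosine half-ramp from 0 to 1
cos_ramp <- function(t, len) ifelse(t <= 0, 0, ifelse(t >= len, 1,
                                                      0.5 * (1 - cos(pi * t / len))))

#' Motif shape in percent of baseline
#'
#' The relative excursion f(t) (percent) over ictal time `t` in
#' `[0, duration]`; zero at both ends.
#'
#' @param spec `sp_motif`.
#' @param t Times since onset, seconds.
#' @param duration Seizure duration, seconds (must exceed the total ramp
#'   time).
#' @param overshoot Optional per-seizure overshoot override, percent.
#' @return Numeric vector, percent change from baseline.
#' @export
motif_shape <- function(spec, t, duration, overshoot = NULL) {
  if (duration <= spec$onset_ramp_s + spec$offset_ramp_s) {
    stop("seizure too short for the motif ramps")
  }
  A <- spec$amplitude
  O <- overshoot %||% spec$overshoot
  up <- cos_ramp(t, spec$onset_ramp_s)
  down <- cos_ramp(duration - t, spec$offset_ramp_s)
  f <- switch(spec$motif,
    decrease = -A * pmin(up, down),
    increase = A * pmin(up, down),
    decrease_then_increase = {
      # dip epoch at -A, transition to +O across the final epoch
      E <- min(spec$offset_epoch_s, 0.5 * duration)
      tr <- cos_ramp(t - (duration - E), min(spec$offset_ramp_s, E / 2))
      level <- -A + (A + O) * tr
      level * pmin(up, down)
    })
  f[t < 0 | t > duration] <- 0
  f
}

#' Ground-truth parameter trajectory for one seizure
#'
#' Builds the theta trajectory over a full analysis segment (pre-onset
#' context, ictal period, post-offset context) by applying the motif shape
#' multiplicatively to the affected parameters: theta_j(t) =
#' baseline_j * (1 + f(t)/100).
#'
#' @param spec `sp_motif`.
#' @param duration Ictal duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param baseline Baseline theta vector (default [ref_params()]).
#' @param pre_s,post_s Context before onset / after offset, seconds.
#' @param overshoot Optional per-seizure overshoot override, percent.
#' @return List: `theta` (n x 5), `time` (seconds relative to onset),
#'   `ictal` (logical mask).
#' @export
make_motif_trajectory <- function(spec, duration, fs = 400,
                                  baseline = ref_params(), pre_s = 0,
                                  post_s = 0, overshoot = NULL) {
  n <- round((pre_s + duration + post_s) * fs)
  tt <- (seq_len(n) - 1) / fs - pre_s
  th <- matrix(baseline, n, 5, byrow = TRUE,
               dimnames = list(NULL, theta_names()))
  f <- motif_shape(spec, tt, duration, overshoot)
  for (p in spec$params) th[, p] <- th[, p] * (1 + f / 100)
  list(theta = th, time = tt, ictal = tt >= 0 & tt <= duration)
}

#' Synthetic seizure catalog specification
#'
#' @param n_seizures Number of seizures (>= 20 to satisfy the pipeline's
#'   inclusion rule).
#' @param duration_meanlog Log-mean(s) of the lognormal duration
#'   component(s): one value (unimodal) or two (bimodal).  Defaults match
#'   short ~30 s and long ~90 s populations.
#' @param duration_sdlog Log-SDs, recycled to the number of components.
#' @param mixture_weight Probability of the first (short) component when
#'   bimodal.
#' @param n_channels Channels per recording.
#' @param channels_affected Indices of the focal channels carrying the
#'   motif; other channels stay at baseline dynamics.
#' @param process_noise_sd Per-step z-state noise SD driving the model.
#' @param obs_noise_sd Observation noise SD, volts.
#' @param amplitude_jitter Relative SD of a per-seizure multiplicative
#'   jitter on the motif amplitude and overshoot (seizure-to-seizure
#'   variability; duration-independent by construction).
#' @param pre_s,post_s Segment context, seconds.
#' @param fs Sampling rate, Hz.
#' @param baseline Baseline theta.
#' @param seed Integer seed.
#' @return List of class `sp_catalog_spec`.
#' @export
catalog_spec <- function(n_seizures = 100,
                         duration_meanlog = c(log(30), log(90)),
                         duration_sdlog = 0.3,
                         mixture_weight = 0.5,
                         n_channels = 2,
                         channels_affected = 1,
                         process_noise_sd = 0.05,
                         obs_noise_sd = 3e-4,
                         amplitude_jitter = 0.1,
                         pre_s = 130, post_s = 10, fs = 400,
                         baseline = ref_params(), seed = 1) {
  stopifnot(n_seizures >= 20, length(duration_meanlog) %in% 1:2,
            mixture_weight > 0, mixture_weight < 1,
            all(channels_affected %in% seq_len(n_channels)))
  duration_sdlog <- rep_len(duration_sdlog, length(duration_meanlog))
  structure(as.list(environment()), class = "sp_catalog_spec")
}

#' Sample seizure durations from the catalog's lognormal (mixture) model
#'
#' @param spec `sp_catalog_spec`.
#' @param seed Optional seed override.
#' @return data.frame: `duration` (seconds, snapped to the sample grid),
#'   `component` (1 = short, 2 = long; all 1 when unimodal).
#' @export
sample_durations <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_seizures
  k <- length(spec$duration_meanlog)
  comp <- if (k == 1) rep(1L, n) else {
    ifelse(stats::runif(n) < spec$mixture_weight, 1L, 2L)
  }
  d <- stats::rlnorm(n, meanlog = spec$duration_meanlog[comp],
                     sdlog = spec$duration_sdlog[comp])
  d <- round(d * spec$fs) / spec$fs
  data.frame(duration = d, component = comp)
}

#' Generate one synthetic seizure
#'
#' Builds the ground-truth parameter trajectory and simulates model-based
#' ECoG for every channel: affected channels follow the motif, unaffected
#' channels keep baseline parameters (both with process and observation
#' noise, independently drawn per channel).
#'
#' @param spec `sp_catalog_spec`.
#' @param motif `sp_motif`.
#' @param duration Seizure duration, seconds.
#' @param overshoot Optional per-seizure overshoot override, percent.
#' @param ecog Simulate ECoG (set FALSE to return only the trajectory).
#' @return List: `segment` (`sp_segment`-compatible: `data`, `fs`,
#'   `t0_rel_onset`), `true_theta` (n x 5 for affected channels), `time`,
#'   `duration`.
#' @export
generate_seizure <- function(spec, motif, duration, overshoot = NULL,
                             ecog = TRUE) {
  traj <- make_motif_trajectory(motif, duration, fs = spec$fs,
                                baseline = spec$baseline,
                                pre_s = spec$pre_s, post_s = spec$post_s,
                                overshoot = overshoot)
  n <- nrow(traj$theta)
  dat <- NULL
  if (ecog) {
    dat <- matrix(0, spec$n_channels, n)
    base_th <- matrix(spec$baseline, n, 5, byrow = TRUE)
    for (ch in seq_len(spec$n_channels)) {
      th <- if (ch %in% spec$channels_affected) traj$theta else base_th
      sim <- simulate_nmm(theta = th, fs = spec$fs,
                          process_noise_sd = spec$process_noise_sd,
                          obs_noise_sd = spec$obs_noise_sd)
      dat[ch, ] <- sim$observation
    }
    rownames(dat) <- paste0("Ch", seq_len(spec$n_channels))
  }
  segment <- structure(list(data = dat, fs = spec$fs,
                            t0_rel_onset = -spec$pre_s, rejected = FALSE),
                       class = "sp_segment")
  list(segment = segment, true_theta = traj$theta, time = traj$time,
       duration = duration)
}

#' Generate a ground-truth seizure bundle
#'
#' Samples a duration catalog and generates every seizure's parameter
#' trajectory and (optionally) ECoG.  Long and short seizures share an
#' identical onset epoch; with `link > 0` the pre-offset overshoot of the
#' linked parameter grows with duration (overshoot percent =
#' `motif$overshoot + link * (duration - median duration)`), so
#' duration-connectivity correlations appear only before offset, never
#' before onset.
#'
#' @param spec `sp_catalog_spec`.
#' @param motif `sp_motif` shared by all seizures.
#' @param link Offset-effect size, percent overshoot per second of
#'   duration (0 = no duration link).
#' @param link_param Parameter carrying the duration link (default
#'   `alpha_ep`; must be in `motif$params`).
#' @param ecog Simulate ECoG per seizure (FALSE returns trajectories only).
#' @return List of class `sp_bundle`: `catalog` (annotations with
#'   durations and components), `seizures` (list from
#'   [generate_seizure()]), `spec`, `motif`, `link`, `seed`.
#' @export
generate_bundle <- function(spec, motif = motif_spec(), link = 0,
                            link_param = "alpha_ep", ecog = TRUE) {
  stopifnot(link_param %in% motif$params || link == 0)
  set.seed(spec$seed)
  cat <- sample_durations(spec, seed = NULL)
  med <- stats::median(cat$duration)
  seizures <- vector("list", nrow(cat))
  onset_clock <- spec$pre_s
  ann <- NULL
  jitter_sd <- spec$amplitude_jitter %||% 0
  for (i in seq_len(nrow(cat))) {
    jit <- if (jitter_sd > 0) max(0.2, stats::rnorm(1, 1, jitter_sd)) else 1
    mi <- motif
    mi$amplitude <- motif$amplitude * jit
    mi$overshoot <- motif$overshoot * jit
    ov <- if (link > 0) {
      max(0, motif$overshoot + link * (cat$duration[i] - med)) * jit
    } else NULL
    seizures[[i]] <- generate_seizure_linked(spec, mi, cat$duration[i],
                                             link_param, ov, ecog)
    ann <- rbind(ann, data.frame(
      patient_id = "SYN1", seizure_id = i,
      onset = onset_clock, offset = onset_clock + cat$duration[i],
      duration = cat$duration[i], component = cat$component[i],
      lead_time_ok = TRUE))
    onset_clock <- onset_clock + cat$duration[i] + spec$pre_s + spec$post_s
  }
  structure(list(catalog = ann, seizures = seizures, spec = spec,
                 motif = motif, link = link, link_param = link_param,
                 seed = spec$seed), class = "sp_bundle")
}

motif_only <- function(motif, param) {
  m <- motif
  m$params <- param
  m
}

# one seizure where only `link_param` carries the per-seizure overshoot
generate_seizure_linked <- function(spec, motif, duration, link_param,
                                    overshoot, ecog) {
  if (is.null(overshoot)) {
    return(generate_seizure(spec, motif, duration, ecog = ecog))
  }
  traj <- make_motif_trajectory(motif, duration, fs = spec$fs,
                                baseline = spec$baseline,
                                pre_s = spec$pre_s, post_s = spec$post_s)
  linked <- make_motif_trajectory(motif_only(motif, link_param), duration,
                                  fs = spec$fs, baseline = spec$baseline,
                                  pre_s = spec$pre_s, post_s = spec$post_s,
                                  overshoot = overshoot)
  traj$theta[, link_param] <- linked$theta[, link_param]
  n <- nrow(traj$theta)
  dat <- NULL
  if (ecog) {
    dat <- matrix(0, spec$n_channels, n)
    base_th <- matrix(spec$baseline, n, 5, byrow = TRUE)
    for (ch in seq_len(spec$n_channels)) {
      th <- if (ch %in% spec$channels_affected) traj$theta else base_th
      sim <- simulate_nmm(theta = th, fs = spec$fs,
                          process_noise_sd = spec$process_noise_sd,
                          obs_noise_sd = spec$obs_noise_sd)
      dat[ch, ] <- sim$observation
    }
    rownames(dat) <- paste0("Ch", seq_len(spec$n_channels))
  }
  segment <- structure(list(data = dat, fs = spec$fs,
                            t0_rel_onset = -spec$pre_s, rejected = FALSE),
                       class = "sp_segment")
  list(segment = segment, true_theta = traj$theta, time = traj$time,
       duration = duration)
}

#' Write a bundle to disk
#'
#' Recordings as CSV + JSON sidecars, annotations as CSV, ground-truth
#' trajectories as tidy CSV, and a JSON manifest echoing the spec and seed.
#'
#' @param bundle `sp_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotations(bundle$catalog, file.path(dir, "annotations.csv"))
  for (i in seq_along(bundle$seizures)) {
    sz <- bundle$seizures[[i]]
    if (!is.null(sz$segment$data)) {
      rec <- ecog_recording(sz$segment$data, bundle$spec$fs,
                            patient_id = "SYN1")
      write_recording(rec, file.path(dir, sprintf("seizure_%03d.csv", i)))
    }
    truth <- data.frame(time_s = sz$time, sz$true_theta, check.names = FALSE)
    utils::write.csv(truth, file.path(dir, sprintf("truth_%03d.csv", i)),
                     row.names = FALSE)
  }
  manifest <- list(seed = bundle$seed, link = bundle$link,
                   link_param = bundle$link_param,
                   n_seizures = bundle$spec$n_seizures,
                   fs = bundle$spec$fs,
                   motif = unclass(bundle$motif),
                   spec = unclass(bundle$spec[setdiff(names(bundle$spec),
                                                      "baseline")]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
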