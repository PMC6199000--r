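# ECoG I/O, seizure segment extraction, filtering and signal energy.

#' ECoG recording container
#'
#' @param data channels x samples numeric matrix, volts.
#' @param fs Sampling rate, Hz.
#' @param channel_labels Optional channel names.
#' @param patient_id Identifier.
#' @return List of class `sp_recording`.
#' @export
ecog_recording <- function(data, fs, channel_labels = NULL,
                           patient_id = "P1") {
  data <- as.matrix(data)
  stopifnot(fs > 0, nrow(data) >= 1)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 patient_id = patient_id), class = "sp_recording")
}

#' @export
print.sp_recording <- function(x, ...) {
  cat(sprintf("<sp_recording> %s: %d ch x %d samples at %g Hz (%.1f s)\n",
              x$patient_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Write a recording as CSV plus JSON sidecar
#'
#' One column per channel, samples as rows; fs, labels and patient id in
#' `<path>.json`.
#'
#' @param rec `sp_recording`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels,
                            patient_id = rec$patient_id, units = "V"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording (CSV + JSON sidecar)
#'
#' @param path CSV path written by [write_recording()] (the `<path>.json`
#'   sidecar must exist and carry `fs`).
#' @param format Only `"csv"` is supported.
#' @return `sp_recording`.
#' @export
read_recording <- function(path, format = "csv") {
  format <- match.arg(format)
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop("recording or sidecar not found: ", path)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ecog_recording(t(as.matrix(df)), fs = meta$fs,
                 channel_labels = meta$channel_labels,
                 patient_id = meta$patient_id)
}

#' Seizure annotation record
#'
#' @param patient_id,seizure_id Identifiers.
#' @param onset,offset Seconds on the recording clock; `offset > onset`.
#' @param lead_time_ok Had >= 1 h seizure-free lead time.
#' @return One-row data.frame with a `duration` column.
#' @export
seizure_record <- function(patient_id, seizure_id, onset, offset,
                           lead_time_ok = TRUE) {
  stopifnot(offset > onset)
  data.frame(patient_id = patient_id, seizure_id = seizure_id,
             onset = onset, offset = offset, duration = offset - onset,
             lead_time_ok = lead_time_ok, stringsAsFactors = FALSE)
}

#' Read / write seizure annotations
#'
#' CSV with columns patient_id, seizure_id, onset_s, offset_s (and
#' optionally lead_time_ok).
#'
#' @param path CSV path.
#' @return data.frame of seizure records.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "seizure_id", "onset_s", "offset_s")
                %in% names(df)))
  if (is.null(df$lead_time_ok)) df$lead_time_ok <- TRUE
  out <- data.frame(patient_id = df$patient_id, seizure_id = df$seizure_id,
                    onset = df$onset_s, offset = df$offset_s,
                    duration = df$offset_s - df$onset_s,
                    lead_time_ok = df$lead_time_ok)
  stopifnot(all(out$duration > 0))
  out
}

#' @rdname read_annotations
#' @param ann data.frame of seizure records.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(data.frame(patient_id = ann$patient_id,
                              seizure_id = ann$seizure_id,
                              onset_s = ann$onset, offset_s = ann$offset,
                              lead_time_ok = ann$lead_time_ok),
                   path, row.names = FALSE)
  invisible(path)
}

#' Extract the analysis segment around one seizure
#'
#' Takes the window from `pre_s` seconds before onset to `post_s` seconds
#' after offset (defaults: 5 min before, 1 min after).  Segments whose
#' coverage is incomplete, or that contain a telemetry dropout (a run of
#' exactly-repeated values of at least `dropout_s` seconds on any channel),
#' are rejected with a reason.
#'
#' @param rec `sp_recording`.
#' @param sz One-row seizure record (see [seizure_record()]).
#' @param pre_s,post_s Context before onset / after offset, seconds.
#' @param dropout_s Minimum flatline duration counted as a dropout;
#'   `Inf` disables the check.
#' @return List of class `sp_segment` (`data`, `fs`, `t0_rel_onset`,
#'   `seizure`), or a list with `rejected = TRUE` and a `reason`.
#' @export
extract_segment <- function(rec, sz, pre_s = 300, post_s = 60,
                            dropout_s = 0.25) {
  fs <- rec$fs
  i0 <- round((sz$onset - pre_s) * fs) + 1
  i1 <- round((sz$offset + post_s) * fs)
  if (i0 < 1 || i1 > ncol(rec$data)) {
    return(list(rejected = TRUE, reason = "coverage", seizure = sz))
  }
  dat <- rec$data[, i0:i1, drop = FALSE]
  if (is.finite(dropout_s) && has_dropout(dat, fs, dropout_s)) {
    return(list(rejected = TRUE, reason = "dropout", seizure = sz))
  }
  structure(list(data = dat, fs = fs, t0_rel_onset = -pre_s, seizure = sz,
                 rejected = FALSE), class = "sp_segment")
}

has_dropout <- function(dat, fs, dropout_s) {
  need <- ceiling(dropout_s * fs)
  for (ch in seq_len(nrow(dat))) {
    r <- rle(dat[ch, ])
    if (any(r$lengths >= need)) return(TRUE)
  }
  FALSE
}

#' Zero-phase bandpass + notch filtering
#'
#' Second-order Butterworth bandpass (default 1-180 Hz) followed by a
#' second-order Butterworth bandstop around the mains frequency (default
#' 48-52 Hz), both applied forward-backward (zero phase) with symmetric
#' (mirror) padding of `pad_s` seconds at each end — narrow-band stop
#' filters ring for on the order of 1/bandwidth seconds, so the padding is
#' specified in signal time, not filter taps, and mirroring (rather than
#' odd reflection) preserves the local mean so the junction does not
#' excite the stop-band resonance.
#'
#' @param seg `sp_segment` (or `sp_recording`; any object with `data`
#'   channels x samples and `fs`).
#' @param low,high Bandpass corners, Hz (`high` must be below Nyquist).
#' @param notch Mains frequency, Hz; `NULL` disables the notch.
#' @param notch_halfwidth Half-width of the stop band, Hz.
#' @param pad_s Reflect padding length at each end, seconds.
#' @return The input object with `data` replaced by the filtered signal
#'   (same length).
#' @export
bandpass_notch <- function(seg, low = 1, high = 180, notch = 50,
                           notch_halfwidth = 2, pad_s = 2) {
  fs <- seg$fs
  ny <- fs / 2
  if (high >= ny) stop("bandpass upper corner must be below Nyquist")
  bp <- signal::butter(2, c(low, high) / ny, type = "pass")
  bs <- if (!is.null(notch)) {
    signal::butter(2, c(notch - notch_halfwidth, notch + notch_halfwidth) / ny,
                   type = "stop")
  } else NULL
  out <- seg
  np <- round(pad_s * fs)
  for (ch in seq_len(nrow(seg$data))) {
    x <- filtfilt_pad(bp, seg$data[ch, ], np)
    if (!is.null(bs)) x <- filtfilt_pad(bs, x, np)
    out$data[ch, ] <- x
  }
  out
}

# forward-backward filtering with mirror padding so the filter state is
# warmed up before the retained samples
filtfilt_pad <- function(flt, x, np) {
  np <- min(length(x) - 1, np)
  if (np > 0) {
    head_pad <- x[seq(np + 1, 2)]
    tail_pad <- x[seq(length(x) - 1, length(x) - np)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- signal::filter(flt, xp)
  y <- rev(as.numeric(signal::filter(flt, rev(as.numeric(y)))))
  if (np > 0) y <- y[(np + 1):(np + length(x))]
  y
}

#' Sliding-window signal energy
#'
#' Energy per window is the sum of squared samples over a 1 s window with
#' 50% overlap (hop 0.5 s), per channel plus the cross-channel average.
#' Windows that would overhang the end of the segment are dropped, so
#' window centers align exactly across seizures when segments are aligned
#' at onset.
#'
#' @param seg `sp_segment` (or anything with `data`, `fs`, optionally
#'   `t0_rel_onset`).
#' @param window_s Window length, seconds.
#' @param overlap Fractional overlap in \[0, 1).
#' @return List of class `sp_energy`: `window_centers` (seconds, relative
#'   to onset when known), `energy` (windows x channels), `mean_energy`.
#' @export
compute_energy <- function(seg, window_s = 1, overlap = 0.5) {
  fs <- seg$fs
  N <- round(window_s * fs)
  hop <- round(N * (1 - overlap))
  nsamp <- ncol(seg$data)
  if (nsamp < N) stop("segment shorter than one energy window")
  starts <- seq(1, nsamp - N + 1, by = hop)
  E <- matrix(0, length(starts), nrow(seg$data))
  for (ch in seq_len(nrow(seg$data))) {
    x2 <- seg$data[ch, ]^2
    cs <- c(0, cumsum(x2))
    E[, ch] <- cs[starts + N] - cs[starts]
  }
  colnames(E) <- rownames(seg$data)
  t0 <- if (!is.null(seg$t0_rel_onset)) seg$t0_rel_onset else 0
  centers <- t0 + (starts - 1 + N / 2) / fs
  structure(list(window_centers = centers, energy = E,
                 mean_energy = rowMeans(E)), class = "sp_energy")
}

#' Write an energy series as tidy CSV
#'
#' @param en `sp_energy`.
#' @param path CSV path.
#' @export
write_energy <- function(en, path) {
  df <- data.frame(window_center_s = en$window_centers, en$energy,
                   mean = en$mean_energy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
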