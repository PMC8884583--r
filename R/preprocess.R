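#' Resample a recording
#'
#' Anti-aliased polyphase resampling of every channel to `target_fs`.
#' Annotations are in seconds and pass through unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs target sampling rate in Hz.
#' @return a new `eeg_recording` at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs = 200) {
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop_validation("target_fs must be positive")
  if (abs(rec$fs - target_fs) < 1e-9) return(rec)
  p <- round(target_fs)
  q <- round(rec$fs)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  sig <- t(apply(rec$signal, 1, function(x) signal::resample(x, p, q)))
  new_recording(sig, target_fs, rec$channel_names, rec$patient_id,
                rec$recording_id, rec$annotations)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Bandpass filter a recording
#'
#' Zero-phase 4th-order Butterworth bandpass (applied forward-backward with
#' `signal::filtfilt`), the standard clinical-EEG choice.  The high-pass edge
#' removes the DC component.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz; `0 < lo < hi < fs/2`.
#' @return a filtered `eeg_recording`.
#' @export
bandpass_recording <- function(rec, lo = 0.5, hi = 30) {
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    stop_validation("need 0 < lo < hi < fs/2 (fs = ", rec$fs, ")")
  bf <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  # removing the channel mean first keeps the filter's start-up transient
  # from smearing a large DC offset across the recording edges
  sig <- t(apply(rec$signal, 1,
                 function(x) signal::filtfilt(bf, x - mean(x))))
  new_recording(sig, rec$fs, rec$channel_names, rec$patient_id,
                rec$recording_id, rec$annotations)
}

#' Clamp high-amplitude artifacts
#'
#' Per channel, values outside `mean +/- k * SD` (statistics over that
#' channel's full recording) are clipped to the nearest bound.  Clipping --
#' rather than sample deletion -- keeps the time axis contiguous for the
#' recurrent tracker.
#'
#' @param rec an `eeg_recording`.
#' @param k standard-deviation multiple (default 2).
#' @return a clamped `eeg_recording`.
#' @export
clamp_artifacts <- function(rec, k = 2) {
  sig <- rec$signal
  for (i in seq_len(nrow(sig))) {
    m <- mean(sig[i, ]); s <- sd(sig[i, ])
    if (!is.finite(s) || s == 0) next
    sig[i, ] <- pmin(pmax(sig[i, ], m - k * s), m + k * s)
  }
  new_recording(sig, rec$fs, rec$channel_names, rec$patient_id,
                rec$recording_id, rec$annotations)
}

#' Z-normalize every channel
#'
#' Per channel over the full recording: subtract the mean, divide by the
#' standard deviation, giving mean 0 and variance 1.
#'
#' @param rec an `eeg_recording`.
#' @return a normalized `eeg_recording`.
#' @export
znormalize <- function(rec) {
  sig <- rec$signal
  for (i in seq_len(nrow(sig))) {
    s <- sd(sig[i, ])
    if (!is.finite(s) || s == 0)
      stop_validation("zero-variance channel: ", rec$channel_names[i])
    sig[i, ] <- (sig[i, ] - mean(sig[i, ])) / s
  }
  new_recording(sig, rec$fs, rec$channel_names, rec$patient_id,
                rec$recording_id, rec$annotations)
}

#' Cut a recording into one-second non-overlapping windows
#'
#' Window `t` (0-based) covers `[t * window_s, (t + 1) * window_s)`; a
#' trailing partial window is dropped.  A window is labeled seizure (1) iff
#' its interval overlaps any annotated seizure interval.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length in seconds (default 1).
#' @return an `eeg_windows` object: list with `data` (channels x windows x
#'   samples_per_window array), `fs`, `window_s`, `channel_names`,
#'   `window_labels`, and the source annotations/identifiers.
#' @export
window_recording <- function(rec, window_s = 1) {
  spw <- round(rec$fs * window_s)
  if (spw < 1) stop_validation("fs * window_s must be >= 1")
  nwin <- floor(ncol(rec$signal) / spw)
  if (nwin < 1) stop_validation("recording shorter than one window")
  m <- nrow(rec$signal)
  dat <- array(0, dim = c(m, nwin, spw))
  for (t in seq_len(nwin))
    dat[, t, ] <- rec$signal[, (t - 1) * spw + seq_len(spw), drop = FALSE]
  labels <- window_labels_from(rec$annotations, nwin, window_s)
  structure(list(data = dat, fs = rec$fs, window_s = window_s,
                 channel_names = rec$channel_names, window_labels = labels,
                 annotations = rec$annotations, patient_id = rec$patient_id,
                 recording_id = rec$recording_id),
            class = "eeg_windows")
}

window_labels_from <- function(annotations, nwin, window_s = 1) {
  labels <- integer(nwin)
  starts <- (seq_len(nwin) - 1) * window_s
  for (a in annotations)
    labels[starts < a$offset_s & (starts + window_s) > a$onset_s] <- 1L
  labels
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d ch x %d windows x %d samples (%d seizure)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              sum(x$window_labels)))
  invisible(x)
}

#' Clip a recording around seizure onset
#'
#' Returns the sub-recording `[onset - pre_s, onset + post_s)` (truncated at
#' the recording bounds) around the first annotated seizure, with annotation
#' times re-referenced to the new origin.  Used to focus localization
#' training on the onset transition and away from late-seizure artifact.
#'
#' @param rec an `eeg_recording` with at least one annotation.
#' @param pre_s seconds kept before onset (default 15).
#' @param post_s seconds kept after onset (default 30).
#' @return a clipped `eeg_recording`.
#' @export
clip_around_onset <- function(rec, pre_s = 15, post_s = 30) {
  if (!length(rec$annotations))
    stop_validation("clip_around_onset needs an annotated seizure")
  onset <- rec$annotations[[1]]$onset_s
  dur <- recording_duration(rec)
  t0 <- max(0, onset - pre_s)
  t1 <- min(dur, onset + post_s)
  i0 <- round(t0 * rec$fs)
  i1 <- round(t1 * rec$fs)
  sig <- rec$signal[, (i0 + 1):i1, drop = FALSE]
  ann <- lapply(rec$annotations, function(a) {
    on <- max(0, a$onset_s - t0)
    off <- min(t1 - t0, a$offset_s - t0)
    if (off <= on) return(NULL)
    seizure_annotation(on, off, a$soz_hemisphere, a$soz_region, a$notes)
  })
  ann <- Filter(Negate(is.null), ann)
  new_recording(sig, rec$fs, rec$channel_names, rec$patient_id,
                rec$recording_id, ann)
}

#' Standard preprocessing pipeline
#'
#' Fixed order: resample to `target_fs`, bandpass `band`, clamp at
#' `clamp_k` SDs, z-normalize, then window.  Statistics for clamping and
#' normalization are computed per channel over the full recording.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs resampling target in Hz (default 200).
#' @param band bandpass edges in Hz (default `c(0.5, 30)`).
#' @param clamp_k artifact clamp in SD multiples (default 2).
#' @param window_s window length in seconds (default 1).
#' @return an `eeg_windows` object.
#' @export
preprocess_recording <- function(rec, target_fs = 200, band = c(0.5, 30),
                                 clamp_k = 2, window_s = 1) {
  rec <- resample_recording(rec, target_fs)
  rec <- bandpass_recording(rec, band[1], band[2])
  rec <- clamp_artifacts(rec, clamp_k)
  rec <- znormalize(rec)
  window_recording(rec, window_s)
}
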