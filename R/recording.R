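#' EEG recording container
#'
#' An `eeg_recording` holds a channels-by-samples signal matrix (microvolts),
#' its sampling rate, ordered electrode labels, and clinical seizure
#' annotations.  All times are seconds from the start of the recording,
#' 0-based, with half-open intervals `[onset, offset)`.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one label per signal row.
#' @param patient_id,recording_id opaque identifier strings.
#' @param annotations list of [seizure_annotation()] objects.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(signal, fs, channel_names, patient_id = "",
                          recording_id = "", annotations = list()) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  if (nrow(signal) != length(channel_names))
    stop_validation("signal has ", nrow(signal), " rows but ",
                    length(channel_names), " channel names")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_validation("fs must be a positive scalar")
  if (anyDuplicated(channel_names))
    stop_validation("duplicate channel names: ",
                    paste(unique(channel_names[duplicated(channel_names)]),
                          collapse = ", "))
  dur <- ncol(signal) / fs
  for (a in annotations) {
    if (a$onset_s < 0 || a$offset_s > dur + 1e-9)
      stop_validation("annotation [", a$onset_s, ", ", a$offset_s,
                      ") outside recording [0, ", dur, ")")
  }
  rownames(signal) <- channel_names
  structure(list(patient_id = patient_id, recording_id = recording_id,
                 signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations),
            class = "eeg_recording")
}

#' Seizure annotation
#'
#' @param onset_s,offset_s seizure interval in seconds from recording start,
#'   half-open `[onset_s, offset_s)`; `0 <= onset_s < offset_s`.
#' @param soz_hemisphere one of `"left"`, `"right"`, `"unknown"`.
#' @param soz_region one of `"anterior"`, `"posterior"`, `"unknown"`.
#' @param notes free text.
#' @return an object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(onset_s, offset_s, soz_hemisphere = "unknown",
                               soz_region = "unknown", notes = "") {
  if (!(onset_s >= 0 && onset_s < offset_s))
    stop_validation("need 0 <= onset_s < offset_s, got [",
                    onset_s, ", ", offset_s, ")")
  soz_hemisphere <- match.arg(soz_hemisphere, c("left", "right", "unknown"))
  soz_region <- match.arg(soz_region, c("anterior", "posterior", "unknown"))
  structure(list(onset_s = onset_s, offset_s = offset_s,
                 soz_hemisphere = soz_hemisphere, soz_region = soz_region,
                 notes = notes),
            class = "seizure_annotation")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %.1f s @ %g Hz, %d seizure(s)\n",
              x$patient_id, x$recording_id, nrow(x$signal),
              ncol(x$signal) / x$fs, x$fs, length(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs
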