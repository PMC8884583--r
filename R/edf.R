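#' Canonicalize an EEG channel label
#'
#' Maps raw clinical channel labels onto canonical 10-20 electrode names:
#' strips `"EEG "` prefixes and reference suffixes (`"-REF"`, `"-LE"`,
#' `"-AVG"`, ...), normalizes case, and translates the legacy temporal names
#' T3/T4/T5/T6 to their modern equivalents T7/T8/P7/P8.  Labels that do not
#' resolve to a 10-20 scalp electrode (EKG, EMG, photic, ...) map to the
#' sentinel `"unknown"`; the caller decides whether to drop them.
#' Idempotent: canonical names map to themselves.
#'
#' @param label character vector of raw channel labels.
#' @return character vector of canonical names or `"unknown"`.
#' @export
canonicalize_channel <- function(label) {
  canon <- c(Fp1 = "Fp1", Fp2 = "Fp2", F3 = "F3", F4 = "F4", F7 = "F7",
             F8 = "F8", C3 = "C3", C4 = "C4", T7 = "T7", T8 = "T8",
             P3 = "P3", P4 = "P4", P7 = "P7", P8 = "P8", O1 = "O1",
             O2 = "O2", Fz = "Fz", Cz = "Cz", Pz = "Pz",
             # legacy 10-20 synonyms
             T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
  lut <- setNames(as.character(canon), toupper(names(canon)))
  x <- toupper(trimws(label))
  x <- sub("^EEG[ _]+", "", x)
  x <- sub("[-_ ](REF|LE|RE|AVG|A1|A2|M1|M2|AV)$", "", x)
  x <- trimws(x)
  out <- unname(lut[x])
  out[is.na(out)] <- "unknown"
  out
}

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes a minimal EDF (16-bit) file with one-second data records.  Signals
#' are scaled per channel to the full digital range, so the round-trip error
#' is bounded by the 16-bit quantization of each channel's amplitude range.
#' The recording is truncated to a whole number of seconds.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$signal)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_validation("EDF writer requires an integer sampling rate")
  fs <- round(fs)
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1) stop_validation("recording shorter than one EDF record")
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr(rec$patient_id, 80)
  wr(rec$recording_id, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (v in rec$channel_names) wr(v, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin) wr(formatC(v, digits = 5, format = "g"), 8)
  for (v in pmax) wr(formatC(v, digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round(sweep(sweep(sig, 1, pmin), 1, scale, `*`)) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  # records: for each second, all channels' samples back to back
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)   # samples x records
  out <- integer(n_rec * ns * fs)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    block <- t(dig[, idx[, r], drop = FALSE])     # fs x ns
    out[pos + seq_len(fs * ns)] <- as.integer(block)
    pos <- pos + fs * ns
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Channel labels are canonicalized (see [canonicalize_channel()]); channels
#' that do not resolve to a 10-20 scalp electrode are dropped with a warning.
#' Annotations are attached from an optional CSV sidecar with columns
#' `recording_id, onset_s, offset_s, hemisphere, region, notes`, matched on
#' this file's recording identifier.  The signal is returned at the recorded
#' sampling rate; resampling is the preprocessing pipeline's job.
#'
#' @param path EDF file path.
#' @param annotation_path optional annotation CSV path.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  patient_id <- rd(80)
  recording_id <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8); rd(44)                           # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  total <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little",
                 signed = TRUE)
  sig <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  if (length(unique(spr)) != 1)
    stop_validation("EDF reader supports a single sampling rate per file")
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      sig[i, (r - 1) * spr[i] + seq_len(spr[i])] <- raw[pos + seq_len(spr[i])]
      pos <- pos + spr[i]
    }
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- sweep(sweep(sig, 1, dmin), 1, gain, `*`)
  sig <- sweep(sig, 1, pmin, `+`)

  fs <- spr[1] / rec_dur
  canon <- canonicalize_channel(labels)
  keep <- canon != "unknown" & !duplicated(canon)
  if (!any(keep))
    stop_validation("no channel in ", path, " maps onto the 10-20 montage")
  if (any(!keep))
    warning("dropping non-montage channel(s): ",
            paste(labels[!keep], collapse = ", "), call. = FALSE)
  sig <- sig[keep, , drop = FALSE]
  canon <- canon[keep]

  annotations <- list()
  if (!is.null(annotation_path)) {
    tab <- read_annotations(annotation_path)
    rows <- tab[tab$recording_id == recording_id, , drop = FALSE]
    annotations <- lapply(seq_len(nrow(rows)), function(i)
      seizure_annotation(rows$onset_s[i], rows$offset_s[i],
                         rows$hemisphere[i], rows$region[i],
                         rows$notes[i] %||% ""))
  }
  new_recording(sig, fs, canon, patient_id = patient_id,
                recording_id = recording_id, annotations = annotations)
}

#' Read a seizure annotation sidecar table
#'
#' @param path CSV with columns
#'   `recording_id, onset_s, offset_s, hemisphere, region[, notes]`.
#' @return a data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "onset_s", "offset_s", "hemisphere", "region")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_validation("annotation file lacks column(s): ",
                    paste(miss, collapse = ", "))
  if (is.null(tab$notes)) tab$notes <- ""
  tab
}

#' Write seizure annotations for a set of recordings
#' @param recs list of `eeg_recording` objects.
#' @param path output CSV path.
#' @export
write_annotations <- function(recs, path) {
  rows <- do.call(rbind, lapply(recs, function(r) {
    if (!length(r$annotations)) return(NULL)
    do.call(rbind, lapply(r$annotations, function(a)
      data.frame(recording_id = r$recording_id, onset_s = a$onset_s,
                 offset_s = a$offset_s, hemisphere = a$soz_hemisphere,
                 region = a$soz_region, notes = a$notes,
                 stringsAsFactors = FALSE)))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a channel probability map to CSV
#'
#' One row per window; one column per channel, plus the window index and the
#' max-pooled global probability.  Values survive a round trip within 1e-6.
#'
#' @param map a `channel_prob_map` (channels x windows matrix).
#' @param path output CSV path.
#' @export
write_predictions <- function(map, path) {
  probs <- unclass(map)
  tw <- ncol(probs)
  df <- data.frame(window = seq_len(tw) - 1L)
  for (i in seq_len(nrow(probs))) df[[rownames(probs)[i]]] <- probs[i, ]
  df$global <- if (tw > 0) apply(probs, 2, max) else numeric(0)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a channel probability map written by [write_predictions()]
#' @param path CSV path.
#' @return a `channel_prob_map`.
#' @export
read_predictions <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  chan <- setdiff(names(df), c("window", "global"))
  probs <- t(as.matrix(df[, chan, drop = FALSE]))
  rownames(probs) <- chan
  channel_prob_map(probs, chan)
}
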