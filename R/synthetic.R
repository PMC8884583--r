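#' Simulation configuration
#'
#' Defaults emulate a clinical scalp-EEG seizure cohort: 10-minute
#' recordings at 200 Hz on the lateral 10-20 montage, one focal seizure of
#' 30-120 s per recording with rhythmic 3-7 Hz ictal activity starting on
#' 1-3 onset electrodes inside one (hemisphere, region) zone and spreading
#' to the other electrodes with exponential delays (mean 5 s), 1/f-shaped
#' background noise with a shared common-mode component, and occasional
#' high-amplitude artifact transients.
#'
#' @param n_patients number of patients.
#' @param recordings_per_patient recordings per patient.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param montage electrode list.
#' @param seizure_duration_s length-2 range of seizure durations (s).
#' @param n_onset_channels range of onset-electrode counts.
#' @param propagation_delay_mean_s mean of the exponential per-channel
#'   propagation delay.
#' @param ictal_freq_hz range of the ictal rhythm frequency (Hz).
#' @param ictal_snr amplitude of the fully developed ictal rhythm relative
#'   to the background standard deviation (0 disables the seizure signal).
#' @param artifact_rate_per_min rate of high-amplitude transients.
#' @param seed RNG seed; the same seed reproduces the cohort bit for bit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 8, recordings_per_patient = 3,
                       duration_s = 600, fs = 200,
                       montage = default_montage(),
                       seizure_duration_s = c(30, 120),
                       n_onset_channels = c(1, 3),
                       propagation_delay_mean_s = 5,
                       ictal_freq_hz = c(3, 7), ictal_snr = 4,
                       artifact_rate_per_min = 2, seed = 1L) {
  stopifnot(n_patients >= 1, recordings_per_patient >= 1, duration_s > 0,
            fs > 0, length(montage) >= 2)
  if (duration_s < max(seizure_duration_s) + 60)
    stop_validation("recording too short to hold a seizure with 30 s margins")
  structure(as.list(environment()), class = "sim_config")
}

# 1/f-shaped noise via spectral shaping of white noise
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]        # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))              # flat below 1 Hz
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

zone_electrodes <- function(montage, hemisphere, region) {
  hp <- hemisphere_partition(montage)
  rp <- region_partition(montage)
  h <- if (hemisphere == "left") hp$zone_a else hp$zone_b
  r <- if (region == "anterior") rp$zone_a else rp$zone_b
  intersect(intersect(h, r), montage)
}

#' Simulate one seizure recording with ground truth
#'
#' Background is per-channel 1/f noise plus a shared common-mode component.
#' During the seizure, each onset electrode carries an amplitude-ramped
#' rhythmic oscillation from the onset; every other electrode joins after
#' its exponential propagation delay, attenuated least inside the onset
#' zone.  High-amplitude tapered transients occur at `artifact_rate_per_min`.
#'
#' @param cfg a [sim_config()].
#' @param patient_index,recording_index 1-based indices (determine the
#'   patient's onset zone and the RNG stream).
#' @return list with `recording` (an `eeg_recording`), `truth` (data.frame:
#'   channel, activity_start_s, activity_end_s, is_onset_channel), `zone`
#'   (hemisphere, region), `onset_channels`.
#' @export
simulate_recording <- function(cfg, patient_index = 1, recording_index = 1) {
  zones <- expand.grid(hemisphere = c("left", "right"),
                       region = c("anterior", "posterior"),
                       stringsAsFactors = FALSE)
  zi <- (patient_index - 1) %% 4 + 1
  hemisphere <- zones$hemisphere[zi]
  region <- zones$region[zi]
  set.seed(cfg$seed + 7919L * patient_index + 131L * recording_index)

  m <- length(cfg$montage)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs

  candidates <- zone_electrodes(cfg$montage, hemisphere, region)
  k <- sample(seq(cfg$n_onset_channels[1],
                  min(cfg$n_onset_channels[2], length(candidates))), 1)
  onset_channels <- sample(candidates, k)

  dur <- runif(1, cfg$seizure_duration_s[1], cfg$seizure_duration_s[2])
  onset <- runif(1, 30, cfg$duration_s - dur - 30)
  offset <- onset + dur

  common <- pink_noise(n, cfg$fs)
  sig <- matrix(0, m, n)
  hp <- hemisphere_partition(cfg$montage)
  rp <- region_partition(cfg$montage)
  freq <- runif(1, cfg$ictal_freq_hz[1], cfg$ictal_freq_hz[2])

  starts <- numeric(m)
  amp <- numeric(m)
  for (i in seq_len(m)) {
    el <- cfg$montage[i]
    is_onset <- el %in% onset_channels
    same_h <- (el %in% hp$zone_a) == (onset_channels[1] %in% hp$zone_a)
    same_r <- (el %in% rp$zone_a) == (onset_channels[1] %in% rp$zone_a)
    starts[i] <- if (is_onset) onset
      else min(onset + rexp(1, 1 / cfg$propagation_delay_mean_s), offset)
    amp[i] <- if (is_onset) 1
      else if (same_h && same_r) 0.8
      else if (same_h || same_r) 0.55
      else 0.3
    noise <- pink_noise(n, cfg$fs)
    x <- noise + 0.3 * common
    active <- tt >= starts[i] & tt < offset
    if (any(active) && cfg$ictal_snr > 0) {
      ta <- tt[active] - starts[i]
      ramp <- pmin(ta / 5, 1)                       # 5 s amplitude ramp
      phase <- runif(1, 0, 2 * pi)
      rhythm <- sin(2 * pi * freq * ta + phase) *
        (1 + 0.3 * sin(2 * pi * 0.3 * ta))          # slow amplitude waxing
      x[active] <- x[active] +
        cfg$ictal_snr * amp[i] * ramp * rhythm
    }
    sig[i, ] <- x
  }

  n_art <- rpois(1, cfg$artifact_rate_per_min * cfg$duration_s / 60)
  for (a in seq_len(n_art)) {
    ch <- sample.int(m, 1)
    at <- runif(1, 0, cfg$duration_s - 0.5)
    alen <- round(runif(1, 0.2, 0.5) * cfg$fs)
    i0 <- round(at * cfg$fs) + 1
    idx <- i0:min(i0 + alen - 1, n)
    taper <- sin(pi * seq_along(idx) / length(idx))^2
    sig[ch, idx] <- sig[ch, idx] + sample(c(-8, 8), 1) * taper
  }

  ann <- seizure_annotation(onset, offset, hemisphere, region)
  rec <- new_recording(sig, cfg$fs, cfg$montage,
                       patient_id = sprintf("P%02d", patient_index),
                       recording_id = sprintf("P%02d_R%02d", patient_index,
                                              recording_index),
                       annotations = list(ann))
  truth <- data.frame(channel = cfg$montage,
                      activity_start_s = starts, activity_end_s = offset,
                      is_onset_channel = cfg$montage %in% onset_channels,
                      stringsAsFactors = FALSE)
  list(recording = rec, truth = truth,
       zone = c(hemisphere = hemisphere, region = region),
       onset_channels = onset_channels)
}

#' Simulate a cohort of patients
#'
#' Patients are assigned to the four (hemisphere x region) onset-zone
#' combinations in a balanced round-robin.  Optionally writes the cohort to
#' disk: one EDF per recording, an annotation CSV, a per-channel
#' ground-truth CSV, and a JSON manifest.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing); `NULL` keeps the cohort
#'   in memory only.
#' @return list with `recordings` (list of simulation results) and
#'   `manifest` (per-patient zones data.frame).
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  sims <- list()
  for (p in seq_len(cfg$n_patients))
    for (r in seq_len(cfg$recordings_per_patient))
      sims[[length(sims) + 1]] <- simulate_recording(cfg, p, r)
  manifest <- do.call(rbind, lapply(sims, function(s)
    data.frame(patient_id = s$recording$patient_id,
               recording_id = s$recording$recording_id,
               hemisphere = s$zone[["hemisphere"]],
               region = s$zone[["region"]],
               onset_channels = paste(s$onset_channels, collapse = ";"),
               stringsAsFactors = FALSE)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sims)
      write_edf(s$recording,
                file.path(dir, paste0(s$recording$recording_id, ".edf")))
    write_annotations(lapply(sims, `[[`, "recording"),
                      file.path(dir, "annotations.csv"))
    truth <- do.call(rbind, lapply(sims, function(s)
      cbind(recording_id = s$recording$recording_id, s$truth)))
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(recordings = sims, manifest = manifest)
}
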