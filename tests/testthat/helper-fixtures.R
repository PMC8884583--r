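# Shared fixtures.  The large synthetic cohort and its LOPO detection models
# are expensive, so they are built once per test run and memoised.

fixture_cache <- new.env(parent = emptyenv())

# full-size synthetic study: 8 patients x 3 recordings x 600 s @ 200 Hz
study_fixture <- function() {
  if (!is.null(fixture_cache$study)) return(fixture_cache$study)
  cfg <- sim_config(seed = 1L)
  sims <- simulate_cohort(cfg)$recordings
  cohort <- prepare_cohort(lapply(sims, `[[`, "recording"))
  fixture_cache$study <- list(
    cfg = cfg, sims = sims, cohort = cohort,
    pids = vapply(cohort, `[[`, "", "patient_id"),
    folds = lopo_folds(vapply(cohort, `[[`, "", "patient_id")))
  fixture_cache$study
}

# LOPO detection models for the full-size study (10 epochs)
study_detection <- function() {
  if (!is.null(fixture_cache$detection)) return(fixture_cache$detection)
  fx <- study_fixture()
  fixture_cache$detection <- train_detection(
    fx$cohort, folds = fx$folds, cfg = train_config(epochs = 10, seed = 1L))
  fixture_cache$detection
}

# small cohort for fast end-to-end checks
small_sim_config <- function(seed = 5L, n_patients = 2,
                             recordings_per_patient = 2) {
  sim_config(n_patients = n_patients,
             recordings_per_patient = recordings_per_patient,
             duration_s = 120, fs = 64, seizure_duration_s = c(20, 30),
             seed = seed)
}

small_cohort <- function(seed = 5L, ...) {
  sims <- simulate_cohort(small_sim_config(seed = seed, ...))$recordings
  prepare_cohort(lapply(sims, `[[`, "recording"), target_fs = 64)
}

# a short single-channel test recording with one annotated seizure
toy_recording <- function(fs = 64, duration_s = 30, channels = c("C3", "C4"),
                          onset = 10, offset = 20) {
  if (offset > duration_s) {
    onset <- duration_s * 0.3
    offset <- duration_s * 0.6
  }
  set.seed(99)
  n <- fs * duration_s
  sig <- matrix(rnorm(length(channels) * n), nrow = length(channels))
  new_recording(sig, fs, channels, patient_id = "T", recording_id = "T_R1",
                annotations = list(seizure_annotation(onset, offset)))
}

# brute-force evaluations of the aggregation rules (independent oracle)
naive_max_pool <- function(probs) {
  vapply(seq_len(ncol(probs)), function(t) max(probs[, t]), numeric(1))
}

naive_onset_map <- function(probs) {
  m <- nrow(probs); tw <- ncol(probs)
  trace <- naive_max_pool(probs)
  num <- numeric(m)
  for (i in seq_len(m)) {
    for (t in seq_len(tw - 1)) {
      d <- max(trace[t + 1] - trace[t], 0)
      num[i] <- num[i] + d * probs[i, t + 1]
    }
  }
  den <- sum(num)
  if (den <= 0) rep(1 / m, m) else num / den
}

# pairwise-concordance AU-ROC estimator (ties count one half)
naive_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  mean(cmp)
}
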