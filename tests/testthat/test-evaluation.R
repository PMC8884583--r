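test_that("threshold calibration respects the false-alarm budget", {
  # all-zero baseline traces: detection fires at trace >= theta, so the
  # calibrated threshold sits just above the (zero) trace and flags nothing
  th0 <- calibrate_threshold(rep(0, 3600), rep(0, 3600))
  expect_lt(th0, 1e-5)
  expect_equal(sum(rep(0, 3600) >= th0), 0)
  # certain false alarms everywhere: unattainable -> sentinel above 1
  expect_gt(calibrate_threshold(rep(1, 3600), rep(0, 3600)), 1)
  # 1 h of baseline: 60 s at 0.9, 30 s more at 0.7, rest at 0.1.
  # 90 s >= 0.7 stays within the 2 min/hr budget, so 0.7 is the smallest
  # satisfying threshold (verified by brute force below)
  trace <- c(rep(0.9, 60), rep(0.7, 30), rep(0.1, 3510))
  labels <- rep(0, 3600)
  theta <- calibrate_threshold(trace, labels)
  expect_equal(theta, 0.7)
  brute <- function(th) sum(trace >= th) <= 120
  cands <- sort(unique(trace))
  expect_equal(cands[which(vapply(cands, brute, logical(1)))[1]], theta)
})

test_that("the calibration guarantee holds on random traces", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(500:3000, 1)
    trace <- runif(n)^sample(1:3, 1)
    labels <- as.integer(runif(n) < 0.2)
    if (!any(labels == 0)) labels[1] <- 0L
    theta <- calibrate_threshold(trace, labels, budget_min_per_hr = 2)
    base <- trace[labels == 0]
    fp_s_per_hr <- sum(base >= theta) / (length(base) / 3600)
    expect_lte(fp_s_per_hr, 120 + 1e-9)
  }
})

test_that("window metrics match their definitions and the AUC oracle", {
  wm <- window_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(wm), c(1, 1, 1, 1))
  wm0 <- window_metrics(rep(0, 6), c(1, 0, 1, 0, 0, 0), 0.5)
  expect_equal(unname(wm0[c("sensitivity", "specificity")]), c(0, 1))
  wm2 <- window_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(wm2), c(1, 1, 1, 1))
  # AU-ROC equals the pairwise-concordance estimator
  set.seed(4)
  for (i in 1:10) {
    scores <- runif(100)
    labels <- as.integer(runif(100) < 0.3)
    if (length(unique(labels)) < 2) next
    wm <- window_metrics(scores, labels, 0.5)
    expect_lt(abs(wm["auroc"] - naive_auroc(scores, labels)), 1e-9)
  }
  # single-class labels leave the threshold-free metrics undefined
  expect_true(is.na(window_metrics(runif(5), rep(0, 5), 0.5)["auroc"]))
})

test_that("metric summaries average per recording with SD", {
  traces <- list(c(0.9, 0.1), c(0.8, 0.2), runif(4))
  labels <- list(c(1, 0), c(1, 0), rep(0, 4))
  expect_warning(s <- summarize_window_metrics(traces, labels, 0.5),
                 "excluded")
  expect_equal(s$n[s$metric == "auroc"], 2)
  expect_equal(s$mean[s$metric == "auroc"], 1)
})

test_that("event scoring applies the overlap and latency rules", {
  # predicted interval [110, 300) against seizure [100, 160):
  # one TP with 10 s latency, no FP despite 140 s of post-seizure run-on
  trace <- numeric(3600)
  trace[111:300] <- 1
  ev <- score_events(trace, list(seizure_annotation(100, 160)), 0.5)
  expect_equal(ev$n_detected, 1L)
  expect_equal(ev$sensitivity, 1)
  expect_length(ev$fp_intervals, 0)
  expect_equal(ev$fp_per_hour, 0)
  expect_equal(ev$mean_latency_s, 10)
  # disjoint predicted interval [10, 20) in a 1 h recording: 1 FP per hour
  trace2 <- numeric(3600)
  trace2[11:20] <- 1
  ev2 <- score_events(trace2, list(seizure_annotation(100, 160)), 0.5)
  expect_equal(ev2$sensitivity, 0)
  expect_length(ev2$fp_intervals, 1)
  expect_equal(ev2$fp_per_hour, 1)
  # nothing crosses the threshold
  ev3 <- score_events(numeric(3600), list(seizure_annotation(100, 160)), 0.5)
  expect_equal(ev3$sensitivity, 0)
  expect_equal(ev3$fp_per_hour, 0)
  # early detection clips latency at zero
  trace4 <- numeric(3600)
  trace4[91:120] <- 1
  ev4 <- score_events(trace4, list(seizure_annotation(100, 160)), 0.5)
  expect_equal(ev4$mean_latency_s, 0)
})

test_that("event scoring ignores sub-threshold baseline values", {
  trace <- numeric(600)
  trace[101:160] <- 1
  base <- score_events(trace, list(seizure_annotation(100, 160)), 0.8)
  jitter <- trace
  jitter[trace == 0] <- runif(sum(trace == 0), 0, 0.7)
  jit <- score_events(jitter, list(seizure_annotation(100, 160)), 0.8)
  expect_equal(base$fp_per_hour, jit$fp_per_hour)
  expect_equal(base$n_detected, jit$n_detected)
})

test_that("event scores pool across recordings", {
  t1 <- numeric(3600); t1[111:140] <- 1
  t2 <- numeric(3600); t2[11:20] <- 1
  scores <- list(score_events(t1, list(seizure_annotation(100, 160)), 0.5),
                 score_events(t2, list(seizure_annotation(100, 160)), 0.5))
  agg <- aggregate_event_scores(scores)
  expect_equal(agg$sensitivity, 0.5)
  expect_equal(agg$fp_per_hour, 0.5)
  expect_equal(agg$mean_latency_s, 10)
  expect_equal(agg$total_hours, 2)
})

test_that("localization accuracy averages maps per patient and per class", {
  mont <- default_montage()
  mk <- function(peak) {
    probs <- matrix(0.1, 16, 3, dimnames = list(mont, NULL))
    probs[peak, 2:3] <- c(0.9, 0.95)
    channel_prob_map(probs)
  }
  part <- hemisphere_partition(mont)
  maps <- list(mk("T7"), mk("F3"), mk("T8"), mk("F8"))
  acc <- localization_accuracy(maps, c("p1", "p1", "p2", "p2"),
                               c("left", "left", "right", "right"), part)
  expect_equal(acc$class_averaged, 1)
  expect_equal(unname(acc$per_class), c(1, 1))
  # class-averaged accuracy weighs classes equally regardless of size
  acc2 <- localization_accuracy(list(mk("T7"), mk("F3"), mk("T7")),
                                c("p1", "p2", "p3"),
                                c("left", "left", "right"), part)
  expect_equal(acc2$class_averaged, 0.5)
  # unknown labels are excluded
  acc3 <- localization_accuracy(list(mk("T7"), mk("T8")), c("p1", "p2"),
                                c("left", "unknown"), part)
  expect_equal(nrow(acc3$patient_predictions), 1)
})
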