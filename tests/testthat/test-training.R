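test_that("detection loss is the window-wise binary cross-entropy", {
  # perfect prediction -> essentially zero
  expect_lt(detection_loss(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1e-6)
  # uninformative 0.5 trace -> log 2
  expect_equal(detection_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  # hand arithmetic
  expect_equal(detection_loss(c(0.9, 0.1), c(1, 0)), -log(0.9),
               tolerance = 1e-12)
  expect_error(detection_loss(c(0.5, 0.5), 1), "length")
})

test_that("localization loss is the zone cross-entropy", {
  expect_lt(localization_loss(c(1 - 1e-9, 1e-9), 1), 1e-8)
  expect_equal(localization_loss(c(0.5, 0.5), 2), log(2))
  expect_equal(localization_loss(c(left = 0.826, right = 0.174), "left"),
               -log(0.826))
  expect_error(localization_loss(c(left = 0.8, right = 0.2), "up"),
               "unknown zone")
})

test_that("the combined objective weighs detection by lambda", {
  expect_equal(combined_loss(0.7, 0.4, 0), 0.4)
  expect_equal(combined_loss(0.7, 0, 1), 0.7)
  expect_equal(combined_loss(0.2, 0.4, 0.6), 0.52)
  expect_error(combined_loss(1, 1, 1.5), "lambda")
})

test_that("leave-one-patient-out folds never leak the held-out patient", {
  pids <- rep(c("A", "B", "C"), times = c(3, 2, 4))
  folds <- lopo_folds(pids)
  expect_length(folds, 3)
  for (f in folds) {
    expect_false(any(pids[f$train_idx] == f$held_out_patient))
    expect_true(all(pids[f$test_idx] == f$held_out_patient))
    expect_setequal(c(f$train_idx, f$test_idx), seq_along(pids))
  }
})

test_that("the learning rate halves every 20 epochs", {
  cfg <- train_config(epochs = 50)
  lrs <- vapply(1:50, function(e) ictrack:::lr_at_epoch(cfg, e), numeric(1))
  expect_true(all(lrs[1:20] == 0.01))
  expect_true(all(lrs[21:40] == 0.005))
  expect_true(all(lrs[41:50] == 0.0025))
})

test_that("the max-pool routes the detection gradient to one channel", {
  probs <- matrix(c(0.2, 0.8, 0.6, 0.3), 2, 2)
  lg <- ictrack:::detection_map_grad(probs, c(1, 0))
  expect_equal(lg$dP[1, 1], 0)           # not the arg max at t = 1
  expect_true(lg$dP[2, 1] < 0)           # seizure label pulls prob up
  expect_true(lg$dP[1, 2] > 0)           # baseline label pushes prob down
  expect_equal(lg$dP[2, 2], 0)
  expect_equal(lg$loss, detection_loss(c(0.8, 0.6), c(1, 0)))
})

test_that("the localization gradient matches finite differences", {
  set.seed(33)
  part <- hemisphere_partition(default_montage())
  for (rep in 1:3) {
    probs <- matrix(runif(16 * 6, 0.05, 0.95), 16, 6,
                    dimnames = list(default_montage(), NULL))
    lg <- ictrack:::localization_map_grad(probs, part, "left")
    eps <- 1e-6
    for (k in sample(16 * 6, 15)) {
      p2 <- probs; p2[k] <- p2[k] + eps
      p3 <- probs; p3[k] <- p3[k] - eps
      fd <- (ictrack:::localization_map_grad(p2, part, "left")$loss -
             ictrack:::localization_map_grad(p3, part, "left")$loss) /
        (2 * eps)
      expect_lt(abs(fd - lg$dP[k]) / max(1e-8, abs(fd) + abs(lg$dP[k])),
                1e-4)
    }
  }
})

test_that("window trimming keeps pre/post-seizure context", {
  rec <- toy_recording(fs = 64, duration_s = 60, onset = 30, offset = 40)
  wt <- window_recording(rec)
  tr <- ictrack:::trim_windows(wt, pad_s = 10)
  expect_equal(dim(tr$data)[2], 30)                 # [20, 50)
  expect_equal(which(tr$window_labels == 1), 11:20)
  expect_equal(tr$annotations[[1]]$onset_s, 10)
  cl <- ictrack:::clip_windows_around_onset(wt, pre_s = 15, post_s = 30)
  expect_equal(dim(cl$data)[2], 45)
  expect_equal(cl$annotations[[1]]$onset_s, 15)
})

test_that("training reduces the detection loss on a separable fixture", {
  cohort <- small_cohort(seed = 6)
  cfg <- train_config(epochs = 3, seed = 2, trim_pad_s = 20)
  res <- train_detection(cohort, cfg = cfg)
  for (h in res$histories)
    expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_length(res$models, 2)
})

test_that("training is reproducible bit for bit under a fixed seed", {
  cohort <- small_cohort(seed = 6)
  cfg <- train_config(epochs = 2, seed = 9, trim_pad_s = 20)
  r1 <- train_detection(cohort, folds = lopo_folds(
    vapply(cohort, `[[`, "", "patient_id"))[1], cfg = cfg)
  r2 <- train_detection(cohort, folds = lopo_folds(
    vapply(cohort, `[[`, "", "patient_id"))[1], cfg = cfg)
  expect_identical(r1$models[[1]]$params, r2$models[[1]]$params)
  expect_identical(r1$histories, r2$histories)
})

test_that("localization fine-tuning needs inits and known labels", {
  cohort <- small_cohort(seed = 6)
  folds <- lopo_folds(vapply(cohort, `[[`, "", "patient_id"))
  cfg <- train_config(epochs = 1, seed = 2,
                      task = "localize_hemisphere")
  expect_error(train_localization(cohort, folds, cfg,
                                  init = list(models = list())),
               "one initial model per fold")
  det <- train_detection(cohort, folds = folds,
                         cfg = train_config(epochs = 1, seed = 2,
                                            trim_pad_s = 20))
  res <- train_localization(cohort, folds, cfg, det,
                            lambdas = c(0.3, 0.6))
  expect_length(res$models, 2)            # one model set per lambda
  expect_length(res$models[[1]], 2)       # one model per fold
})
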