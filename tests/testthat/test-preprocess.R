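test_that("resampling changes the length and preserves spectral content", {
  fs <- 256; dur <- 20
  tt <- (0:(fs * dur - 1)) / fs
  rec <- new_recording(matrix(sin(2 * pi * 5 * tt), 1), fs, "C3")
  out <- resample_recording(rec, 200)
  expect_equal(ncol(out$signal), 200 * dur)
  expect_equal(out$fs, 200)
  # dominant spectral peak still at 5 Hz
  spec <- abs(fft(out$signal[1, ]))
  freqs <- (seq_along(spec) - 1) / dur
  half <- freqs <= 100
  expect_lt(abs(freqs[half][which.max(spec[half])] - 5), 0.2)
  # already at target -> identical signal
  expect_identical(resample_recording(out, 200)$signal, out$signal)
  expect_error(resample_recording(rec, -5), "positive")
})

test_that("bandpass suppresses out-of-band energy and passes in-band", {
  fs <- 200; tt <- (0:(fs * 20 - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  r60 <- bandpass_recording(new_recording(matrix(sin(2 * pi * 60 * tt), 1),
                                          fs, "C3"))
  expect_lt(rms(r60$signal[1, ]) / rms(sin(2 * pi * 60 * tt)), 0.01)
  r10 <- bandpass_recording(new_recording(matrix(sin(2 * pi * 10 * tt), 1),
                                          fs, "C3"))
  expect_lt(abs(rms(r10$signal[1, ]) / rms(sin(2 * pi * 10 * tt)) - 1), 0.05)
  rdc <- bandpass_recording(new_recording(matrix(1, 1, fs * 20), fs, "C3"))
  expect_lt(max(abs(rdc$signal)), 1e-6)
  expect_error(bandpass_recording(toy_recording(fs = 50), 0.5, 30), "fs/2")
})

test_that("artifact clamping clips to mean +/- k SD per channel", {
  # constant channel untouched
  rec <- new_recording(matrix(3, 1, 1000), 100, "C3")
  expect_equal(clamp_artifacts(rec)$signal, rec$signal)
  # a lone spike is clipped near 2 SD
  x <- c(rep(0, 999), 100)
  s <- sd(x); m <- mean(x)
  out <- clamp_artifacts(new_recording(matrix(x, 1), 100, "C3"))
  expect_equal(max(out$signal), m + 2 * s, tolerance = 1e-10)
  # standard normal noise: about the 2-sided 2 SD tail gets altered
  set.seed(42)
  z <- rnorm(20000)
  out <- clamp_artifacts(new_recording(matrix(z, 1), 100, "C3"))
  frac <- mean(out$signal[1, ] != z)
  expect_lt(frac, 0.06)
  expect_gt(frac, 0.03)
})

test_that("z-normalization gives every channel mean 0 and variance 1", {
  set.seed(1)
  sig <- rbind(rnorm(2000, 5, 3), rnorm(2000, -2, 0.1))
  rec <- znormalize(new_recording(sig, 100, c("C3", "C4")))
  for (i in 1:2) {
    expect_lt(abs(mean(rec$signal[i, ])), 1e-6)
    expect_lt(abs(var(rec$signal[i, ]) - 1), 1e-6)
  }
  # idempotent
  again <- znormalize(rec)
  expect_equal(again$signal, rec$signal, tolerance = 1e-6)
  flat <- new_recording(matrix(1, 1, 100), 100, "O1")
  expect_error(znormalize(flat), "O1")
})

test_that("windowing cuts 1-s segments and labels seizure overlap", {
  rec <- toy_recording(fs = 64, duration_s = 30, onset = 10, offset = 20)
  wt <- window_recording(rec)
  expect_equal(dim(wt$data), c(2, 30, 64))
  expect_equal(which(wt$window_labels == 1), 11:20)   # windows 10..19
  # trailing partial window dropped
  rec2 <- new_recording(rec$signal[, 1:(64 * 29 + 32)], 64,
                        rec$channel_names)
  expect_equal(dim(window_recording(rec2)$data)[2], 29)
  # fractional annotation bounds label any overlapping window
  rec3 <- new_recording(rec$signal, 64, rec$channel_names,
                        annotations = list(seizure_annotation(10.5, 12.2)))
  expect_equal(which(window_recording(rec3)$window_labels == 1), 11:13)
  expect_error(window_recording(new_recording(matrix(0, 1, 10), 64, "C3")),
               "shorter")
})

test_that("onset clipping keeps [onset - pre, onset + post) within bounds", {
  rec <- toy_recording(fs = 64, duration_s = 60, onset = 30, offset = 40)
  clip <- clip_around_onset(rec, 15, 30)
  expect_equal(ncol(clip$signal) / clip$fs, 45)
  expect_equal(clip$annotations[[1]]$onset_s, 15)
  # truncation at the start
  early <- toy_recording(fs = 64, duration_s = 60, onset = 10, offset = 20)
  expect_equal(ncol(clip_around_onset(early)$signal) / 64, 40)
  # truncation at both ends
  tiny <- toy_recording(fs = 64, duration_s = 20, onset = 5, offset = 15)
  expect_equal(ncol(clip_around_onset(tiny)$signal) / 64, 20)
  expect_error(clip_around_onset(new_recording(matrix(0, 1, 64), 64, "C3")),
               "annotated")
})

test_that("the conditioning chain is near-idempotent end to end", {
  # a signal whose energy sits inside the passband: once conditioned, a
  # second pass through the chain barely changes it
  set.seed(7)
  fs <- 64
  tt <- (0:(fs * 30 - 1)) / fs
  mk <- function() sin(2 * pi * 5 * tt) + 0.3 * sin(2 * pi * 11 * tt + 1) +
    0.03 * rnorm(length(tt))
  rec <- new_recording(rbind(mk(), mk()), fs, c("C3", "C4"))
  run <- function(r) znormalize(clamp_artifacts(bandpass_recording(
    resample_recording(r, 64))))
  once <- run(rec)
  twice <- run(once)
  rel <- sqrt(mean((twice$signal - once$signal)^2)) /
    sqrt(mean(once$signal^2))
  expect_lt(rel, 0.01)
})

test_that("window labels are invariant to resampling", {
  rec <- toy_recording(fs = 64, duration_s = 30, onset = 10, offset = 20)
  l1 <- window_recording(rec)$window_labels
  l2 <- window_recording(resample_recording(rec, 32))$window_labels
  expect_equal(l1, l2)
})
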