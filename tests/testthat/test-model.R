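toy_model <- function(channels = paste0("ch", 1:3), ...) {
  ictrack_model(channels = channels, seed = 7, ...)
}

test_that("encoder maps a one-second window to a length-20 embedding", {
  model <- toy_model()
  h <- encode_windows(model, rnorm(200))
  expect_length(h, 20)
  # shorter windows (lower sampling rate) still give 20 features
  expect_length(encode_windows(model, rnorm(32)), 20)
  # all-zero window with identity batch-norm and zeroed biases -> zeros
  m0 <- model
  for (nm in c("conv1_b", "conv2_b", "conv3_b"))
    m0$params[[nm]][] <- 0
  expect_equal(unname(encode_windows(m0, rep(0, 64))), rep(0, 20),
               tolerance = 1e-6)
})

test_that("the encoder is shared across channels", {
  model <- toy_model()
  x <- rnorm(64)
  # identical windows on two different channels -> identical embeddings
  x2 <- array(0, dim = c(2, 1, 64))
  x2[1, 1, ] <- x; x2[2, 1, ] <- x
  h <- encode_windows(model, x2)
  expect_equal(h[, 1, 1], h[, 1, 2], tolerance = 1e-6)
})

test_that("the bidirectional tracker emits 80-dim order-sensitive outputs", {
  model <- toy_model()
  h_seq <- matrix(rnorm(20 * 45), 20, 45)
  o <- track_channel(model, h_seq)
  expect_equal(dim(o), c(80, 45))
  rev_o <- track_channel(model, h_seq[, 45:1])
  expect_false(isTRUE(all.equal(o, rev_o[, 45:1], tolerance = 1e-4)))
  expect_error(track_channel(model, h_seq[, 0]), "empty")
  # ablation is the identity
  ab <- toy_model(ablate_blstm = TRUE)
  expect_identical(track_channel(ab, h_seq), h_seq)
})

test_that("the classifier head emits probability pairs summing to one", {
  model <- toy_model()
  o <- matrix(rnorm(80 * 5), 80, 5)
  p <- classify_channel(model, o)
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  # zero weights and bias -> exactly 0.5
  m0 <- model
  m0$params$head_w[] <- 0; m0$params$head_b[] <- 0
  expect_equal(unname(classify_channel(m0, o)["seizure", ]), rep(0.5, 5))
  # the head is shared: same input, same output on any channel
  expect_equal(classify_channel(model, o), classify_channel(model, o))
  expect_error(classify_channel(model, matrix(0, 10, 5)), "does not match")
})

test_that("forward produces a channels x windows probability map", {
  model <- toy_model()
  x <- array(rnorm(3 * 7 * 64), dim = c(3, 7, 64))
  map <- predict(model, x)
  expect_equal(dim(map), c(3, 7))
  expect_true(all(map >= 0 & map <= 1))
})

test_that("the network is channel-permutation equivariant", {
  model <- toy_model(channels = paste0("ch", 1:4))
  x <- array(rnorm(4 * 6 * 64), dim = c(4, 6, 64))
  p <- unclass(predict(model, x))
  perm <- c(3, 1, 4, 2)
  pp <- unclass(predict(model, x[perm, , , drop = FALSE]))
  expect_equal(pp, p[perm, ], tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("window-permutation equivariance holds only for the ablation", {
  x <- array(rnorm(2 * 8 * 64), dim = c(2, 8, 64))
  perm <- sample(8)
  ab <- toy_model(channels = c("a", "b"), ablate_blstm = TRUE)
  p_ab <- unclass(predict(ab, x))
  pp_ab <- unclass(predict(ab, x[, perm, , drop = FALSE]))
  expect_equal(pp_ab, p_ab[, perm], tolerance = 1e-5, ignore_attr = TRUE)
  full <- toy_model(channels = c("a", "b"))
  p_f <- unclass(predict(full, x))
  pp_f <- unclass(predict(full, x[, perm, , drop = FALSE]))
  expect_false(isTRUE(all.equal(pp_f, p_f[, perm], tolerance = 1e-3)))
})

test_that("parameter count is independent of the channel count", {
  n_par <- function(m) sum(vapply(ictrack:::trainable_names(m),
                                  function(nm) length(m$params[[nm]]),
                                  numeric(1)))
  expect_equal(n_par(toy_model(channels = paste0("c", 1:4))),
               n_par(toy_model(channels = paste0("c", 1:19))))
})

test_that("montage mismatches are rejected with the missing channels", {
  model <- ictrack_model(channels = c("C3", "C4"), seed = 1)
  rec <- toy_recording(fs = 64, duration_s = 5, channels = c("C3", "O1"))
  wt <- window_recording(rec)
  expect_error(predict(model, wt), "C4")
})

test_that("analytic gradients match finite differences (double path)", {
  set.seed(42)
  M <- 3; Tw <- 6; S <- 16
  model <- ictrack_model(channels = paste0("ch", 1:M), seed = 7,
                         precision = "double")
  x <- array(rnorm(M * Tw * S), dim = c(M, Tw, S))
  labels <- rep(c(0, 1), length.out = Tw)
  loss_of <- function(m) {
    fwd <- ictrack:::net_forward(m, x, training = TRUE)
    idx <- max.col(t(fwd$probs), ties.method = "first")
    trace <- fwd$probs[cbind(idx, seq_len(Tw))]
    detection_loss(trace, labels, eps = 1e-12)
  }
  fwd <- ictrack:::net_forward(model, x, training = TRUE)
  lg <- ictrack:::detection_map_grad(fwd$probs, labels)
  grads <- ictrack:::net_backward(model, fwd, lg$dP)
  eps <- 1e-6
  for (nm in ictrack:::trainable_names(model)) {
    g <- grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      fd <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-8, abs(fd) + abs(g[i])), 1e-3,
                label = paste("relative gradient error for", nm))
    }
  }
})

test_that("float and double forward passes agree", {
  set.seed(8)
  x <- array(rnorm(2 * 5 * 32), dim = c(2, 5, 32))
  mf <- ictrack_model(channels = c("a", "b"), seed = 3)
  md <- mf; md$config$precision <- "double"
  pf <- ictrack:::net_forward(mf, x)$probs
  pd <- ictrack:::net_forward(md, x)$probs
  expect_equal(pf, pd, tolerance = 1e-4)
})

test_that("checkpoints round-trip through a single file", {
  model <- toy_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params)
  expect_equal(back$config, model$config)
  x <- array(rnorm(3 * 4 * 32), dim = c(3, 4, 32))
  expect_equal(unclass(predict(model, x)), unclass(predict(back, x)))
})
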