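#' Channel-wise seizure tracking model
#'
#' Builds an untrained model: a 3-layer 1D CNN encoder shared across
#' electrodes (20 kernels; first layer kernel length 7 / padding 3 followed
#' by LeakyReLU, max-pooling of kernel 2 and batch normalization; layers 2-3
#' kernel length 3 / padding 1 with LeakyReLU, batch normalization and an
#' identity residual connection around each; global average pooling to a
#' length-20 embedding), a bidirectional LSTM tracker of 40 hidden units
#' shared across electrodes (output size 80), and a per-window 2-class
#' softmax head.  With `ablate_blstm = TRUE` the tracker is an identity
#' pass-through and the head reads the 20-dim embeddings directly.
#'
#' Convolutions use stride 1; the max-pool uses stride 2.  Weights follow
#' the usual fan-in-scaled uniform initialization; batch-norm starts as the
#' identity map with unit running variance.
#'
#' @param channels electrode montage the model expects (order-free;
#'   parameters are shared across channels, so the parameter count does not
#'   depend on this).
#' @param ablate_blstm drop the recurrent tracker (No-BLSTM ablation).
#' @param leaky_slope LeakyReLU negative slope (default 0.01).
#' @param precision `"float"` (training/inference) or `"double"` (used by
#'   numerical verification).
#' @param seed optional integer seed for the weight initialization.
#' @return an object of class `ictrack_model`.
#' @export
ictrack_model <- function(channels = default_montage(), ablate_blstm = FALSE,
                          leaky_slope = 0.01, precision = "float",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- function(nr, nc, fan_in) {
    b <- 1 / sqrt(fan_in)
    matrix(runif(nr * nc, -b, b), nr, nc)
  }
  uv <- function(n, fan_in) runif(n, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  d_head <- if (ablate_blstm) 20L else 80L
  params <- list(
    conv1_w = u(20, 7, 7), conv1_b = uv(20, 7),
    bn1_gamma = rep(1, 20), bn1_beta = rep(0, 20),
    bn1_mean = rep(0, 20), bn1_var = rep(1, 20),
    conv2_w = u(20, 60, 60), conv2_b = uv(20, 60),
    bn2_gamma = rep(1, 20), bn2_beta = rep(0, 20),
    bn2_mean = rep(0, 20), bn2_var = rep(1, 20),
    conv3_w = u(20, 60, 60), conv3_b = uv(20, 60),
    bn3_gamma = rep(1, 20), bn3_beta = rep(0, 20),
    bn3_mean = rep(0, 20), bn3_var = rep(1, 20),
    head_w = u(2, d_head, d_head), head_b = uv(2, d_head),
    leaky_slope = leaky_slope)
  if (!ablate_blstm) {
    params <- c(params, list(
      lstm_f_wi = u(160, 20, 40), lstm_f_wh = u(160, 40, 40),
      lstm_f_b = uv(160, 40),
      lstm_b_wi = u(160, 20, 40), lstm_b_wh = u(160, 40, 40),
      lstm_b_b = uv(160, 40)))
  }
  structure(list(params = params,
                 config = list(channels = channels,
                               ablate_blstm = ablate_blstm,
                               leaky_slope = leaky_slope,
                               precision = precision,
                               embedding_dim = 20L, hidden_units = 40L)),
            class = "ictrack_model")
}

#' @export
print.ictrack_model <- function(x, ...) {
  np <- sum(vapply(trainable_names(x), function(nm) length(x$params[[nm]]),
                   numeric(1)))
  cat(sprintf("<ictrack_model> %s, %d trainable parameters, %d-channel montage\n",
              if (x$config$ablate_blstm) "No-BLSTM ablation" else "CNN-BLSTM",
              as.integer(np), length(x$config$channels)))
  invisible(x)
}

trainable_names <- function(model) {
  nm <- c("conv1_w", "conv1_b", "bn1_gamma", "bn1_beta",
          "conv2_w", "conv2_b", "bn2_gamma", "bn2_beta",
          "conv3_w", "conv3_b", "bn3_gamma", "bn3_beta",
          "head_w", "head_b")
  if (!model$config$ablate_blstm)
    nm <- c(nm, "lstm_f_wi", "lstm_f_wh", "lstm_f_b",
            "lstm_b_wi", "lstm_b_wh", "lstm_b_b")
  nm
}

check_montage <- function(model, channel_names) {
  missing <- setdiff(model$config$channels, channel_names)
  if (length(missing))
    stop_validation("input lacks montage channel(s): ",
                    paste(missing, collapse = ", "))
  extra <- setdiff(channel_names, model$config$channels)
  if (length(extra))
    stop_validation("input has channel(s) outside the montage: ",
                    paste(extra, collapse = ", "))
  invisible(TRUE)
}

as_window_array <- function(wt) {
  if (inherits(wt, "eeg_windows")) wt$data
  else if (is.array(wt) && length(dim(wt)) == 3) wt
  else stop_validation("expected an eeg_windows object or a 3-d array")
}

# low-level forward; training = TRUE returns the backward handle and batch
# statistics, training = FALSE returns probabilities, embeddings and tracker
# outputs computed with the frozen running statistics
net_forward <- function(model, x, training = FALSE) {
  dims <- dim(x)
  if (dims[3] < 2) stop_validation("windows must hold at least 2 samples")
  .net_forward_cpp(model$params, x, training, model$config$ablate_blstm,
                   model$config$precision)
}

net_backward <- function(model, fwd, dprobs) {
  .net_backward_cpp(fwd$ptr, dprobs, fwd$precision)
}

#' Per-channel seizure probabilities for a windowed recording
#'
#' Applies the encoder, tracker and classifier to every channel
#' independently (shared weights, no cross-channel mixing), returning the
#' channels x windows matrix of seizure probabilities.
#'
#' @param object an `ictrack_model`.
#' @param wt an `eeg_windows` object whose channels match the model montage.
#' @param ... unused.
#' @return a `channel_prob_map`.
#' @export
predict.ictrack_model <- function(object, wt, ...) {
  x <- as_window_array(wt)
  chans <- if (inherits(wt, "eeg_windows")) wt$channel_names
           else rownames(wt) %||% paste0("ch", seq_len(dim(x)[1]))
  if (inherits(wt, "eeg_windows")) check_montage(object, chans)
  out <- net_forward(object, x, training = FALSE)
  channel_prob_map(out$probs, chans)
}

#' Channel probability map
#'
#' @param probs channels x windows matrix of seizure probabilities in
#'   `[0, 1]`.
#' @param channel_names electrode labels, one per row.
#' @return an object of class `channel_prob_map` (a matrix).
#' @export
channel_prob_map <- function(probs, channel_names = rownames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(channel_names)) {
    if (nrow(probs) > 0) stop_validation("channel names are required")
    channel_names <- character(0)
  }
  if (length(channel_names) != nrow(probs))
    stop_validation("one channel name per probability row required")
  if (nrow(probs) > 0 && ncol(probs) > 0 &&
      (min(probs) < -1e-9 || max(probs) > 1 + 1e-9))
    stop_validation("probabilities must lie in [0, 1]")
  rownames(probs) <- channel_names
  structure(probs, class = c("channel_prob_map", "matrix", "array"))
}

#' @export
print.channel_prob_map <- function(x, ...) {
  cat(sprintf("<channel_prob_map> %d ch x %d windows, max %.3f\n",
              nrow(x), ncol(x), if (length(x)) max(x) else NA_real_))
  invisible(x)
}

#' Encode one-second windows into embeddings
#'
#' Runs only the shared CNN encoder (inference mode, frozen batch-norm
#' statistics).  Accepts a single window (numeric vector), a matrix of
#' windows (windows x samples), or a channels x windows x samples array.
#'
#' @param model an `ictrack_model`.
#' @param x window data.
#' @return embeddings: a length-20 vector for a single window, otherwise an
#'   array with a leading dimension of 20.
#' @export
encode_windows <- function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- array(x, dim = c(1, 1, length(x)))
  else if (length(dim(x)) == 2) x <- array(x, dim = c(1, dim(x)))
  out <- net_forward(model, x, training = FALSE)
  h <- out$h   # 20 x (M*T), channel-major
  if (single) drop(h)
  else {
    m <- dim(x)[1]; tw <- dim(x)[2]
    array(h, dim = c(20, tw, m))
  }
}

#' Track one channel's embedding sequence
#'
#' Applies the shared bidirectional LSTM to a 20 x T embedding sequence,
#' returning the 80 x T concatenated forward/backward hidden states.  For
#' the No-BLSTM ablation this is the identity.
#'
#' @param model an `ictrack_model`.
#' @param h_seq numeric matrix, 20 x T.
#' @return tracker outputs, (80 or 20) x T.
#' @export
track_channel <- function(model, h_seq) {
  h_seq <- as.matrix(h_seq)
  if (ncol(h_seq) < 1) stop_validation("empty embedding sequence")
  if (model$config$ablate_blstm) return(h_seq)
  p <- model$params
  fwd <- .lstm_seq_cpp(p$lstm_f_wi, p$lstm_f_wh, p$lstm_f_b, h_seq)
  bwd <- .lstm_seq_cpp(p$lstm_b_wi, p$lstm_b_wh, p$lstm_b_b,
                       h_seq[, rev(seq_len(ncol(h_seq))), drop = FALSE])
  rbind(fwd, bwd[, rev(seq_len(ncol(h_seq))), drop = FALSE])
}

#' Classify tracker outputs into per-window probabilities
#'
#' Softmax over \{baseline, seizure\} of the affine map `W o[t] + b`,
#' shared across channels.
#'
#' @param model an `ictrack_model`.
#' @param o_seq tracker outputs, D x T with D matching the head.
#' @return 2 x T matrix with rows `baseline`, `seizure`; columns sum to 1.
#' @export
classify_channel <- function(model, o_seq) {
  o_seq <- as.matrix(o_seq)
  if (nrow(o_seq) != ncol(model$params$head_w))
    stop_validation("tracker output size ", nrow(o_seq),
                    " does not match classifier head (",
                    ncol(model$params$head_w), ")")
  z <- model$params$head_w %*% o_seq + model$params$head_b
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  p <- sweep(e, 2, colSums(e), `/`)
  rownames(p) <- c("baseline", "seizure")
  p
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the parameters and configuration.
#'
#' @param model an `ictrack_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ictrack_model")) stop_validation("not a model checkpoint")
  m
}

# update running batch-norm statistics from one training forward pass
update_bn_stats <- function(model, batch_stats, momentum = 0.1) {
  for (nm in names(batch_stats)) {
    model$params[[nm]] <- (1 - momentum) * model$params[[nm]] +
      momentum * batch_stats[[nm]]
  }
  model
}
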