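#' Training configuration
#'
#' Defaults follow the published detection schedule: 50 epochs, weight decay
#' 1e-4, batches of 4 recordings, initial learning rate 0.01 halved every 20
#' epochs.  `lambda_sz` weighs the detection loss inside the combined
#' localization objective.  `grad_clip` caps the global gradient norm per
#' optimizer step, a standard stabilizer for recurrent nets (set `Inf` to
#' disable).
#'
#' @param epochs training epochs.
#' @param weight_decay L2 coefficient applied to all trainable parameters.
#' @param batch_size recordings per optimizer step.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_step epochs between decays.
#' @param lambda_sz detection-loss weight in `[0, 1]` for localization.
#' @param grad_clip global gradient-norm cap.
#' @param trim_pad_s seconds of pre-/post-seizure context kept when trimming
#'   recordings for detection training.
#' @param seed RNG seed for initialization and shuffling.
#' @param task `"detect"`, `"localize_hemisphere"` or `"localize_region"`.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50, weight_decay = 1e-4, batch_size = 4,
                         lr = 0.01, lr_decay = 0.5, lr_step = 20,
                         lambda_sz = 0.6, grad_clip = 5, trim_pad_s = 120,
                         seed = 1L, task = "detect") {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_step >= 1)
  if (lambda_sz < 0 || lambda_sz > 1)
    stop_validation("lambda_sz must lie in [0, 1]")
  task <- match.arg(task,
                    c("detect", "localize_hemisphere", "localize_region"))
  structure(list(epochs = epochs, weight_decay = weight_decay,
                 batch_size = batch_size, lr = lr, lr_decay = lr_decay,
                 lr_step = lr_step, lambda_sz = lambda_sz,
                 grad_clip = grad_clip, trim_pad_s = trim_pad_s,
                 seed = as.integer(seed), task = task),
            class = "train_config")
}

#' Detection loss: window-wise binary cross-entropy
#'
#' Mean over windows of the cross-entropy between the max-pooled global
#' trace and the clinician's 0/1 window annotation.
#'
#' @param trace global trace in `[0, 1]`.
#' @param labels 0/1 vector of the same length.
#' @param eps probability clip.
#' @return scalar loss.
#' @export
detection_loss <- function(trace, labels, eps = 1e-7) {
  if (length(trace) != length(labels))
    stop_validation("trace and labels differ in length")
  p <- pmin(pmax(trace, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# d detection_loss / d trace; denominators floored so that the gradient at
# the softmax logit, dL/dz = dL/dp * p(1-p), stays the stable (p - y)/T
detection_loss_grad <- function(trace, labels, floor = 1e-8) {
  (trace - labels) / pmax(trace * (1 - trace), floor) / length(trace)
}

#' Localization loss: cross-entropy on a zone score pair
#'
#' @param pair probability pair summing to 1 (e.g. from [zone_scores()]).
#' @param label index (1/2) or zone name matching `names(pair)`.
#' @param eps probability clip.
#' @return scalar `-log(pair[label])`.
#' @export
localization_loss <- function(pair, label, eps = 1e-12) {
  if (is.character(label)) {
    if (!label %in% names(pair))
      stop_validation("unknown zone label: ", label)
    label <- match(label, names(pair))
  }
  -log(max(pair[label], eps))
}

#' Combined localization objective
#'
#' `L = lambda_sz * detection + localization`.
#'
#' @param det detection loss.
#' @param loc localization loss.
#' @param lambda_sz weight in `[0, 1]`.
#' @return scalar loss.
#' @export
combined_loss <- function(det, loc, lambda_sz) {
  if (lambda_sz < 0 || lambda_sz > 1)
    stop_validation("lambda_sz must lie in [0, 1]")
  lambda_sz * det + loc
}

#' Leave-one-patient-out folds
#'
#' One fold per patient: every recording of that patient is held out, all
#' other recordings train.
#'
#' @param patient_ids character vector, one entry per recording.
#' @return list of folds: `held_out_patient`, `train_idx`, `test_idx`.
#' @export
lopo_folds <- function(patient_ids) {
  lapply(unique(patient_ids), function(p) {
    test <- which(patient_ids == p)
    fold <- list(held_out_patient = p,
                 train_idx = setdiff(seq_along(patient_ids), test),
                 test_idx = test)
    stopifnot(!any(patient_ids[fold$train_idx] == p))
    fold
  })
}

# gradient of the detection loss w.r.t. the full probability map: the max
# pool routes each window's gradient to its arg-max channel (subgradient,
# first max on ties)
detection_map_grad <- function(probs, labels) {
  trace_idx <- max.col(t(probs), ties.method = "first")
  trace <- probs[cbind(trace_idx, seq_len(ncol(probs)))]
  g <- detection_loss_grad(trace, labels)
  dP <- matrix(0, nrow(probs), ncol(probs))
  dP[cbind(trace_idx, seq_len(ncol(probs)))] <- g
  list(dP = dP, loss = detection_loss(trace, labels))
}

# loss and gradient of the zone cross-entropy w.r.t. the probability map,
# differentiating through Eq-style onset aggregation (increments of the
# max-pooled trace weighting channel activity at the entered window)
localization_map_grad <- function(probs, part, label) {
  m <- nrow(probs); tw <- ncol(probs)
  trace_idx <- max.col(t(probs), ties.method = "first")
  trace <- probs[cbind(trace_idx, seq_len(tw))]
  delta <- pmax(diff(trace), 0)
  act <- probs[, -1, drop = FALSE]            # channel activity at t+1
  raw <- as.numeric(act %*% delta)
  z <- sum(raw)
  zones <- zone_of(part, rownames(probs))
  if (is.character(label)) label <- match(label, part$labels)
  if (z <= 0) {                               # degenerate: uniform scores
    cs <- rep(1 / m, m)
    pa <- sum(cs[zones == part$labels[1]])
    pb <- sum(cs[zones == part$labels[2]])
    pair <- c(pa, pb) / (pa + pb)
    return(list(dP = matrix(0, m, tw),
                loss = localization_loss(pair, label), pair = pair))
  }
  cs <- raw / z
  pa <- sum(cs[zones == part$labels[1]])
  pb <- sum(cs[zones == part$labels[2]])
  r <- pa + pb
  pair <- c(pa, pb) / r
  loss <- localization_loss(pair, label)

  # d loss / d zone sums, for loss = -log(zone_label / (pa + pb))
  dpa <- 1 / r - (label == 1) / max(pa, 1e-12)
  dpb <- 1 / r - (label == 2) / max(pb, 1e-12)
  dcs <- ifelse(zones == part$labels[1], dpa,
                ifelse(zones == part$labels[2], dpb, 0))
  draw <- (dcs - sum(dcs * cs)) / z
  dP <- matrix(0, m, tw)
  dP[, -1] <- dP[, -1, drop = FALSE] + outer(draw, delta)
  ddelta <- as.numeric(crossprod(act, draw))
  dtrace <- numeric(tw)
  pos <- which(delta > 0)
  dtrace[pos + 1] <- dtrace[pos + 1] + ddelta[pos]
  dtrace[pos] <- dtrace[pos] - ddelta[pos]
  dP[cbind(trace_idx, seq_len(tw))] <-
    dP[cbind(trace_idx, seq_len(tw))] + dtrace
  list(dP = dP, loss = loss, pair = pair)
}

# trim a windowed recording to pad_s seconds of pre-/post-seizure context
trim_windows <- function(wt, pad_s = 120) {
  if (!length(wt$annotations)) return(wt)
  on <- min(vapply(wt$annotations, `[[`, 0, "onset_s"))
  off <- max(vapply(wt$annotations, `[[`, 0, "offset_s"))
  tw <- dim(wt$data)[2]
  t0 <- max(0, floor(on - pad_s))
  t1 <- min(tw, ceiling(off + pad_s))
  keep <- (t0 + 1):t1
  wt$data <- wt$data[, keep, , drop = FALSE]
  wt$window_labels <- wt$window_labels[keep]
  wt$annotations <- lapply(wt$annotations, function(a)
    seizure_annotation(a$onset_s - t0, a$offset_s - t0,
                       a$soz_hemisphere, a$soz_region, a$notes))
  wt
}

# clip a windowed recording around onset for localization training
clip_windows_around_onset <- function(wt, pre_s = 15, post_s = 30) {
  if (!length(wt$annotations))
    stop_validation("cannot clip an unannotated recording")
  on <- wt$annotations[[1]]$onset_s
  tw <- dim(wt$data)[2]
  t0 <- max(0, floor(on - pre_s))
  t1 <- min(tw, ceiling(on + post_s))
  keep <- (t0 + 1):t1
  wt$data <- wt$data[, keep, , drop = FALSE]
  wt$window_labels <- wt$window_labels[keep]
  wt$annotations <- lapply(wt$annotations, function(a) {
    o1 <- max(0, a$onset_s - t0); o2 <- min(t1 - t0, a$offset_s - t0)
    if (o2 <= o1) NULL
    else seizure_annotation(o1, o2, a$soz_hemisphere, a$soz_region, a$notes)
  })
  wt$annotations <- Filter(Negate(is.null), wt$annotations)
  wt
}

# one SGD step from accumulated gradients (sum over n_acc recordings)
sgd_step <- function(model, acc, n_acc, lr, cfg) {
  nms <- trainable_names(model)
  sq <- 0
  for (nm in nms) {
    acc[[nm]] <- acc[[nm]] / n_acc
    sq <- sq + sum(acc[[nm]]^2)
  }
  gn <- sqrt(sq)
  scale <- if (is.finite(cfg$grad_clip) && gn > cfg$grad_clip)
    cfg$grad_clip / gn else 1
  for (nm in nms) {
    g <- acc[[nm]] * scale + cfg$weight_decay * model$params[[nm]]
    model$params[[nm]] <- model$params[[nm]] - lr * g
  }
  model
}

lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^((epoch - 1) %/% cfg$lr_step)
}

# shared optimizer loop; loss_fn(model_fwd_out, entry) -> list(loss, dP)
run_training <- function(model, entries, cfg, loss_fn, verbose = FALSE) {
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0))
  n <- length(entries)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch)
    order <- sample.int(n)
    losses <- numeric(0)
    i <- 1
    while (i <= n) {
      batch <- order[i:min(i + cfg$batch_size - 1, n)]
      acc <- NULL
      for (j in batch) {
        e <- entries[[j]]
        fwd <- net_forward(model, e$x, training = TRUE)
        model <- update_bn_stats(model, fwd$batch_stats)
        lg <- loss_fn(fwd$probs, e)
        grads <- net_backward(model, fwd, lg$dP)
        losses <- c(losses, lg$loss)
        if (is.null(acc)) acc <- grads
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
      }
      model <- sgd_step(model, acc, length(batch), lr, cfg)
      i <- i + cfg$batch_size
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses), lr = lr))
    if (verbose)
      message(sprintf("  epoch %2d  lr %.4g  loss %.4f", epoch, lr,
                      mean(losses)))
  }
  list(model = model, history = history)
}

#' Train detection models with leave-one-patient-out cross-validation
#'
#' Per fold, trains a fresh model on the training recordings (trimmed to
#' `trim_pad_s` seconds of pre-/post-seizure context) with the window-wise
#' cross-entropy on the max-pooled global trace.  Deterministic given
#' `cfg$seed`.
#'
#' @param cohort list of entries, each a list with `wt` (an `eeg_windows`)
#'   and `patient_id`; see [prepare_cohort()].
#' @param folds folds from [lopo_folds()]; default: one per patient.
#' @param cfg a [train_config()].
#' @param ablate_blstm train the No-BLSTM ablation.
#' @param verbose print per-epoch losses.
#' @return list with `models` (one per fold), `histories`, `folds`.
#' @export
train_detection <- function(cohort, folds = NULL, cfg = train_config(),
                            ablate_blstm = FALSE, verbose = FALSE) {
  if (!length(cohort)) stop_validation("empty cohort")
  pids <- vapply(cohort, `[[`, "", "patient_id")
  if (is.null(folds)) folds <- lopo_folds(pids)
  loss_fn <- function(probs, e) detection_map_grad(probs, e$labels)
  models <- list(); histories <- list()
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    if (!length(fold$train_idx)) stop_validation("fold with empty training set")
    set.seed(cfg$seed + k)
    model <- ictrack_model(channels = cohort[[1]]$wt$channel_names,
                           ablate_blstm = ablate_blstm)
    entries <- lapply(cohort[fold$train_idx], function(e) {
      wt <- trim_windows(e$wt, cfg$trim_pad_s)
      list(x = wt$data, labels = wt$window_labels)
    })
    if (verbose) message("fold ", k, "/", length(folds),
                         " (hold out ", fold$held_out_patient, ")")
    res <- run_training(model, entries, cfg, loss_fn, verbose)
    models[[k]] <- res$model
    histories[[k]] <- res$history
  }
  list(models = models, histories = histories, folds = folds)
}

#' Fine-tune for localization with the combined loss
#'
#' Initializes each fold from the corresponding detection model and retrains
#' on recordings clipped around seizure onset with
#' `lambda_sz * detection + zone cross-entropy`.  Recordings with an unknown
#' zone label are skipped with a warning.  With several `lambdas`, one model
#' is produced per (fold, lambda) pair.
#'
#' @param cohort as in [train_detection()].
#' @param folds folds matching `init$folds`.
#' @param cfg a [train_config()] with a localization `task`.
#' @param init result of [train_detection()] (or a list of models, one per
#'   fold).
#' @param lambdas detection-loss weights to sweep (default `cfg$lambda_sz`).
#' @param pre_s,post_s onset clip extent in seconds.
#' @param verbose print per-epoch losses.
#' @return list with `models` (`models[[lambda]][[fold]]`), `histories`,
#'   `folds`, `lambdas`.
#' @export
train_localization <- function(cohort, folds = NULL, cfg = train_config(),
                               init, lambdas = NULL, pre_s = 15, post_s = 30,
                               verbose = FALSE) {
  if (cfg$task == "detect")
    stop_validation("cfg$task must be a localization task")
  init_models <- if (!is.null(init$models)) init$models else init
  if (is.null(folds)) folds <- init$folds
  if (is.null(folds)) stop_validation("folds are required")
  if (length(init_models) != length(folds))
    stop_validation("need one initial model per fold")
  if (is.null(lambdas)) lambdas <- cfg$lambda_sz
  part_for <- function(chans) {
    if (cfg$task == "localize_hemisphere") hemisphere_partition(chans)
    else region_partition(chans)
  }
  label_field <- if (cfg$task == "localize_hemisphere") "soz_hemisphere"
                 else "soz_region"

  models <- list(); histories <- list()
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    mods <- list(); hists <- list()
    for (k in seq_along(folds)) {
      fold <- folds[[k]]
      model <- init_models[[k]]
      part <- part_for(model$config$channels)
      entries <- list()
      for (e in cohort[fold$train_idx]) {
        if (!length(e$wt$annotations)) next
        lab <- e$wt$annotations[[1]][[label_field]]
        if (lab == "unknown") {
          warning("skipping ", e$wt$recording_id, ": unknown ", cfg$task,
                  " label", call. = FALSE)
          next
        }
        wt <- clip_windows_around_onset(e$wt, pre_s, post_s)
        entries[[length(entries) + 1]] <-
          list(x = wt$data, labels = wt$window_labels, zone = lab)
      }
      if (!length(entries))
        stop_validation("no labeled recordings in fold ", k)
      loss_fn <- function(probs, e) {
        rownames(probs) <- model$config$channels
        det <- detection_map_grad(probs, e$labels)
        loc <- localization_map_grad(probs, part, e$zone)
        list(loss = combined_loss(det$loss, loc$loss, lam),
             dP = lam * det$dP + loc$dP)
      }
      set.seed(cfg$seed + 1000L * li + k)
      if (verbose) message("lambda ", lam, ", fold ", k)
      res <- run_training(model, entries, cfg, loss_fn, verbose)
      mods[[k]] <- res$model
      hists[[k]] <- res$history
    }
    models[[li]] <- mods
    histories[[li]] <- hists
  }
  list(models = models, histories = histories, folds = folds,
       lambdas = lambdas)
}

#' Assemble a preprocessed cohort from recordings
#'
#' Runs the standard preprocessing pipeline on every recording and pairs the
#' windowed tensor with its patient identifier.
#'
#' @param recs list of `eeg_recording` objects.
#' @param ... passed to [preprocess_recording()].
#' @return list of entries `list(wt, patient_id, recording_id)`.
#' @export
prepare_cohort <- function(recs, ...) {
  lapply(recs, function(r)
    list(wt = preprocess_recording(r, ...), patient_id = r$patient_id,
         recording_id = r$recording_id))
}
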