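#' Calibrate the detection threshold to a false-alarm budget
#'
#' Searching over the observed trace values, returns the smallest threshold
#' such that the total duration of baseline windows at or above it, per hour
#' of baseline, stays within `budget_min_per_hr` minutes (default: 2 minutes
#' of false positive detection per hour).  If no threshold attains the
#' budget below certainty the sentinel `1 + 1e-6` is returned.
#'
#' @param traces a global trace (numeric vector) or list of traces.
#' @param labels matching 0/1 window labels (vector or list).
#' @param budget_min_per_hr false-positive budget, minutes per hour.
#' @param window_s window duration in seconds.
#' @return threshold in `[0, 1]`, or the sentinel `1 + 1e-6`.
#' @export
calibrate_threshold <- function(traces, labels, budget_min_per_hr = 2,
                                window_s = 1) {
  if (!is.list(traces)) { traces <- list(traces); labels <- list(labels) }
  tr <- unlist(traces); lb <- unlist(labels)
  if (length(tr) != length(lb))
    stop_validation("traces and labels differ in length")
  base <- tr[lb == 0]
  if (!length(base)) stop_validation("no baseline windows to calibrate on")
  budget_s_per_hr <- budget_min_per_hr * 60
  base_hours <- length(base) * window_s / 3600
  # candidate thresholds: ascending observed values; fp time is a step
  # function non-increasing in theta, so take the first value within budget
  cand <- sort(unique(tr))
  sb <- sort(base)
  n_ge <- length(base) - findInterval(cand, sb, left.open = TRUE)
  ok <- n_ge * window_s / base_hours <= budget_s_per_hr
  if (any(ok)) return(cand[which(ok)[1]])
  # no observed value satisfies the budget (detection fires at trace >=
  # theta, so even the smallest observed value can flag every window);
  # anything strictly above the maximum observed value yields zero
  # false-positive time and is still below certainty when max < 1
  if (max(tr) < 1) return(max(tr) + 1e-6)
  1 + 1e-6
}

#' Window-level detection metrics
#'
#' Sensitivity and specificity at a threshold plus threshold-free AU-ROC
#' and AU-PR over the window scores of one recording.  Recordings whose
#' labels are all one class have undefined AU-ROC and return `NA` for the
#' threshold-free metrics.
#'
#' @param trace global trace for one recording.
#' @param labels 0/1 window labels.
#' @param threshold detection threshold.
#' @return named vector: `sensitivity`, `specificity`, `auroc`, `aupr`.
#' @export
window_metrics <- function(trace, labels, threshold = 0.5) {
  if (length(trace) != length(labels))
    stop_validation("trace and labels differ in length")
  pred <- as.integer(trace >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (length(unique(labels)) < 2) {
    auroc <- NA_real_; aupr <- NA_real_
  } else {
    auroc <- as.numeric(pROC::auc(pROC::roc(labels, trace, quiet = TRUE,
                                            direction = "<")))
    aupr <- average_precision(trace, labels)
  }
  c(sensitivity = sens, specificity = spec, auroc = auroc, aupr = aupr)
}

# area under the precision-recall curve (average-precision estimator);
# tied scores are evaluated as one block at the block's trailing precision
average_precision <- function(scores, labels) {
  npos <- sum(labels)
  if (npos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / npos
  last <- rev(!duplicated(rev(sc)))   # last index of each distinct score
  sum(prec[last] * diff(c(0, rec[last])))
}

#' Summarize window metrics across recordings
#'
#' Per-recording metrics averaged with their standard deviation (mean +/- SD
#' reporting).  Recordings with undefined AU-ROC (single-class labels) are
#' excluded from the threshold-free averages with a warning.
#'
#' @param traces list of global traces.
#' @param labels list of matching label vectors.
#' @param threshold detection threshold.
#' @return data.frame with one row per metric: mean, sd, n.
#' @export
summarize_window_metrics <- function(traces, labels, threshold = 0.5) {
  per <- mapply(window_metrics, traces, labels,
                MoreArgs = list(threshold = threshold))
  if (anyNA(per["auroc", ]))
    warning(sum(is.na(per["auroc", ])),
            " recording(s) excluded from AU-ROC/AU-PR (single-class labels)",
            call. = FALSE)
  data.frame(metric = rownames(per),
             mean = rowMeans(per, na.rm = TRUE),
             sd = apply(per, 1, sd, na.rm = TRUE),
             n = apply(per, 1, function(x) sum(!is.na(x))),
             row.names = NULL)
}

#' Event-level seizure scoring
#'
#' Maximal runs of windows with `trace >= threshold` become predicted
#' seizure intervals.  An interval overlapping any annotated seizure is a
#' true positive; intervals lying entirely in baseline are false positives.
#' A true seizure counts as detected if at least one predicted interval
#' overlaps it; its latency is `max(0, first overlapping interval start -
#' onset)`.  Post-seizure continuation of a true-positive interval is not
#' penalized.  The false-positive rate is denominated in total recording
#' hours.
#'
#' @param trace global trace for one recording.
#' @param annotations list of `seizure_annotation`s (may be empty).
#' @param threshold detection threshold.
#' @param window_s window duration in seconds.
#' @return an `event_score`: list with `tp_intervals`, `fp_intervals`,
#'   `n_true_seizures`, `n_detected`, `sensitivity`, `fp_per_hour`,
#'   `latencies_s`, `mean_latency_s`, `total_hours`.
#' @export
score_events <- function(trace, annotations, threshold, window_s = 1) {
  tw <- length(trace)
  above <- trace >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pred <- cbind(start = (starts[runs$values] - 1) * window_s,
                end = ends[runs$values] * window_s)
  seiz <- if (length(annotations))
    cbind(onset = vapply(annotations, `[[`, 0, "onset_s"),
          offset = vapply(annotations, `[[`, 0, "offset_s"))
  else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("onset", "offset")))

  overlaps <- function(a0, a1, b0, b1) a0 < b1 & a1 > b0
  tp <- list(); fp <- list()
  if (nrow(pred)) {
    for (i in seq_len(nrow(pred))) {
      hit <- nrow(seiz) > 0 &&
        any(overlaps(pred[i, 1], pred[i, 2], seiz[, 1], seiz[, 2]))
      if (hit) tp[[length(tp) + 1]] <- pred[i, ]
      else fp[[length(fp) + 1]] <- pred[i, ]
    }
  }
  lat <- numeric(0); detected <- 0L
  if (nrow(seiz)) {
    for (s in seq_len(nrow(seiz))) {
      ov <- which(nrow(pred) > 0 &
                    overlaps(pred[, 1], pred[, 2], seiz[s, 1], seiz[s, 2]))
      if (length(ov)) {
        detected <- detected + 1L
        lat <- c(lat, max(0, pred[min(ov), 1] - seiz[s, 1]))
      }
    }
  }
  hours <- tw * window_s / 3600
  structure(list(
    tp_intervals = tp, fp_intervals = fp,
    n_true_seizures = nrow(seiz), n_detected = detected,
    sensitivity = if (nrow(seiz)) detected / nrow(seiz) else NA_real_,
    fp_per_hour = if (hours > 0) length(fp) / hours else NA_real_,
    latencies_s = lat,
    mean_latency_s = if (length(lat)) mean(lat) else NA_real_,
    total_hours = hours), class = "event_score")
}

#' @export
print.event_score <- function(x, ...) {
  cat(sprintf(
    "<event_score> %d/%d seizures detected, %d FP (%.2f/hr), latency %.1f s\n",
    x$n_detected, x$n_true_seizures, length(x$fp_intervals), x$fp_per_hour,
    x$mean_latency_s))
  invisible(x)
}

#' Pool event scores across recordings
#'
#' @param scores list of `event_score`s.
#' @return named list: pooled `sensitivity`, `fp_per_hour`,
#'   `mean_latency_s`, counts.
#' @export
aggregate_event_scores <- function(scores) {
  ns <- sum(vapply(scores, `[[`, 0, "n_true_seizures"))
  nd <- sum(vapply(scores, `[[`, 0, "n_detected"))
  nfp <- sum(vapply(scores, function(s) length(s$fp_intervals), 0))
  hrs <- sum(vapply(scores, `[[`, 0, "total_hours"))
  lat <- unlist(lapply(scores, `[[`, "latencies_s"))
  list(sensitivity = if (ns) nd / ns else NA_real_,
       fp_per_hour = if (hrs > 0) nfp / hrs else NA_real_,
       mean_latency_s = if (length(lat)) mean(lat) else NA_real_,
       n_true_seizures = ns, n_detected = nd, n_fp = nfp,
       total_hours = hrs)
}

#' Localization accuracy over held-out patients
#'
#' Per recording, the onset map's zone scores give a zone prediction; the
#' patient-level prediction averages the channel onset maps across the
#' patient's recordings before taking the arg-max.  Reports per-class
#' accuracy and the class-averaged accuracy (classes weighted equally
#' regardless of size).
#'
#' @param maps list of `channel_prob_map`s, one per recording.
#' @param patient_ids character vector aligned with `maps`.
#' @param true_labels zone label per recording (`part$labels` values);
#'   recordings labeled `"unknown"` are excluded.
#' @param part a `zone_partition`.
#' @return list with `patient_predictions` (data.frame), `per_class`,
#'   `class_averaged`.
#' @export
localization_accuracy <- function(maps, patient_ids, true_labels, part) {
  keep <- true_labels %in% part$labels
  maps <- maps[keep]; patient_ids <- patient_ids[keep]
  true_labels <- true_labels[keep]
  if (!length(maps)) stop_validation("no recordings with known zone labels")
  oms <- lapply(maps, compute_onset_map)
  rows <- list()
  for (p in unique(patient_ids)) {
    idx <- which(patient_ids == p)
    avg <- Reduce(`+`, lapply(oms[idx], `[[`, "channel_scores")) / length(idx)
    om <- structure(list(channel_scores = avg, degenerate = FALSE),
                    class = "onset_map")
    zs <- zone_scores(om, part)
    truth <- unique(true_labels[idx])
    if (length(truth) != 1)
      stop_validation("conflicting zone labels for patient ", p)
    rows[[p]] <- data.frame(patient_id = p,
                            predicted = part$labels[which.max(zs)],
                            truth = truth,
                            score_a = zs[1], score_b = zs[2],
                            row.names = NULL)
  }
  df <- do.call(rbind, rows)
  per_class <- vapply(part$labels, function(cl) {
    n <- sum(df$truth == cl)
    if (n == 0) NA_real_ else mean(df$predicted[df$truth == cl] == cl)
  }, numeric(1))
  list(patient_predictions = df, per_class = per_class,
       class_averaged = mean(per_class, na.rm = TRUE))
}
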