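#' Global detection trace by max-pooling across channels
#'
#' The recording-level seizure probability at window `t` is the maximum
#' predicted probability over the individual channels, so the network
#' registers a seizure as soon as any one electrode enters the seizure
#' state.
#'
#' @param map a `channel_prob_map` (channels x windows).
#' @return numeric vector of length T (the global trace).
#' @export
global_max_pool <- function(map) {
  if (nrow(map) == 0) stop_validation("probability map has zero channels")
  apply(unclass(map), 2, max)
}

#' Positive first differences of the global trace
#'
#' `delta[t] = max(trace[t+1] - trace[t], 0)` over the `T - 1` consecutive
#' window transitions: near 1 for a confident transition from baseline into
#' seizure, and 0 wherever the predicted seizure probability stays the same
#' or decreases.
#'
#' @param trace numeric global trace of length `T >= 2`.
#' @return nonnegative numeric vector of length `T - 1`.
#' @export
onset_increments <- function(trace) {
  if (length(trace) < 2)
    stop_validation("onset increments need at least 2 windows")
  pmax(diff(trace), 0)
}

#' Channel-level seizure-onset-zone map
#'
#' Weights each channel's seizure activity by the onset activity of the
#' global trace and normalizes over channels:
#' `score[i] = sum_t delta[t] * map[i, t+1] / sum_j sum_t delta[t] * map[j, t+1]`.
#' Each transition weights the channel activity at the window just entered.
#' A channel already in seizure at the first window contributes no onset
#' mass; if there is no positive increment anywhere the map degenerates to
#' the uniform distribution and is flagged (`attr(, "degenerate")`).
#'
#' @param map a `channel_prob_map` (channels x windows, `T >= 2`).
#' @param trace optional precomputed global trace (defaults to
#'   [global_max_pool()] of `map`).
#' @return an object of class `onset_map`: list with `channel_scores` (named,
#'   summing to 1), and `degenerate` flag.
#' @export
compute_onset_map <- function(map, trace = NULL) {
  probs <- unclass(map)
  if (is.null(trace)) trace <- global_max_pool(map)
  if (length(trace) != ncol(probs))
    stop_validation("trace length does not match the probability map")
  delta <- onset_increments(trace)
  raw <- as.numeric(probs[, -1, drop = FALSE] %*% delta)
  z <- sum(raw)
  degenerate <- z <= 0
  scores <- if (degenerate) rep(1 / nrow(probs), nrow(probs)) else raw / z
  names(scores) <- rownames(probs)
  structure(list(channel_scores = scores, degenerate = degenerate),
            class = "onset_map")
}

#' @export
print.onset_map <- function(x, ...) {
  top <- names(sort(x$channel_scores, decreasing = TRUE))[1]
  cat(sprintf("<onset_map> %d electrodes, peak %s (%.3f)%s\n",
              length(x$channel_scores), top, max(x$channel_scores),
              if (x$degenerate) " [degenerate: no onset mass]" else ""))
  invisible(x)
}

#' Aggregate an onset map into zone scores
#'
#' Sums the channel onset scores over each zone of a partition and
#' renormalizes the pair so it remains a proper probability distribution
#' after mass on excluded (midline) electrodes is discarded.  If both raw
#' sums are zero the uninformative pair `(0.5, 0.5)` is returned and flagged.
#'
#' @param om an `onset_map`.
#' @param part a `zone_partition`.
#' @return named numeric pair summing to 1, with attribute `degenerate`.
#' @export
zone_scores <- function(om, part) {
  sc <- om$channel_scores
  known <- names(sc) %in% c(part$zone_a, part$zone_b, part$excluded)
  if (!all(known))
    stop_validation("electrode(s) missing from the partition: ",
                    paste(names(sc)[!known], collapse = ", "))
  a <- sum(sc[names(sc) %in% part$zone_a])
  b <- sum(sc[names(sc) %in% part$zone_b])
  tot <- a + b
  if (tot <= 0) {
    out <- c(0.5, 0.5)
    degenerate <- TRUE
  } else {
    out <- c(a, b) / tot
    degenerate <- FALSE
  }
  names(out) <- part$labels
  attr(out, "degenerate") <- degenerate
  out
}

#' Full localization of a probability map
#'
#' Convenience wrapper: onset map plus hemisphere and region scores.
#'
#' @param map a `channel_prob_map`.
#' @param montage electrode list for the partitions (defaults to the map's
#'   channels).
#' @return an `onset_map` with `hemisphere_scores` and `region_scores`.
#' @export
localize_map <- function(map, montage = rownames(map)) {
  om <- compute_onset_map(map)
  om$hemisphere_scores <- zone_scores(om, hemisphere_partition(montage))
  om$region_scores <- zone_scores(om, region_partition(montage))
  om
}

#' Write an onset map to CSV (electrode, score)
#' @param om an `onset_map`.
#' @param path output path.
#' @export
write_onset_map <- function(om, path) {
  write.csv(data.frame(electrode = names(om$channel_scores),
                       score = unname(om$channel_scores)),
            path, row.names = FALSE)
  invisible(path)
}
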