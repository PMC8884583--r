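#' Default 10-20 scalp montage
#'
#' The 16 lateral electrodes of the 10-20 placement system in a fixed
#' frontal-to-occipital order, optionally followed by the midline electrodes
#' Fz, Cz, Pz.  Midline electrodes carry no lateralization information and
#' are excluded from both localization partitions, so they are off by
#' default.  Order is deterministic across calls.
#'
#' @param include_midline include Fz, Cz, Pz.
#' @return ordered character vector of electrode names.
#' @export
default_montage <- function(include_midline = FALSE) {
  m <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
         "T7", "C3", "Cz", "C4", "T8",
         "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  if (!include_midline) m <- setdiff(m, c("Fz", "Cz", "Pz"))
  m
}

#' Zone partition of the montage
#'
#' @param name `"hemisphere"` or `"region"`.
#' @param zone_a,zone_b disjoint electrode sets covering the montage together
#'   with `excluded`.
#' @param excluded electrodes scored by the model but belonging to neither
#'   zone (midline).
#' @return an object of class `zone_partition`.
#' @export
zone_partition <- function(name, zone_a, zone_b, excluded = character(0),
                           labels = c("a", "b")) {
  if (length(intersect(zone_a, zone_b)))
    stop_validation("zones overlap: ",
                    paste(intersect(zone_a, zone_b), collapse = ", "))
  structure(list(name = name, zone_a = zone_a, zone_b = zone_b,
                 excluded = excluded, labels = labels),
            class = "zone_partition")
}

#' Left/right hemisphere partition
#'
#' Odd-numbered 10-20 electrodes form the left hemisphere, even-numbered the
#' right; midline (z) electrodes are excluded.
#'
#' @param montage electrode list the partition must cover.
#' @return a `zone_partition` with labels `c("left", "right")`.
#' @export
hemisphere_partition <- function(montage = default_montage()) {
  left <- c("Fp1", "F3", "F7", "C3", "T7", "P3", "P7", "O1")
  right <- c("Fp2", "F4", "F8", "C4", "T8", "P4", "P8", "O2")
  p <- zone_partition("hemisphere",
                      intersect(montage, left), intersect(montage, right),
                      setdiff(montage, c(left, right)),
                      labels = c("left", "right"))
  check_partition(p, montage)
  p
}

#' Anterior/posterior head-region partition
#'
#' The anterior zone holds the frontal-row electrodes (coarsely aligned with
#' frontal-lobe seizure foci); the posterior zone holds central, temporal,
#' parietal and occipital electrodes (temporal and parietal foci).  F7/F8 sit
#' on the frontal/temporal border and must live in exactly one zone; they are
#' assigned anterior here (F-row), overridable via `overrides`.
#'
#' @param montage electrode list the partition must cover.
#' @param overrides named character vector mapping electrode ->
#'   `"anterior"`/`"posterior"` to move individual electrodes.
#' @return a `zone_partition` with labels `c("anterior", "posterior")`.
#' @export
region_partition <- function(montage = default_montage(),
                             overrides = NULL) {
  anterior <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz")
  posterior <- c("C3", "C4", "T7", "T8", "P3", "P4", "P7", "P8",
                 "O1", "O2", "Cz", "Pz")
  for (el in names(overrides)) {
    anterior <- setdiff(anterior, el)
    posterior <- setdiff(posterior, el)
    if (overrides[[el]] == "anterior") anterior <- c(anterior, el)
    else posterior <- c(posterior, el)
  }
  p <- zone_partition("region",
                      intersect(montage, anterior),
                      intersect(montage, posterior),
                      setdiff(montage, c(anterior, posterior)),
                      labels = c("anterior", "posterior"))
  check_partition(p, montage)
  p
}

check_partition <- function(p, montage) {
  covered <- c(p$zone_a, p$zone_b, p$excluded)
  if (!setequal(covered, montage) ||
      length(covered) != length(montage))
    stop_validation("partition does not cover the montage exactly once")
  invisible(p)
}

#' Zone membership lookup
#' @param p a `zone_partition`.
#' @param electrodes character vector.
#' @return factor with levels `p$labels` plus `"excluded"`.
#' @export
zone_of <- function(p, electrodes) {
  out <- ifelse(electrodes %in% p$zone_a, p$labels[1],
                ifelse(electrodes %in% p$zone_b, p$labels[2], "excluded"))
  factor(out, levels = c(p$labels, "excluded"))
}
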