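# Per-nodule analysis: FROC curves, sensitivity at fixed false-positive
# rates, the competition performance metric (CPM), and 6 mm size-subgroup
# construction.

default_fp_rates <- c(1/8, 1/4, 1/2, 1, 2, 4)

# Interpolate FROC sensitivity at target FP rates.
# `fp`/`sens` are the achieved sweep points in threshold-descending order
# (both non-decreasing). At a query rate equal to an achieved FP value the
# highest sensitivity there applies (the top of a vertical segment);
# strictly between two achieved values, "linear" interpolates between the
# top of the left segment and the bottom of the right one - i.e. along the
# sweep path - while "step" carries the left value forward. Below the
# smallest achieved rate the sensitivity is 0; above the largest, the final
# plateau applies.
froc_interpolate <- function(fp, sens, rates, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  vs <- sort(unique(fp))
  smax <- vapply(vs, function(v) max(sens[fp == v]), 0)
  smin <- vapply(vs, function(v) min(sens[fp == v]), 0)
  k <- length(vs)
  vapply(rates, function(f) {
    if (f < vs[1L]) return(0)
    if (f >= vs[k]) return(smax[k])
    j <- findInterval(f, vs)
    if (f == vs[j]) return(smax[j])
    if (interpolation == "step") return(smax[j])
    smax[j] + (smin[j + 1L] - smax[j]) * (f - vs[j]) / (vs[j + 1L] - vs[j])
  }, 0)
}

#' FROC curve and CPM for a matched nodule set
#'
#' Sweeps the decision threshold over the distinct mark confidences (plus
#' `Inf`). At each threshold `t`, the nodule-level sensitivity is the
#' fraction of qualifying nodules with at least one lesion-localizing mark
#' of confidence `>= t`, and the false-positive rate is the number of
#' non-lesion marks with confidence `>= t` divided by the number of scans.
#' Sensitivities at the target FP rates are read off the curve (see
#' `interpolation`), and the CPM is their arithmetic mean.
#'
#' @param match A `cad_match` from [match_marks()].
#' @param fp_rates Target false-positive-per-scan rates, strictly
#'   increasing. Default `1/8, 1/4, 1/2, 1, 2, 4`.
#' @param interpolation `"linear"` (default) interpolates between achieved
#'   curve points; `"step"` carries the last achieved sensitivity forward.
#' @param fp_scan_denominator `"all"` (default) divides false positives by
#'   included abnormal plus normal scans; `"abnormal"` restricts both the
#'   false-positive count and the denominator to included abnormal scans.
#' @return A `froc_result`: list with `points` (threshold, fp_per_scan,
#'   sensitivity), `fp_rates`, `sensitivities_at_rates`, `cpm`,
#'   `n_nodules`, `n_scans`.
#' @export
froc <- function(match, fp_rates = default_fp_rates,
                 interpolation = c("linear", "step"),
                 fp_scan_denominator = c("all", "abnormal")) {
  stopifnot(inherits(match, "cad_match"))
  interpolation <- match.arg(interpolation)
  fp_scan_denominator <- match.arg(fp_scan_denominator)
  if (any(diff(fp_rates) <= 0) || any(fp_rates <= 0))
    stop_validation("froc(): fp_rates must be positive and strictly increasing")

  ns <- match$nodule_set
  nodules <- ns$nodules
  if (nrow(nodules) == 0L)
    stop_undefined("froc(): the nodule set has no qualifying nodules")
  scans <- if (fp_scan_denominator == "all")
    c(ns$abnormal_scans, ns$normal_scans) else ns$abnormal_scans
  n_scans <- length(scans)
  if (n_scans == 0L) stop_undefined("froc(): empty scan list")

  mk <- match$marks
  lesion <- mk[mk$label == "lesion", , drop = FALSE]
  # best (highest-confidence) hitting mark per nodule; -Inf when never hit
  best <- rep(-Inf, nrow(nodules))
  if (nrow(lesion)) {
    agg <- tapply(lesion$probability, lesion$matched_nodule_id, max)
    idx <- match(names(agg), nodules$nodule_id)
    best[idx] <- as.numeric(agg)
  }
  fp_conf <- mk$probability[mk$label == "non_lesion" & mk$scan_id %in% scans]

  thresholds <- c(Inf, sort(unique(c(lesion$probability, fp_conf)),
                            decreasing = TRUE))
  sens <- vapply(thresholds, function(t) mean(best >= t), 0)
  fp <- vapply(thresholds, function(t) sum(fp_conf >= t), 0) / n_scans

  sens_at <- froc_interpolate(fp, sens, fp_rates, interpolation)
  structure(list(
    points = data.frame(threshold = thresholds, fp_per_scan = fp,
                        sensitivity = sens),
    fp_rates = fp_rates,
    sensitivities_at_rates = sens_at,
    cpm = cpm(sens_at),
    n_nodules = nrow(nodules),
    n_scans = n_scans
  ), class = "froc_result")
}

#' @export
print.froc_result <- function(x, ...) {
  cat(sprintf("FROC over %d nodules on %d scans\n", x$n_nodules, x$n_scans))
  cat("  FP/scan:     ", paste(format(x$fp_rates, digits = 3), collapse = "  "), "\n")
  cat("  sensitivity: ", paste(sprintf("%.3f", x$sensitivities_at_rates),
                               collapse = "  "), "\n")
  cat(sprintf("  CPM = %.3f\n", x$cpm))
  invisible(x)
}

#' Competition performance metric
#'
#' The CPM is the arithmetic mean of the nodule-level sensitivities at the
#' fixed false-positive-per-scan rates (conventionally 1/8, 1/4, 1/2, 1, 2
#' and 4).
#'
#' @param sensitivities_at_rates Non-empty numeric vector of sensitivities,
#'   each in `[0, 1]`.
#' @return Their mean.
#' @export
cpm <- function(sensitivities_at_rates) {
  if (length(sensitivities_at_rates) == 0L)
    stop_validation("cpm(): empty sensitivity list")
  if (any(!is.finite(sensitivities_at_rates)) ||
      any(sensitivities_at_rates < 0 | sensitivities_at_rates > 1))
    stop_validation("cpm(): sensitivities must be finite and in [0, 1]")
  mean(sensitivities_at_rates)
}

#' Restrict a nodule set to a diameter subgroup
#'
#' Keeps as qualifying only the nodules on the requested side of the size
#' threshold (`lt`: diameter strictly below; `ge`: at or above, so a nodule
#' of exactly the threshold diameter belongs to the `ge` subgroup).
#' Out-of-subgroup qualifying nodules become irrelevant: CAD marks on them
#' count neither as true nor as false positives. The included scan list is
#' unchanged (so false-positive denominators are comparable across
#' subgroups); scans holding at least one in-subgroup nodule are recorded
#' in `subgroup_scans` and serve as the positive class in per-scan subgroup
#' ROC analysis. A scan with nodules on both sides of the threshold belongs
#' to both subgroups.
#'
#' @param nodule_set A `nodule_set`.
#' @param threshold_mm Size threshold in mm, default 6.
#' @param side `"lt"` or `"ge"`.
#' @return A new `nodule_set` with `subgroup` and `subgroup_scans` set.
#' @export
subgroup_nodules <- function(nodule_set, threshold_mm = 6, side = c("lt", "ge")) {
  stopifnot(inherits(nodule_set, "nodule_set"))
  side <- match.arg(side)
  if (!is.numeric(threshold_mm) || threshold_mm <= 0)
    stop_validation("subgroup_nodules(): threshold_mm must be positive")
  keep <- if (side == "lt") nodule_set$nodules$diameter_mm < threshold_mm
          else nodule_set$nodules$diameter_mm >= threshold_mm
  out <- nodule_set
  out$nodules <- nodule_set$nodules[keep, , drop = FALSE]
  out$irrelevant_nodules <- rbind(nodule_set$irrelevant_nodules,
                                  nodule_set$nodules[!keep, , drop = FALSE])
  out$subgroup <- list(threshold_mm = threshold_mm, side = side)
  out$subgroup_scans <- sort(unique(out$nodules$scan_id))
  out
}

#' Per-scan scores for a size subgroup
#'
#' Rebuilds the subgrouped ground truth, re-matches the marks against it,
#' and assembles scan scores in which the positives are the abnormal scans
#' holding at least one in-subgroup nodule and the negatives are all normal
#' scans. Scan probabilities are maximum mark confidences as in
#' [scan_scores()].
#'
#' @param match A `cad_match` produced against the full (un-subgrouped)
#'   nodule set.
#' @inheritParams subgroup_nodules
#' @return Data frame of scan scores (see [scan_scores()]).
#' @export
perscan_subgroup_scores <- function(match, threshold_mm = 6, side = c("lt", "ge")) {
  stopifnot(inherits(match, "cad_match"))
  side <- match.arg(side)
  sub <- subgroup_nodules(match$nodule_set, threshold_mm, side)
  if (length(sub$subgroup_scans) == 0L)
    stop_undefined(sprintf(
      "perscan_subgroup_scores(): no abnormal scan has a nodule with diameter %s %g mm",
      if (side == "lt") "<" else ">=", threshold_mm))
  rematch <- match_marks(match$marks[.mark_cols], sub,
                         hit_multiplier = match$hit_multiplier,
                         strict = match$strict)
  scan_scores(rematch)
}
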