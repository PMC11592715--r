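# Scan-level analysis: maximum-confidence scan scores, Mann-Whitney AUC,
# DeLong structural-component variance/covariance, paired AUC comparison,
# and operating-point metrics.

#' Scan-level probability
#'
#' The scan-level score is the highest confidence over all retained CAD
#' marks on the scan, regardless of mark label (on abnormal scans both
#' lesion and non-lesion localizations contribute; on normal scans only
#' non-lesion marks exist). A scan with no marks scores exactly 0, so a
#' normal scan with no detections counts as correctly low.
#'
#' @param match A `cad_match` from [match_marks()].
#' @param scan_id Scan identifier.
#' @return A single number in `[0, 1]`.
#' @export
scan_probability <- function(match, scan_id) {
  stopifnot(inherits(match, "cad_match"))
  p <- match$marks$probability[match$marks$scan_id == scan_id]
  if (length(p) == 0L) 0 else max(p)
}

#' Assemble scan-level scores for ROC analysis
#'
#' Positives are the included abnormal scans of the active nodule set (or,
#' for a subgrouped set, the scans holding at least one in-subgroup
#' nodule); negatives are all normal scans. Each scan's probability is the
#' maximum mark confidence, 0 when the scan has no marks.
#'
#' @param match A `cad_match`.
#' @return Data frame with `scan_id`, `truth` (logical, `TRUE` = abnormal),
#'   `probability`.
#' @export
scan_scores <- function(match) {
  stopifnot(inherits(match, "cad_match"))
  ns <- match$nodule_set
  positives <- ns$subgroup_scans %||% ns$abnormal_scans
  if (length(positives) == 0L)
    stop_undefined("scan_scores(): no positive scans in the active (sub)set")
  scans <- c(positives, ns$normal_scans)
  prob <- vapply(scans, function(s) scan_probability(match, s), 0)
  data.frame(scan_id = scans,
             truth = rep(c(TRUE, FALSE),
                         c(length(positives), length(ns$normal_scans))),
             probability = unname(prob),
             stringsAsFactors = FALSE)
}

check_scores <- function(scores, need_both = TRUE) {
  stopifnot(is.data.frame(scores),
            all(c("truth", "probability") %in% names(scores)))
  m <- sum(scores$truth); n <- sum(!scores$truth)
  if (need_both && (m == 0L || n == 0L))
    stop_undefined("ROC undefined: need at least one positive and one negative scan")
  invisible(list(m = m, n = n))
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The AUC is the mean over all (positive, negative) scan pairs of the
#' kernel: 1 when the positive scores higher, 1/2 on a tie, 0 otherwise.
#' Computed via midranks, which is algebraically identical to the pairwise
#' mean.
#'
#' @param scores Data frame with logical `truth` and numeric `probability`
#'   (as from [scan_scores()]).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores) {
  check_scores(scores)
  pos <- scores$probability[scores$truth]
  neg <- scores$probability[!scores$truth]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: v10[i] = mean_j psi(pos_i, neg_j),
# v01[j] = mean_i psi(pos_i, neg_j), with the tie kernel psi = 1/0.5/0.
delong_components <- function(pos, neg) {
  K <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(auc = mean(K), v10 = rowMeans(K), v01 = colMeans(K))
}

#' DeLong variance of the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from structural
#' components: `var = S10 / n_pos + S01 / n_neg`, where `S10` and `S01` are
#' the sample variances of the per-positive and per-negative components.
#'
#' @inheritParams roc_auc
#' @return The estimated variance (a single non-negative number).
#' @export
delong_variance <- function(scores) {
  cnt <- check_scores(scores)
  if (cnt$m < 2L || cnt$n < 2L)
    stop_undefined("DeLong variance undefined: need >= 2 positives and >= 2 negatives")
  comp <- delong_components(scores$probability[scores$truth],
                            scores$probability[!scores$truth])
  var(comp$v10) / cnt$m + var(comp$v01) / cnt$n
}

#' ROC summary with DeLong confidence interval
#'
#' @inheritParams roc_auc
#' @param conf_level Confidence level; the interval is the normal
#'   approximation `auc +/- z * sqrt(var)`, clipped to `[0, 1]`.
#' @param operating Optional operating point, passed as a list of arguments
#'   to [operating_point()] (e.g. `list(target_specificity = 0.8)`).
#' @return A `roc_result`: list with `auc`, `auc_variance`, `ci95`,
#'   `n_pos`, `n_neg`, and optionally `operating_point`.
#' @export
roc_with_ci <- function(scores, conf_level = 0.95, operating = NULL) {
  cnt <- check_scores(scores)
  auc <- roc_auc(scores)
  v <- delong_variance(scores)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
  res <- list(auc = auc, auc_variance = v, ci95 = ci,
              n_pos = cnt$m, n_neg = cnt$n, operating_point = NULL)
  if (!is.null(operating))
    res$operating_point <- do.call(operating_point, c(list(scores), operating))
  structure(res, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  if (!is.null(x$operating_point))
    with(x$operating_point,
         cat(sprintf("  operating point: threshold %.3f, accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
                     threshold, accuracy, sensitivity, specificity)))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of the same scans scored under two conditions. The
#' difference's variance uses the DeLong structural-component covariance:
#' `z = (auc_b - auc_a) / sqrt(var_a + var_b - 2 cov)`, with a two-sided
#' normal p-value. When the variance of the difference is exactly zero the
#' documented convention is `p = 1` if the AUCs are equal and `p = 0`
#' otherwise.
#'
#' @param a,b Score data frames for the two conditions; they must cover the
#'   same scans with the same truth labels (rows are aligned by `scan_id`
#'   when present, otherwise by position).
#' @return A `delong_test`: list with `auc_a`, `auc_b`, `delta`
#'   (`auc_b - auc_a`), `z`, `p_value`, and the variance pieces.
#' @export
delong_paired_test <- function(a, b) {
  check_scores(a); check_scores(b)
  if (!is.null(a$scan_id) && !is.null(b$scan_id)) {
    a <- a[order(a$scan_id), , drop = FALSE]
    b <- b[order(b$scan_id), , drop = FALSE]
    if (!identical(a$scan_id, b$scan_id))
      stop_validation("delong_paired_test(): the two conditions cover different scans")
  } else if (nrow(a) != nrow(b)) {
    stop_validation("delong_paired_test(): unequal numbers of scans")
  }
  if (!identical(a$truth, b$truth))
    stop_validation("delong_paired_test(): truth labels differ between conditions")
  m <- sum(a$truth); n <- sum(!a$truth)
  if (m < 2L || n < 2L)
    stop_undefined("paired DeLong test undefined: need >= 2 positives and >= 2 negatives")

  ca <- delong_components(a$probability[a$truth], a$probability[!a$truth])
  cb <- delong_components(b$probability[b$truth], b$probability[!b$truth])
  var_a <- var(ca$v10) / m + var(ca$v01) / n
  var_b <- var(cb$v10) / m + var(cb$v01) / n
  cov_ab <- cov(ca$v10, cb$v10) / m + cov(ca$v01, cb$v01) / n
  delta <- cb$auc - ca$auc
  var_d <- var_a + var_b - 2 * cov_ab

  if (var_d <= 0 || !is.finite(var_d)) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    z <- delta / sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
                 p_value = p, var_a = var_a, var_b = var_b, cov_ab = cov_ab),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC %.3f vs %.3f (delta %+.3f), z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p_value))
  invisible(x)
}

#' Operating-point metrics at a threshold
#'
#' A scan is predicted positive when its probability is `>= threshold`
#' (closed on the positive side). In `target_specificity` mode the
#' threshold is the smallest candidate (the distinct observed scores, plus
#' `Inf`) whose specificity is at least the target.
#'
#' @inheritParams roc_auc
#' @param threshold Fixed decision threshold (exclusive with
#'   `target_specificity`).
#' @param target_specificity Specificity target in `[0, 1]`.
#' @return List with `threshold`, `accuracy`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(scores, threshold = NULL, target_specificity = NULL) {
  check_scores(scores)
  if (is.null(threshold) == is.null(target_specificity))
    stop_validation("operating_point(): give exactly one of threshold, target_specificity")
  truth <- scores$truth
  at <- function(t) {
    pred <- scores$probability >= t
    list(threshold = t,
         accuracy = mean(pred == truth),
         sensitivity = mean(pred[truth]),
         specificity = mean(!pred[!truth]))
  }
  if (!is.null(threshold)) return(at(threshold))
  if (target_specificity > 1 || target_specificity < 0)
    stop_validation("operating_point(): target specificity must be in [0, 1]")
  candidates <- c(sort(unique(scores$probability)), Inf)
  for (t in candidates) {
    op <- at(t)
    if (op$specificity >= target_specificity) return(op)
  }
  stop_undefined("operating_point(): specificity target unattainable")  # unreachable
}
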