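# CSV dialects, report assembly, and the end-to-end evaluation driver.
#
# Annotation CSV: scan_id, reader_id, coordX, coordY, coordZ,
#   major_axis_mm, minor_axis_mm (world mm, period decimal separator,
#   header required).
# Manifest CSV: scan_id, label in {abnormal, normal}.
# Mark CSV (LUNA16 candidates dialect): seriesuid (or scan_id), coordX,
#   coordY, coordZ, probability in [0, 1].
# Consensus CSV: nodule_id, scan_id, coordX, coordY, coordZ, diameter_mm,
#   n_readers.

read_csv_strict <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("%s: file not found", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a multi-reader annotation CSV
#'
#' @param path Path to a CSV with columns `scan_id`, `reader_id`,
#'   `coordX`, `coordY`, `coordZ`, `major_axis_mm`, `minor_axis_mm`.
#' @return Validated annotation data frame. Malformed rows raise an error
#'   naming the file, row and column.
#' @export
read_annotations <- function(path) {
  validate_annotations(read_csv_strict(path), file = path)
}

#' Read a scan manifest CSV
#'
#' @param path Path to a CSV with columns `scan_id` and `label`
#'   (`abnormal` or `normal`).
#' @return Validated manifest data frame.
#' @export
read_scan_manifest <- function(path) {
  validate_manifest(read_csv_strict(path), file = path)
}

#' Read a CAD mark CSV (LUNA16 candidates dialect)
#'
#' @param path Path to a CSV with columns `seriesuid` (or `scan_id`),
#'   `coordX`, `coordY`, `coordZ`, `probability`.
#' @return Validated mark data frame (column `scan_id`).
#' @export
read_cad_marks <- function(path) {
  validate_marks(read_csv_strict(path), file = path)
}

#' Write annotation / manifest / mark / consensus tables
#'
#' Plain CSV writers for the dialects read by the `read_*` functions.
#' Numeric columns round-trip to well below 1e-9 mm.
#'
#' @param x Table to write.
#' @param path Output path.
#' @name cadeval-writers
NULL

#' @rdname cadeval-writers
#' @export
write_annotations <- function(x, path) {
  write.csv(validate_annotations(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cadeval-writers
#' @export
write_scan_manifest <- function(x, path) {
  write.csv(validate_manifest(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cadeval-writers
#' @export
write_cad_marks <- function(x, path) {
  write.csv(validate_marks(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cadeval-writers
#' @export
write_consensus <- function(x, path) {
  cols <- c("nodule_id", "scan_id", "coordX", "coordY", "coordZ",
            "diameter_mm", "n_readers")
  write.csv(x[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

roc_report <- function(r) {
  if (is.null(r)) return(NULL)
  list(auc = r$auc, auc_variance = r$auc_variance,
       ci95 = list(lo = r$ci95[1], hi = r$ci95[2]),
       n_pos = r$n_pos, n_neg = r$n_neg,
       operating_point = r$operating_point)
}

froc_report <- function(f) {
  if (is.null(f)) return(NULL)
  list(fp_rates = f$fp_rates, sensitivities = f$sensitivities_at_rates,
       cpm = f$cpm, n_nodules = f$n_nodules, n_scans = f$n_scans)
}

comparison_report <- function(x) {
  if (is.null(x)) return(NULL)
  list(auc_a = x$auc_a, auc_b = x$auc_b, delta = x$delta, z = x$z,
       p_value = x$p_value)
}

#' Run the full two-condition evaluation
#'
#' Executes the complete analysis: consolidate reader annotations, build
#' the agreement-graded nodule set, match each condition's CAD marks,
#' compute scan-level ROC/AUC with DeLong confidence intervals (overall and
#' per 6 mm size subgroup), FROC curves with CPM (overall and per
#' subgroup), and - when exactly two conditions are supplied - paired
#' DeLong comparisons between them.
#'
#' @param manifest Scan manifest data frame (or a `read_scan_manifest()`
#'   result).
#' @param annotations Reader annotation data frame.
#' @param marks Named list of CAD mark data frames, one per condition.
#' @param set_label `"A"` (>= 2 of 3 readers) or `"B"` (all 3).
#' @param hit_multiplier,merge_multiplier Radius multipliers for the hit
#'   and same-nodule rules (defaults 1.5).
#' @param fp_rates FROC target false-positive rates.
#' @param fp_scan_denominator `"all"` or `"abnormal"` (see [froc()]).
#' @param subgroup_threshold_mm Size threshold for subgroup analyses
#'   (default 6; `NULL` to skip subgroups).
#' @param operating Optional operating-point arguments (see
#'   [roc_with_ci()]), e.g. `list(target_specificity = 0.8)`.
#' @param strict Count marks on sub-agreement nodules as false positives
#'   (default `FALSE`: they are ignored).
#' @return A `cad_report` list: `nodule_set` summary and accounting,
#'   per-condition results (`roc`, `froc`, subgroup variants, match label
#'   counts), and `comparisons` (paired DeLong tests and CPM deltas).
#' @export
run_evaluation <- function(manifest, annotations, marks,
                           set_label = c("B", "A"),
                           hit_multiplier = 1.5, merge_multiplier = 1.5,
                           fp_rates = default_fp_rates,
                           fp_scan_denominator = c("all", "abnormal"),
                           subgroup_threshold_mm = 6,
                           operating = NULL, strict = FALSE) {
  set_label <- match.arg(set_label)
  fp_scan_denominator <- match.arg(fp_scan_denominator)
  if (hit_multiplier <= 0 || merge_multiplier <= 0)
    stop_validation("run_evaluation(): multipliers must be positive")
  if (!is.list(marks) || is.null(names(marks)) || any(names(marks) == ""))
    stop_validation("run_evaluation(): marks must be a named list, one table per condition")
  manifest <- validate_manifest(manifest)

  consensus <- consolidate_annotations(annotations, merge_multiplier)
  ns <- build_nodule_set(consensus, manifest, set_label)
  if (nrow(ns$nodules) == 0L)
    stop_undefined(sprintf(
      "run_evaluation(): nodule set %s is empty (no nodule reaches %d-reader agreement)",
      set_label, ns$min_agreement))

  eval_condition <- function(mk) {
    m <- match_marks(mk, ns, hit_multiplier, strict)
    sc <- scan_scores(m)
    out <- list(
      match_counts = as.list(table(factor(
        m$marks$label, levels = c("lesion", "irrelevant", "non_lesion")))),
      n_marks_dropped = m$n_dropped,
      scores = sc,
      roc = roc_with_ci(sc, operating = operating),
      froc = froc(m, fp_rates, fp_scan_denominator = fp_scan_denominator),
      subgroups = NULL)
    if (!is.null(subgroup_threshold_mm)) {
      out$subgroups <- lapply(setNames(c("lt", "ge"), c("lt", "ge")), function(side) {
        sub <- subgroup_nodules(ns, subgroup_threshold_mm, side)
        if (nrow(sub$nodules) == 0L) return(NULL)
        msub <- match_marks(mk, sub, hit_multiplier, strict)
        scsub <- scan_scores(msub)
        list(scores = scsub,
             roc = roc_with_ci(scsub, operating = operating),
             froc = froc(msub, fp_rates, fp_scan_denominator = fp_scan_denominator))
      })
    }
    out
  }

  conditions <- lapply(marks, eval_condition)

  comparisons <- NULL
  if (length(conditions) == 2L) {
    cn <- names(conditions)
    a <- conditions[[1L]]; b <- conditions[[2L]]
    comparisons <- list(
      conditions = cn,
      roc = delong_paired_test(a$scores, b$scores),
      cpm_delta = b$froc$cpm - a$froc$cpm,
      subgroups = NULL)
    if (!is.null(subgroup_threshold_mm)) {
      comparisons$subgroups <- lapply(setNames(c("lt", "ge"), c("lt", "ge")),
                                      function(side) {
        sa <- a$subgroups[[side]]; sb <- b$subgroups[[side]]
        if (is.null(sa) || is.null(sb)) return(NULL)
        list(roc = delong_paired_test(sa$scores, sb$scores),
             cpm_delta = sb$froc$cpm - sa$froc$cpm)
      })
    }
  }

  structure(list(
    set_label = set_label,
    parameters = list(hit_multiplier = hit_multiplier,
                      merge_multiplier = merge_multiplier,
                      fp_rates = fp_rates,
                      fp_scan_denominator = fp_scan_denominator,
                      subgroup_threshold_mm = subgroup_threshold_mm,
                      strict = strict),
    accounting = list(
      n_abnormal_manifest = sum(manifest$label == "abnormal"),
      n_normal = sum(manifest$label == "normal"),
      n_included = length(ns$abnormal_scans),
      n_excluded = length(ns$excluded_scans),
      n_nodules = nrow(ns$nodules),
      n_irrelevant_nodules = nrow(ns$irrelevant_nodules)),
    nodule_set = ns,
    conditions = conditions,
    comparisons = comparisons
  ), class = "cad_report")
}

#' @export
print.cad_report <- function(x, ...) {
  cat(sprintf("CAD evaluation, nodule set %s\n", x$set_label))
  with(x$accounting, cat(sprintf(
    "  scans: %d abnormal (%d included, %d excluded), %d normal; %d nodules\n",
    n_abnormal_manifest, n_included, n_excluded, n_normal, n_nodules)))
  for (cn in names(x$conditions)) {
    cc <- x$conditions[[cn]]
    cat(sprintf("  [%s] AUC %.3f (%.3f-%.3f), CPM %.3f\n", cn,
                cc$roc$auc, cc$roc$ci95[1], cc$roc$ci95[2], cc$froc$cpm))
  }
  if (!is.null(x$comparisons)) {
    cmp <- x$comparisons
    cat(sprintf("  paired DeLong %s vs %s: delta AUC %+.3f, p = %.4g; delta CPM %+.3f\n",
                cmp$conditions[1], cmp$conditions[2], cmp$roc$delta,
                cmp$roc$p_value, cmp$cpm_delta))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (full-precision numbers) plus per-condition ROC and
#' FROC curve CSVs into `dir`.
#'
#' @param report A `cad_report` from [run_evaluation()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cad_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  json <- list(
    set_label = report$set_label,
    parameters = report$parameters,
    accounting = report$accounting,
    conditions = lapply(report$conditions, function(cc) {
      list(match_counts = cc$match_counts,
           n_marks_dropped = cc$n_marks_dropped,
           roc = roc_report(cc$roc),
           froc = froc_report(cc$froc),
           subgroups = lapply(cc$subgroups, function(s) {
             if (is.null(s)) NULL
             else list(roc = roc_report(s$roc), froc = froc_report(s$froc))
           }))
    }),
    comparisons = if (is.null(report$comparisons)) NULL else list(
      conditions = report$comparisons$conditions,
      roc = comparison_report(report$comparisons$roc),
      cpm_delta = report$comparisons$cpm_delta,
      subgroups = lapply(report$comparisons$subgroups, function(s) {
        if (is.null(s)) NULL
        else list(roc = comparison_report(s$roc), cpm_delta = s$cpm_delta)
      })))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  for (cn in names(report$conditions)) {
    cc <- report$conditions[[cn]]
    write.csv(cc$froc$points,
              file.path(dir, sprintf("froc_%s.csv", cn)), row.names = FALSE)
    sc <- cc$scores
    th <- c(Inf, sort(unique(sc$probability), decreasing = TRUE))
    curve <- data.frame(
      threshold = th,
      fpr = vapply(th, function(t) mean(sc$probability[!sc$truth] >= t), 0),
      tpr = vapply(th, function(t) mean(sc$probability[sc$truth] >= t), 0))
    write.csv(curve, file.path(dir, sprintf("roc_%s.csv", cn)),
              row.names = FALSE)
  }
  invisible(dir)
}
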