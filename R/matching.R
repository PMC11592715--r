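# Classification of CAD marks against consensus ground truth.
#
# A mark localizes a nodule when its centre lies strictly within
# `hit_multiplier` times the nodule radius (consensus diameter / 2),
# Euclidean distance over x, y, z in world mm. Marks hitting only
# sub-agreement ("irrelevant") nodules are excluded from both true- and
# false-positive counting, the convention used for sub-threshold
# annotations in LUNA16-style evaluation.

.mark_cols <- c("scan_id", "coordX", "coordY", "coordZ", "probability")

validate_marks <- function(marks, file = NULL) {
  src <- if (is.null(file)) "" else sprintf("%s: ", file)
  if (!is.data.frame(marks))
    stop_validation(sprintf("%smarks must be a data.frame", src))
  if ("seriesuid" %in% names(marks) && !"scan_id" %in% names(marks))
    names(marks)[names(marks) == "seriesuid"] <- "scan_id"
  missing_cols <- setdiff(.mark_cols, names(marks))
  if (length(missing_cols))
    stop_validation(sprintf("%smissing column(s): %s", src,
                            paste(missing_cols, collapse = ", ")))
  marks <- marks[.mark_cols]
  marks$scan_id <- as.character(marks$scan_id)
  if (nrow(marks) == 0L)
    for (cl in setdiff(.mark_cols, "scan_id"))
      marks[[cl]] <- as.numeric(marks[[cl]])
  for (cl in c("coordX", "coordY", "coordZ", "probability")) {
    v <- marks[[cl]]
    if (!is.numeric(v))
      stop_validation(sprintf("%scolumn '%s' is not numeric", src, cl))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_validation(sprintf("%snon-finite value in column '%s', row %d",
                              src, cl, bad[1L]))
  }
  bad <- which(marks$probability < 0 | marks$probability > 1)
  if (length(bad))
    stop_validation(sprintf(
      "%sconfidence outside [0, 1] in column 'probability', row %d",
      src, bad[1L]))
  rownames(marks) <- NULL
  marks
}

#' Does a CAD mark hit a consensus nodule?
#'
#' A mark localizes a nodule when the Euclidean distance (x, y, z, world mm)
#' from the mark centre to the consensus centre is strictly less than
#' `hit_multiplier` times the nodule radius (half the consensus diameter).
#' The nodule's own size defines the tolerance; the mark's size estimate, if
#' any, is ignored.
#'
#' @param mark One CAD mark (one-row data frame or list: `scan_id`,
#'   `coordX`, `coordY`, `coordZ`).
#' @param nodule One consensus nodule (`scan_id`, `coordX`, `coordY`,
#'   `coordZ`, `diameter_mm`).
#' @param hit_multiplier Radius multiple, default 1.5.
#' @return `TRUE` or `FALSE` (strict inequality: a mark exactly at the
#'   threshold distance is a miss).
#' @export
is_hit <- function(mark, nodule, hit_multiplier = 1.5) {
  if (as.character(mark$scan_id) != as.character(nodule$scan_id))
    stop_validation("is_hit(): mark and nodule are from different scans")
  d <- sqrt((mark$coordX - nodule$coordX)^2 + (mark$coordY - nodule$coordY)^2 +
              (mark$coordZ - nodule$coordZ)^2)
  as.logical(d < hit_multiplier * nodule$diameter_mm / 2)
}

#' Match CAD marks to a nodule set
#'
#' Labels every retained mark as `lesion` (hits at least one qualifying
#' nodule; assigned to the nearest hit nodule, ties broken by smaller
#' `nodule_id`), `irrelevant` (hits no qualifying nodule but at least one
#' sub-agreement nodule), or `non_lesion` (a false-positive candidate).
#' Marks on scans excluded from the active nodule set are dropped and
#' counted. Duplicate identical marks are retained: they inflate
#' false-positive counts but a nodule still counts once toward sensitivity.
#'
#' @param marks Data frame of CAD marks (`scan_id`, `coordX`, `coordY`,
#'   `coordZ`, `probability` in `[0, 1]`; the LUNA16 `seriesuid` column name
#'   is accepted for `scan_id`). All marks must lie on scans known to the
#'   cohort (included or excluded abnormal scans, or normal scans).
#' @param nodule_set A `nodule_set` from [build_nodule_set()] (possibly
#'   subgrouped by [subgroup_nodules()]).
#' @param hit_multiplier Radius multiple of the hit criterion, default 1.5.
#' @param strict If `TRUE`, marks that would be `irrelevant` are counted as
#'   `non_lesion` (false positives) instead.
#' @return A `cad_match` object: list with `marks` (the retained marks plus
#'   `label`, `matched_nodule_id`, `distance_mm`), the `nodule_set`,
#'   `n_dropped` (marks on excluded scans), `hit_multiplier`, `strict`.
#' @export
match_marks <- function(marks, nodule_set, hit_multiplier = 1.5, strict = FALSE) {
  stopifnot(inherits(nodule_set, "nodule_set"))
  marks <- validate_marks(marks)
  known <- c(nodule_set$abnormal_scans, nodule_set$excluded_scans,
             nodule_set$normal_scans)
  unknown <- setdiff(unique(marks$scan_id), known)
  if (length(unknown))
    stop_validation(sprintf("marks reference scans unknown to the cohort: %s",
                            paste(unknown, collapse = ", ")))
  dropped <- marks$scan_id %in% nodule_set$excluded_scans
  n_dropped <- sum(dropped)
  marks <- marks[!dropped, , drop = FALSE]
  rownames(marks) <- NULL

  n <- nrow(marks)
  label <- rep("non_lesion", n)
  matched <- rep(NA_character_, n)
  dist_mm <- rep(NA_real_, n)

  assign_nearest <- function(mk, nods) {
    # distances to every nodule on the scan; hits are strictly inside
    d <- sqrt((nods$coordX - mk$coordX)^2 + (nods$coordY - mk$coordY)^2 +
                (nods$coordZ - mk$coordZ)^2)
    hit <- d < hit_multiplier * nods$diameter_mm / 2
    if (!any(hit)) return(NULL)
    idx <- which(hit)[order(d[hit], nods$nodule_id[hit])][1L]
    list(nodule_id = nods$nodule_id[idx], distance = d[idx])
  }

  for (sid in unique(marks$scan_id)) {
    rows <- which(marks$scan_id == sid)
    qual <- nodule_set$nodules[nodule_set$nodules$scan_id == sid, , drop = FALSE]
    irr <- nodule_set$irrelevant_nodules[
      nodule_set$irrelevant_nodules$scan_id == sid, , drop = FALSE]
    if (nrow(qual) == 0L && nrow(irr) == 0L) next
    for (i in rows) {
      mk <- marks[i, ]
      hit <- if (nrow(qual)) assign_nearest(mk, qual) else NULL
      if (!is.null(hit)) {
        label[i] <- "lesion"
        matched[i] <- hit$nodule_id
        dist_mm[i] <- hit$distance
        next
      }
      if (!strict && nrow(irr)) {
        hit <- assign_nearest(mk, irr)
        if (!is.null(hit)) {
          label[i] <- "irrelevant"
          matched[i] <- hit$nodule_id
          dist_mm[i] <- hit$distance
        }
      }
    }
  }

  marks$label <- label
  marks$matched_nodule_id <- matched
  marks$distance_mm <- dist_mm
  structure(list(marks = marks, nodule_set = nodule_set,
                 n_dropped = n_dropped, hit_multiplier = hit_multiplier,
                 strict = strict),
            class = "cad_match")
}

#' @export
print.cad_match <- function(x, ...) {
  tab <- table(factor(x$marks$label,
                      levels = c("lesion", "irrelevant", "non_lesion")))
  cat(sprintf("CAD match against nodule set %s (hit radius %g x r)\n",
              x$nodule_set$label, x$hit_multiplier))
  cat(sprintf("  %d marks retained: %d lesion, %d irrelevant, %d non-lesion\n",
              nrow(x$marks), tab[["lesion"]], tab[["irrelevant"]],
              tab[["non_lesion"]]))
  cat(sprintf("  %d marks dropped (excluded scans)\n", x$n_dropped))
  invisible(x)
}
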