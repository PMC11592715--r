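# Multi-reader annotation model and consensus ground-truth construction.
#
# Each radiologist marks a nodule by its axial major/minor axes; the
# annotation's diameter is the mean of the two axes and its radius half of
# that. Annotations from different readers refer to the same nodule when
# their centres are closer than 1.5x the mean of the two radii; merged
# clusters become consensus nodules whose centre and diameter are plain
# averages over all member annotations.

.ann_cols <- c("scan_id", "reader_id", "coordX", "coordY", "coordZ",
               "major_axis_mm", "minor_axis_mm")
.ann_num_cols <- c("coordX", "coordY", "coordZ", "major_axis_mm", "minor_axis_mm")

# Validate an annotation table; returns it with character ids.
# `file` is used to address errors when the table came from disk.
validate_annotations <- function(annotations, file = NULL) {
  src <- if (is.null(file)) "" else sprintf("%s: ", file)
  if (!is.data.frame(annotations))
    stop_validation(sprintf("%sannotations must be a data.frame", src))
  missing_cols <- setdiff(.ann_cols, names(annotations))
  if (length(missing_cols))
    stop_validation(sprintf("%smissing column(s): %s", src,
                            paste(missing_cols, collapse = ", ")))
  ann <- annotations[.ann_cols]
  ann$scan_id <- as.character(ann$scan_id)
  ann$reader_id <- as.character(ann$reader_id)
  if (nrow(ann) == 0L)  # header-only files parse as logical NA columns
    for (cl in .ann_num_cols) ann[[cl]] <- as.numeric(ann[[cl]])
  for (cl in .ann_num_cols) {
    v <- ann[[cl]]
    if (!is.numeric(v))
      stop_validation(sprintf("%scolumn '%s' is not numeric", src, cl))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_validation(sprintf("%snon-finite value in column '%s', row %d",
                              src, cl, bad[1L]))
  }
  bad <- which(!(ann$minor_axis_mm > 0))
  if (length(bad))
    stop_validation(sprintf("%snon-positive minor_axis_mm, row %d", src, bad[1L]))
  bad <- which(ann$major_axis_mm < ann$minor_axis_mm)
  if (length(bad))
    stop_validation(sprintf(
      "%smajor_axis_mm smaller than minor_axis_mm, row %d (column major_axis_mm)",
      src, bad[1L]))
  rownames(ann) <- NULL
  ann
}

# Mean-of-axes diameter and its radius, in mm.
annotation_diameter <- function(annotations) {
  (annotations$major_axis_mm + annotations$minor_axis_mm) / 2
}
annotation_radius <- function(annotations) annotation_diameter(annotations) / 2

#' Do two reader annotations refer to the same nodule?
#'
#' Two annotations on the same scan are merged when the Euclidean distance
#' between their centres (x, y, z, in world mm) is strictly less than
#' `merge_multiplier` times the average of their radii. The radius of an
#' annotation is half its diameter, the diameter being the mean of the
#' annotated major and minor axes.
#'
#' @param a,b Single annotations: one-row data frames (or lists) with fields
#'   `scan_id`, `coordX`, `coordY`, `coordZ`, `major_axis_mm`, `minor_axis_mm`.
#' @param merge_multiplier Multiple of the mean radius below which two
#'   centres are considered the same nodule. Default 1.5.
#' @return `TRUE` or `FALSE`. Symmetric in `a` and `b`; the comparison is a
#'   strict `<`, so a centre distance exactly at the threshold does not merge.
#' @examples
#' a <- data.frame(scan_id = "s", reader_id = "r1", coordX = 0, coordY = 0,
#'                 coordZ = 0, major_axis_mm = 6, minor_axis_mm = 6)
#' b <- transform(a, reader_id = "r2", coordX = 4)
#' same_nodule(a, b)  # distance 4 < 1.5 * 3 = 4.5
#' @export
same_nodule <- function(a, b, merge_multiplier = 1.5) {
  if (as.character(a$scan_id) != as.character(b$scan_id))
    stop_validation("same_nodule(): annotations are from different scans")
  ra <- (a$major_axis_mm + a$minor_axis_mm) / 4
  rb <- (b$major_axis_mm + b$minor_axis_mm) / 4
  d <- sqrt((a$coordX - b$coordX)^2 + (a$coordY - b$coordY)^2 +
              (a$coordZ - b$coordZ)^2)
  as.logical(d < merge_multiplier * (ra + rb) / 2)
}

# Union-find over the pairwise merge relation within one scan.
# Returns cluster labels 1..k ordered by first occurrence.
cluster_scan_annotations <- function(sub, merge_multiplier) {
  n <- nrow(sub)
  if (n == 1L) return(1L)
  r <- annotation_radius(sub)
  cen <- as.matrix(sub[, c("coordX", "coordY", "coordZ")])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (d < merge_multiplier * (r[i] + r[j]) / 2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Consolidate multi-reader annotations into consensus nodules
#'
#' Within each scan, annotations are clustered as the connected components
#' of the graph whose edges are [same_nodule()] pairs (the pairwise rule is
#' not transitive; connected components resolve chains deterministically and
#' independently of input order). Each cluster becomes one consensus nodule:
#' its centre is the componentwise arithmetic mean of the member centres,
#' its diameter the mean of the member diameters, and `n_readers` the number
#' of distinct readers among the members (a reader may contribute more than
#' one member to a cluster; averaging uses all members).
#'
#' Nodule ids are assigned deterministically: annotations are put in a
#' canonical order (scan, reader, coordinates), and clusters are numbered by
#' the first member in that order, so any permutation of the input rows
#' yields the same consensus table.
#'
#' @param annotations Data frame of reader annotations (columns `scan_id`,
#'   `reader_id`, `coordX`, `coordY`, `coordZ`, `major_axis_mm`,
#'   `minor_axis_mm`; world mm).
#' @param merge_multiplier Same-nodule threshold multiplier, default 1.5.
#' @return Data frame with one row per consensus nodule: `nodule_id`,
#'   `scan_id`, `coordX`, `coordY`, `coordZ`, `diameter_mm`, `n_readers`,
#'   and a list-column `members` holding each cluster's member annotations.
#'   Empty input gives a zero-row frame.
#' @export
consolidate_annotations <- function(annotations, merge_multiplier = 1.5) {
  ann <- validate_annotations(annotations)
  empty <- data.frame(nodule_id = character(), scan_id = character(),
                      coordX = numeric(), coordY = numeric(), coordZ = numeric(),
                      diameter_mm = numeric(), n_readers = integer(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(ann) == 0L) return(empty)

  ord <- order(ann$scan_id, ann$reader_id, ann$coordX, ann$coordY, ann$coordZ,
               ann$major_axis_mm, ann$minor_axis_mm)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL

  pieces <- lapply(unique(ann$scan_id), function(sid) {
    sub <- ann[ann$scan_id == sid, , drop = FALSE]
    rownames(sub) <- NULL
    cl <- cluster_scan_annotations(sub, merge_multiplier)
    k <- max(cl)
    out <- data.frame(
      nodule_id = sprintf("%s-n%03d", sid, seq_len(k)),
      scan_id = sid,
      coordX = vapply(seq_len(k), function(g) mean(sub$coordX[cl == g]), 0),
      coordY = vapply(seq_len(k), function(g) mean(sub$coordY[cl == g]), 0),
      coordZ = vapply(seq_len(k), function(g) mean(sub$coordZ[cl == g]), 0),
      diameter_mm = vapply(seq_len(k), function(g)
        mean(annotation_diameter(sub[cl == g, , drop = FALSE])), 0),
      n_readers = vapply(seq_len(k), function(g)
        length(unique(sub$reader_id[cl == g])), 0L),
      stringsAsFactors = FALSE)
    out$members <- lapply(seq_len(k), function(g) sub[cl == g, , drop = FALSE])
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

# Validate a scan manifest: scan_id unique, label in {abnormal, normal}.
validate_manifest <- function(manifest, file = NULL) {
  src <- if (is.null(file)) "" else sprintf("%s: ", file)
  if (!is.data.frame(manifest) || !all(c("scan_id", "label") %in% names(manifest)))
    stop_validation(sprintf("%smanifest needs columns scan_id, label", src))
  manifest$scan_id <- as.character(manifest$scan_id)
  manifest$label <- as.character(manifest$label)
  dup <- manifest$scan_id[duplicated(manifest$scan_id)]
  if (length(dup))
    stop_validation(sprintf("%sduplicate scan_id in manifest: %s", src, dup[1L]))
  bad <- which(!manifest$label %in% c("abnormal", "normal"))
  if (length(bad))
    stop_validation(sprintf(
      "%smanifest label must be 'abnormal' or 'normal', row %d (column label)",
      src, bad[1L]))
  manifest[c("scan_id", "label")]
}

#' Build an agreement-graded nodule set
#'
#' Grades consensus nodules by reader agreement and partitions the abnormal
#' scans accordingly. Set `"A"` keeps nodules at least two readers agreed on
#' (`n_readers >= 2`); set `"B"` keeps nodules all three readers agreed on
#' (`n_readers >= 3`). Abnormal scans with no qualifying nodule are excluded
#' from downstream analysis for that set; qualifying-threshold failures on
#' *included* scans are kept aside as "irrelevant" nodules (CAD marks on
#' them later count neither as true nor as false positives).
#'
#' @param consensus Consensus nodule table from [consolidate_annotations()].
#' @param manifest Scan manifest data frame (`scan_id`, `label` in
#'   `{abnormal, normal}`). A consensus nodule on a scan labelled normal (or
#'   absent from the manifest) is a hard error: the annotations and the
#'   manifest disagree.
#' @param label `"A"` (at least 2 of 3 readers) or `"B"` (all 3).
#' @return A `nodule_set` object: list with `label`, `min_agreement`,
#'   `nodules`, `irrelevant_nodules`, `abnormal_scans` (included),
#'   `excluded_scans`, `normal_scans`.
#' @export
build_nodule_set <- function(consensus, manifest, label = c("A", "B")) {
  label <- match.arg(label)
  manifest <- validate_manifest(manifest)
  min_agreement <- if (label == "A") 2L else 3L

  scan_label <- manifest$label[match(consensus$scan_id, manifest$scan_id)]
  unknown <- unique(consensus$scan_id[is.na(scan_label)])
  if (length(unknown))
    stop_validation(sprintf("consensus nodules on scans missing from manifest: %s",
                            paste(unknown, collapse = ", ")))
  on_normal <- unique(consensus$scan_id[scan_label == "normal"])
  if (length(on_normal))
    stop_validation(sprintf("consensus nodules on scans labelled normal: %s",
                            paste(on_normal, collapse = ", ")))

  qualifying <- consensus$n_readers >= min_agreement
  abnormal_ids <- manifest$scan_id[manifest$label == "abnormal"]
  included <- sort(unique(consensus$scan_id[qualifying]))
  structure(list(
    label = label,
    min_agreement = min_agreement,
    nodules = consensus[qualifying, , drop = FALSE],
    irrelevant_nodules = consensus[!qualifying & consensus$scan_id %in% included,
                                   , drop = FALSE],
    abnormal_scans = included,
    excluded_scans = setdiff(abnormal_ids, included),
    normal_scans = sort(manifest$scan_id[manifest$label == "normal"]),
    subgroup = NULL,
    subgroup_scans = NULL
  ), class = "nodule_set")
}

#' @export
print.nodule_set <- function(x, ...) {
  cat(sprintf("Nodule set %s (agreement >= %d of 3 readers)\n",
              x$label, x$min_agreement))
  cat(sprintf("  %d qualifying nodules on %d included abnormal scans\n",
              nrow(x$nodules), length(x$abnormal_scans)))
  cat(sprintf("  %d abnormal scans excluded (no qualifying nodule), %d normal scans\n",
              length(x$excluded_scans), length(x$normal_scans)))
  cat(sprintf("  %d irrelevant (sub-threshold) nodules on included scans\n",
              nrow(x$irrelevant_nodules)))
  if (!is.null(x$subgroup))
    cat(sprintf("  size subgroup: diameter %s %g mm (%d scans with in-subgroup nodules)\n",
                if (x$subgroup$side == "lt") "<" else ">=",
                x$subgroup$threshold_mm, length(x$subgroup_scans)))
  invisible(x)
}
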