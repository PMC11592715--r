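# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (pairwise loops, Warshall closure, exhaustive sweeps)
# so they share no code path with the implementation they check.

make_ann <- function(scan, reader, x, y, z, major, minor = major) {
  data.frame(scan_id = scan, reader_id = reader, coordX = x, coordY = y,
             coordZ = z, major_axis_mm = major, minor_axis_mm = minor,
             stringsAsFactors = FALSE)
}

make_mark <- function(scan, x, y, z, p) {
  data.frame(scan_id = scan, coordX = x, coordY = y, coordZ = z,
             probability = p, stringsAsFactors = FALSE)
}

# Brute-force clustering by transitive closure (Warshall) of the pairwise
# same-nodule relation, for one scan's annotations.
bf_clusters <- function(sub, merge_multiplier = 1.5) {
  n <- nrow(sub)
  A <- diag(n) > 0
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      A[i, j] <- same_nodule(sub[i, ], sub[j, ], merge_multiplier)
    for (k in seq_len(n)) A <- A | outer(A[, k], A[k, ], "&")
  }
  keys <- apply(A, 1, paste, collapse = "")
  match(keys, unique(keys))
}

# Canonical representation of a partition of annotations into clusters:
# sorted list of sorted member keys, independent of labels and order.
partition_key <- function(sub, labels) {
  member_key <- sprintf("%s|%s|%.9f|%.9f|%.9f|%.9f|%.9f", sub$scan_id,
                        sub$reader_id, sub$coordX, sub$coordY, sub$coordZ,
                        sub$major_axis_mm, sub$minor_axis_mm)
  unname(sort(vapply(split(member_key, labels),
                     function(g) paste(sort(g), collapse = "; "), "")))
}

# Partition implied by a consensus table's members list-column.
consensus_partition <- function(consensus, scan) {
  rows <- consensus[consensus$scan_id == scan, ]
  member_key <- function(m) sprintf("%s|%s|%.9f|%.9f|%.9f|%.9f|%.9f",
                                    m$scan_id, m$reader_id, m$coordX, m$coordY,
                                    m$coordZ, m$major_axis_mm, m$minor_axis_mm)
  unname(sort(vapply(rows$members,
                     function(m) paste(sort(member_key(m)), collapse = "; "), "")))
}

random_annotations <- function(n_scans, max_per_scan, box = 30) {
  pieces <- lapply(seq_len(n_scans), function(s) {
    n <- sample.int(max_per_scan, 1)
    make_ann(sprintf("s%02d", s),
             sample(c("R1", "R2", "R3"), n, replace = TRUE),
             runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
             major = runif(n, 4, 12), minor = runif(n, 2, 4))
  })
  do.call(rbind, pieces)
}

# Pairwise Mann-Whitney AUC by explicit enumeration.
bf_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Exhaustive FROC evaluation at one threshold, straight from a match.
bf_froc_point <- function(match, t, fp_scans) {
  mk <- match$marks
  nod <- match$nodule_set$nodules
  detected <- vapply(nod$nodule_id, function(id) {
    any(mk$label == "lesion" & mk$matched_nodule_id == id & mk$probability >= t)
  }, TRUE)
  fps <- sum(mk$label == "non_lesion" & mk$probability >= t &
               mk$scan_id %in% fp_scans)
  c(sensitivity = mean(detected), fp_per_scan = fps / length(fp_scans))
}

# A tiny hand-built cohort: one abnormal scan with two well-separated
# nodules (2 readers each), one normal scan.
tiny_cohort <- function() {
  ann <- rbind(
    make_ann("abn1", "R1", 0, 0, 0, 8), make_ann("abn1", "R2", 0, 0, 0, 8),
    make_ann("abn1", "R1", 100, 0, 0, 6), make_ann("abn1", "R2", 100, 0, 0, 6))
  manifest <- data.frame(scan_id = c("abn1", "nrm1"),
                         label = c("abnormal", "normal"),
                         stringsAsFactors = FALSE)
  ns <- build_nodule_set(consolidate_annotations(ann), manifest, "A")
  list(annotations = ann, manifest = manifest, nodule_set = ns)
}
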