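# Consensus construction: the pairwise same-nodule rule, connected-component
# consolidation, and agreement-graded nodule sets.

test_that("same_nodule applies the strict 1.5x mean-radius rule", {
  a <- make_ann("s", "R1", 0, 0, 0, 6)
  b <- make_ann("s", "R2", 4, 0, 0, 6)   # radii 3, threshold 4.5, distance 4
  expect_true(same_nodule(a, b))
  expect_true(same_nodule(b, a))

  # identical centres merge for any positive radii
  expect_true(same_nodule(make_ann("s", "R1", 1, 2, 3, 0.5),
                          make_ann("s", "R2", 1, 2, 3, 40)))

  # distance exactly at the threshold does not merge (strict <)
  b45 <- make_ann("s", "R2", 4.5, 0, 0, 6)
  expect_false(same_nodule(a, b45))
  expect_true(same_nodule(a, b45, merge_multiplier = 1.5 + 1e-9))

  # asymmetric axes: diameter is the mean of the axes
  c1 <- make_ann("s", "R1", 0, 0, 0, major = 8, minor = 4)  # d = 6, r = 3
  expect_true(same_nodule(c1, b))

  expect_error(same_nodule(a, make_ann("t", "R2", 0, 0, 0, 6)),
               class = "cadeval_validation_error")
})

test_that("consolidation averages members and counts distinct readers", {
  # singleton
  one <- consolidate_annotations(make_ann("s", "R1", 1, 2, 3, 5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_readers, 1L)
  expect_equal(one$diameter_mm, 5)

  # two mergeable annotations average componentwise
  two <- consolidate_annotations(rbind(make_ann("s", "R1", 0, 0, 0, 6),
                                       make_ann("s", "R2", 4, 0, 0, 6)))
  expect_equal(nrow(two), 1L)
  expect_equal(c(two$coordX, two$coordY, two$coordZ), c(2, 0, 0),
               tolerance = 1e-12)
  expect_equal(two$diameter_mm, 6)
  expect_equal(two$n_readers, 2L)

  # chain merge: A-B and B-C mergeable, A-C not; one component of three
  chain <- rbind(make_ann("s", "R1", 0, 0, 0, 6),
                 make_ann("s", "R2", 4, 0, 0, 6),
                 make_ann("s", "R3", 8, 0, 0, 6))
  expect_false(same_nodule(chain[1, ], chain[3, ]))
  got <- consolidate_annotations(chain)
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_readers, 3L)
  expect_equal(got$coordX, 4)
  expect_identical(consensus_partition(got, "s"),
                   partition_key(got$members[[1]], rep(1, 3)))

  # same reader twice in one cluster: counted once, averaged over all members
  twice <- consolidate_annotations(rbind(make_ann("s", "R1", 0, 0, 0, 6),
                                         make_ann("s", "R1", 2, 0, 0, 6),
                                         make_ann("s", "R2", 1, 0, 0, 6)))
  expect_equal(nrow(twice), 1L)
  expect_equal(twice$n_readers, 2L)
  expect_equal(twice$coordX, 1)

  # empty input is fine
  expect_equal(nrow(consolidate_annotations(make_ann("s", "R1", 0, 0, 0, 6)[0, ])),
               0L)
})

test_that("consolidation equals brute-force transitive closure (<= 12 per scan)", {
  set.seed(101)
  for (rep in 1:20) {
    ann <- random_annotations(n_scans = 3, max_per_scan = 12)
    got <- consolidate_annotations(ann)
    # conservation: members partition the input
    expect_equal(sum(vapply(got$members, nrow, 0L)), nrow(ann))
    for (s in unique(ann$scan_id)) {
      sub <- ann[ann$scan_id == s, ]
      rownames(sub) <- NULL
      expect_identical(consensus_partition(got, s),
                       partition_key(sub, bf_clusters(sub)))
    }
  }
})

test_that("consolidation is invariant under input permutation", {
  set.seed(202)
  for (rep in 1:10) {
    ann <- random_annotations(n_scans = 2, max_per_scan = 8)
    base <- consolidate_annotations(ann)
    perm <- consolidate_annotations(ann[sample.int(nrow(ann)), ])
    expect_identical(base, perm)
  }
})

test_that("nodule sets grade by agreement and record exclusions", {
  ann <- rbind(
    make_ann("a1", c("R1", "R2", "R3"), 0, 0, 0, 6),     # 3-reader nodule
    make_ann("a2", c("R1", "R2"), 0, 0, 0, 6),           # 2-reader nodule
    make_ann("a3", "R1", 0, 0, 0, 6),                    # 1-reader nodule
    make_ann("a4", c("R1", "R2", "R3"), 0, 0, 0, 8),     # 3-reader ...
    make_ann("a4", c("R1", "R2"), 60, 0, 0, 6))          # ... plus 2-reader
  manifest <- data.frame(scan_id = c("a1", "a2", "a3", "a4", "n1"),
                         label = c(rep("abnormal", 4), "normal"))
  cons <- consolidate_annotations(ann)

  A <- build_nodule_set(cons, manifest, "A")
  expect_setequal(A$abnormal_scans, c("a1", "a2", "a4"))
  expect_setequal(A$excluded_scans, "a3")
  expect_equal(nrow(A$nodules), 4L)
  expect_equal(nrow(A$irrelevant_nodules), 0L)

  B <- build_nodule_set(cons, manifest, "B")
  expect_setequal(B$abnormal_scans, c("a1", "a4"))
  expect_setequal(B$excluded_scans, c("a2", "a3"))
  expect_true(all(B$nodules$n_readers == 3L))
  # the 2-reader nodule on the included scan a4 is irrelevant, not excluded
  expect_equal(B$irrelevant_nodules$scan_id, "a4")
  expect_equal(B$irrelevant_nodules$n_readers, 2L)

  # nesting: B nodules are a subset of A nodules, B scans of A scans
  expect_true(all(B$nodules$nodule_id %in% A$nodules$nodule_id))
  expect_true(all(B$abnormal_scans %in% A$abnormal_scans))

  # a consensus nodule on a normal scan is a manifest inconsistency
  bad <- consolidate_annotations(make_ann("n1", "R1", 0, 0, 0, 6))
  expect_error(build_nodule_set(bad, manifest, "A"),
               class = "cadeval_validation_error")
})

test_that("set nesting holds on random cohorts", {
  set.seed(303)
  coh <- generate_cohort(synthetic_config(seed = 9, n_abnormal = 25,
                                          n_normal = 10))
  cons <- consolidate_annotations(coh$annotations)
  A <- build_nodule_set(cons, coh$manifest, "A")
  B <- build_nodule_set(cons, coh$manifest, "B")
  expect_gte(nrow(A$nodules), nrow(B$nodules))
  expect_true(all(B$nodules$nodule_id %in% A$nodules$nodule_id))
  expect_length(intersect(A$abnormal_scans, A$excluded_scans), 0)
})
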