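# Per-nodule metrics: FROC sweep, rate interpolation, CPM, size subgroups.

test_that("FROC on the two-scan three-mark fixture follows the sweep rule", {
  tc <- tiny_cohort()  # nodules at x = 0 (d 8) and x = 100 (d 6) on abn1
  marks <- rbind(make_mark("abn1", 0, 0, 0, 0.9),    # hit on nodule 1
                 make_mark("abn1", 50, 0, 0, 0.8),   # non-lesion
                 make_mark("abn1", 100, 0, 0, 0.6))  # hit on nodule 2
  m <- match_marks(marks, tc$nodule_set)
  expect_equal(sort(m$marks$label), sort(c("lesion", "non_lesion", "lesion")))

  f <- froc(m)  # 2 scans (abn1 + nrm1), 2 nodules
  expect_equal(f$n_scans, 2L)
  expect_equal(f$points$fp_per_scan, c(0, 0, 0.5, 0.5))
  expect_equal(f$points$sensitivity, c(0, 0.5, 0.5, 1))
  # rates inside (0, 0.5) stay on the horizontal segment at 0.5; at and
  # beyond the 0.5 FP/scan vertical the full sensitivity applies
  expect_equal(f$sensitivities_at_rates, c(0.5, 0.5, 1, 1, 1, 1))
  expect_equal(f$cpm, mean(c(0.5, 0.5, 1, 1, 1, 1)))

  # step mode carries the last achieved sensitivity forward
  fs <- froc(m, interpolation = "step")
  expect_equal(fs$sensitivities_at_rates, c(0.5, 0.5, 1, 1, 1, 1))
})

test_that("perfect and silent detectors give CPM 1 and 0", {
  tc <- tiny_cohort()
  perfect <- match_marks(rbind(make_mark("abn1", 0, 0, 0, 1),
                               make_mark("abn1", 100, 0, 0, 1)),
                         tc$nodule_set)
  fp <- froc(perfect)
  expect_equal(fp$sensitivities_at_rates, rep(1, 6))
  expect_equal(fp$cpm, 1)

  silent <- match_marks(make_mark("abn1", 0, 0, 0, 1)[0, ], tc$nodule_set)
  f0 <- froc(silent)
  expect_equal(f0$sensitivities_at_rates, rep(0, 6))
  expect_equal(f0$cpm, 0)

  empty_set <- tc$nodule_set
  empty_set$nodules <- empty_set$nodules[0, ]
  expect_error(froc(match_marks(make_mark("abn1", 0, 0, 0, 1), empty_set)),
               class = "cadeval_undefined_error")
})

test_that("FROC sweep equals exhaustive per-threshold evaluation (<= 20 marks)", {
  set.seed(31)
  for (rep in 1:8) {
    coh <- generate_cohort(synthetic_config(seed = 100 + rep, n_abnormal = 4,
                                            n_normal = 3))
    ns <- build_nodule_set(consolidate_annotations(coh$annotations),
                           coh$manifest, "A")
    mk <- coh$marks[[1]]
    mk <- mk[!mk$scan_id %in% ns$excluded_scans, , drop = FALSE]
    mk <- head(mk, 20)
    m <- match_marks(mk, ns)
    f <- froc(m)
    fp_scans <- c(ns$abnormal_scans, ns$normal_scans)
    for (i in seq_len(nrow(f$points))) {
      bf <- bf_froc_point(m, f$points$threshold[i], fp_scans)
      expect_equal(f$points$sensitivity[i], unname(bf["sensitivity"]))
      expect_equal(f$points$fp_per_scan[i], unname(bf["fp_per_scan"]))
    }
  }
})

test_that("FROC is monotone and responds correctly to added marks", {
  set.seed(57)
  coh <- generate_cohort(synthetic_config(seed = 21, n_abnormal = 12,
                                          n_normal = 8))
  ns <- build_nodule_set(consolidate_annotations(coh$annotations),
                         coh$manifest, "A")
  mk <- coh$marks[[2]]
  m <- match_marks(mk, ns)
  f <- froc(m)

  # sensitivity non-decreasing along the sweep and across target rates
  expect_true(all(diff(f$points$sensitivity) >= 0))
  expect_true(all(diff(f$points$fp_per_scan) >= 0))
  expect_true(all(diff(f$sensitivities_at_rates) >= -1e-12))
  expect_true(f$cpm >= min(f$sensitivities_at_rates) - 1e-12 &&
                f$cpm <= max(f$sensitivities_at_rates) + 1e-12)

  # an extra non-lesion mark can only lower sensitivity at fixed rates
  sid <- ns$normal_scans[1]
  worse <- froc(match_marks(rbind(mk, make_mark(sid, 0, 0, 0, 0.99)), ns))
  expect_true(all(worse$sensitivities_at_rates <=
                    f$sensitivities_at_rates + 1e-12))

  # an extra lesion-hitting mark can only raise it
  nod <- ns$nodules[1, ]
  better <- froc(match_marks(
    rbind(mk, make_mark(nod$scan_id, nod$coordX, nod$coordY, nod$coordZ, 0.99)),
    ns))
  expect_true(all(better$sensitivities_at_rates >=
                    f$sensitivities_at_rates - 1e-12))
})

test_that("cpm is the mean and rejects bad input", {
  expect_equal(cpm(rep(0.7, 6)), 0.7)
  expect_equal(cpm(c(0, 1)), 0.5)
  expect_error(cpm(numeric(0)), class = "cadeval_validation_error")
  expect_error(cpm(c(0.5, 1.2)), class = "cadeval_validation_error")
})

test_that("size subgroups split at 6 mm with ge owning the boundary", {
  ann <- rbind(make_ann("a1", c("R1", "R2"), 0, 0, 0, 4),     # 4 mm
               make_ann("a1", c("R1", "R2"), 60, 0, 0, 8),    # 8 mm
               make_ann("a2", c("R1", "R2"), 0, 0, 0, 6))     # exactly 6 mm
  manifest <- data.frame(scan_id = c("a1", "a2", "n1"),
                         label = c("abnormal", "abnormal", "normal"))
  A <- build_nodule_set(consolidate_annotations(ann), manifest, "A")

  lt <- subgroup_nodules(A, 6, "lt")
  ge <- subgroup_nodules(A, 6, "ge")
  expect_equal(lt$nodules$diameter_mm, 4)
  expect_setequal(ge$nodules$diameter_mm, c(8, 6))  # boundary goes to ge
  # scan a1 has nodules on both sides: member of both subgroups
  expect_true("a1" %in% lt$subgroup_scans && "a1" %in% ge$subgroup_scans)
  # out-of-subgroup qualifying nodules become irrelevant, scans stay included
  expect_equal(nrow(lt$irrelevant_nodules), 2L)
  expect_identical(lt$abnormal_scans, A$abnormal_scans)
  # near-zero threshold with ge reproduces the full set
  expect_identical(subgroup_nodules(A, 1e-9, "ge")$nodules, A$nodules)

  # per-scan subgroup scores: one positive per subgroup here for ge
  marks <- rbind(make_mark("a1", 0, 0, 0, 0.9), make_mark("n1", 5, 5, 5, 0.3))
  m <- match_marks(marks, A)
  sge <- perscan_subgroup_scores(m, 6, "ge")
  expect_setequal(sge$scan_id[sge$truth], c("a1", "a2"))
  expect_equal(sge$scan_id[!sge$truth], "n1")
  slt <- perscan_subgroup_scores(m, 6, "lt")
  expect_equal(sum(slt$truth), 1L)
  expect_error(perscan_subgroup_scores(m, 0.5, "lt"),
               class = "cadeval_undefined_error")
})

test_that("overall sensitivity is the nodule-weighted blend of subgroups", {
  coh <- generate_cohort(synthetic_config(seed = 33, n_abnormal = 20,
                                          n_normal = 10, guaranteed_hit = TRUE))
  ns <- build_nodule_set(consolidate_annotations(coh$annotations),
                         coh$manifest, "A")
  mk <- coh$marks[[2]]
  m_all <- match_marks(mk, ns)
  m_lt <- match_marks(mk, subgroup_nodules(ns, 6, "lt"))
  m_ge <- match_marks(mk, subgroup_nodules(ns, 6, "ge"))
  f_all <- froc(m_all); f_lt <- froc(m_lt); f_ge <- froc(m_ge)

  for (t in f_all$points$threshold) {
    s_all <- f_all$points$sensitivity[match(t, f_all$points$threshold)]
    s_lt <- bf_froc_point(m_lt, t, c(ns$abnormal_scans, ns$normal_scans))["sensitivity"]
    s_ge <- bf_froc_point(m_ge, t, c(ns$abnormal_scans, ns$normal_scans))["sensitivity"]
    blend <- (s_lt * f_lt$n_nodules + s_ge * f_ge$n_nodules) /
      (f_lt$n_nodules + f_ge$n_nodules)
    expect_equal(s_all, unname(blend), tolerance = 1e-12)
  }
})
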