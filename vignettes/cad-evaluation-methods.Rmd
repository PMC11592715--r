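---
title: "Methods: evaluating lesion-localization CAD against multi-reader ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating lesion-localization CAD against multi-reader ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadeval)
```

This vignette is the package's account of its statistical methods: the
ground-truth model, the matching rule, the scan- and nodule-level metrics,
the synthetic cohort generator, and the numerical conventions chosen where
the field's informal definitions leave room.

## Ground truth from multiple readers

A reader annotates a nodule by drawing its major and minor axes on the
axial slice where it appears largest; the working diameter is the mean of
the two axis lengths and the radius half of that. Readers disagree both on
presence and on placement, so per-reader marks must be consolidated before
any detector can be scored against them.

Two annotations on the same scan are taken to describe the same nodule
when the Euclidean distance between their centres (x, y, z in world mm) is
*strictly* less than 1.5 times the average of their radii. This pairwise
relation is not transitive — A may merge with B and B with C while A and C
are too far apart — so `consolidate_annotations()` clusters annotations as
the connected components of the merge graph (union–find). Connected
components are the standard order-independent resolution; the suite checks
the result against brute-force transitive closure and under input
permutation. Each cluster becomes one consensus nodule with the unweighted
arithmetic mean of member centres and diameters, and an agreement count of
*distinct* readers (a reader contributing two annotations to one cluster
is counted once for agreement but both members enter the averages — the
agreement criterion needs distinct readers, while the average is simply
over available measurements).

`build_nodule_set()` grades the result: set A keeps nodules with at least
2-of-3 reader agreement, set B only unanimous ones. An abnormal scan with
no qualifying nodule is excluded from that set's analysis entirely; its
marks are dropped rather than being counted as false positives, since
ground truth on it is unknown. Sub-agreement nodules on *included* scans
are retained as "irrelevant": evidence too weak to reward a detector for,
but too strong to punish it with.

Assumptions worth stating: coordinates must already be in world mm
(voxel-to-world conversion is the caller's job), and all distances are
isotropic 3D Euclidean — including the through-plane axis, even though
thick-slice annotations quantize z. Both multipliers default to 1.5 and
are exposed (`merge_multiplier`, `hit_multiplier`) because they are
conventions, not laws.

## Matching CAD marks

A mark localizes a nodule when its centre lies strictly within 1.5 times
the consensus radius of the consensus centre; the mark's own size estimate
plays no role. A mark inside several qualifying nodules is assigned to the
nearest one, ties broken by the lexicographically smaller nodule id — the
least surprising deterministic rule, needed because the hit balls of close
nodules can overlap. Multiple marks may hit one nodule: the nodule counts
once toward sensitivity (detected at threshold *t* if any hitting mark has
confidence ≥ *t*) and none of those marks count as false positives. Marks
hitting only irrelevant nodules are ignored by default; `strict = TRUE`
counts them as false positives instead, for sensitivity analyses of that
convention.

## Per-scan analysis

The scan-level score is the maximum mark confidence on the scan, with the
convention that a markless scan scores exactly 0 — required so that a
normal scan with no detections counts as a correct rejection rather than
missing data. AUC is the Mann–Whitney estimator with ties scored ½
(confidences are nominally continuous but file rounding creates ties).

Variances come from DeLong's structural components: with positives
\(x_i\) and negatives \(y_j\), the components are
\(V^{10}_i = \tfrac1n\sum_j \psi(x_i, y_j)\) and
\(V^{01}_j = \tfrac1m\sum_i \psi(x_i, y_j)\), and
\(\widehat{\mathrm{var}} = S^{10}/m + S^{01}/n\). Confidence intervals are
the plain normal approximation AUC ± 1.96·SE clipped to [0, 1]; no logit
transform. The paired test for two conditions on the same scans uses the
component covariances; its z statistic is the AUC difference over the
standard error of the difference. When that variance is exactly zero
(e.g. both conditions separate perfectly) the documented convention is
p = 1 for a zero difference and p = 0 otherwise. The implementation is
checked against `pROC`'s independent DeLong code, against a stratified
bootstrap, and for type-I calibration on simulated paired cohorts.

Operating points use the closed-on-the-positive-side rule "predict
abnormal iff score ≥ threshold". In `target_specificity` mode the
threshold is the smallest candidate (observed score values, plus ∞)
whose specificity meets the target — the vendor thresholds behind
published accuracy/sensitivity/specificity triplets are rarely stated, so
the package reports operating points only under this explicit rule and
makes no claim to reproduce any vendor's cells.

## Per-nodule analysis

The FROC sweep evaluates every distinct confidence (plus ∞): sensitivity
is the fraction of qualifying nodules detected at the threshold, the FP
rate is non-lesion marks at or above it divided by the number of scans.
Sensitivities at the target rates 1/8, 1/4, 1/2, 1, 2, 4 FP/scan are read
off the achieved curve; their mean is the CPM. Six rates are the default
(some toolkits add 8 FP/scan; the rate list is configurable).

Interpolation needs care because the achieved curve is a path, not a
function: lowering the threshold past a true positive adds sensitivity at
constant FP rate (a vertical segment). The convention here: at a query
rate exactly equal to an achieved FP value, the top of the vertical
segment applies; strictly between two achieved values, sensitivity is
interpolated linearly between the top of the left segment and the bottom
of the right one — i.e. along the sweep path itself. Below the smallest
achieved rate sensitivity is 0; above the largest, the final plateau
applies. A step-function mode (`interpolation = "step"`) carries the last
achieved sensitivity forward instead. Both are monotone; the linear mode
matches common FROC practice with smooth published curves.

Two FP-denominator modes exist because published "false positives per
scan" rarely states whether normal scans enter the denominator: `"all"`
(default — included abnormal plus normal scans, since both classes are
processed by the detector) and `"abnormal"`.

Size subgroups split qualifying nodules at 6 mm, with the boundary
diameter in the ≥ 6 mm group. Out-of-subgroup qualifying nodules become
irrelevant (their marks are neither rewarded nor punished), while the
included scan list — and hence the FP denominator — stays fixed, keeping
subgroup FROC curves comparable. For per-scan subgroup ROC the positive
class is the scans holding at least one in-subgroup nodule; a scan with
nodules on both sides of 6 mm is a positive in both subgroups. The suite
verifies the accounting identity that overall sensitivity at any threshold
is the nodule-count-weighted mean of the two subgroup sensitivities.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating process of a two-condition
paired reader study; it exists so that the pipeline's statistical
behaviour (calibration, parameter recovery, directional comparisons) can
be tested end to end. Per abnormal scan, a zero-truncated Poisson number
of lesions (rate 2.0, so roughly 2.3 lesions per abnormal scan) with
log-normal diameters (median 3.6 mm, σ_log 0.45) placed uniformly in a
300 × 300 × 250 mm box. Three readers each detect a lesion of diameter *d*
with probability `plogis(0.15 + 0.25 d)` — about 0.75 at the median size —
and annotate it with Gaussian centre jitter (SD 0.2 radii per axis),
multiplicative diameter jitter (log-SD 0.08) and a random major/minor
split that preserves the mean axis. Each detector condition detects each
lesion with its own logistic size curve, marks it with Gaussian
localization error (SD radius/3 per axis, which keeps essentially all
lesion marks inside the 1.5 r hit ball) and a Beta-distributed confidence,
and adds Poisson false positives with low-skewed Beta confidences. Both
conditions share the scans and lesions, as a paired design requires.

The defaults encode the study conditions the package targets: cohort
scale 350 abnormal / 330 normal scans; a size mix putting roughly 85% of
consensus nodules under 6 mm (the log-normal CDF at 6 mm is 0.872, and
reader size-bias brings the 2-of-3 consensus expectation to ≈ 0.85 — the
generator is tested against this closed form, not against a hand-picked
constant); reader sensitivity ≈ 0.75 at the median so the unanimous set
holds about half as many nodules as the 2-of-3 set; and two detector
profiles, a weaker "original 5 mm" (`plogis(-0.9 + 0.45 d)`, TP
confidence Beta(3.5, 2.5), 4 FP/scan) and a uniformly stronger "refined
1 mm" (`plogis(0.2 + 0.55 d)`, Beta(5, 2), 3 FP/scan) — ordered in
detection probability at every size and stochastically ordered in
confidence, so the refined profile should win both AUC and CPM in nearly
every seeded cohort; a property test requires it in at least 95 of 100
seeds.

`closed_form_targets()` supplies the analytic expectations the tests
recover: FP/scan equals the Poisson rate; the FROC plateau equals the
expected detector sensitivity under the consensus-reweighted diameter law
\(E[s_c(d)\,w(d)]/E[w(d)]\) with \(w\) the probability that enough readers
annotate (computed by numerical integration); and `binormal_auc()` gives
the Gaussian-scores AUC identity used by the ROC oracles.

What the generator does *not* emulate — so passing tests say nothing about
these: image content (no HU values, no ground-glass vs part-solid texture,
no partial-volume effect), lung-shaped geometry, reader correlation beyond
independence, per-reader skill differences, and any real detector's
confidence distribution. Reader-model parameters are configuration, not
claims about any particular radiologist panel.

Determinism: every scan draws from its own RNG substream derived from
(seed, scan index), so a cohort is byte-reproducible and subsetting scans
does not shift the draws of the rest.

## Numerical conventions and degenerate inputs

* All threshold comparisons on distances are strict (`<`), matching
  "less than"/"within" conventions; mark-retention and operating-point
  rules on confidences are closed (`>=`). Both are asserted at the exact
  boundary in the tests.
* Consensus centre/diameter averaging is plain `mean()`; the suite checks
  componentwise agreement to 1e-12 on hand-built cases.
* Single-class ROC input, an empty nodule set, and an empty subgroup
  positive class raise classed errors (`cadeval_undefined_error`) rather
  than returning NaN; malformed files raise `cadeval_validation_error`
  naming file, row and column.
* Duplicate identical marks are retained (they inflate FP counts only);
  marks on excluded scans are dropped with a count.
* Report JSON carries full precision; printed summaries round to 3
  decimals.

## Problem sizes used by the test suite

The statistical checks run at sizes chosen to make their Monte-Carlo error
small relative to the tolerance being asserted: DeLong type-I calibration
uses 2000 simulated paired cohorts of 150 scans (binomial SE ≈ 0.005
around the nominal 0.05, against an acceptance band of ±0.015); the
variance check compares against a 10,000-replicate bootstrap at n = 200;
parameter recovery uses one full-scale cohort (350/330) plus 100 seeded
cohorts of 150/130 scans for the directional profile comparison; oracle
equivalence runs exhaustively at the scales where exhaustion is feasible
(≤ 200 scores, ≤ 20 marks, ≤ 12 annotations per scan).

## Known limitations

* Matching is centre-distance only; no IoU/Dice overlap of segmentation
  masks, and no non-maximum suppression of near-duplicate marks.
* ROC comparison is the paired DeLong test only — no reader-study variance
  components (Obuchowski–Rockette/JAFROC) and no covariate adjustment;
  FROC confidence bands are not provided.
* The subgroup re-matching convention can, in the rare case of a mark
  inside hit balls of nodules from both subgroups, reassign that mark to
  the in-subgroup nodule; the whole-equals-blend identity is exact only
  when hit balls do not straddle the size threshold.
* The consensus model treats readers symmetrically; there is no seniority
  weighting or adjudication stage.
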