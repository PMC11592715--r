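# cadeval

Evaluation of lesion-localization CAD (computer-aided detection) systems
for lung nodules on chest CT, against ground truth consolidated from
multiple radiologist readers.

The typical question this package answers: *given the same scans processed
under two imaging conditions — say, native thick-slice 5 mm CT versus a
deep-learning slice-thickness-reduced 1 mm reconstruction — did the CAD
system get significantly better?* It answers it at two levels: per scan
(did the system flag abnormal scans?) and per nodule (did it localize the
individual lesions, and at what false-positive cost?).

## What it computes

**Consensus ground truth.** Each reader marks a nodule by its axial major
and minor axes; the diameter is their mean, the radius half of that. Two
annotations on a scan refer to the same nodule when their centre distance
is strictly below 1.5× the mean of the two radii; clusters are the
connected components of this pairwise relation, and each becomes one
consensus nodule with averaged centre and diameter and an agreement count
(distinct readers). Nodule set **A** keeps nodules at least 2 of 3 readers
agreed on; set **B** those all 3 agreed on. Abnormal scans with no
qualifying nodule are excluded from that set's analysis.

**Hit criterion.** A CAD mark (x, y, z, confidence ∈ [0, 1]) localizes a
nodule when its centre lies strictly within 1.5·r of the consensus centre,
r the consensus radius. Marks hitting only sub-agreement nodules are
"irrelevant": neither true nor false positives.

**Per-scan ROC.** A scan's score is the highest mark confidence on it
(0 with no marks). With included abnormal scans as positives and normal
scans as negatives, the package computes the Mann–Whitney AUC

&nbsp;&nbsp;&nbsp;&nbsp;Â = (1/mn) Σᵢ Σⱼ [ψ(xᵢ, yⱼ)], ψ = 1 if xᵢ > yⱼ, ½ if equal, 0 otherwise,

with DeLong structural-component variance for confidence intervals
(Â ± 1.96·SE) and the paired DeLong test
z = (Â_b − Â_a)/√(V_a + V_b − 2C_ab) for comparing the two conditions on
the same scans.

**Per-nodule FROC.** Sweeping the confidence threshold gives
(false positives per scan, nodule sensitivity) points; sensitivities are
read off at FP rates 1/8, 1/4, 1/2, 1, 2, 4 and averaged into the
competition performance metric (CPM). Subgroup analyses split nodules at
6 mm (the Lung-RADS-motivated threshold; a 6.0 mm nodule belongs to the
≥ 6 mm group).

**Synthetic cohorts.** `synthetic_config()` / `generate_cohort()` simulate
the whole data-generating process — true lesions with a log-normal size
law, three imperfect jittered readers, and two paired detector profiles
with logistic size-dependent sensitivity, Beta confidences and Poisson
false positives — so every stage of the pipeline can be exercised,
calibrated and stress-tested without clinical data.

## Worked example

```r
library(cadeval)

cfg    <- synthetic_config(seed = 42, n_abnormal = 80, n_normal = 60)
cohort <- generate_cohort(cfg)
report <- run_evaluation(cohort$manifest, cohort$annotations, cohort$marks,
                         set_label = "B",
                         operating = list(target_specificity = 0.8))
report
#> CAD evaluation, nodule set B
#>   scans: 80 abnormal (57 included, 23 excluded), 60 normal; 83 nodules
#>   [original_5mm] AUC 0.889 (0.826-0.952), CPM 0.530
#>   [refined_1mm] AUC 0.972 (0.946-0.998), CPM 0.847
#>   paired DeLong original_5mm vs refined_1mm: delta AUC +0.083, p = 0.0105; delta CPM +0.317

report$conditions$refined_1mm$froc
#> FROC over 83 nodules on 117 scans
#>   FP/scan:      0.125  0.250  0.500  1.000  2.000  4.000
#>   sensitivity:  0.735  0.795  0.843  0.880  0.916  0.916
#>   CPM = 0.847
```

Reading it: 23 of the 80 abnormal scans had no nodule all three synthetic
readers agreed on, so they leave the set-B analysis (their CAD marks are
neither rewarded nor penalized). Under the weaker "original 5 mm" detector
profile the scan-level AUC is 0.889; the stronger "refined 1 mm" profile
reaches 0.972, and the paired DeLong test puts p ≈ 0.01 on that difference.
At the nodule level the stronger profile finds 91.6% of consensus nodules
at 2 false positives per scan, for a CPM of 0.847. The operating point
reported under each ROC is the smallest threshold reaching specificity
0.80. `write_report(report, "out/")` writes the full JSON report plus ROC
and FROC curve CSVs.

Real data enter through the same frames: `read_annotations()`,
`read_scan_manifest()` and `read_cad_marks()` read the documented CSV
dialects (the mark format is the LUNA16 candidates dialect:
`seriesuid, coordX, coordY, coordZ, probability`).

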