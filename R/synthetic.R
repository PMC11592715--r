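# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the evaluation pipeline assumes: a
# paired two-condition study in which abnormal scans carry one or more true
# lesions, three readers independently annotate each lesion with imperfect
# detection and jittered geometry (so both >=2-reader and 3-reader
# consensus sets arise), and each detector condition emits one
# confidence-scored mark per detected lesion plus Poisson-distributed
# non-lesion marks. Lesions and scans are shared across conditions. No
# image content is modelled: lesion positions are uniform in a box, which
# is irrelevant to the evaluation arithmetic.

#' Detector condition profile
#'
#' Per-nodule detection probability is `plogis(sens_alpha + sens_beta * d)`
#' at true diameter `d` mm; detected lesions get one mark with a
#' Beta-distributed confidence and an isotropic Gaussian localization
#' offset; non-lesion marks arrive Poisson per scan, uniform in the volume,
#' with a low-skewed Beta confidence.
#'
#' @param sens_alpha,sens_beta Logistic detection curve coefficients.
#' @param tp_conf Length-2 Beta shape for true-lesion confidences.
#' @param loc_jitter_frac Localization jitter SD per axis, as a fraction of
#'   the true lesion radius. Default 1/3, which keeps essentially all
#'   lesion marks inside the 1.5-radius hit criterion.
#' @param fp_rate Mean non-lesion marks per scan (Poisson rate, `>= 0`).
#' @param fp_conf Length-2 Beta shape for non-lesion confidences.
#' @return A `detector_profile` list.
#' @export
detector_profile <- function(sens_alpha, sens_beta, tp_conf = c(5, 2),
                             loc_jitter_frac = 1/3, fp_rate = 4,
                             fp_conf = c(2, 5)) {
  stopifnot(length(tp_conf) == 2L, length(fp_conf) == 2L,
            all(tp_conf > 0), all(fp_conf > 0),
            fp_rate >= 0, loc_jitter_frac >= 0)
  structure(list(sens_alpha = sens_alpha, sens_beta = sens_beta,
                 tp_conf = tp_conf, loc_jitter_frac = loc_jitter_frac,
                 fp_rate = fp_rate, fp_conf = fp_conf),
            class = "detector_profile")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline targets: ~350
#' abnormal and ~330 normal scans; a log-normal lesion diameter law whose
#' consensus mix puts roughly 85% of nodules below 6 mm; three readers of
#' moderate, size-dependent sensitivity so that the 3-of-3 consensus set
#' holds about half as many nodules as the 2-of-3 set; and two paired
#' detector profiles, a weaker "original 5 mm" and a uniformly stronger
#' "refined 1 mm" (higher detection curve, higher-skewed true-positive
#' confidences, fewer false positives).
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration including the seed.
#' @param n_abnormal,n_normal Numbers of abnormal and normal scans.
#' @param nodules_per_abnormal Mean of the underlying Poisson for lesions
#'   per abnormal scan, truncated at zero (every abnormal scan has >= 1).
#' @param diameter_median_mm,diameter_sigma_log Log-normal diameter law
#'   (median in mm, SD on the log scale).
#' @param volume_box_mm Length-3 extents (mm) for uniform lesion placement.
#' @param reader Reader model: logistic detection curve
#'   `plogis(alpha + beta * d)`, per-axis centre jitter SD as a fraction of
#'   the lesion radius, multiplicative (log-scale) diameter jitter SD, and
#'   `axis_spread` (annotated major/minor axes are `d * (1 +/- u)`,
#'   `u ~ U(0, axis_spread)`, so their mean stays at the jittered diameter).
#' @param detectors Named list of [detector_profile()]s, one per condition.
#' @param guaranteed_hit If `TRUE`, lesion-mark offsets are truncated at
#'   1.4 true radii, so (with reader jitter off) every emitted lesion mark
#'   satisfies the hit rule exactly; used to separate matching-rule tests
#'   from sensitivity-model tests.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_abnormal = 350L, n_normal = 330L,
                             nodules_per_abnormal = 2.0,
                             diameter_median_mm = 3.6,
                             diameter_sigma_log = 0.45,
                             volume_box_mm = c(300, 300, 250),
                             reader = list(alpha = 0.15, beta = 0.25,
                                           center_jitter_frac = 0.2,
                                           diameter_jitter_sd = 0.08,
                                           axis_spread = 0.15),
                             detectors = list(
                               original_5mm = detector_profile(
                                 sens_alpha = -0.9, sens_beta = 0.45,
                                 tp_conf = c(3.5, 2.5), fp_rate = 4),
                               refined_1mm = detector_profile(
                                 sens_alpha = 0.2, sens_beta = 0.55,
                                 tp_conf = c(5, 2), fp_rate = 3)),
                             guaranteed_hit = FALSE) {
  stopifnot(n_abnormal >= 1L, n_normal >= 0L, nodules_per_abnormal > 0,
            diameter_median_mm > 0, diameter_sigma_log > 0,
            length(volume_box_mm) == 3L, all(volume_box_mm > 0),
            length(detectors) >= 1L, !is.null(names(detectors)),
            all(vapply(detectors, inherits, TRUE, "detector_profile")),
            reader$center_jitter_frac >= 0, reader$diameter_jitter_sd >= 0,
            reader$axis_spread >= 0, reader$axis_spread < 1)
  structure(list(seed = as.integer(seed), n_abnormal = as.integer(n_abnormal),
                 n_normal = as.integer(n_normal),
                 nodules_per_abnormal = nodules_per_abnormal,
                 diameter_median_mm = diameter_median_mm,
                 diameter_sigma_log = diameter_sigma_log,
                 volume_box_mm = volume_box_mm, reader = reader,
                 detectors = detectors, guaranteed_hit = guaranteed_hit),
            class = "synthetic_config")
}

# Per-scan RNG substream seed: a fixed mixing of (seed, scan index), kept
# below 2^31 so set.seed() accepts it. Subsetting scans leaves the draws of
# every other scan unchanged.
scan_seed <- function(seed, i) {
  ((abs(seed) %% 100000) * 100003 + i * 7919 + 17) %% 2147483629
}

# Zero-truncated Poisson via inverse CDF on U(P(K=0), 1).
rztpois <- function(n, lambda) {
  qpois(runif(n, exp(-lambda), 1), lambda)
}

#' Generate a synthetic paired two-condition cohort
#'
#' Fully deterministic given the configuration (one RNG substream per scan,
#' derived from the seed and the scan index). Both detector conditions see
#' the same scans and the same true lesions, as in a paired design.
#'
#' @param config A [synthetic_config()].
#' @return List with `manifest` (scan_id, label), `annotations` (one row
#'   per reader mark), `marks` (named list of per-condition CAD mark
#'   tables: scan_id, coordX/Y/Z, probability), and `truth` (the true
#'   lesions and per-condition mark provenance; for parameter-recovery
#'   checks only - the evaluation pipeline never reads it).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  abn_ids <- sprintf("abn%04d", seq_len(config$n_abnormal))
  nrm_ids <- sprintf("nrm%04d", seq_len(config$n_normal))
  manifest <- data.frame(scan_id = c(abn_ids, nrm_ids),
                         label = rep(c("abnormal", "normal"),
                                     c(config$n_abnormal, config$n_normal)),
                         stringsAsFactors = FALSE)
  box <- config$volume_box_mm
  rd <- config$reader
  conds <- names(config$detectors)
  readers <- c("R1", "R2", "R3")

  ann <- list(); lesions <- list()
  cmarks <- setNames(vector("list", length(conds)), conds)
  for (cc in conds) cmarks[[cc]] <- list()

  for (i in seq_along(manifest$scan_id)) {
    sid <- manifest$scan_id[i]
    abnormal <- manifest$label[i] == "abnormal"
    set.seed(scan_seed(config$seed, i))

    if (abnormal) {
      k <- rztpois(1L, config$nodules_per_abnormal)
      d <- rlnorm(k, log(config$diameter_median_mm), config$diameter_sigma_log)
      cen <- cbind(runif(k, 0, box[1]), runif(k, 0, box[2]), runif(k, 0, box[3]))
      lesions[[sid]] <- data.frame(
        scan_id = sid, lesion_id = sprintf("%s-L%02d", sid, seq_len(k)),
        coordX = cen[, 1], coordY = cen[, 2], coordZ = cen[, 3],
        diameter_mm = d, stringsAsFactors = FALSE)

      for (r in readers) {
        p <- plogis(rd$alpha + rd$beta * d)
        det <- runif(k) < p
        for (j in which(det)) {
          off <- rnorm(3, 0, rd$center_jitter_frac * d[j] / 2)
          dj <- d[j] * exp(rnorm(1, 0, rd$diameter_jitter_sd))
          u <- runif(1, 0, rd$axis_spread)
          ann[[length(ann) + 1L]] <- data.frame(
            scan_id = sid, reader_id = r,
            coordX = cen[j, 1] + off[1], coordY = cen[j, 2] + off[2],
            coordZ = cen[j, 3] + off[3],
            major_axis_mm = dj * (1 + u), minor_axis_mm = dj * (1 - u),
            stringsAsFactors = FALSE)
        }
      }
    }

    for (cc in conds) {
      prof <- config$detectors[[cc]]
      rows <- list()
      if (abnormal) {
        k <- nrow(lesions[[sid]])
        d <- lesions[[sid]]$diameter_mm
        det <- runif(k) < plogis(prof$sens_alpha + prof$sens_beta * d)
        for (j in which(det)) {
          off <- rnorm(3, 0, prof$loc_jitter_frac * d[j] / 2)
          if (config$guaranteed_hit) {
            len <- sqrt(sum(off^2))
            cap <- 1.4 * d[j] / 2
            if (len > cap) off <- off * cap / len
          }
          rows[[length(rows) + 1L]] <- data.frame(
            scan_id = sid,
            coordX = lesions[[sid]]$coordX[j] + off[1],
            coordY = lesions[[sid]]$coordY[j] + off[2],
            coordZ = lesions[[sid]]$coordZ[j] + off[3],
            probability = rbeta(1, prof$tp_conf[1], prof$tp_conf[2]),
            source_lesion = lesions[[sid]]$lesion_id[j],
            stringsAsFactors = FALSE)
        }
      }
      nf <- rpois(1L, prof$fp_rate)
      if (nf > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = sid,
          coordX = runif(nf, 0, box[1]), coordY = runif(nf, 0, box[2]),
          coordZ = runif(nf, 0, box[3]),
          probability = rbeta(nf, prof$fp_conf[1], prof$fp_conf[2]),
          source_lesion = NA_character_, stringsAsFactors = FALSE)
      }
      if (length(rows))
        cmarks[[cc]][[length(cmarks[[cc]]) + 1L]] <- do.call(rbind, rows)
    }
  }

  bind <- function(lst, cols) {
    if (length(lst) == 0L) {
      out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
      out$scan_id <- character(0)
      return(out[cols])
    }
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  annotations <- bind(unname(ann), .ann_cols)
  truth_marks <- lapply(cmarks, bind, cols = c(.mark_cols, "source_lesion"))
  marks <- lapply(truth_marks, function(m) m[.mark_cols])
  lesion_tab <- bind(unname(lesions),
                     c("scan_id", "lesion_id", "coordX", "coordY", "coordZ",
                       "diameter_mm"))
  list(manifest = manifest, annotations = annotations, marks = marks,
       truth = list(lesions = lesion_tab, marks = truth_marks,
                    config = config))
}

#' Closed-form expectations for a synthetic configuration
#'
#' Analytic summaries used to check the generator and the pipeline against
#' each other: the expected false-positive rate per scan (the Poisson
#' mean), the asymptotic FROC plateau (expected detector sensitivity over
#' the consensus-nodule diameter distribution, i.e. the lesion diameter law
#' reweighted by the probability that enough readers annotate the lesion),
#' and the expected fraction of consensus nodules below 6 mm.
#'
#' @param config A [synthetic_config()].
#' @param agreement `"A"` (>= 2 of 3 readers) or `"B"` (all 3): which
#'   consensus weighting to use.
#' @return List with `expected_fp_per_scan` (named per condition),
#'   `froc_plateau` (named per condition), `fraction_lt6mm`, and
#'   `fraction_lt6mm_truth` (unweighted diameter law).
#' @export
closed_form_targets <- function(config, agreement = c("B", "A")) {
  stopifnot(inherits(config, "synthetic_config"))
  agreement <- match.arg(agreement)
  mu <- log(config$diameter_median_mm); sg <- config$diameter_sigma_log
  f <- function(d) dlnorm(d, mu, sg)
  p <- function(d) plogis(config$reader$alpha + config$reader$beta * d)
  w <- function(d) {
    pd <- p(d)
    if (agreement == "A") 3 * pd^2 * (1 - pd) + pd^3 else pd^3
  }
  wmass <- integrate(function(d) w(d) * f(d), 0, Inf)$value
  plateau <- vapply(config$detectors, function(prof) {
    integrate(function(d)
      plogis(prof$sens_alpha + prof$sens_beta * d) * w(d) * f(d),
      0, Inf)$value / wmass
  }, 0)
  frac_lt6 <- integrate(function(d) w(d) * f(d), 0, 6)$value / wmass
  list(expected_fp_per_scan = vapply(config$detectors, `[[`, 0, "fp_rate"),
       froc_plateau = plateau,
       fraction_lt6mm = frac_lt6,
       fraction_lt6mm_truth = plnorm(6, mu, sg))
}

#' Binormal AUC
#'
#' Closed-form AUC when positive and negative scores are Gaussian:
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Used as an
#' analytic oracle for ROC code on simulated scores.
#'
#' @param mu_pos,mu_neg Class means.
#' @param sd_pos,sd_neg Class standard deviations (default 1).
#' @return The AUC.
#' @export
binormal_auc <- function(mu_pos, mu_neg, sd_pos = 1, sd_neg = 1) {
  pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
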