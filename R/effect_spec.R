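#' Convert a percent difference to a log-scale effect
#'
#' Growth models act on `log(Q)`, so a male-vs-female difference of `p`
#' percent corresponds to an additive log effect `log(1 + p/100)`.
#' `log_to_pct()` is the inverse.
#'
#' @param pct Percent difference (e.g. `7.38` for "7.38% larger in males").
#' @return Log-scale effect size.
#' @export
#' @examples
#' pct_to_log(7.38)
#' log_to_pct(pct_to_log(7.38))
pct_to_log <- function(pct) log(1 + pct / 100)

#' @rdname pct_to_log
#' @param delta Log-scale effect size.
#' @export
log_to_pct <- function(delta) 100 * (exp(delta) - 1)

#' Build a ground-truth effect specification for the synthetic generator
#'
#' One row per directly generated region. The generator draws, for region
#' `r` and a scan at gestational week `W` (centred at the 27-week reference),
#' \deqn{\log Q = \beta_0 + \sum_k g_k (W-27)^k + \delta\,[male] +
#'   \gamma (W-27)[male] + u_{subject} + \varepsilon,}
#' with `u ~ N(0, subject_sd^2)` drawn once per (subject, region) and
#' `eps ~ N(0, residual_sd^2)` per row.
#'
#' @param region Region name (e.g. `"WM"`, `"Temporal_CORT"`).
#' @param baseline Expected female value at 27 gestational weeks, in the
#'   measure's units (mm^3, mm^2 or mm^-1); must be positive.
#' @param growth Numeric vector (length 1-4) of polynomial growth
#'   coefficients on centred weeks, log units per week^k.
#' @param pct_effect Male-vs-female percent difference at 27 weeks.
#' @param interaction Sex-by-age interaction, log units per week.
#' @param subject_sd,residual_sd Between-subject and residual standard
#'   deviations, log units; must be non-negative.
#' @param measure_kind One of `"volume_mm3"`, `"area_mm2"`, `"curv_mm-1"`.
#' @return A one-row tibble; rows from repeated calls can be bound together.
#' @export
#' @examples
#' effect_spec("WM", baseline = 66800, growth = c(0.10, -0.003),
#'             pct_effect = 7.38)
effect_spec <- function(region, baseline, growth, pct_effect = 0,
                        interaction = 0, subject_sd = 0.08,
                        residual_sd = 0.05,
                        measure_kind = c("volume_mm3", "area_mm2", "curv_mm-1")) {
  measure_kind <- match.arg(measure_kind)
  assert_positive(baseline, "baseline")
  if (subject_sd < 0 || residual_sd < 0) {
    stop("subject_sd and residual_sd must be non-negative.", call. = FALSE)
  }
  if (length(growth) < 1 || length(growth) > 4) {
    stop("`growth` must have 1 to 4 coefficients.", call. = FALSE)
  }
  growth <- c(growth, rep(0, 4 - length(growth)))
  tibble::tibble(
    region = region, measure_kind = measure_kind,
    baseline_log = log(baseline),
    growth1 = growth[1], growth2 = growth[2],
    growth3 = growth[3], growth4 = growth[4],
    sex_log_effect = pct_to_log(pct_effect),
    sex_age_interaction = interaction,
    subject_sd = subject_sd, residual_sd = residual_sd
  )
}

#' Default ground-truth effects for the synthetic study
#'
#' Directly generated regions: the six intracranial tissue/fluid
#' compartments (CORT, WM, DGM, CEREB, VENT, SCSF), whole-brain surface
#' area (AREA) and average absolute mean curvature (CURV), plus per-lobe
#' curvatures. Baselines are plausible mid-gestation magnitudes chosen so
#' that the composed sums (ICV, TBV) carry sex effects consistent with the
#' per-compartment ones; sex effects default to the magnitudes reported in
#' longitudinal fetal MRI morphometry. CSF compartments carry inflated
#' variance components, reflecting their much higher relative variability.
#'
#' @return A tibble of effect specifications, one row per region.
#' @export
default_effect_spec <- function() {
  dplyr::bind_rows(
    effect_spec("CORT",  baseline = 28600, growth = c(0.14,  0.002), pct_effect = 5.08),
    effect_spec("WM",    baseline = 66800, growth = c(0.10, -0.003), pct_effect = 7.38),
    effect_spec("DGM",   baseline = 8900,  growth = c(0.10, -0.002), pct_effect = 3.52),
    effect_spec("CEREB", baseline = 6700,  growth = c(0.14,  0.002), pct_effect = 3.40),
    effect_spec("VENT",  baseline = 4960,  growth = c(0.02,  0),     pct_effect = 17.96,
                subject_sd = 0.25, residual_sd = 0.10),
    effect_spec("SCSF",  baseline = 49200, growth = c(0.06, -0.002), pct_effect = 2.67,
                subject_sd = 0.20, residual_sd = 0.10),
    effect_spec("AREA",  baseline = 15000, growth = c(0.12,  0.002), pct_effect = 3.68,
                measure_kind = "area_mm2"),
    effect_spec("CURV",  baseline = 0.10,  growth = c(0.03,  0.001), pct_effect = -2.20,
                subject_sd = 0.05, residual_sd = 0.04, measure_kind = "curv_mm-1"),
    effect_spec("Frontal_CURV",   baseline = 0.095, growth = c(0.03, 0.001),
                pct_effect = -1.75, subject_sd = 0.05, residual_sd = 0.04,
                measure_kind = "curv_mm-1"),
    effect_spec("Parietal_CURV",  baseline = 0.105, growth = c(0.03, 0.001),
                pct_effect = -2.76, subject_sd = 0.05, residual_sd = 0.04,
                measure_kind = "curv_mm-1"),
    effect_spec("Temporal_CURV",  baseline = 0.100, growth = c(0.03, 0.001),
                pct_effect = -1.37, subject_sd = 0.05, residual_sd = 0.04,
                measure_kind = "curv_mm-1"),
    effect_spec("Occipital_CURV", baseline = 0.102, growth = c(0.03, 0.001),
                pct_effect = -3.71, subject_sd = 0.05, residual_sd = 0.04,
                measure_kind = "curv_mm-1")
  )
}

#' Lobe decomposition specification
#'
#' Lobe values of a parent measure are generated as shares of the parent via
#' a softmax over per-lobe logit trajectories, which guarantees the lobes
#' sum to the parent exactly at every age. `sex_pct_target` is the intended
#' lobe-level male-vs-female percent difference at 27 weeks; the generator
#' converts these to logit offsets (exact up to a common softmax
#' renormalisation constant shared by all lobes of the parent).
#'
#' @param parent Parent region name whose value is decomposed.
#' @param lobes Character vector of lobe names (suffix appended to parent).
#' @param base_share Female lobe shares at 27 weeks; must sum to 1.
#' @param logit_growth Matrix (lobes x 4) of polynomial logit trajectory
#'   coefficients on centred weeks; rows may be zero.
#' @param sex_pct_target Lobe-level percent differences at 27 weeks.
#' @param logit_subject_sd,logit_residual_sd Gaussian jitter on the logits
#'   at subject and scan level (log-odds units); sums remain exact.
#' @return A list describing one parent decomposition.
#' @export
lobe_spec <- function(parent,
                      lobes = c("Frontal", "Parietal", "Temporal", "Occipital"),
                      base_share,
                      logit_growth = NULL,
                      sex_pct_target = rep(0, length(lobes)),
                      logit_subject_sd = 0.03, logit_residual_sd = 0.02) {
  stopifnot(length(base_share) == length(lobes),
            length(sex_pct_target) == length(lobes))
  if (abs(sum(base_share) - 1) > 1e-8) {
    stop("`base_share` must sum to 1.", call. = FALSE)
  }
  if (is.null(logit_growth)) {
    logit_growth <- matrix(0, length(lobes), 4)
  }
  list(parent = parent, lobes = lobes, base_share = base_share,
       logit_growth = logit_growth,
       sex_logit_offset = pct_to_log(sex_pct_target),
       logit_subject_sd = logit_subject_sd,
       logit_residual_sd = logit_residual_sd)
}

#' @rdname lobe_spec
#' @export
default_lobe_spec <- function() {
  lg <- rbind(
    Frontal   = c(0.030,  0.0020, 0, 0),
    Parietal  = c(-0.010, -0.0020, 0.00050, 0),
    Temporal  = c(0.000,  0.0020, 0, -0.00001),
    Occipital = c(-0.020, 0.0000, 0, 0)
  )
  list(
    lobe_spec("CORT", base_share = c(0.34, 0.27, 0.21, 0.18),
              logit_growth = lg,
              sex_pct_target = c(5.38, 4.95, 5.09, 4.40) - 5.08),
    lobe_spec("WM", base_share = c(0.36, 0.26, 0.20, 0.18),
              logit_growth = lg,
              sex_pct_target = c(7.63, 5.80, 8.01, 8.02) - 7.38),
    lobe_spec("AREA", base_share = c(0.33, 0.27, 0.22, 0.18),
              logit_growth = lg,
              sex_pct_target = c(4.06, 2.70, 4.54, 3.46) - 3.68)
  )
}

#' Left-right asymmetry specification
#'
#' Generates `<region>_left` / `<region>_right` variants sharing one
#' biological signal (growth, sex effect, subject effect and scan noise from
#' the parent region's effect row), with a male-only rightward log offset:
#' for males `log R - log L = male_right_log_offset`, for females 0.
#' Independent per-hemisphere measurement noise (`hemi_sd`) must stay small
#' relative to the shared within-subject components: the right side enters
#' the asymmetry regression as a covariate, so independent noise on it
#' attenuates its coefficient by about `hemi_sd^2 / sigma_within^2` and
#' leaks a corresponding fraction of the shared sex effect into the
#' asymmetry coefficient. The default is a token value that only prevents
#' a degenerate (zero-residual) fit.
#'
#' @param region Parent region (must appear in the effect spec or be a lobe).
#' @param male_right_log_offset Male-only rightward offset, log units.
#' @param hemi_sd Independent per-hemisphere noise sd, log units.
#' @return A list describing one asymmetric region pair.
#' @export
asymmetry_spec <- function(region, male_right_log_offset, hemi_sd = 5e-4) {
  list(region = region, offset = male_right_log_offset, hemi_sd = hemi_sd)
}

#' @rdname asymmetry_spec
#' @export
default_asymmetry_spec <- function() {
  list(asymmetry_spec("Frontal_WM", male_right_log_offset = pct_to_log(0.98)))
}
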