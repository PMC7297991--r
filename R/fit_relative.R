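# Relative (global-covaried) growth models: the response region's log value
# is modelled with log of the matching global reference as a covariate, so
# the sex effect is the residual (share-like) difference beyond global scale.

#' Specification of a relative growth model
#'
#' @param region Response region `Q`.
#' @param reference Global reference `G`: ICV for volumes, whole-brain AREA
#'   for areas, whole-brain CURV for curvatures. Must be of the same
#'   measure kind as `Q` and never equal to it.
#' @param degree Age-polynomial degree: 2 for global measures, 4 for lobes.
#' @return A `relative_spec` list.
#' @export
relative_spec <- function(region, reference = NULL, degree = 2) {
  if (!degree %in% c(2, 4)) stop("degree must be 2 or 4.", call. = FALSE)
  structure(list(region = region, reference = reference, degree = degree),
            class = "relative_spec")
}

default_reference <- function(kind) {
  switch(kind,
         volume_mm3 = "ICV",
         area_mm2 = "AREA",
         `curv_mm-1` = "CURV",
         stop("unknown measure kind: ", kind, call. = FALSE))
}

#' Fit the relative growth model for one region
#'
#' Fits
#' \deqn{\log Q \approx a\,[male] + bW[male] + \sum_k c_k W^k + g \log G}
#' with a subject random intercept, where `G` is the per-scan global
#' reference (time-varying covariate). The sex effect `a` is the residual
#' difference after accounting for global scale; report it with
#' [percent_difference()].
#'
#' @param table Measure tibble containing both `Q` and `G` for every scan.
#' @param spec A [relative_spec()], or a region name (reference then chosen
#'   by measure kind, degree 2).
#' @param basis Optional [build_poly_basis()].
#' @return A `growth_fit` with kind `"relative"`.
#' @export
#' @examples
#' coh <- generate_cohort(seed = 1)
#' tab <- generate_measures(coh, default_effect_spec(), seed = 2,
#'                          lobes = default_lobe_spec())
#' fit <- fit_relative_model(tab, relative_spec("WM", "ICV", degree = 2))
#' percent_difference(fit)
fit_relative_model <- function(table, spec, basis = NULL) {
  if (is.character(spec)) spec <- relative_spec(spec)
  stopifnot(inherits(spec, "relative_spec"))
  rows <- dplyr::filter(table, .data$region == !!spec$region)
  if (nrow(rows) == 0) stop("region not found: ", spec$region, call. = FALSE)
  kind <- rows$measure_kind[1]
  reference <- spec$reference %||% default_reference(kind)
  if (reference == spec$region) {
    stop("a measure cannot be its own reference.", call. = FALSE)
  }
  ref_rows <- dplyr::filter(table, .data$region == !!reference)
  if (nrow(ref_rows) > 0 && ref_rows$measure_kind[1] != kind) {
    stop("reference ", reference, " (", ref_rows$measure_kind[1],
         ") does not match the measure kind of ", spec$region,
         " (", kind, ").", call. = FALSE)
  }
  g <- aligned_region_values(table, spec$region, reference)
  if (is.null(basis)) basis <- build_poly_basis(rows$gest_week, spec$degree)
  d <- growth_frame(table, spec$region, basis, extra_log = list(log_G = g))
  terms <- c("sex", paste0("w", seq_len(basis$degree)), "log_G", "sex:w1")
  m <- fit_growth_core(d, terms, "relative", spec$region, basis$degree)
  m$basis <- basis
  m$reference <- reference
  m
}

#' Partial-residual growth trajectories in measurement units
#'
#' Removes the global-reference and subject contributions from the fitted
#' relative model and back-transforms, yielding per-scan residual values
#' and smooth sex-specific fitted curves suitable for plotting relative
#' (share-like) growth.
#'
#' @param model A `growth_fit` from [fit_relative_model()].
#' @param n_grid Number of ages for the fitted curves.
#' @return List of tibbles `points` (per-scan residual values) and
#'   `curves` (fitted male/female trajectories over the age range).
#' @export
residual_trajectory <- function(model, n_grid = 100) {
  stopifnot(inherits(model, "growth_fit"), model$kind == "relative")
  d <- model$data
  cf <- setNames(model$coefficients$estimate, model$coefficients$term)
  g_hat <- cf[["log_G"]]
  mean_logG <- mean(d$log_G)
  partial <- d$log_value - g_hat * (d$log_G - mean_logG)
  points <- tibble::tibble(subject_id = d$subject_id, sex = d$sex,
                           gest_week = d$gest_week,
                           residual_value = exp(partial))
  rng <- range(d$gest_week)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  wb <- eval_basis(model$basis, grid)
  base <- cf[["(Intercept)"]] + g_hat * mean_logG
  for (j in seq_len(ncol(wb))) {
    nm <- paste0("w", j)
    if (nm %in% names(cf)) base <- base + cf[[nm]] * wb[, j]
  }
  curves <- dplyr::bind_rows(
    tibble::tibble(sex = "F", gest_week = grid, fitted_value = exp(base)),
    tibble::tibble(sex = "M", gest_week = grid,
                   fitted_value = exp(base + (cf[["sexM"]] %||% 0) +
                                        (if ("sexM:w1" %in% names(cf))
                                          cf[["sexM:w1"]] * wb[, 1] else 0)))
  ) |> dplyr::mutate(sex = sex_factor(.data$sex))
  list(points = points, curves = curves)
}
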