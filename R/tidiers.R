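# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted growth model
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with term, estimate, std.error, df, statistic, p.value.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) x$coefficients

#' @rdname tidy.growth_fit
#' @return `glance()`: one row with variance components, df method, fit
#'   size and (for mixed fits) REML criterion.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, region = x$region, degree = x$degree,
    tau2 = unname(x$variance_components["tau2"]),
    sigma2 = unname(x$variance_components["sigma2"]),
    df_method = x$df_method,
    nobs = nrow(x$data),
    n_subjects = length(unique(x$data$subject_id)),
    reml_criterion = if (inherits(x$fit, "merMod")) {
      as.numeric(lme4::REMLcrit(x$fit))
    } else {
      NA_real_
    }
  )
}

#' Tidy a TBM permutation result
#'
#' @param x A `tbm_result`.
#' @param ... Unused.
#' @return One row per tested contrast: corrected threshold, flagged voxel
#'   count, permutation count and seed.
#' @method tidy tbm_result
#' @export
tidy.tbm_result <- function(x, ...) {
  tibble::tibble(
    contrast = c("sex", "sex_age"),
    threshold = c(x$threshold_sex, x$threshold_sexage),
    n_flagged = c(sum(x$sig_sex), sum(x$sig_sexage)),
    n_perm = x$n_perm, alpha = x$alpha, seed = x$seed
  )
}

#' Plot observed data and fitted sex-specific growth curves
#'
#' Back-transforms the fitted log-domain model to measurement units and
#' overlays the per-scan values, giving the familiar diverging male/female
#' growth-fan picture.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  cf <- setNames(object$coefficients$estimate, object$coefficients$term)
  grid <- seq(min(d$gest_week), max(d$gest_week), length.out = 100)
  wb <- eval_basis(object$basis, grid)
  lin <- rep(cf[["(Intercept)"]], length(grid))
  for (j in seq_len(ncol(wb))) {
    nm <- paste0("w", j)
    if (nm %in% names(cf)) lin <- lin + cf[[nm]] * wb[, j]
  }
  for (nm in intersect(c("log_G", "log_R"), names(cf))) {
    lin <- lin + cf[[nm]] * mean(d[[nm]])
  }
  curves <- dplyr::bind_rows(
    tibble::tibble(sex = "F", gest_week = grid, value = exp(lin)),
    tibble::tibble(sex = "M", gest_week = grid,
                   value = exp(lin + (cf[["sexM"]] %||% 0) +
                                 (if ("sexM:w1" %in% names(cf))
                                   cf[["sexM:w1"]] * wb[, 1] else 0)))
  ) |> dplyr::mutate(sex = sex_factor(.data$sex))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gest_week,
                                  y = exp(.data$log_value),
                                  colour = .data$sex)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$value), linewidth = 0.9) +
    ggplot2::labs(x = "Gestational week", y = object$region,
                  title = paste0(object$kind, " growth model: ", object$region)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a TBM map with its significance outline
#'
#' @param object A `tbm_result`.
#' @param slice Slice index along the third axis (default: middle).
#' @param which `"t_sex"`, `"effect_sex"` or `"t_sexage"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tbm_result
#' @export
autoplot.tbm_result <- function(object, slice = NULL,
                                which = c("t_sex", "effect_sex", "t_sexage"),
                                ...) {
  which <- match.arg(which)
  vol <- object$fit[[which]]
  dims <- dim(vol$values)
  slice <- slice %||% ceiling(dims[3] / 2)
  sig <- if (which == "t_sexage") object$sig_sexage else object$sig_sex
  d <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  d$value <- as.vector(vol$values[, , slice])
  d$in_mask <- as.vector(vol$mask[, , slice])
  d$flagged <- as.vector(sig[, , slice])
  d$value[!d$in_mask] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = dplyr::filter(d, .data$flagged),
                        shape = ".", colour = "black") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("TBM ", which, " (slice ", slice, ")"),
                  fill = which) +
    ggplot2::theme_minimal()
}

#' Plot residual relative-growth trajectories
#'
#' @param x Output of [residual_trajectory()].
#' @return A ggplot of partial-residual points with fitted male/female
#'   curves, measurement units.
#' @export
plot_residual_trajectory <- function(x) {
  ggplot2::ggplot(x$points,
                  ggplot2::aes(.data$gest_week, .data$residual_value,
                               colour = .data$sex)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = x$curves,
                       ggplot2::aes(y = .data$fitted_value), linewidth = 0.9) +
    ggplot2::labs(x = "Gestational week", y = "Residual measure") +
    ggplot2::theme_minimal()
}
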