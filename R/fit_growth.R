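# Log-domain polynomial growth models with subject random intercepts.
#
# One internal fitting core serves the absolute, relative and asymmetry
# models; they differ only in the covariates added to the age polynomial.

# Build the per-scan modelling frame for one region.
growth_frame <- function(table, region, basis, extra_log = NULL) {
  rows <- dplyr::filter(table, .data$region == !!region)
  if (nrow(rows) == 0) stop("region not found in table: ", region, call. = FALSE)
  if (any(rows$value <= 0)) {
    stop("non-positive values for region ", region,
         "; log transform undefined.", call. = FALSE)
  }
  d <- rows |>
    dplyr::transmute(subject_id = .data$subject_id,
                     sex = sex_factor(.data$sex),
                     gest_week = .data$gest_week,
                     log_value = log(.data$value))
  if (!is.null(extra_log)) {
    for (nm in names(extra_log)) {
      v <- extra_log[[nm]]
      if (any(v <= 0)) stop("covariate ", nm, " must be positive.", call. = FALSE)
      d[[nm]] <- log(v)
    }
  }
  add_basis_columns(d, basis)
}

# Values of a covariate region aligned to the rows of `region` by scan_id.
aligned_region_values <- function(table, region, covariate) {
  lhs <- dplyr::filter(table, .data$region == !!region)
  rhs <- dplyr::filter(table, .data$region == !!covariate)
  idx <- match(lhs$scan_id, rhs$scan_id)
  if (anyNA(idx)) {
    stop("covariate region ", covariate, " missing for scans: ",
         paste(head(lhs$scan_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  rhs$value[idx]
}

# Fit log_value on the supplied fixed-effect terms with a subject random
# intercept (REML, Satterthwaite p-values). Falls back to OLS when the
# response is a numerically exact function of the design (zero residual
# variance), where the mixed model degenerates.
fit_growth_core <- function(data, fixed_terms, kind, region, degree) {
  if (length(unique(data$sex)) < 2) {
    stop("both sexes must be present to estimate a sex effect.", call. = FALSE)
  }
  if (min(table(data$sex[!duplicated(data$subject_id)])) < 2) {
    stop("need at least 2 subjects per sex.", call. = FALSE)
  }
  rhs <- paste(fixed_terms, collapse = " + ")
  ols <- lm(stats::as.formula(paste("log_value ~", rhs)), data = data)
  sing_tol <- 1e-10
  singular_fit <- sd(residuals(ols)) < sing_tol
  one_scan_each <- max(table(data$subject_id)) == 1
  if (singular_fit || one_scan_each) {
    # zero residual variance degenerates the mixed model; with a single
    # scan per subject the intercept/residual split is unidentified and the
    # GLS fixed effects coincide with OLS either way ("perfect fit"
    # warnings from summary() are expected in the exact case)
    co <- suppressWarnings(summary(ols))$coefficients
    fit <- ols
    coefs <- tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                            std.error = unname(co[, 2]), df = ols$df.residual,
                            statistic = unname(co[, 3]),
                            p.value = unname(co[, 4]))
    s2 <- if (singular_fit) 0 else sum(residuals(ols)^2) / ols$df.residual
    vc <- c(tau2 = 0, sigma2 = s2)
    df_method <- "ols"
    vcov_fix <- suppressWarnings(vcov(ols))
  } else {
    f <- stats::as.formula(paste("log_value ~", rhs, "+ (1 | subject_id)"))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = data, REML = TRUE)
    ))
    co <- coef(summary(fit))
    coefs <- tibble::tibble(term = rownames(co),
                            estimate = unname(co[, "Estimate"]),
                            std.error = unname(co[, "Std. Error"]),
                            df = unname(co[, "df"]),
                            statistic = unname(co[, "t value"]),
                            p.value = unname(co[, "Pr(>|t|)"]))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(tau2 = vcs$vcov[vcs$grp == "subject_id"],
            sigma2 = vcs$vcov[vcs$grp == "Residual"])
    df_method <- "satterthwaite"
    vcov_fix <- as.matrix(vcov(fit))
  }
  structure(list(fit = fit, coefficients = coefs, vcov = vcov_fix,
                 variance_components = vc, df_method = df_method,
                 kind = kind, region = region, degree = degree,
                 data = data),
            class = "growth_fit")
}

coef_value <- function(model, term) {
  i <- match(term, model$coefficients$term)
  if (is.na(i)) 0 else model$coefficients$estimate[i]
}

coef_p <- function(model, term) {
  i <- match(term, model$coefficients$term)
  if (is.na(i)) NA_real_ else model$coefficients$p.value[i]
}

#' Fit the absolute growth model for one region
#'
#' Fits the log-domain polynomial growth model
#' \deqn{\log Q \approx a\,[male] + b W [male] + c W + d W^2}
#' (higher powers per `degree`) with a subject random intercept, by REML,
#' on the orthonormal age basis. `a` is the sex effect, `b` the sex-age
#' interaction; Satterthwaite p-values are reported for both.
#'
#' @param table Long-format measure tibble (see [generate_measures()]).
#' @param region Region to model.
#' @param basis Optional [build_poly_basis()]; defaults to a basis built on
#'   the region's own scan weeks.
#' @param degree Polynomial degree when `basis` is not supplied.
#' @return A `growth_fit` object; see [tidy.growth_fit()],
#'   [percent_difference()], [bootstrap_ci()].
#' @export
#' @examples
#' coh <- generate_cohort(seed = 1)
#' tab <- generate_measures(coh, default_effect_spec(), seed = 2)
#' fit <- fit_absolute_model(tab, "WM")
#' percent_difference(fit)
fit_absolute_model <- function(table, region, basis = NULL, degree = 2) {
  rows <- dplyr::filter(table, .data$region == !!region)
  if (nrow(rows) == 0) stop("region not found in table: ", region, call. = FALSE)
  if (is.null(basis)) basis <- build_poly_basis(rows$gest_week, degree)
  d <- growth_frame(table, region, basis)
  terms <- c("sex", paste0("w", seq_len(basis$degree)), "sex:w1")
  m <- fit_growth_core(d, terms, "absolute", region, basis$degree)
  m$basis <- basis
  m
}

#' Male-vs-female percent difference at a reporting age
#'
#' Back-transforms the fitted sex contrast to the measurement domain:
#' `100 * (exp(a + b * w(at_week)) - 1)`, where `w(at_week)` is the
#' degree-1 basis value at the reporting age. With a zero interaction this
#' is age-independent (a constant fractional male-female ratio).
#'
#' @param model A `growth_fit`.
#' @param at_week Reporting age in gestational weeks (default 27).
#' @param family_size Number of two-sided tests in the reporting family,
#'   for the Bonferroni flag.
#' @return A one-row tibble: region, estimate_pct, p_sex, p_interaction,
#'   bonferroni_survives, family_size.
#' @export
percent_difference <- function(model, at_week = 27.0, family_size = 1) {
  stopifnot(inherits(model, "growth_fit"))
  rng <- range(model$basis$weeks)
  if (at_week < rng[1] || at_week > rng[2]) {
    warning("reporting age ", at_week, " lies outside the fitted range [",
            round(rng[1], 1), ", ", round(rng[2], 1), "]; extrapolating.")
  }
  w1 <- unname(eval_basis(model$basis, at_week)[1, 1])
  a <- coef_value(model, "sexM")
  b <- coef_value(model, "sexM:w1")
  p_sex <- coef_p(model, "sexM")
  p_int <- coef_p(model, "sexM:w1")
  tibble::tibble(
    region = model$region,
    model = model$kind,
    at_week = at_week,
    estimate_pct = log_to_pct(a + b * w1),
    p_sex = p_sex,
    p_interaction = p_int,
    family_size = family_size,
    bonferroni_survives = bonferroni_flag(p_sex, family_size)
  )
}

#' Bonferroni survival flag
#'
#' `TRUE` iff `p < 0.05 / m` (strict), the correction used when reporting a
#' family of `m` two-sided sex-difference tests.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Family size, a positive integer.
#' @param alpha Family-wise level.
#' @return Logical vector.
#' @export
#' @examples
#' bonferroni_flag(6.2e-7, 26)
bonferroni_flag <- function(p, m, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0,1].", call. = FALSE)
  if (m < 1) stop("family size must be >= 1.", call. = FALSE)
  !is.na(p) & p < alpha / m
}

#' Parametric bootstrap confidence interval for the percent difference
#'
#' Simulates `B` response vectors from the fitted mixed model (fixed
#' effects plus fresh subject intercepts and residuals), refits each, and
#' returns percentile 2.5/97.5 bounds of the back-transformed percent
#' difference at the reporting age.
#'
#' @param model A `growth_fit`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param at_week Reporting age.
#' @return Tibble with ci_low_pct, ci_high_pct, n_fail, B.
#' @export
bootstrap_ci <- function(model, B = 1000, seed, at_week = 27.0) {
  stopifnot(inherits(model, "growth_fit"))
  if (B < 100) stop("B must be >= 100.", call. = FALSE)
  w1 <- unname(eval_basis(model$basis, at_week)[1, 1])
  pct_of <- function(cf) {
    a <- cf[["sexM"]] %||% 0
    b <- if ("sexM:w1" %in% names(cf)) cf[["sexM:w1"]] else 0
    log_to_pct(a + b * w1)
  }
  est <- with(list(cf = setNames(model$coefficients$estimate,
                                 model$coefficients$term)),
              pct_of(as.list(cf)))
  if (model$df_method == "ols" &&
      sum(model$variance_components) < 1e-20) {
    return(tibble::tibble(ci_low_pct = est, ci_high_pct = est,
                          n_fail = 0L, B = as.integer(B)))
  }
  sims <- with_seed(seed, simulate(model$fit, nsim = B,
                                   use.u = FALSE,
                                   allow.new.levels = FALSE))
  stats_b <- purrr::map_dbl(sims, function(y) {
    tryCatch({
      rf <- suppressMessages(suppressWarnings(lme4::refit(model$fit, y)))
      pct_of(as.list(lme4::fixef(rf)))
    }, error = function(e) NA_real_)
  })
  n_fail <- sum(is.na(stats_b))
  if (n_fail > 0.1 * B) {
    stop(sprintf("bootstrap refit failure rate %.1f%% exceeds 10%%.",
                 100 * n_fail / B), call. = FALSE)
  }
  q <- quantile(stats_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble::tibble(ci_low_pct = q[1], ci_high_pct = q[2],
                 n_fail = as.integer(n_fail), B = as.integer(B))
}

#' Breusch-Pagan heteroscedasticity diagnostic
#'
#' Fits the age polynomial to the region's values in the chosen domain and
#' regresses squared residuals on gestational week (the standard
#' Breusch-Pagan construction). Multiplicative growth makes raw-domain
#' residual spread increase with age; the log transform removes it.
#'
#' @param table Measure tibble.
#' @param region Region to test.
#' @param domain `"raw"` or `"log"`.
#' @param degree Age-polynomial degree for the mean model.
#' @return Tibble with statistic, p.value, domain, region.
#' @export
heteroscedasticity_diag <- function(table, region, domain = c("raw", "log"),
                                    degree = 2) {
  domain <- match.arg(domain)
  rows <- dplyr::filter(table, .data$region == !!region)
  if (nrow(rows) < 20) stop("need at least 20 rows.", call. = FALSE)
  y <- if (domain == "log") log(rows$value) else rows$value
  d <- data.frame(y = y, w = rows$gest_week)
  fit <- lm(y ~ poly(w, degree), data = d)
  if (sd(residuals(fit)) < 1e-12) {
    warning("constant residuals; heteroscedasticity test undefined.")
    return(tibble::tibble(statistic = 0, p.value = 1,
                          domain = domain, region = region))
  }
  bp <- lmtest::bptest(fit, varformula = ~ w, data = d)
  tibble::tibble(statistic = unname(bp$statistic), p.value = unname(bp$p.value),
                 domain = domain, region = region)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$kind, "model for", x$region,
      "(degree", paste0(x$degree, ","), x$df_method, "df)\n")
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}
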