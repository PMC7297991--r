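test_that("noise-free generated data are recovered exactly", {
  scans <- paired_scan_table(30)
  spec <- wm_spec(pct = 7.38, subject_sd = 0, residual_sd = 0)
  tab <- generate_measures(scans, spec, seed = 1, compose = FALSE)
  fit <- fit_absolute_model(tab, "WM")
  expect_equal(fit$df_method, "ols")
  pd <- percent_difference(fit)
  expect_equal(pd$estimate_pct, 7.38, tolerance = 1e-6)
  # fitted values interpolate the generating trajectory
  expect_lt(max(abs(fitted(fit$fit) - fit$data$log_value)), 1e-8)
})

test_that("back-transform consistency holds across the effect range", {
  scans <- paired_scan_table(20)
  for (delta in c(-0.2, -0.05, 0, 0.07, 0.2)) {
    spec <- effect_spec("R", baseline = 1000, growth = c(0.1, -0.002),
                        subject_sd = 0, residual_sd = 0)
    spec$sex_log_effect <- delta
    tab <- generate_measures(scans, spec, seed = 1, compose = FALSE)
    pd <- percent_difference(fit_absolute_model(tab, "R"))
    expect_equal(pd$estimate_pct, 100 * (exp(delta) - 1), tolerance = 1e-6)
  }
})

test_that("with one scan per subject the fixed effects equal plain OLS", {
  # oracle: direct OLS on the same design (random intercept unidentifiable;
  # GLS with compound symmetry collapses to OLS when every block has size 1)
  coh <- generate_cohort(cohort_schedule(n_male = c(40, 0, 0),
                                         n_female = c(40, 0, 0)), seed = 3)
  tab <- generate_measures(coh, wm_spec(subject_sd = 0.1), seed = 4,
                           compose = FALSE)
  fit <- fit_absolute_model(tab, "WM")
  d <- fit$data
  ols <- lm(log_value ~ sex + w1 + w2 + sex:w1, data = d)
  expect_equal(fit$coefficients$estimate[match(names(coef(ols)),
                                               fit$coefficients$term)],
               unname(coef(ols)), tolerance = 1e-6)
  # total variance is preserved even though the split is unidentified
  expect_equal(sum(fit$variance_components),
               sum(residuals(ols)^2) / ols$df.residual, tolerance = 0.05)
})

test_that("swapping the sex reference level negates the sex coefficient", {
  coh <- generate_cohort(small_schedule(), seed = 6)
  tab <- generate_measures(coh, wm_spec(), seed = 7, compose = FALSE)
  fit <- fit_absolute_model(tab, "WM")
  flipped <- dplyr::mutate(tab, sex = factor(ifelse(sex == "M", "F", "M"),
                                             levels = c("F", "M")))
  fit2 <- fit_absolute_model(flipped, "WM")
  a1 <- fit$coefficients$estimate[fit$coefficients$term == "sexM"]
  a2 <- fit2$coefficients$estimate[fit2$coefficients$term == "sexM"]
  expect_equal(a1, -a2, tolerance = 1e-3)
})

test_that("percent difference warns on extrapolation and handles b = 0", {
  coh <- generate_cohort(small_schedule(), seed = 2)
  tab <- generate_measures(coh, wm_spec(), seed = 3, compose = FALSE)
  fit <- fit_absolute_model(tab, "WM")
  expect_warning(percent_difference(fit, at_week = 40), "extrapolat")
  pd27 <- percent_difference(fit)
  expect_true(pd27$p_sex >= 0 && pd27$p_sex <= 1)
})

test_that("fitting errors are informative", {
  coh <- generate_cohort(small_schedule(), seed = 2)
  tab <- generate_measures(coh, wm_spec(), seed = 3, compose = FALSE)
  expect_error(fit_absolute_model(tab, "nope"), "region")
  neg <- dplyr::mutate(tab, value = value - 2 * mean(value))
  expect_error(fit_absolute_model(neg, "WM"), "non-positive")
  onesex <- dplyr::filter(tab, sex == "F")
  expect_error(fit_absolute_model(onesex, "WM"), "both sexes")
})

test_that("bonferroni flag applies the strict threshold", {
  expect_true(bonferroni_flag(6.20e-7, 26))
  expect_false(bonferroni_flag(1.0, 26))
  expect_false(bonferroni_flag(0.05 / 26, 26))  # strict inequality
  expect_true(bonferroni_flag(1e-4, 26))        # 1e-4 < 0.05/26
  expect_error(bonferroni_flag(1.2, 26), "0,1")
  expect_error(bonferroni_flag(0.01, 0), "family")
})

test_that("bootstrap CIs are deterministic and degenerate without noise", {
  scans <- paired_scan_table(15)
  tab0 <- generate_measures(scans, wm_spec(subject_sd = 0, residual_sd = 0),
                            seed = 1, compose = FALSE)
  fit0 <- fit_absolute_model(tab0, "WM")
  ci0 <- bootstrap_ci(fit0, B = 100, seed = 9)
  expect_equal(ci0$ci_low_pct, ci0$ci_high_pct)
  expect_equal(ci0$ci_low_pct, 7.38, tolerance = 1e-6)

  coh <- generate_cohort(small_schedule(), seed = 5)
  tab <- generate_measures(coh, wm_spec(), seed = 6, compose = FALSE)
  fit <- fit_absolute_model(tab, "WM")
  ci1 <- bootstrap_ci(fit, B = 100, seed = 21)
  ci2 <- bootstrap_ci(fit, B = 100, seed = 21)
  expect_identical(ci1, ci2)
  expect_lt(ci1$ci_low_pct, percent_difference(fit)$estimate_pct)
  expect_gt(ci1$ci_high_pct, percent_difference(fit)$estimate_pct)
  expect_error(bootstrap_ci(fit, B = 50, seed = 1), ">= 100")
})

test_that("heteroscedasticity diagnostic flags multiplicative data in the raw domain", {
  coh <- generate_cohort(cohort_schedule(), seed = 31)
  tab <- generate_measures(coh, wm_spec(subject_sd = 0.1, residual_sd = 0.08),
                           seed = 32, compose = FALSE)
  raw <- heteroscedasticity_diag(tab, "WM", "raw")
  logd <- heteroscedasticity_diag(tab, "WM", "log")
  expect_lt(raw$p.value, 0.05)
  expect_gt(logd$p.value, 0.001)
  const <- dplyr::mutate(tab, value = 5)
  expect_warning(out <- heteroscedasticity_diag(const, "WM", "log"),
                 "constant")
  expect_equal(out$p.value, 1)
  expect_error(heteroscedasticity_diag(tab[1:10, ], "WM"), "20 rows")
})
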