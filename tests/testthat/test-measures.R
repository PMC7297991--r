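test_that("sum-composition invariants hold exactly on every draw", {
  coh <- generate_cohort(small_schedule(), seed = 2)
  tab <- generate_measures(coh, default_effect_spec(), seed = 3,
                           lobes = default_lobe_spec())
  sums <- function(regions) {
    tab |>
      dplyr::filter(region %in% regions) |>
      dplyr::summarise(s = sum(value), .by = scan_id) |>
      dplyr::arrange(scan_id) |>
      dplyr::pull(s)
  }
  one <- function(r) {
    tab |> dplyr::filter(region == r) |> dplyr::arrange(scan_id) |>
      dplyr::pull(value)
  }
  expect_identical(one("ICV"),
                   sums(c("CORT", "WM", "DGM", "CEREB", "VENT", "SCSF")))
  expect_identical(one("TBV"), sums(c("CORT", "WM", "DGM", "CEREB")))
  lobes <- paste0(c("Frontal", "Parietal", "Temporal", "Occipital"), "_WM")
  expect_equal(one("WM"), sums(lobes), tolerance = 1e-12)
  areas <- paste0(c("Frontal", "Parietal", "Temporal", "Occipital"), "_AREA")
  expect_equal(one("AREA"), sums(areas), tolerance = 1e-12)
  expect_true(all(tab$value > 0))
})

test_that("noise-free, effect-free draws depend on week only", {
  scans <- paired_scan_table(10)
  spec <- wm_spec(pct = 0, subject_sd = 0, residual_sd = 0)
  tab <- generate_measures(scans, spec, seed = 1, compose = FALSE)
  expected <- spec$baseline_log + spec$growth1 * (tab$gest_week - 27) +
    spec$growth2 * (tab$gest_week - 27)^2
  expect_equal(log(tab$value), expected, tolerance = 1e-12)
  by_week <- split(tab$value, tab$gest_week)
  for (v in by_week) expect_lt(diff(range(v)), 1e-9)
})

test_that("geometric-mean male/female ratio matches the generating effect", {
  # oracle: direct geometric means on the generated table at matched ages
  scans <- paired_scan_table(n_per_sex = 1500)
  tab <- generate_measures(scans, wm_spec(pct = 7.38), seed = 42,
                           compose = FALSE)
  gm <- tab |>
    dplyr::summarise(m = mean(log(value)), .by = sex)
  ratio <- exp(gm$m[gm$sex == "M"] - gm$m[gm$sex == "F"])
  mc_se <- sqrt(2 * (0.08^2 + 0.05^2) / 1500)
  expect_lt(abs(log(ratio) - log(1.0738)), 3 * mc_se)
})

test_that("raw-domain spread grows with age while log-domain spread does not", {
  coh <- generate_cohort(cohort_schedule(), seed = 9)
  tab <- generate_measures(coh, wm_spec(), seed = 10, compose = FALSE)
  tert <- dplyr::ntile(tab$gest_week, 3)
  detrend <- function(y) residuals(lm(y ~ poly(tab$gest_week, 2)))
  raw_sd <- tapply(detrend(tab$value), tert, sd)
  log_sd <- tapply(detrend(log(tab$value)), tert, sd)
  expect_gt(raw_sd[3], raw_sd[1])
  expect_lt(abs(log_sd[3] - log_sd[1]) / log_sd[1], 0.5)
})

test_that("lobe shares sum to one and carry their sex offsets at 27 weeks", {
  # noiseless shares: lobe/parent ratio at the reference week is the softmax
  # of the configured offsets
  scans <- paired_scan_table(n_per_sex = 6, weeks = 27)
  ls <- lobe_spec("WM", lobes = c("A", "B"), base_share = c(0.4, 0.6),
                  sex_pct_target = c(3.40, -2.27),
                  logit_subject_sd = 0, logit_residual_sd = 0)
  tab <- generate_measures(scans, wm_spec(pct = 0, subject_sd = 0,
                                          residual_sd = 0),
                           seed = 1, lobes = list(ls), compose = FALSE)
  wide <- tab |>
    dplyr::select(scan_id, sex, region, value) |>
    tidyr::pivot_wider(names_from = region, values_from = value)
  shareA <- wide$A_WM / wide$WM
  rF <- mean(shareA[wide$sex == "F"]); rM <- mean(shareA[wide$sex == "M"])
  kappa <- log(0.4 * 1.0340 + 0.6 * (1 - 0.0227))
  expect_equal(log(rM / rF), log(1.0340) - kappa, tolerance = 1e-9)
})

test_that("invalid generator inputs raise informative errors", {
  coh <- generate_cohort(small_schedule(), seed = 1)
  bad <- wm_spec(); bad$subject_sd <- -1
  expect_error(generate_measures(coh, bad, seed = 1), "non-negative")
  expect_error(
    generate_measures(coh, wm_spec(), seed = 1,
                      lobes = list(lobe_spec("CORT", base_share = c(0.5, 0.5),
                                             lobes = c("A", "B")))),
    "CORT")
  expect_error(
    generate_measures(coh, wm_spec(), seed = 1,
                      asymmetry = list(asymmetry_spec("DGM", 0.01))),
    "DGM")
  expect_error(effect_spec("X", baseline = -5, growth = 0.1), "positive")
})

test_that("measure generation is deterministic and CSV round-trips", {
  coh <- generate_cohort(small_schedule(), seed = 4)
  a <- generate_measures(coh, default_effect_spec(), seed = 7)
  b <- generate_measures(coh, default_effect_spec(), seed = 7)
  expect_identical(a, b)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measures(a, path)
  back <- read_measures(path)
  expect_equal(back$value, a$value, tolerance = 1e-12)
  expect_equal(as.character(back$sex), as.character(a$sex))
  empty <- generate_measures(
    generate_cohort(cohort_schedule(n_male = c(0, 0, 0),
                                    n_female = c(0, 0, 0)), seed = 1),
    default_effect_spec(), seed = 1)
  expect_equal(nrow(empty), 0)
})
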