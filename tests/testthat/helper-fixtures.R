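# Shared fixtures: reduced cohorts and handmade scan tables keep unit tests
# fast; full-size cohorts are used only where a test is about the study's n.

small_schedule <- function() {
  cohort_schedule(n_male = c(10, 5, 5), n_female = c(12, 5, 4))
}

# Scan table with identical age grids for both sexes (useful when a test
# needs exact age matching between the sexes).
paired_scan_table <- function(n_per_sex = 40, weeks = c(20, 24, 28, 32, 36)) {
  grid <- rep(weeks, length.out = n_per_sex)
  tibble::tibble(
    scan_id = sprintf("P%03d_T1", seq_len(2 * n_per_sex)),
    subject_id = sprintf("P%03d", seq_len(2 * n_per_sex)),
    sex = factor(rep(c("F", "M"), each = n_per_sex), levels = c("F", "M")),
    gest_week = c(grid, grid)
  )
}

wm_spec <- function(pct = 7.38, subject_sd = 0.08, residual_sd = 0.05,
                    interaction = 0) {
  effect_spec("WM", baseline = 66800, growth = c(0.10, -0.003),
              pct_effect = pct, interaction = interaction,
              subject_sd = subject_sd, residual_sd = residual_sd)
}

# Coefficient lookup via the public tidier (0 when the term is absent).
coef_of <- function(model, term) {
  tb <- tidy(model)
  i <- match(term, tb$term)
  if (is.na(i)) 0 else tb$estimate[i]
}
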