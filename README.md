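# fetalgrowth

Statistical modelling of male–female differences in fetal brain growth
from repeated MRI morphometry.

## The problem

Longitudinal fetal MRI studies measure brain volumes, surface areas and
curvatures repeatedly between ~18 and ~37 gestational weeks (GW), on an
unbalanced schedule (most fetuses scanned once, some twice or three
times, 4–6 weeks apart). Growth over this window is multiplicative, so
raw measures are heteroscedastic in age; sex differences are small
fractional offsets riding on an order-of-magnitude growth curve.
`fetalgrowth` implements the full analysis chain for such data:

* **Absolute growth** — log-domain quadratic mixed-effects model,
  `log Q ≈ a·[male] + b·W·[male] + c·W + d·W² + u_subject + ε`, fit by
  REML with Satterthwaite p-values; the sex effect is reported as the
  percent difference at 27 GW, `100(e^{a + b·w27} − 1)`, with
  parametric-bootstrap 95% CIs and strict Bonferroni flags
  (`p < 0.05/m`).
* **Relative growth** — the same model with the matching global measure
  as a log covariate (`+ g·log G`; ICV for volumes, whole-brain AREA for
  areas, CURV for curvatures), degree 2 for global measures and degree 4
  for lobes, isolating residual (share-like) sex differences.
* **Asymmetry** — regression of the left side on the right
  (`log Q_LEFT ≈ … + e·log Q_RIGHT + f·log G`); the sex coefficient
  captures residual asymmetry differences, reported under a documented
  rightward-positive convention.
* **Tensor-based morphometry** — voxelwise OLS of smoothed, log
  Jacobian-determinant maps on sex, an age polynomial to degree 4 and the
  log mean Jacobian, with family-wise error controlled by maxT
  permutation (sex labels exchanged at the subject level).
* **Surface metrics** — per-label triangle areas and per-vertex mean
  curvature by two-ring quadric fitting; regional CURV is the mean |H|.
* **Synthetic cohort** — a generator reproducing the study sampling
  structure (162 fetuses, 268 scans, 88/42/32 with one/two/three scans,
  139/129 male/female scans, 18.0–36.8 GW) with known effect sizes,
  exact sum composition (ICV, TBV, lobe shares), Jacobian phantoms and
  labelled test meshes, so every stage is testable by parameter
  recovery.

The design, defaults and numerical decisions are documented in the
methods vignette (`vignettes/fetal-growth-methods.Rmd`).

## Worked example

```r
library(fetalgrowth)

coh <- generate_cohort(cohort_schedule(), seed = 42)  # 162 fetuses, 268 scans
tab <- generate_measures(coh, default_effect_spec(), seed = 43,
                         lobes = default_lobe_spec(),
                         asymmetry = default_asymmetry_spec())

fit <- fit_absolute_model(tab, "WM")
percent_difference(fit, family_size = 26)
#> # A tibble: 1 x 8
#>   region model    at_week estimate_pct       p_sex p_interaction family_size bonferroni_survives
#>   <chr>  <chr>      <dbl>        <dbl>       <dbl>         <dbl>       <dbl> <lgl>
#> 1 WM     absolute      27         8.01 0.000000304         0.712          26 TRUE
```

The default generator plants a 7.38% male excess in white matter; this
seed recovers 8.01% (single seeds scatter with sd ~1.2 points — the test
suite checks the mean over >=20 seeds against the truth within
Monte-Carlo error). `p_sex` is the Satterthwaite p-value for the sex
term, and the Bonferroni flag applies the 26-test family of the absolute
table. Continuing:

```r
bootstrap_ci(fit, B = 1000, seed = 3)     # percentile CI in percent units
#> # A tibble: 1 x 4
#>   ci_low_pct ci_high_pct n_fail     B
#>        <dbl>       <dbl>  <int>  <int>
#> 1       5.03        11.3      0   1000
fit_relative_model(tab, relative_spec("WM", "ICV", 2)) |> percent_difference()
fit_asymmetry_model(tab, "Frontal_WM")$result
run_study(study_config(seed = 7))         # full table-style report bundle
```

`autoplot()` methods draw the male/female growth fans and TBM slice
maps; `tidy()`/`glance()` give broom-style summaries of any fit.

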