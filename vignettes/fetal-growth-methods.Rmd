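---
title: "Modelling sex differences in fetal brain growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sex differences in fetal brain growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalgrowth)
```

# The problem

Between 18 and 37 gestational weeks (GW) the human fetal brain grows by
roughly an order of magnitude while folding and regional specialisation
unfold. Quantifying how male and female brains differ over this period
requires modelling repeated, unbalanced morphometric measures — most
subjects contribute one scan, some two or three, 4–6 weeks apart — and
doing so on a scale where growth is well behaved.

`fetalgrowth` implements that analysis as a reusable pipeline: log-domain
polynomial mixed-effects growth models for absolute measures, relative
(global-covaried) models for regional shares, a regression-based
left–right asymmetry test, voxelwise tensor-based morphometry (TBM) with
maxT permutation control, and surface area/curvature summaries on labelled
meshes. Because the cohort that motivates this design is not publicly
deposited, the package ships a synthetic-cohort generator that reproduces
the sampling structure and known effect sizes, so every stage is
verifiable by parameter recovery.

# Absolute growth model

Biological growth is multiplicative: small proportional perturbations
accumulate, so the spread of raw volumes increases with age
(heteroscedasticity), while log-transformed measures have roughly
age-constant spread. All models therefore act on `log(Q)`:

$$\log Q \approx a\,[male] + b\,W\,[male] + c\,W + d\,W^2 + u_{subject} + \varepsilon$$

with `W` the gestational week as a scaled-and-centred orthonormal
polynomial basis (`build_poly_basis()`, a thin wrapper around the standard
orthogonal-polynomial construction, evaluable at new ages), a subject
random intercept `u`, and REML estimation with Satterthwaite p-values
(`lmerTest`). The quadratic degree follows from the shape of fetal growth
in this window: growth accelerates but does not yet converge to an
asymptote, so saturating models (Gompertz, logistic) are unnecessary and a
single step beyond linear captures the curvature.

The sex effect is reported in measurement units as the percent difference
at a reference age,

$$100\,(e^{\,\hat a + \hat b\, w_{27}} - 1),$$

where $w_{27}$ is the degree-1 basis value at 27.0 GW — the reference age
used throughout (the cohort mean is 27.6, but 27 is the conventional
reporting age here, and with $\hat b \approx 0$ the estimate is
age-independent: a constant fractional male/female ratio). Confidence
intervals come from a parametric bootstrap (`bootstrap_ci()`): `B`
response vectors are simulated from the fitted model — fixed effects plus
fresh random intercepts and residuals — refit, and the percent-difference
statistic is collected; 2.5/97.5 percentiles are reported in percent
units. `B = 1000` by default, 200 in the test suite's coverage study.
Bonferroni flags use the strict rule `p < 0.05/m` with family sizes 26
(absolute table) and 20 (relative and asymmetry tables).

Degenerate inputs: if the response is an exact function of the design
(zero residual variance, as in noise-free recovery tests) the mixed model
is singular, and the fitter falls back to ordinary least squares, recorded
as `df_method = "ols"`. The same fallback serves cohorts with exactly one
scan per subject, where the intercept/residual variance split is
unidentified but GLS fixed effects provably coincide with OLS.

# Relative and asymmetry models

Relative growth asks whether a region outgrows the global measure it
belongs to. Rather than modelling ratios (which misbehave as regression
responses), the global reference enters as a log covariate:

$$\log Q \approx a\,[male] + b\,W\,[male] + \textstyle\sum_k c_k W^k + g \log G,$$

with `G` = ICV for volumes, whole-brain AREA for areas, whole-brain CURV
for curvatures, matched per scan (time-varying covariate). Degree 2 is
used for global measures, degree 4 for lobes — the lowest degree able to
express the up-to-three critical points that differently timed lobe
growth spurts induce in share trajectories. `log G` is not orthogonalised
against the age basis; its coefficient is freely estimated. A measure is
never used as its own reference.

The asymmetry test models the left side on the right side
(`fit_asymmetry_model()`):

$$\log Q_{LEFT} \approx a\,[male] + b\,W\,[male] + cW + dW^2 + e \log Q_{RIGHT} + f \log G.$$

Because the response is the left side, a male-only *rightward* asymmetry
appears as a negative `a`; the reported difference is
$100(e^{-(\hat a + \hat b w_{27})} - 1)$, so a pure male rightward log
offset `d` in the data round-trips to exactly $100(e^{d}-1)$ percent.
The sign convention is recorded in every result. A caveat established
during design: the right side is a covariate, so any *independent*
measurement noise on it attenuates `e` by about
$\eta^2/\sigma^2_{within}$ and leaks the same fraction of the shared sex
effect into `a`. The synthetic generator therefore gives the left/right
pair one shared biological signal and only a token independent noise
(`hemi_sd = 5e-4`) whose sole purpose is to keep the fit non-degenerate.

# Tensor-based morphometry

Per-scan Jacobian-determinant maps `|J(x)|` (local volume change relative
to a common anatomical space) are smoothed with a 4-mm FWHM Gaussian
(sigma = FWHM/√(8 ln 2) per axis, normalised kernel, reflect padding —
the choice that leaves both constants and total mass invariant), log
transformed, and fit voxelwise by OLS on
`[male, W…W⁴, W·male, log Ḡ]`, where `Ḡ` is the in-mask mean Jacobian
(global size). The voxel estimator is deliberately OLS, not mixed-effects:
repeated measures are respected instead in the permutation scheme, which
exchanges sex labels at the *subject* level so all scans of a subject move
together. Family-wise error is controlled by maxT: each permutation
records the maximum |T| over in-mask voxels, and the corrected two-sided
threshold is the `ceiling(0.95·(B+1))`-th order statistic of that
distribution — the `+1` makes the observed map exchangeable with the
permutations, so flagging `|T| ≥ threshold` guarantees FWER ≤ α. The
full-scale analysis uses 20,000 permutations; desk-scale suites use 500,
which resolves the 95th percentile adequately (the FWER study below uses
exactly that). A constant `Ḡ` (as with identical input maps) is dropped
from the design rather than allowed to make it singular; voxels with zero
residual variance report T = 0 and are counted.

# Surface metrics

Region areas sum triangle areas, assigning each triangle to the majority
label of its three vertices (ties to the lowest label id —
deterministic). Mean curvature is estimated per vertex by fitting the
five-parameter quadric $z \approx a_1x + a_2y + a_3x^2 + a_4xy + a_5y^2$
to the two-ring neighbourhood expressed in a tangent frame built from the
area-weighted vertex normal, then

$$H = \frac{a_3(1+a_2^2) - a_4a_1a_2 + a_5(1+a_1^2)}{(1+a_1^2+a_2^2)^{3/2}}.$$

Under this parameterisation a convex surface seen along its outward
normal has negative H; regional summaries use |H|, so the sign convention
only matters for effect directions and is documented where reported. The
regional CURV summary is the *unweighted* mean of |H| over valid vertices
carrying the label (mean of absolute values, not absolute value of the
mean; area weighting is available as an option but is not the default).
Vertices with fewer than five two-ring neighbours expand to the
three-ring (the quadric has five parameters); if the local fit is still
rank-deficient the vertex is marked invalid and excluded from averages,
never imputed.

# The synthetic cohort

`generate_cohort()` reproduces the emulated study's structure exactly:
162 fetuses, 81 per sex, with 41/22/18 males and 47/20/14 females having
one/two/three scans — 268 scans, 139 male and 129 female. Ages span
18.0–36.8 GW; repeat scans are 4–6 weeks apart. The age distribution
within the range is not documented for the emulated study, so first-scan
ages are uniform on `[18, 36.8 − 5(n_scans−1)]` (so later scans fit) and
gaps uniform on [4, 6], truncating the last scan at 36.8 when needed —
the truncation cannot compress a gap below 4 weeks given the first-scan
window.

`generate_measures()` draws, per region,
`log Q = baseline + growth(W−27) + δ·[male] + γ(W−27)·[male] + u + ε`,
which makes growth multiplicative, values strictly positive, raw-domain
spread age-increasing and log-domain spread age-constant — exactly the
regime the log transform is for. Key defaults and why:

* **Variance components** `σ = 0.05`, `τ = 0.08` log units — chosen so
  simulated CI widths are of the same order as the reported intervals;
  CSF compartments get inflated components (`τ` 0.20–0.25, `σ` 0.10),
  reflecting their much larger relative variability.
* **Sex effects** default to the reported percent differences (WM 7.38,
  CORT 5.08, DGM 3.52, CEREB 3.40, VENT 17.96, …), converted as
  `δ = log(1 + p/100)`.
* **Baselines** are plausible mid-gestation magnitudes (e.g. TBV ≈ 111
  cm³ at 27 GW) with one deliberate calibration: composed measures (ICV =
  six compartments, TBV = four tissues) inherit their sex effect as the
  share-weighted blend of component effects, so component baselines were
  chosen once to make the blends consistent with the reported global
  effects (developing WM ≈ 60% of TBV at mid-gestation, extra-axial CSF a
  substantial ICV fraction). Sum invariants hold *exactly* on every draw.
* **Lobes** are generated as softmax shares of their parent with per-lobe
  polynomial logit trajectories — shares sum to 1 at every age by
  construction, and the multi-peak relative trajectories that motivate
  the degree-4 model arise naturally. Per-lobe sex offsets are applied on
  the logit scale; they are exact up to a common renormalisation constant
  across the parent's lobes, so single-region recovery experiments
  generate their region directly instead.
* **Jacobian phantoms** are analytic:
  `|J| = scale³ · exp(focal offsets) · exp(smoothed noise)`, with the
  global scale tied to ICV (or an age curve) plus per-scan log-normal
  jitter (`global_scale_sd = 0.05`). The jitter matters: without
  between-subject size variability, the mean-Jacobian covariate is
  collinear with any focal sex effect and the voxel model cannot separate
  them — a genuine identifiability property of the design, not an
  artefact.
* **Meshes** are icospheres/ellipsoids with optional angular-sector
  labels; spheres give the exact curvature oracle `|H| = 1/R`.

What the generator does *not* emulate: MRI intensities, motion,
segmentation error, spatial correlation of regional measures beyond the
sum constraints, non-uniform age sampling, or cohort attrition. Passing
recovery tests therefore demonstrates that the *statistical pipeline* is
unbiased and calibrated under the stated sampling structure — not that
the upstream image-processing chain is accurate.

# Problem sizes and numerical choices

The test suite runs recovery at the study's own size (268 scans), with
20–30 seed replicates per criterion and Monte-Carlo-SE tolerances; the
bootstrap coverage study uses 200 replicate datasets of a half-scale
cohort (41 subjects, ~68 scans) at B = 200; the permutation FWER study
uses 100 null phantoms at 16³ voxels and 500 permutations; curvature
oracles use subdivision-4 icospheres (2562 vertices). These sizes were
chosen to put Monte-Carlo error well inside each tolerance while keeping
the suite comfortably desk-scale.

Other numerical decisions: the OLS fallback triggers when the residual
standard deviation of a pilot OLS fit is below 1e-10; permutation
thresholds use order statistics, never interpolated quantiles; softmax
shares are computed in log space and renormalised exactly; kernel radii
larger than the grid are handled by full symmetric reflection; bootstrap
refit failures are tolerated up to 10% of replicates and reported,
beyond that the CI errors out.

# Known limitations

* The asymmetry percentage's mapping from the model coefficient is a
  convention (documented and tagged in every result); other definitions
  differ in the second order.
* Lobe-level sex offsets in the share construction are exact only at the
  reference week and up to a common renormalisation; hierarchical tables
  are therefore approximate at the per-lobe level (direct generation is
  exact and is what the recovery experiments use).
* The voxelwise estimator ignores within-subject correlation except
  through permutation blocking; with many repeated scans per subject a
  mixed-effects voxel model would be preferable.
* Percent differences at 27 GW fold the interaction term in
  (`a + b·w27`); with a strong interaction the single-age summary hides
  age dependence — inspect `p_interaction` and `autoplot()` curves.

# A worked example

```{r example, eval = FALSE}
library(fetalgrowth)

coh <- generate_cohort(cohort_schedule(), seed = 1)
tab <- generate_measures(coh, default_effect_spec(), seed = 2,
                         lobes = default_lobe_spec(),
                         asymmetry = default_asymmetry_spec())

fit <- fit_absolute_model(tab, "WM")
percent_difference(fit, family_size = 26)
bootstrap_ci(fit, B = 1000, seed = 3)
autoplot(fit)

run_study(study_config(seed = 7))
```
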