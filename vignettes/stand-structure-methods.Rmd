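---
title: "Methods: non-spatial stand structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-spatial stand structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(standstruct)
```

This vignette is the package's own account of its models, the choices
behind them, and what the validation suite does and does not demonstrate.

## The data model

A plot inventory is two delimited tables.  The tree table records, per
stem, the plot id, DBH (cm, > 0), total height (m, > 1.3 — DBH is measured
at 1.3 m), crown width (m, the average of two perpendicular crown
diameters) and crown length (m, first living branch to tip).  The height
to base of the live crown (`hblc = height − crown_length`) and the live
crown ratio (`crown_length / height`) are derived on read, never stored;
`crown_length ≤ height` is a hard validation error, because a violated
record cannot be a measurement of the geometry these formulas assume.

The plot table carries the site covariates: city, stand age (yr), altitude
(m), slope direction (the eight compass aspects), landform (hill,
low-mountain, mid-mountain), soil type (red, lateritic-red, yellow), stand
density (stems per 1,000 m²), and optional mean annual temperature and
precipitation.  Landform is checked against its altitude band (hill
200–500 m, low-mountain 500–1,000 m, mid-mountain 1,000–3,500 m) but a
mismatch only warns: real plots occur below 200 m, where the band scheme
is silent, and we accept the recorded label rather than invent a rule.

## Horizontal structure

DBH values are binned into the fixed classes ≤5, 5–8, 8–12, …, 36–40 cm.
The "≤5" class forces an upper-closed reading, so all intervals are
`(a, b]`: a 8.0 cm stem belongs to 5–8.  Values above 40 cm are an error
by default (`allow_overflow = TRUE` folds them into the top class with a
warning); silently folding would hide data problems in a scheme that, by
construction, expects no such tree.

Structural diversity is the Shannon–Wiener index over the ten class
proportions, natural logarithm, with `0·ln 0 := 0`, so
`0 ≤ H ≤ ln 10 ≈ 2.303`.  Skewness and kurtosis use the population
(biased) moment estimators `m₃/m₂^1.5` and `m₄/m₂² − 3`; the excess form
is chosen so near-uniform distributions score negative kurtosis, which is
how flat diameter profiles are conventionally read.  The quadratic
class-proportion curve is unweighted least squares of proportion on class
midpoint (first midpoint 2.5 cm) with a pointwise 95% confidence band;
count-weighting was considered and rejected because the curve summarises
the *profile shape*, in which each class is one observation.

### The k-sample Anderson–Darling test

No installed package provides the k-sample Anderson–Darling test, so the
midrank (tie-adjusted) rank statistic is implemented here in full.  For
pooled distinct values `z_j` with multiplicities `l_j`, group sizes `n_i`,
`N` total, midrank-adjusted cumulative counts `M_aij` (per group) and
`B_aj` (pooled),

```
A²akN = (N−1)/N · Σ_i (1/n_i) Σ_j (l_j/N) · (N·M_aij − n_i·B_aj)² /
        (B_aj(N − B_aj) − N·l_j/4)
```

with the exact finite-N null variance used to standardize the statistic.
The default p-value is by seeded permutation of group labels,
`p = (1 + #{perm ≥ obs})/(1 + B)` with `B = 9999` by default — exactly
testable against exhaustive enumeration on tiny inputs, and free of the
interpolation error of the asymptotic tables.  An asymptotic mode
(logit-linear interpolation through the standard critical-value table,
extended linearly beyond it) is provided for large samples where
permutation is unnecessary.  If all pooled values are identical the
statistic is defined as 0 and p as 1: no relabelling can discriminate.
The statistic and variance were cross-checked against an independent
implementation (`scipy.stats.anderson_ksamp`, midrank variant) and the
reference value is frozen in the test suite.

Pairwise age-stage comparisons use the Wilcoxon rank-sum test with the
normal approximation and tie correction.  The six stage pairs are reported
unadjusted: the table is descriptive, each pair is read on its own, and
any multiplicity policy is the reader's to apply.

## Diversity drivers

Per-plot Shannon H is regressed on the seven drivers with a
gradient-boosted ensemble of shallow regression trees (squared-error
loss).  Defaults: learning rate 0.01, depth 3, bag fraction 0.75, at most
3,000 rounds with the count chosen by seeded 5-fold cross-validation and
early stopping.  Two defaults deserve explanation:

- **Categorical splits are native (level-subset), not one-hot.**  With a
  few dozen plots and an eight-level aspect factor, one-hot dummies have
  ~4 plots per level; any minimum-leaf constraint near that size forbids
  exactly the splits that carry an aspect signal, and the factor's gain is
  diluted across eight columns.  Level-subset splits keep the factor's
  contribution in single, well-supported splits.
- **Minimum 2 observations per leaf.**  The conventional 5 is meant for
  datasets orders of magnitude larger; at ~31 plots it nearly disables
  splitting on minority factor levels.  Two keeps leaves estimable while
  letting real small-sample signals through.

Relative influence is each predictor's share of total split gain across
the ensemble (read from the model dump, so numeric and categorical splits
are treated identically), normalized to percentages summing to 100;
predictors never split on get exactly 0.  Because influence on ~31 plots
is genuinely unstable, the report includes the across-fold standard
deviation of each percentage, obtained by refitting on each CV training
split.  Marginal effects are partial dependence: the chosen predictors are
clamped to each point of a grid (50 equally spaced points over the
observed range for numeric predictors, observed levels for factors) and
predictions are averaged over the training rows; at most three variables,
matching the deepest display the analysis uses.  Influence is attribution,
not causation.

## Vertical structure

TSTRAT assigns strata per plot (competition is local): sort by descending
height (ties by descending DBH, then input order, for reproducibility);
the tallest unassigned tree founds a stratum with cut-off
`CPS = 0.4·CL + HBLC = height − 0.6·CL` — competition for light is
strongest in the top 60% of the crown; every unassigned tree with height
≥ the cut-off joins (boundary trees join the *upper* stratum); the first
shorter tree founds the next stratum.  The founder-then-sweep loop is the
normative algorithm here; the cut-off formula alone does not define an
assignment.  Pooled layer summaries are tree-weighted.

## Path analysis

For each age stage (taken from the plot's stand age — tree ages are not
recorded — and pooling trees across plots within the stage), the crown
response is regressed on DBH and height by OLS.  The direct path
coefficient is the standardized partial coefficient `P_yi = bᵢsᵢ/s_y`;
the indirect coefficient of predictor *i* is its effect transmitted
through the other predictor, `r_ij·P_yj`, the orientation under which the
Wright decomposition `cor(xᵢ, y) = P_yi + r_ij·P_yj` holds exactly — the
test suite asserts it to 1e-10 on every fit.  With two predictors each
has exactly one indirect channel, so the table has one direct and one
indirect column per predictor.  Significance is the classical
homoskedastic t-test on the OLS coefficient; exact p-values are stored and
`***` rendered at p < 0.001.  Predictors with `|r| > 0.999` are rejected
as ill-conditioned.  No intercept is reported: path analysis concerns
standardized effects only.

## The synthetic stand generator

The study's inventory is not deposited, so the generator produces
inventories with the statistical structure the analysis assumes, and with
known ground truth for every estimator.  Its defaults are the study
conditions, chosen once:

- **Layout**: nine cities, 31 plots of 1,000 m² (25 m × 40 m), 3,633
  trees split evenly over each city's plots; stand ages 8–51 yr, altitude
  105–1,250 m, density 80–150 stems per 1,000 m², temperature
  15.5–18.5 °C, precipitation 1,200–1,800 mm; aspect and soil uniform over
  their vocabularies; landform derived from the altitude bands.
- **DBH**: Weibull, truncated to (1, 40] cm by inverse-CDF, because the
  class scheme ends at 40 cm and the emulated survey observes no larger
  stem.  The scale is set per age stage so the (untruncated) mean matches
  the stage means 8.73, 12.19, 14.4 and 21.75 cm; the shape — base 2.6 —
  controls spread and hence diversity, monotonically over the relevant
  range (verified empirically in the test suite, not assumed).
- **Drivers**: each covariate adds to the Weibull shape.  By default
  slope direction dominates (north-facing aspects get lower shape, hence
  higher diversity), with smaller density, landform, altitude, soil,
  precipitation and temperature effects.  The `driver_recovery_params()`
  preset — 31 single-stage plots, slope the sole driver — scales the
  aspect deltas by 1.7, the value at which replicate simulation puts the
  between-aspect spread of expected per-plot H at three times the
  within-plot sampling standard deviation (the prescribed 3:1
  effect-to-noise regime for recovery studies).
- **Height**: `H = 1.3 + s·a·DBH^b·exp(ε)` with `a = 4.3`, `b = 0.28`,
  `sd(ε) = 0.04`, and a per-plot site multiplier
  `s = exp(N(0, 0.13))`.  The flat exponent plus site effect encodes a
  fact about even-aged plantations: height varies across sites far more
  than within a plot.  This keeps tree heights in the survey's 5.4–20 m
  span while giving plots the simple one-to-few-layer vertical structure
  (dominant layer ≈ 90% of stems) that motivates a TSTRAT summary.
- **Crowns**: linear in DBH and height with Gaussian noise (width
  `0.5 + 0.15·DBH + 0.05·H`, sd 0.35; length `−0.5 + 0.08·DBH + 0.45·H`,
  sd 0.5), so the true standardized path coefficients follow in closed
  form from the generating covariance — `true_path_coefficients()`
  computes them with truncated-Weibull moments by numerical integration
  (relative tolerance 1e-10) and the log-normal height noise analytically.
  Crown length is clamped to `[0, height]`; clamp events are counted and
  stay well under 1% at the defaults.  `simulate_path_data()` generates
  standardized crown data with *exactly* known direct coefficients for
  recovery tests.

What the generator does **not** emulate: spatial tree positions and
neighbour competition, growth or mortality over time, measurement error,
multimodal diameter distributions from disturbance, and within-plot age
mixtures.  Passing tests therefore demonstrate correctness of the
estimators under the stated generative assumptions — not that real
inventories satisfy those assumptions.

## Numerical choices and degenerate inputs

- Binning boundary: exactly-on-edge values join the lower class (upper
  closure); empty distributions make the Shannon index an error, not NaN.
- Moments: population estimators; constant samples and n < 3 are errors.
- Permutation p-values always include the observed labelling in the
  numerator and denominator, so p > 0 and the null distribution of p is
  sub-uniform (the test suite checks type-I error at α = 0.05 is within
  binomial bounds at 1,000 replicates).
- TSTRAT ties: height ties sort by descending DBH then input order;
  equal-to-cut-off trees join the upper stratum.
- Determinism: every stochastic routine takes or derives an integer seed;
  boosting runs single-threaded with seeded fold assignment, and the
  end-to-end pipeline writes byte-identical reports across repeated runs
  of one configuration.

## Problem sizes

The validation suite sizes its simulations to be decisive yet quick: the
default 31-plot/3,633-tree inventory for end-to-end checks; 10⁵–2×10⁵
trees where a closed-form moment or coefficient is being approached;
1,000 replicates for permutation calibration; 200 random stands for the
stratification invariances; 20 seeded replicates for driver recovery.
These sizes are the package's documented choices and are inherited by
`scripts/acceptance.R`.

## Known limitations

- Influence percentages on ~31 plots carry large across-fold dispersion;
  ranks beyond the first position should not be over-read.
- The asymptotic Anderson–Darling p-value is an interpolation, reliable
  only inside roughly the 0.01–0.25 range of its table; use permutation
  when the p-value matters.
- Path analysis here is strictly linear with two predictors; it is not a
  structural-equation model and fits no latent structure.
- The stage label of a tree is its plot's stage: within-plot age variation
  is invisible to the stage comparisons.
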