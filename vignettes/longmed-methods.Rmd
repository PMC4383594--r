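---
title: "Statistical methods behind longmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind longmed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmed)
```

longmed analyzes longitudinal clinical studies in which many outcomes —
typically 0–10 visual-analog-scale (VAS) symptom intensities — are recorded
for each subject at a handful of scheduled evaluation occasions. This
vignette is the package's own account of the statistical machinery: what
each method assumes, which tunable parameters matter, how the synthetic
data generator is built, and where the numerically delicate choices lie.

## The data model

Data enter in *long format*: one row per subject-evaluation, with three
mandatory columns (subject ID, evaluation date, evaluation occasion) plus
one or more outcome columns and optional covariates, one of which may be a
binary grouping variable. `validate_roles()` enforces the structural
invariants — non-missing keys, unique `(id, occasion)` pairs, parseable
dates, numeric outcomes, two-level grouping — and fixes the occasion order:
levels that all parse as numbers are sorted numerically, otherwise
first-appearance order is used (overridable via `occasion_levels`). The
first level is always the baseline/reference.

Two derived quantities matter downstream:

* **Days since first evaluation** (`add_days_since_first()`): whole days
  between a row's date and the subject's earliest date. This is the numeric
  time axis for mixed models and timeline plots.
* **Dichotomization** (`dichotomize()`): `value > threshold` codes 1,
  `value <= threshold` codes 0, missing stays missing. The inequality is
  deliberately *strict* so that threshold 0 on a VAS scale encodes symptom
  presence (a recorded 0 means "absent"). This rule is applied everywhere a
  binary view of a numeric outcome is requested.

Dates are parsed as ISO-8601 first, then `%d.%m.%Y`, with an explicit
`date_format` escape hatch — delimited exports are not consistent about
date dialects, so the format is a declared role rather than a guess.

## Descriptive summaries

Numeric outcomes are summarized by median and interquartile range;
quartiles use linear interpolation between order statistics (the type-7
rule, R's default). The convention matters at small n — `{1,2,3,4}` gives
quartiles 1.75 and 3.25 under type 7 — so it is fixed and tested rather
than left to chance.

The 95% CI for the median is a **percentile bootstrap** with `B = 2000`
resamples by default: resample n values with replacement, take the 2.5th
and 97.5th percentiles of the bootstrap medians. The percentile method (not
BCa) is used; `B` and the seed are exposed so intervals are exactly
reproducible. Its coverage is a property of the pair (estimator, n): the
acceptance suite measures it at n = 200 over 500 replicates against a
known continuous distribution and requires 95% ± 3 points. With fewer than
two observations the interval degenerates to the single value rather than
erroring, because summary tables must still render for sparse cells.

Proportions get the **exact Clopper–Pearson interval** by Beta-quantile
inversion, with the conventional endpoints 0 at `x = 0` and 1 at `x = n`.
For the published count 152/225 this gives 68% (61%–74%) after rounding to
whole percentages, which is the package's display rule for proportions
(numeric summaries round to 2 decimals for display; machine outputs keep
full precision).

## Two-group comparisons and multiplicity

At a chosen occasion, each outcome is compared between the two groups with
the **Mann–Whitney test** (numeric) or the **two-sample proportion test
with Yates continuity correction** (binary). The Mann–Whitney p is exact
by enumeration for tie-free samples with fewer than 9 per group, and
otherwise uses the normal approximation with tie and continuity
correction. VAS data are heavily tied, so the approximation is the
practically relevant branch.

Testing 16 outcomes at α = 0.05 without adjustment gives a familywise
error rate of `1 − 0.95^16 ≈ 0.56`; the FWER first exceeds one half at 14
independent tests (`fwer_independent()`). Four multiplicity columns are
therefore available in `compare_groups(adjust = TRUE)`:

* **Holm–Bonferroni** step-down adjusted p values (FWER control under any
  dependence, but conservative for correlated outcomes);
* **Westfall–Young min-P permutation** adjusted p values;
* **Benjamini–Hochberg** and **Benjamini–Yekutieli** Q values — the
  minimum false discovery rate at which each test may be called
  significant, the BY variant valid under arbitrary dependence.

The min-P engine (`minp_adjust()`) permutes group labels at the subject
level, keeping each subject's row of outcomes intact so the correlation
structure of the outcomes is preserved in the permutation distribution.
For the outcome with the i-th smallest observed p, the adjusted value is

    (1 + #{b : min over not-yet-rejected outcomes of p_b <= p_(i)}) / (B + 1)

with monotonicity enforced along the step-down path. The *step-down*
variant is the default because it is uniformly more powerful than the
single-step version while controlling the same error rate; the reference
literature admits either reading, so `variant = "single-step"` switches to
the conservative form. The `(1 + count)/(B + 1)` estimator keeps the
smallest attainable p at `1/(B+1)` and avoids zero p values; the default
`B = 999` balances resolution against cost. Inside the permutation loop
the p values are computed by a vectorized normal-approximation
Mann–Whitney (identical to `wilcox.test(exact = FALSE, correct = TRUE)`,
asserted in the tests) or a vectorized Yates chi-squared — the same
statistic as the observed analysis, so observed and permuted p values are
exchangeable. A constant outcome column receives raw p 1 and simply rides
along. Subjects with a missing group label are dropped with a logged
count.

Two properties pin the implementation down: duplicating an outcome column
must not change any adjusted value (perfect correlation incurs no
penalty), and the empirical FWER under simulated global nulls — both
independent and strongly correlated — must stay at the nominal level
within Monte-Carlo tolerance. The test suite checks both, the latter with
1000 replicates of 10 outcomes on 30 subjects and `B = 500`.

## Cross-sectional regression

`regress_outcomes()` fits a *separate univariate model per outcome* at one
occasion: ordinary least squares for numeric outcomes (slopes are mean
differences when the covariate is binary, and the p value is then exactly
the equal-variance two-sample t-test's — a machine-precision identity in
the tests), logistic regression for dichotomized outcomes with estimates
reported as odds ratios.

**Firth's correction** (`firth_logistic()`) maximizes the
Jeffreys-penalized log-likelihood `l(β) + ½ log det I(β)` by Newton
iteration on the hat-modified score
`U*_j = Σ_i (y_i − π_i + h_i(½ − π_i)) x_ij`, with step-halving on the
penalized likelihood and convergence declared when the score max-norm
drops below 1e-8 (at most 50 iterations). Under complete separation the
unpenalized estimate diverges to infinity — `logistic_ml()` detects and
flags this — while the penalized estimate stays finite; for a single
binary covariate it coincides with the 0.5-per-cell corrected log odds
ratio, so the canonical 2×2 separation `(2,0;0,2)` must return
`log 25 ≈ 3.219`, which the acceptance suite checks to 1e-4. Confidence
intervals are Wald on the penalized estimates; profile-penalized-likelihood
intervals would be a defensible alternative (the source application does
not say which it used) and are noted as an extension.

**Restricted cubic splines** model nonlinear covariate-outcome shapes.
`rcs_basis()` builds the truncated-power restricted basis normalized by
`(t_k − t_1)²`; by construction the nonlinear columns vanish at and below
the first knot and every fitted function is exactly linear beyond both
boundary knots (the tests verify second differences below 1e-8 out
there). Knots default to the standard quantiles — 0.10/0.50/0.90 for
k = 3, 0.05/0.35/0.65/0.95 for k = 4, 0.05/0.275/0.50/0.725/0.95 for
k = 5 — and k = 3 is the default because per-occasion samples in this
kind of study are small. `fit_rcs_curve()` returns the fitted curve over a
grid with *pointwise* delta-method 95% bands (the simultaneous-band
alternative is out of scope) plus two joint Wald tests: overall
association (all spline terms) and nonlinearity (nonlinear terms only).

## Random-intercept mixed models

Over all evaluation times, `fit_random_intercept()` fits one of three
forms per outcome, always with a subject-level random intercept:
covariate only; covariate plus occasion as a categorical effect with
baseline as reference; covariate plus days-since-first as a numeric
effect. The occasion form is appropriate when visits are scheduled and a
separate level per visit is wanted; the days form assumes linearity in
time (on the logit scale for binary outcomes).

Numeric outcomes are fitted by REML, binary ones by maximum likelihood
with the Laplace approximation (`lme4`), reported as odds ratios. CIs and
p values are Wald with the plain normal approximation — no
degrees-of-freedom correction — because the reference application names
neither an estimation method nor a CI type; published estimates from such
models are therefore only reproducible to about two decimals, and that
caveat is inherited here. Parameter recovery is verified on synthetic
cohorts (100 replicates of 200 subjects with occasion effects
−0.5/−1.0/−1.5 and intercept SD 1): biases must stay within 3 Monte-Carlo
standard errors. Recovery is checked with the generator's
`round_and_clip = FALSE`, i.e. on the latent Gaussian scale — once values
are rounded to 0.1 and clipped to [0, 10], the stated effects are no
longer the truth of the *observed* scale (floor censoring attenuates
them), so a clipped-scale recovery test would measure the censoring, not
the estimator.

## Clustering and plots

Ordering of subjects and outcomes in lasagna plots and heat maps comes
from agglomerative hierarchical clustering with Euclidean distance and
complete linkage, whose merge heights are monotone. Missing cells are
mean-imputed per feature *only inside the distance computation* (count
recorded), because the plots legitimately display incomplete data; the
rendered cells keep their missingness and are drawn white. This choice
changes leaf orders relative to other missing-data policies and is
therefore stated prominently. Ties in the distance matrix are resolved by
`stats::hclust`'s lowest-index-first rule, making leaf orders
reproducible.

Spearman correlation matrices use pairwise-complete observations; a pair
with fewer than 3 complete cases is set to `NA` and flagged. The plot
family — boxplots (two facet transpositions), spaghetti plots with seeded
random subject subsets, lasagna plots, timeline bubble plots with three
x-axis choices (zero values draw no bubble), correlation heat maps,
dendrograms, clustered data heat maps, proportion bar plots — all return
ggplot objects, and `write_figure()` emits PNG plus EPS (or SVG/PDF)
without transparency so the vector output is faithful.

## The synthetic-data generator

`generate_em_like()` emulates the *structure* of a multi-symptom early
Lyme borreliosis cohort — it makes no attempt to reproduce any real
dataset's values. Defaults, chosen once: 225 subjects; occasions at days
0/14/180/365; 16 outcomes on a 0–10 scale at 0.1 resolution; latent
intercept 3; shared visit-level factor with loading 0.7 (driving positive
cross-outcome correlation); occasion effects 0/−0.5/−1/−1.5 (the
decreasing symptom trend); subject random-intercept SD 1; residual SD 1.5;
group prevalence 0.5 with no group effect unless requested; monotone
dropout with per-visit hazards 0/0.05/0.10/0.15 (missingness concentrated
at late follow-ups, subjects never return). Values are rounded and clipped
to mimic the VAS instrument; `round_and_clip = FALSE` exposes the latent
scale for recovery tests. The full ground truth (parameters, subject
effects, attendance matrix) is attached to the returned data, and
generation is bit-reproducible given a seed.

What the generator does *not* emulate: informative dropout (attendance is
independent of symptom levels), outcome-specific variances or loadings,
skewed zero-inflated VAS distributions beyond what clipping induces,
time-varying covariates, or measurement drift. Passing tests on these
fixtures therefore demonstrate correctness of the estimators under a
well-specified model, not robustness to those real-data features.

Two adversarial generators complete the module: `generate_global_null()`
(equicorrelated outcomes, exchangeable labels, no effect — the input for
FWER/FDR operating characteristics) and `generate_separable()` (a
covariate that perfectly predicts a binary outcome — the Firth stress
case).

## Problem sizes and numerical conventions

The heavier simulation checks run at deliberately chosen sizes: 1000
global-null replicates (k = 10, n = 30, B = 500) for the min-P FWER, 500
replicates at n = 200 with B = 2000 for bootstrap coverage, 100 replicates
of 200 subjects for mixed-model recovery, and an exhaustive grid of
p-vectors up to length 6 for the Holm/BH/BY brute-force identity. The
acceptance script uses 500/500/50 replicates for the same quantities.

Other conventions, collected in one place: missing markers are the empty
string and literal `NA`; probabilities outside [0, 1] are domain errors,
not warnings; all RNG-dependent functions take an explicit seed and leave
the global RNG state untouched (`withr::with_seed`); Wald intervals are
used throughout unless stated otherwise; output tables preserve the input
outcome order; CLI outputs carry a provenance header (command, seed,
package version).

## Known limitations

No k > 2 group comparisons or paired tests; no multivariable
cross-sectional models; no random slopes, nested random effects or GEE;
no wide-format input; no simultaneous confidence bands for spline curves;
Wald (not profile) intervals for Firth fits; mixed-model inference relies
on the normal approximation, which is optimistic for small numbers of
subjects.
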