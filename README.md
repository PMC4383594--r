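# longmed

Scriptable analysis of long-format longitudinal medical data with many
outcomes.

Clinical follow-up studies often record a dozen or more outcomes — for
example 0–10 visual-analog-scale symptom intensities — for every subject at
a handful of scheduled evaluation occasions. Analyzing such data well
requires tools that spreadsheets lack and that are scattered across
statistical packages: descriptive tables with honest confidence intervals,
two-group screening across all outcomes under multiplicity control,
per-outcome regression that survives small and separated samples, mixed
models for the repeated measurements, and trajectory graphics that scale
beyond a few subjects. longmed collects these behind a tidyverse-style API
(tibbles in, tibbles out, `ggplot2` figures, `tidy()`/`glance()` methods)
plus a small command-line interface, for biostatisticians and
epidemiologists who want the analyses of a longitudinal symptom study to be
reproducible from a script.

## What it computes

* **Data model** — long-format TSV/CSV with declared variable roles
  (subject ID, date, occasion, outcomes, covariates, binary grouping),
  validation of the structural invariants, days-since-first-evaluation
  offsets, strict-threshold dichotomization (`value > t`), data overviews.
* **Summaries** — per outcome × occasion: median/IQR (type-7 quartiles)
  with percentile-bootstrap 95% CI for the median (B = 2000), or
  counts/proportions with exact Clopper–Pearson intervals; missing counts
  always reported.
* **Two-group comparisons** — Mann–Whitney (numeric) or Yates-corrected
  proportion test (binary) per outcome, with Holm-adjusted p values,
  Westfall–Young step-down **min-P permutation** adjusted p values
  (subject-level label permutation preserving outcome correlation,
  `(1+count)/(B+1)` estimator), and Benjamini–Hochberg / Benjamini–Yekutieli
  Q values. The FWER of m independent tests at level α is
  `1 − (1 − α)^m`; at α = 0.05 it exceeds one half beyond 13 outcomes,
  which is why the adjustments exist.
* **Cross-sectional regression** — per-outcome univariate linear or
  logistic fits at one occasion; **Firth's penalized likelihood**
  (`l(β) + ½ log det I(β)`, Newton with hat-modified score) for separated
  or small binary data; **restricted cubic splines** (Harrell basis,
  quantile knots, k = 3–5) with pointwise 95% bands and joint Wald tests
  for association and nonlinearity.
* **Longitudinal regression** — random-intercept mixed models in three
  forms (covariate; covariate + occasion categorical with baseline
  reference; covariate + days numeric), REML for linear and Laplace for
  logistic outcomes, Wald intervals, odds-ratio reporting.
* **Clustering & plots** — Euclidean/complete-linkage hierarchical
  ordering, pairwise Spearman matrices, and the full plot family: boxplot
  grids, spaghetti plots with seeded subsets, lasagna plots, timeline
  bubble plots, correlation heat maps, dendrograms, clustered data heat
  maps, proportion bar plots; figures export to PNG + EPS.
* **Synthetic cohorts** — `generate_em_like()` draws EM-study-shaped
  datasets (correlated VAS outcomes, decreasing time trend, monotone
  dropout) with the full ground truth attached, plus global-null and
  complete-separation fixtures for operating-characteristic checks.

## Worked example

```r
library(longmed)

# a synthetic 120-subject cohort with a planted group effect
d <- generate_em_like(sim_config(n_subjects = 120, group_effect = 1), seed = 42)
data_overview(d)
#> Longitudinal data overview
#>   observations:     437
#>   unique subjects:  120
#>   occasions:        4
#>   evaluations/subject:  1x:3  2x:12  3x:10  4x:95
```

437 rows, not 480: monotone dropout removed late visits for 25 subjects.
Summaries of symptom presence (dichotomized at 0) at baseline:

```r
summarize_outcomes(d, binary = TRUE, threshold = 0) |>
  dplyr::filter(occasion == "0") |> head(3)
#>   outcome    occasion     n n_missing n_positive proportion ci_low ci_high
#> 1 symptom_01 0          120         0        115      0.958  0.905   0.986
#> 2 symptom_02 0          120         0        112      0.933  0.873   0.971
#> 3 symptom_03 0          120         0        118      0.983  0.941   0.998
```

Each row is an exact binomial interval around the observed proportion.
Screening all 16 symptoms for a baseline group difference, with the four
multiplicity columns:

```r
compare_groups(d, occasion = "0", adjust = TRUE, B = 999, seed = 42) |>
  dplyr::select(outcome, median_1, median_2, raw_p, holm_p, perm_p, q_bh, q_by) |>
  head(5)
#>   outcome    median_1 median_2    raw_p  holm_p perm_p    q_bh   q_by
#> 1 symptom_01      3.2      4.4 0.00395  0.0553   0.048 0.0211  0.0712
#> 2 symptom_02      3.4      3.6 0.0621   0.559    0.339 0.118   0.399
#> 3 symptom_03      3        4   0.0664   0.559    0.339 0.118   0.399
#> 4 symptom_04      3.3      3.8 0.106    0.739    0.455 0.159   0.539
#> 5 symptom_05      2.9      3.7 0.000552 0.00883  0.009 0.00883 0.0299
```

For symptom_01, Holm (0.055) just misses the 0.05 line while the
correlation-aware permutation adjustment (0.048) does not — the typical
gain from min-P on positively correlated outcomes. The time course of one
symptom across all visits, with a subject-level random intercept:

```r
fit_random_intercept(d, "symptom_01", covariate = "occasion", form = "covariate")
#> Random-intercept linear mixed model for `symptom_01` (covariate form)
#>   437 observations from 120 subjects; random-intercept SD 0.666
#>   term         estimate ci_low ci_high   p_value
#> 1 (Intercept)     3.56    3.25   3.87  2.52e-111
#> 2 occasion:14    -0.791  -1.20  -0.382 1.52e-  4
#> 3 occasion:180   -1.25   -1.67  -0.823 7.53e-  9
#> 4 occasion:365   -1.54   -1.98  -1.11  3.73e- 12
```

Each occasion coefficient is the estimated mean change from baseline;
intensity falls monotonically over follow-up, as generated.

Plots follow the same pattern: `plot_lasagna(d, "symptom_01")`,
`plot_spaghetti(d, "symptom_01", subset_size = 10, seed = 1)`,
`autoplot(spearman_matrix(d, occasion = "0"))`, and so on;
`write_figure()` writes any of them as PNG plus EPS.

A command-line interface mirrors the analysis tabs of an interactive
session (`echo`, `overview`, `summary`, `compare`, `cluster`, `plot`,
`regress`, `mixed`, `simulate`):

```sh
Rscript inst/cli/longmed compare --input data.tsv \
  --id subject --date date --occasion-col occasion \
  --outcomes symptom_01,symptom_02 --grouping group \
  --occasion 0 --adjust --permutations 999 --seed 1 --out-dir results/
```

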