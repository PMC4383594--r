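#' Configuration for the synthetic longitudinal symptom generator
#'
#' Describes a cohort patterned on a multi-symptom erythema migrans study:
#' subjects evaluated on a few scheduled occasions, each reporting many
#' 0-10 visual-analog-scale symptom intensities that are positively
#' correlated across symptoms, decrease over follow-up, and thin out at
#' later visits through monotone dropout.
#'
#' The outcome for subject i, occasion t, outcome j is generated on a
#' latent continuous scale as
#' `intercept_j + b_i + loading * f_it + occasion_effect_t +
#'  group_effect * group_i + e_ijt`,
#' with `b_i ~ N(0, random_intercept_sd^2)` (shared across occasions and
#' outcomes), `f_it ~ N(0, 1)` a visit-level latent factor shared across
#' outcomes (driving their positive correlation) and
#' `e_ijt ~ N(0, noise_sd^2)`. With `round_and_clip = TRUE` the value is
#' then rounded to `resolution` and clipped to `outcome_range`, mimicking
#' the visual-analog-scale instrument.
#'
#' @param n_subjects Number of subjects.
#' @param occasion_days Strictly increasing evaluation days starting at 0.
#' @param n_outcomes Number of outcome columns.
#' @param outcome_range Bounds of the reported scale.
#' @param resolution Rounding resolution of the reported scale.
#' @param intercepts Latent intercept per outcome (recycled).
#' @param factor_loading Loading of the shared visit-level factor, in
#'   `[0, 1)` as a correlation driver.
#' @param occasion_effects Fixed effect per occasion; the first entry must
#'   be 0 (baseline reference).
#' @param group_effect Fixed difference added to the second group.
#' @param group_prob Probability of membership in the second group.
#' @param random_intercept_sd Between-subject SD.
#' @param noise_sd Residual SD.
#' @param dropout_probs Per-occasion probability of dropping out at that
#'   visit (first entry must be 0); with `monotone_dropout` a subject who
#'   misses a visit never returns.
#' @param monotone_dropout Enforce non-returning dropout.
#' @param round_and_clip Report rounded/clipped values (`TRUE`) or the
#'   latent Gaussian value (`FALSE`, useful for parameter-recovery checks).
#' @param baseline_date Calendar date of every subject's first evaluation.
#' @param day_jitter_sd SD (days) of jitter added to follow-up visit days.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 225,
                       occasion_days = c(0, 14, 180, 365),
                       n_outcomes = 16,
                       outcome_range = c(0, 10),
                       resolution = 0.1,
                       intercepts = 3,
                       factor_loading = 0.7,
                       occasion_effects = c(0, -0.5, -1, -1.5),
                       group_effect = 0,
                       group_prob = 0.5,
                       random_intercept_sd = 1,
                       noise_sd = 1.5,
                       dropout_probs = c(0, 0.05, 0.10, 0.15),
                       monotone_dropout = TRUE,
                       round_and_clip = TRUE,
                       baseline_date = as.Date("2010-01-01"),
                       day_jitter_sd = 0) {
  if (occasion_days[1] != 0 || is.unsorted(occasion_days, strictly = TRUE)) {
    abort("`occasion_days` must be strictly increasing and start at 0.",
          class = "longmed_config_error")
  }
  k <- length(occasion_days)
  if (length(occasion_effects) != k || occasion_effects[1] != 0) {
    abort("`occasion_effects` must match `occasion_days` with first entry 0.",
          class = "longmed_config_error")
  }
  if (length(dropout_probs) != k || dropout_probs[1] != 0) {
    abort("`dropout_probs` must match `occasion_days` with first entry 0.",
          class = "longmed_config_error")
  }
  if (factor_loading < 0 || factor_loading >= 1) {
    abort("`factor_loading` must be in [0, 1).", class = "longmed_config_error")
  }
  if (noise_sd <= 0 || random_intercept_sd < 0) {
    abort("`noise_sd` must be positive and `random_intercept_sd` non-negative.",
          class = "longmed_config_error")
  }
  structure(
    list(n_subjects = n_subjects, occasion_days = occasion_days,
         n_outcomes = n_outcomes, outcome_range = outcome_range,
         resolution = resolution, intercepts = intercepts,
         factor_loading = factor_loading, occasion_effects = occasion_effects,
         group_effect = group_effect, group_prob = group_prob,
         random_intercept_sd = random_intercept_sd, noise_sd = noise_sd,
         dropout_probs = dropout_probs, monotone_dropout = monotone_dropout,
         round_and_clip = round_and_clip,
         baseline_date = as.Date(baseline_date),
         day_jitter_sd = day_jitter_sd),
    class = "sim_config")
}

#' Generate a synthetic long-format longitudinal dataset
#'
#' Draws a dataset under [sim_config()] and returns it as a validated
#' `longitudinal_df` with columns `subject`, `date`, `occasion` (day
#' label), outcomes `symptom_01 ...`, a binary `group` covariate, and the
#' full ground-truth record (true parameters, subject effects, dropout) as
#' attribute `ground_truth`. Bit-reproducible given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `longitudinal_df`; `attr(x, "ground_truth")` holds the truth.
#' @export
generate_em_like <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() {
    n <- config$n_subjects
    k <- length(config$occasion_days)
    q <- config$n_outcomes
    mu <- rep_len(config$intercepts, q)
    b <- rnorm(n, 0, config$random_intercept_sd)
    group <- as.numeric(rbinom(n, 1, config$group_prob))

    # visit attendance with (optionally monotone) dropout
    present <- matrix(TRUE, n, k)
    for (t in seq_len(k)[-1]) {
      drop_now <- runif(n) < config$dropout_probs[t]
      present[, t] <- if (config$monotone_dropout)
        present[, t - 1] & !drop_now else !drop_now
    }

    f <- matrix(rnorm(n * k), n, k)
    jit <- matrix(0, n, k)
    if (config$day_jitter_sd > 0 && k > 1) {
      jit[, -1] <- round(matrix(rnorm(n * (k - 1), 0, config$day_jitter_sd),
                                n, k - 1))
    }

    rows <- vector("list", k)
    for (t in seq_len(k)) {
      idx <- which(present[, t])
      if (!length(idx)) next
      lat <- outer(b[idx] + config$factor_loading * f[idx, t] +
                     config$occasion_effects[t] +
                     config$group_effect * group[idx],
                   mu, `+`) +
        matrix(rnorm(length(idx) * q, 0, config$noise_sd), length(idx), q)
      if (config$round_and_clip) {
        lat <- pmin(pmax(round(lat / config$resolution) * config$resolution,
                         config$outcome_range[1]), config$outcome_range[2])
      }
      colnames(lat) <- sprintf("symptom_%02d", seq_len(q))
      rows[[t]] <- cbind(
        tibble(subject = sprintf("S%03d", idx),
               date = config$baseline_date + config$occasion_days[t] +
                 jit[idx, t],
               occasion = as.character(config$occasion_days[t]),
               group = group[idx]),
        as_tibble(lat))
    }
    out <- bind_rows(rows)
    out <- arrange(out, .data$subject,
                   match(.data$occasion, as.character(config$occasion_days)))
    truth <- list(config = config, subject_effects = b, group = group,
                  present = present, seed = seed)
    list(data = out, truth = truth)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  both_groups <- length(unique(res$data$group)) == 2
  roles <- var_roles(
    id = "subject", date = "date", occasion = "occasion",
    outcomes = sprintf("symptom_%02d", seq_len(config$n_outcomes)),
    covariates = "group",
    grouping = if (both_groups) "group",
    occasion_levels = as.character(config$occasion_days))
  d <- validate_roles(res$data, roles)
  attr(d, "ground_truth") <- res$truth
  d
}

#' Generate a two-group dataset under the global null
#'
#' One evaluation per subject, `k` equicorrelated outcomes
#' (`y = sqrt(correlation) * f + sqrt(1 - correlation) * e` with a shared
#' factor `f`), and exchangeable group labels carrying no effect. Used for
#' the operating-characteristic checks of the multiplicity adjustments
#' (familywise error rate, false discovery rate).
#'
#' @param n Subjects per group (at least 4).
#' @param k Number of outcomes.
#' @param correlation Equicorrelation of the outcomes, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with `subject`, `group` (logical: second group) and
#'   outcome columns `y01 ...`.
#' @export
generate_global_null <- function(n = 15, k = 10, correlation = 0, seed = NULL) {
  stopifnot(n >= 4, k >= 1, correlation >= 0, correlation < 1)
  run <- function() {
    N <- 2 * n
    f <- rnorm(N)
    Y <- sqrt(correlation) * matrix(f, N, k) +
      sqrt(1 - correlation) * matrix(rnorm(N * k), N, k)
    colnames(Y) <- sprintf("y%02d", seq_len(k))
    cbind(tibble(subject = sprintf("S%03d", seq_len(N)),
                 group = rep(c(FALSE, TRUE), each = n)),
          as_tibble(Y))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a completely separated binary-outcome dataset
#'
#' A covariate that perfectly predicts the binary outcome, the canonical
#' failure case of unpenalized logistic regression (the estimate diverges
#' to infinity) and the motivating case for Firth's correction.
#'
#' @param n Number of observations (at least 4, even).
#' @param seed Optional integer seed (adds no randomness in the canonical
#'   construction; kept for interface symmetry).
#' @return A tibble with columns `x` (0/1 covariate) and `y` (0/1 outcome),
#'   with `y == x`.
#' @export
generate_separable <- function(n = 4, seed = NULL) {
  stopifnot(n >= 4, n %% 2 == 0)
  tibble(x = rep(c(0, 1), each = n / 2),
         y = rep(c(0L, 1L), each = n / 2))
}
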