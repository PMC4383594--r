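#' Random-intercept mixed model over all evaluation times
#'
#' Fits one of three model forms for a single outcome, with a
#' subject-specific random intercept capturing the repeated measurements:
#'
#' * `"covariate"`: outcome ~ covariate + (1 | subject)
#' * `"covariate_occasion"`: outcome ~ covariate + occasion + (1 | subject),
#'   occasion entered as a categorical fixed effect with the baseline
#'   occasion as reference
#' * `"covariate_days"`: outcome ~ covariate + days-since-first + (1 | subject),
#'   time entered as a numeric fixed effect
#'
#' The covariate may be omitted (`covariate = NULL`) to model the time
#' course alone, or may itself be the occasion/days column. Numeric
#' outcomes use restricted maximum likelihood (REML) via [lme4::lmer()];
#' binary outcomes use maximum likelihood with the Laplace approximation
#' via [lme4::glmer()] and are reported as odds ratios. Confidence
#' intervals and p values are Wald with the normal approximation (no
#' degrees-of-freedom correction).
#'
#' @param data A `longitudinal_df`.
#' @param outcome Name of the outcome column.
#' @param covariate Optional name of a covariate column (fixed effect).
#' @param form One of `"covariate"`, `"covariate_occasion"`,
#'   `"covariate_days"`.
#' @param family `"auto"` (logistic iff the modeled outcome is 0/1),
#'   `"linear"` or `"logistic"`.
#' @param binary Dichotomize the outcome at `threshold` before fitting.
#' @param threshold Dichotomization threshold (default: roles' threshold,
#'   else 0).
#' @param level Confidence level.
#' @return An object of class `mixed_fit`: list with `terms` (tibble of
#'   fixed effects on the slope or odds-ratio scale),
#'   `random_intercept_sd`, `model_form`, `family`, `outcome`, `n_obs`,
#'   `n_subjects` and the underlying lme4 `fit`.
#' @export
fit_random_intercept <- function(data, outcome, covariate = NULL,
                                 form = c("covariate", "covariate_occasion",
                                          "covariate_days"),
                                 family = c("auto", "linear", "logistic"),
                                 binary = FALSE, threshold = NULL,
                                 level = 0.95) {
  form <- arg_match(form)
  family <- arg_match(family)
  roles <- roles_of(data)
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome `", outcome, "` not in data."),
          class = "longmed_role_error")
  }
  d <- as_tibble(add_days_since_first(data, col = ".days"))
  d$.y <- d[[outcome]]
  if (binary) {
    if (is.null(threshold)) {
      threshold <- if (!is.null(roles$threshold)) roles$threshold else 0
    }
    d$.y <- dichotomize(d$.y, threshold)
  }
  d$.id <- as.character(d[[roles$id]])
  d$.occ <- d[[roles$occasion]]

  rhs <- character()
  if (!is.null(covariate)) {
    if (!covariate %in% names(d)) {
      abort(paste0("Covariate `", covariate, "` not in data."),
            class = "longmed_role_error")
    }
    cov_term <- if (identical(covariate, roles$occasion)) ".occ" else
      paste0("`", covariate, "`")
    rhs <- c(rhs, cov_term)
  }
  if (form == "covariate_occasion" && !identical(covariate, roles$occasion)) {
    rhs <- c(rhs, ".occ")
  }
  if (form == "covariate_days") rhs <- c(rhs, ".days")
  if (!length(rhs)) {
    abort("Model has no fixed effects; supply a covariate or a time form.",
          class = "longmed_role_error")
  }
  fml <- as.formula(paste(".y ~", paste(rhs, collapse = " + "), "+ (1 | .id)"))

  keep <- !is.na(d$.y)
  if (!is.null(covariate)) keep <- keep & !is.na(d[[covariate]])
  d <- d[keep, , drop = FALSE]
  if (var_zero(d$.y)) {
    abort("Outcome has zero variance after missing removal.",
          class = "longmed_degenerate_error")
  }
  multi <- table(d$.id)
  if (sum(multi >= 2) < 2) {
    abort("Need at least 2 subjects with at least 2 evaluations.",
          class = "longmed_validation_error")
  }
  if (family == "auto") {
    family <- if (all(d$.y %in% c(0, 1))) "logistic" else "linear"
  }

  fit <- tryCatch({
    if (family == "linear") {
      lme4::lmer(fml, data = d, REML = TRUE)
    } else {
      if (!all(d$.y %in% c(0, 1))) {
        abort("Logistic family requires a 0/1 outcome (use `binary = TRUE`).",
              class = "longmed_type_error")
      }
      lme4::glmer(fml, data = d, family = binomial(), nAGQ = 1)
    }
  }, error = function(e) {
    abort(paste0("Mixed model failed to converge: ", conditionMessage(e)),
          class = "longmed_convergence_error")
  })

  s <- as.data.frame(coef(summary(fit)))
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  z <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  lab <- rownames(s)
  lab <- sub("^\\.occ", "occasion:", lab)
  lab <- sub("^\\.days$", "days_since_first", lab)
  lab <- gsub("`", "", lab)
  or_scale <- family == "logistic"
  terms <- tibble(
    term = lab,
    estimate = if (or_scale) exp(est) else est,
    ci_low = if (or_scale) exp(est - z * se) else est - z * se,
    ci_high = if (or_scale) exp(est + z * se) else est + z * se,
    p_value = p)

  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == ".id" & vc$var1 == "(Intercept)"][1]

  structure(
    list(terms = terms, random_intercept_sd = ri_sd, model_form = form,
         family = family, outcome = outcome,
         effect_scale = if (or_scale) "odds-ratio" else "slope",
         n_obs = nrow(d), n_subjects = n_distinct(d$.id), fit = fit),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Random-intercept %s mixed model for `%s` (%s form)\n",
              x$family, x$outcome, x$model_form))
  cat(sprintf("  %d observations from %d subjects; random-intercept SD %.3f\n",
              x$n_obs, x$n_subjects, x$random_intercept_sd))
  print(x$terms)
  invisible(x)
}

#' @rdname fit_random_intercept
#' @param x A `mixed_fit`.
#' @param ... Unused.
#' @export
tidy.mixed_fit <- function(x, ...) {
  mutate(x$terms, outcome = x$outcome, .before = 1)
}

#' @rdname fit_random_intercept
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble(outcome = x$outcome, family = x$family, model_form = x$model_form,
         effect_scale = x$effect_scale,
         random_intercept_sd = x$random_intercept_sd,
         n_obs = x$n_obs, n_subjects = x$n_subjects)
}

#' Fit the same random-intercept model to every outcome
#'
#' @inheritParams fit_random_intercept
#' @param outcomes Outcome columns (default: all declared outcomes).
#' @return A list of `mixed_fit` objects, one per outcome; failures are
#'   recorded as `NULL` with a warning.
#' @export
mixed_outcomes <- function(data, covariate = NULL,
                           form = c("covariate", "covariate_occasion",
                                    "covariate_days"),
                           family = c("auto", "linear", "logistic"),
                           binary = FALSE, threshold = NULL,
                           outcomes = NULL, level = 0.95) {
  roles <- roles_of(data)
  outcomes <- outcomes %||% roles$outcomes
  fits <- purrr::map(outcomes, function(o) {
    tryCatch(
      fit_random_intercept(data, o, covariate = covariate, form = form,
                           family = family, binary = binary,
                           threshold = threshold, level = level),
      error = function(e) {
        warn(paste0("Outcome `", o, "`: ", conditionMessage(e)))
        NULL
      })
  })
  setNames(fits, outcomes)
}

#' Combine mixed-model fits into one per-outcome table
#'
#' @param results A list of `mixed_fit` objects (as from
#'   [mixed_outcomes()]); `NULL` entries are skipped.
#' @return A tibble of class `mixed_tbl` with one row per outcome and fixed
#'   term plus the per-model random-intercept SD.
#' @export
tidy_mixed_table <- function(results) {
  results <- purrr::compact(results)
  if (!length(results)) {
    return(structure(
      tibble(outcome = character(), term = character(), estimate = numeric(),
             ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
             random_intercept_sd = numeric(), family = character(),
             model_form = character()),
      class = c("mixed_tbl", class(tibble()))))
  }
  fams <- unique(purrr::map_chr(results, "family"))
  if (length(fams) > 1) {
    abort("All results must share one family (linear or logistic).",
          class = "longmed_validation_error")
  }
  out <- purrr::map_dfr(results, function(r) {
    mutate(tidy(r), random_intercept_sd = r$random_intercept_sd,
           family = r$family, model_form = r$model_form)
  })
  class(out) <- c("mixed_tbl", class(out))
  out
}

#' Forest plot of mixed-model fixed effects across outcomes
#'
#' @param object A `mixed_tbl` from [tidy_mixed_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixed_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$term != "(Intercept)", , drop = FALSE]
  df$outcome <- factor(df$outcome, levels = rev(unique(df$outcome)))
  or_scale <- all(df$family == "logistic")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = if (or_scale) 1 else 0,
                        linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = if (or_scale) "Odds ratio (95% CI)" else
      "Slope (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (or_scale) p <- p + ggplot2::scale_x_log10()
  p
}
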