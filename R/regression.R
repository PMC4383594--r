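#' Univariate linear regression for one outcome
#'
#' Least-squares fit of one outcome on one covariate. Categorical
#' covariates are expanded with the first level as reference. Confidence
#' intervals are Wald t-based. With a binary covariate the slope is the
#' estimated mean difference and its p value is identical to the
#' equal-variance two-sample t-test.
#'
#' @param y Numeric outcome vector.
#' @param x Covariate vector (numeric, factor or character).
#' @param level Confidence level.
#' @return An object of class `reg_fit` with a [tidy()] method; `terms` is
#'   a tibble of `(term, estimate, ci_low, ci_high, p_value)` including the
#'   intercept.
#' @export
fit_linear <- function(y, x, level = 0.95) {
  dat <- prep_uni(y, x)
  if (var_zero(as.numeric(as.factor(dat$x)))) {
    abort("Covariate is constant; the slope is not identifiable.",
          class = "longmed_singularity_error")
  }
  fit <- lm(y ~ x, data = dat)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = level)
  terms <- tibble(term = clean_terms(rownames(s)),
                  estimate = unname(s[, 1]),
                  std_error = unname(s[, 2]),
                  ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                  p_value = unname(s[, 4]))
  new_reg_fit(terms, family = "linear", effect_scale = "slope",
              penalized = FALSE, fit = fit, n = nrow(dat))
}

#' Univariate logistic regression for one outcome
#'
#' Logistic fit of a binary outcome on one covariate, reported as odds
#' ratios with Wald 95% confidence intervals. With `firth = TRUE` the
#' Jeffreys-penalized fit of [firth_logistic()] is used, which stays finite
#' under complete separation; without it a separated fit is flagged as
#' diverged.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Covariate vector.
#' @param firth Use Firth's penalized likelihood.
#' @param level Confidence level.
#' @return An object of class `reg_fit`; estimates in `terms` are on the
#'   odds-ratio scale (intercept: baseline odds), and `diverged` records
#'   whether an unpenalized fit hit the separation failure mode.
#' @export
fit_logistic <- function(y, x, firth = FALSE, level = 0.95) {
  dat <- prep_uni(y, x)
  if (!all(dat$y %in% c(0, 1))) {
    abort("`y` must be binary 0/1 for the logistic family.",
          class = "longmed_type_error")
  }
  if (var_zero(dat$y)) {
    abort("Outcome is constant; logistic model is degenerate.",
          class = "longmed_degenerate_error")
  }
  if (var_zero(as.numeric(as.factor(dat$x)))) {
    abort("Covariate is constant; the slope is not identifiable.",
          class = "longmed_singularity_error")
  }
  X <- model.matrix(~x, data = dat)
  z <- qnorm(1 - (1 - level) / 2)
  if (firth) {
    ff <- firth_logistic(X, dat$y, level = level)
    terms <- tibble(term = clean_terms(names(ff$coefficients)),
                    estimate = exp(unname(ff$coefficients)),
                    ci_low = exp(unname(ff$ci_low)),
                    ci_high = exp(unname(ff$ci_high)),
                    p_value = unname(ff$p_value))
    return(new_reg_fit(terms, family = "logistic", effect_scale = "odds-ratio",
                       penalized = TRUE, fit = ff, n = nrow(dat),
                       diverged = FALSE))
  }
  ml <- logistic_ml(X, dat$y)
  fit <- glm(y ~ x, data = dat, family = binomial())
  s <- summary(fit)$coefficients
  terms <- tibble(term = clean_terms(rownames(s)),
                  estimate = exp(unname(s[, 1])),
                  ci_low = exp(unname(s[, 1] - z * s[, 2])),
                  ci_high = exp(unname(s[, 1] + z * s[, 2])),
                  p_value = unname(s[, 4]))
  new_reg_fit(terms, family = "logistic", effect_scale = "odds-ratio",
              penalized = FALSE, fit = fit, n = nrow(dat),
              diverged = ml$diverged)
}

prep_uni <- function(y, x) {
  if (is.character(x)) x <- factor(x)
  keep <- !is.na(y) & !is.na(x)
  dat <- data.frame(y = y[keep], x = x[keep])
  if (is.factor(dat$x)) dat$x <- droplevels(dat$x)
  p <- if (is.factor(dat$x)) nlevels(dat$x) else 2
  if (nrow(dat) < p + 2) {
    abort("Too few complete cases for the model.",
          class = "longmed_validation_error")
  }
  dat
}

clean_terms <- function(nms) {
  out <- sub("^x", "", nms)
  out[out == ""] <- "covariate"
  out[nms == "(Intercept)"] <- "(Intercept)"
  out
}

new_reg_fit <- function(terms, family, effect_scale, penalized, fit, n,
                        diverged = FALSE) {
  structure(list(terms = terms, family = family, effect_scale = effect_scale,
                 penalized = penalized, fit = fit, n = n, diverged = diverged),
            class = "reg_fit")
}

#' @export
print.reg_fit <- function(x, ...) {
  fam <- paste0(toupper(substring(x$family, 1, 1)), substring(x$family, 2))
  cat(sprintf("%s regression (%s%s), n = %d%s\n",
              fam, x$effect_scale,
              if (x$penalized) ", Firth-penalized" else "", x$n,
              if (isTRUE(x$diverged)) " [DIVERGED: separation]" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname fit_linear
#' @param x A `reg_fit`.
#' @param ... Unused.
#' @export
tidy.reg_fit <- function(x, ...) x$terms

#' @rdname fit_linear
#' @export
glance.reg_fit <- function(x, ...) {
  tibble(family = x$family, effect_scale = x$effect_scale,
         penalized = x$penalized, n = x$n, diverged = isTRUE(x$diverged))
}

#' Per-outcome univariate regression at one evaluation occasion
#'
#' Fits a separate model for each declared outcome against one covariate at
#' one occasion: linear regression for numeric outcomes, logistic
#' regression (optionally Firth-penalized) when `binary = TRUE` after
#' dichotomization at the roles' threshold.
#'
#' @param data A `longitudinal_df`.
#' @param covariate Name of the covariate column.
#' @param occasion Occasion level to restrict to.
#' @param binary Model presence/absence instead of intensity.
#' @param threshold Dichotomization threshold for binary mode.
#' @param firth Use Firth's correction (logistic family only).
#' @param level Confidence level.
#' @return A tibble of class `regression_tbl`, one row per outcome and
#'   model term, with columns `outcome, term, estimate, ci_low, ci_high,
#'   p_value, family, effect_scale, penalized, n, note`.
#' @export
regress_outcomes <- function(data, covariate, occasion, binary = FALSE,
                             threshold = NULL, firth = FALSE, level = 0.95) {
  roles <- roles_of(data)
  d <- as_tibble(at_occasion(data, occasion))
  if (!covariate %in% names(d)) {
    abort(paste0("Covariate `", covariate, "` not in data."),
          class = "longmed_role_error")
  }
  if (binary && is.null(threshold)) {
    threshold <- if (!is.null(roles$threshold)) roles$threshold else 0
  }
  x <- d[[covariate]]
  out <- purrr::map_dfr(roles$outcomes, function(o) {
    y <- d[[o]]
    if (binary) y <- dichotomize(y, threshold)
    res <- tryCatch({
      f <- if (binary) fit_logistic(y, x, firth = firth, level = level)
      else fit_linear(y, x, level = level)
      mutate(f$terms, outcome = o, family = f$family,
             effect_scale = f$effect_scale, penalized = f$penalized,
             n = f$n,
             note = if (isTRUE(f$diverged)) "separation: estimate diverged" else "")
    }, error = function(e) {
      tibble(term = NA_character_, estimate = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
             outcome = o, family = if (binary) "logistic" else "linear",
             effect_scale = if (binary) "odds-ratio" else "slope",
             penalized = firth, n = NA_integer_, note = conditionMessage(e))
    })
    select(res, "outcome", dplyr::everything())
  })
  class(out) <- c("regression_tbl", class(out))
  out
}

#' Forest-style plot of per-outcome regression estimates
#'
#' Shows the covariate effect (slope or odds ratio) for every outcome with
#' its confidence interval; intercept rows are omitted.
#'
#' @param object A `regression_tbl` from [regress_outcomes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regression_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$term) & df$term != "(Intercept)", , drop = FALSE]
  df$outcome <- factor(df$outcome, levels = rev(unique(df$outcome)))
  or_scale <- all(df$effect_scale == "odds-ratio")
  ref <- if (or_scale) 1 else 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (or_scale) "Odds ratio (95% CI)" else
      "Slope / mean difference (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (or_scale) p <- p + ggplot2::scale_x_log10()
  p
}
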