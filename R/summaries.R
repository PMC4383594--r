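#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics (the type-7
#' rule, R's default). Missing values are dropped.
#'
#' @param values Numeric vector.
#' @return One-row tibble with `n`, `n_missing`, `median`, `q1`, `q3`
#'   (all-`NA` summary row when no non-missing value remains).
#' @export
median_iqr <- function(values) {
  stopifnot(is.numeric(values))
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (!length(v)) {
    return(tibble(n = 0L, n_missing = n_missing,
                  median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  tibble(n = length(v), n_missing = n_missing,
         median = q[2], q1 = q[1], q3 = q[3])
}

#' Percentile-bootstrap confidence interval for the median
#'
#' Resamples the data with replacement `B` times and takes the
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the bootstrap
#' medians. Deterministic given `seed`.
#'
#' @param values Numeric vector (missing values dropped).
#' @param B Number of bootstrap iterations (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Named numeric vector `c(ci_low, ci_high)`. With fewer than two
#'   non-missing values the interval degenerates to the single value.
#' @export
bootstrap_median_ci <- function(values, B = 2000, level = 0.95, seed = NULL) {
  stopifnot(is.numeric(values), B >= 1, level > 0, level < 1)
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) return(c(ci_low = NA_real_, ci_high = NA_real_))
  if (n == 1) return(c(ci_low = v, ci_high = v))
  run <- function() {
    idx <- sample.int(n, n * B, replace = TRUE)
    meds <- apply(matrix(v[idx], nrow = n, ncol = B), 2, median)
    unname(quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  }
  ci <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile inversion of the binomial tail probabilities; the lower
#' endpoint is 0 when `x = 0` and the upper endpoint 1 when `x = n`.
#'
#' @param x Success count.
#' @param n Trial count.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)` on the proportion scale.
#' @export
#' @examples
#' clopper_pearson_ci(152, 225)  # rounds to 61% and 74%
clopper_pearson_ci <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n >= 1)
  if (x < 0 || x > n) {
    abort("`x` must lie in [0, n].", class = "longmed_domain_error")
  }
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(ci_low = low, ci_high = high)
}

#' Per-occasion descriptive statistics for all outcomes
#'
#' One row per outcome and evaluation occasion. In numeric mode each row
#' carries the median, quartiles and a percentile-bootstrap CI for the
#' median; in binary mode the outcomes are dichotomized at the roles'
#' threshold (or `threshold`) and each row carries the positive count, the
#' proportion and its exact binomial CI. Missing-value counts are always
#' reported.
#'
#' @param data A `longitudinal_df`.
#' @param binary Summarize presence/absence instead of intensity.
#' @param threshold Dichotomization threshold for binary mode; defaults to
#'   the threshold declared in the roles, else 0.
#' @param B,level,seed Bootstrap settings passed to
#'   [bootstrap_median_ci()] (numeric mode only).
#' @return A tibble of class `summary_tbl`.
#' @export
summarize_outcomes <- function(data, binary = FALSE, threshold = NULL,
                               B = 2000, level = 0.95, seed = NULL) {
  roles <- roles_of(data)
  d <- as_tibble(data)
  occ <- d[[roles$occasion]]
  if (binary && is.null(threshold)) {
    threshold <- if (!is.null(roles$threshold)) roles$threshold else 0
  }

  build <- function() {
    purrr::map_dfr(roles$outcomes, function(out) {
      purrr::map_dfr(levels(occ), function(lev) {
        v <- d[[out]][occ == lev]
        if (binary) {
          b <- dichotomize(v, threshold)
          n_missing <- sum(is.na(b))
          bb <- b[!is.na(b)]
          n <- length(bb)
          x <- sum(bb)
          ci <- if (n >= 1) clopper_pearson_ci(x, n, level) else
            c(ci_low = NA_real_, ci_high = NA_real_)
          tibble(outcome = out, occasion = lev, n = n, n_missing = n_missing,
                 n_positive = x,
                 proportion = if (n >= 1) x / n else NA_real_,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]))
        } else {
          mi <- median_iqr(v)
          ci <- bootstrap_median_ci(v, B = B, level = level, seed = NULL)
          tibble(outcome = out, occasion = lev, n = mi$n,
                 n_missing = mi$n_missing, median = mi$median,
                 q1 = mi$q1, q3 = mi$q3,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]))
        }
      })
    })
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  attr(out, "mode") <- if (binary) "binary" else "numeric"
  attr(out, "threshold") <- if (binary) threshold else NULL
  class(out) <- c("summary_tbl", class(out))
  out
}

#' Dot-and-error-bar plot of a summary table
#'
#' Point estimates (medians or proportions) with their confidence
#' intervals, one panel per evaluation occasion.
#'
#' @param object A `summary_tbl` from [summarize_outcomes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.summary_tbl <- function(object, ...) {
  mode <- attr(object, "mode", exact = TRUE)
  est <- if (identical(mode, "binary")) "proportion" else "median"
  df <- as_tibble(object)
  df$outcome <- factor(df$outcome, levels = rev(unique(df$outcome)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[est]], y = .data$outcome)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~occasion) +
    ggplot2::labs(x = if (identical(mode, "binary"))
      "Proportion with positive outcome (95% CI)" else "Median (95% CI)",
      y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.summary_tbl
#' @export
plot_summary <- autoplot.summary_tbl

#' Familywise error rate of independent tests
#'
#' Probability of at least one false positive when `m` independent true-null
#' hypotheses are each tested at level `alpha`: `1 - (1 - alpha)^m`. At
#' `alpha = 0.05` this first exceeds 0.50 at `m = 14`.
#'
#' @param m Number of tests (vectorized).
#' @param alpha Per-test significance level.
#' @return Numeric vector of FWER values.
#' @export
fwer_independent <- function(m, alpha = 0.05) {
  stopifnot(all(m >= 0), alpha >= 0, alpha <= 1)
  1 - (1 - alpha)^m
}
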