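#' Mann-Whitney (Wilcoxon rank-sum) two-group test
#'
#' Two-sided test for a location shift between two independent samples.
#' Exact enumeration of the rank distribution is used for small tie-free
#' samples (fewer than 9 per group); otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @return One-row tibble with `statistic` (the U statistic for `x`),
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort("Both groups need at least one non-missing value.",
          class = "longmed_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) < 9 && length(y) < 9
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (use_exact) "exact" else "normal approximation")
}

#' Two-sample test for equality of proportions with continuity correction
#'
#' Chi-squared test on a 2x2 table with Yates continuity correction (1 df).
#'
#' @param table A 2x2 matrix of counts: rows are groups, columns outcome
#'   levels.
#' @return One-row tibble with `statistic`, `p_value`, `flagged` (TRUE when
#'   a zero margin made the comparison impossible).
#' @export
prop_test_cc <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  pt <- suppressWarnings(prop.test(table, correct = TRUE))
  tibble(statistic = unname(pt$statistic), p_value = pt$p.value,
         flagged = FALSE)
}

#' Holm-Bonferroni step-down adjusted p values
#'
#' @param p Vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in the original order.
#' @export
holm_adjust <- function(p) {
  check_probs(p)
  p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg Q values
#'
#' The minimum false discovery rate at which each test may be called
#' significant, under independence or positive dependence.
#'
#' @param p Vector of raw p values in `[0, 1]`.
#' @return Q values in the original order.
#' @export
bh_qvalues <- function(p) {
  check_probs(p)
  p.adjust(p, method = "BH")
}

#' Benjamini-Hochberg-Yekutieli Q values
#'
#' As [bh_qvalues()] but valid under arbitrary dependence (p values are
#' first inflated by `sum(1/(1:m))`); always at least as large as BH.
#'
#' @param p Vector of raw p values in `[0, 1]`.
#' @return Q values in the original order.
#' @export
by_qvalues <- function(p) {
  check_probs(p)
  p.adjust(p, method = "BY")
}

check_probs <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must be numeric in [0, 1].", class = "longmed_domain_error")
  }
  invisible(p)
}

#' Compare two groups of subjects on every outcome at one occasion
#'
#' Restricts the data to one evaluation occasion, drops rows with a missing
#' group label (with a message), and tests each outcome for a between-group
#' difference: Mann-Whitney for numeric outcomes, proportion test with
#' continuity correction for dichotomized outcomes. With `adjust = TRUE`
#' four multiplicity columns are appended: Holm-adjusted p, step-down min-P
#' permutation-adjusted p, and BH / BY Q values.
#'
#' @param data A `longitudinal_df` with a declared grouping role (or pass
#'   `grouping`).
#' @param occasion Occasion level at which to compare.
#' @param grouping Optional grouping column name overriding the roles.
#' @param binary Compare presence/absence (dichotomized at `threshold`)
#'   instead of intensity.
#' @param threshold Dichotomization threshold (default: roles' threshold,
#'   else 0).
#' @param adjust Append the four multiplicity-adjustment columns.
#' @param B Number of random permutations for the min-P adjustment.
#' @param seed Integer seed for the permutation draw.
#' @return A tibble of class `comparison_tbl`, one row per outcome.
#' @export
compare_groups <- function(data, occasion, grouping = NULL, binary = FALSE,
                           threshold = NULL, adjust = FALSE, B = 999,
                           seed = NULL) {
  roles <- roles_of(data)
  grouping <- grouping %||% roles$grouping
  if (is.null(grouping)) {
    abort("No grouping column declared or supplied.", class = "longmed_role_error")
  }
  if (binary && is.null(threshold)) {
    threshold <- if (!is.null(roles$threshold)) roles$threshold else 0
  }
  d <- as_tibble(at_occasion(data, occasion))
  g <- d[[grouping]]
  n_dropped <- sum(is.na(g))
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped, " row(s) with missing group label."))
    d <- d[!is.na(g), , drop = FALSE]
    g <- d[[grouping]]
  }
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) {
    abort("Grouping column must have exactly two observed levels.",
          class = "longmed_role_error")
  }
  in2 <- as.character(g) == lev[2]

  rows <- purrr::map_dfr(roles$outcomes, function(out) {
    v <- d[[out]]
    if (binary) {
      b <- dichotomize(v, threshold)
      x1 <- b[!in2]; x2 <- b[in2]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      tab <- rbind(c(sum(x1 == 1), sum(x1 == 0)),
                   c(sum(x2 == 1), sum(x2 == 0)))
      tst <- prop_test_cc(tab)
      tibble(outcome = out,
             n_1 = length(x1), positive_1 = sum(x1), prop_1 = mean(x1),
             n_2 = length(x2), positive_2 = sum(x2), prop_2 = mean(x2),
             raw_p = tst$p_value, flagged = tst$flagged)
    } else {
      x1 <- v[!in2]; x2 <- v[in2]
      m1 <- median_iqr(x1); m2 <- median_iqr(x2)
      flagged <- m1$n == 0 || m2$n == 0 || var_zero(c(x1, x2))
      p <- if (m1$n >= 1 && m2$n >= 1 && !var_zero(c(x1, x2)))
        mann_whitney(x1, x2)$p_value else NA_real_
      tibble(outcome = out,
             n_1 = m1$n, median_1 = m1$median, q1_1 = m1$q1, q3_1 = m1$q3,
             n_2 = m2$n, median_2 = m2$median, q1_2 = m2$q1, q3_2 = m2$q3,
             raw_p = p, flagged = flagged)
    }
  })

  if (adjust) {
    ok <- !is.na(rows$raw_p)
    holm <- perm <- qbh <- qby <- rep(NA_real_, nrow(rows))
    if (any(ok)) {
      holm[ok] <- holm_adjust(rows$raw_p[ok])
      qbh[ok] <- bh_qvalues(rows$raw_p[ok])
      qby[ok] <- by_qvalues(rows$raw_p[ok])
      ymat <- as.matrix(d[roles$outcomes[ok]])
      if (binary) ymat <- apply(ymat, 2, dichotomize, threshold = threshold)
      mp <- minp_adjust(ymat, in2, B = B,
                        test = if (binary) "prop_cc" else "mann_whitney",
                        seed = seed)
      perm[ok] <- mp$perm_p
    }
    rows$holm_p <- holm
    rows$perm_p <- perm
    rows$q_bh <- qbh
    rows$q_by <- qby
  }

  attr(rows, "groups") <- lev
  attr(rows, "occasion") <- as.character(occasion)
  attr(rows, "n_dropped_missing_group") <- n_dropped
  class(rows) <- c("comparison_tbl", class(rows))
  rows
}

var_zero <- function(v) {
  v <- v[!is.na(v)]
  length(v) == 0 || length(unique(v)) == 1
}

#' P-value overview plot for a comparison table
#'
#' Dot chart of raw and (when present) adjusted p values per outcome, with a
#' reference line at 0.05.
#'
#' @param object A `comparison_tbl` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_tbl <- function(object, ...) {
  df <- as_tibble(object)
  keep <- intersect(c("raw_p", "holm_p", "perm_p", "q_bh", "q_by"), names(df))
  long <- tidyr::pivot_longer(df[c("outcome", keep)], -"outcome",
                              names_to = "adjustment", values_to = "p")
  long$outcome <- factor(long$outcome, levels = rev(unique(df$outcome)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$p, y = .data$outcome,
                                     shape = .data$adjustment)) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = "dashed") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "P / Q value", y = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
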