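#' Default knot positions for a restricted cubic spline
#'
#' Knots are placed at the standard quantiles used by Harrell:
#' k = 3 at (0.10, 0.50, 0.90); k = 4 at (0.05, 0.35, 0.65, 0.95);
#' k = 5 at (0.05, 0.275, 0.50, 0.725, 0.95).
#'
#' @param x Numeric vector (missing values dropped).
#' @param k Number of knots (3, 4 or 5).
#' @return Ascending numeric vector of knot positions.
#' @export
default_knots <- function(x, k = 3) {
  if (!k %in% 3:5) abort("`k` must be 3, 4 or 5.", class = "longmed_domain_error")
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  if (length(ux) < k) {
    abort(paste0("Need at least ", k, " distinct values for ", k, " knots."),
          class = "longmed_knot_error")
  }
  if (length(ux) == k) return(ux)
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  kn <- unname(quantile(x, probs, type = 7))
  if (any(diff(kn) <= 0)) {
    abort("Quantile knots are not strictly increasing; too few distinct values.",
          class = "longmed_knot_error")
  }
  kn
}

#' Restricted cubic spline basis (truncated power form)
#'
#' Builds the Harrell restricted cubic basis: the linear term plus `k - 2`
#' nonlinear columns
#' `((x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})) / (t_k-t_1)^2`.
#' Any linear combination of the columns is exactly linear in `x` beyond
#' both boundary knots, and the nonlinear columns vanish at and below the
#' first knot.
#'
#' @param x Numeric vector.
#' @param knots Ascending numeric vector of at least 3 knots.
#' @return Numeric matrix with columns `x`, `x1`, ..., `x{k-2}`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3) abort("Need at least 3 knots.", class = "longmed_domain_error")
  if (is.unsorted(knots, strictly = TRUE)) {
    abort("Knots must be strictly ascending.", class = "longmed_domain_error")
  }
  t1 <- knots[1]; tkm1 <- knots[k - 1]; tk <- knots[k]
  norm <- (tk - t1)^2
  cube <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cube(x - tj) -
       cube(x - tkm1) * (tk - tj) / (tk - tkm1) +
       cube(x - tk) * (tkm1 - tj) / (tk - tkm1)) / norm
  }, numeric(length(x)))
  nl <- matrix(nl, nrow = length(x))
  out <- cbind(x, nl)
  colnames(out) <- c("x", paste0("x", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Fit a restricted-cubic-spline association curve
#'
#' Regresses a single outcome on a restricted cubic spline of a numeric
#' covariate (least squares for numeric outcomes, logistic regression for
#' binary ones) and returns the fitted curve over a grid with pointwise
#' delta-method 95% confidence bands, together with joint Wald tests for
#' the overall association (all spline terms) and for nonlinearity (the
#' nonlinear terms only).
#'
#' @param y Outcome vector (numeric, or 0/1 for the logistic family).
#' @param x Numeric covariate.
#' @param k Number of knots (3, 4 or 5), placed by [default_knots()] unless
#'   `knots` is given.
#' @param family `"linear"` or `"logistic"`.
#' @param knots Optional explicit knot vector.
#' @param grid_length Number of grid points for the fitted curve.
#' @param level Confidence level of the pointwise band.
#' @return An object of class `rcs_curve`: list with `curve` (tibble of
#'   `x`, `fit`, `ci_low`, `ci_high` on the response scale), `knots`,
#'   `p_overall`, `p_nonlinear`, `family` and the underlying model `fit`.
#' @export
fit_rcs_curve <- function(y, x, k = 3, family = c("linear", "logistic"),
                          knots = NULL, grid_length = 100, level = 0.95) {
  family <- arg_match(family)
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(unique(x)) < 3) {
    abort("Covariate is (nearly) constant; cannot place spline knots.",
          class = "longmed_knot_error")
  }
  knots <- knots %||% default_knots(x, k)
  basis <- rcs_basis(x, knots)
  df <- data.frame(y = y, basis)
  fml <- as.formula(paste("y ~", paste(colnames(basis), collapse = " + ")))
  fit <- if (family == "linear") lm(fml, data = df) else
    glm(fml, data = df, family = binomial())

  grid <- seq(min(x), max(x), length.out = grid_length)
  gb <- data.frame(rcs_basis(grid, knots))
  pr <- predict(fit, newdata = gb, se.fit = TRUE,
                type = if (family == "linear") "response" else "link")
  z <- if (family == "linear")
    qt(1 - (1 - level) / 2, df = fit$df.residual) else
    qnorm(1 - (1 - level) / 2)
  lo <- pr$fit - z * pr$se.fit
  hi <- pr$fit + z * pr$se.fit
  est <- pr$fit
  if (family == "logistic") {
    est <- plogis(est); lo <- plogis(lo); hi <- plogis(hi)
  }
  curve <- tibble(x = grid, fit = est, ci_low = lo, ci_high = hi)

  all_terms <- colnames(basis)
  nonlin <- setdiff(all_terms, "x")
  structure(
    list(curve = curve, knots = knots, family = family, fit = fit,
         p_overall = wald_joint_p(fit, all_terms),
         p_nonlinear = if (length(nonlin)) wald_joint_p(fit, nonlin) else NA_real_),
    class = "rcs_curve")
}

wald_joint_p <- function(fit, terms) {
  b <- coef(fit)[terms]
  V <- vcov(fit)[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  pchisq(stat, df = length(b), lower.tail = FALSE)
}

#' @export
print.rcs_curve <- function(x, ...) {
  cat("Restricted cubic spline curve (", x$family, " family, ",
      length(x$knots), " knots)\n", sep = "")
  cat("  knots:        ", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat("  p overall:    ", format.pval(x$p_overall), "\n")
  cat("  p nonlinear:  ", format.pval(x$p_nonlinear), "\n")
  invisible(x)
}

#' @rdname fit_rcs_curve
#' @param object An `rcs_curve`.
#' @param ... Unused.
#' @export
glance.rcs_curve <- function(x, ...) {
  tibble(family = x$family, n_knots = length(x$knots),
         p_overall = x$p_overall, p_nonlinear = x$p_nonlinear)
}

#' Plot a fitted spline curve with its confidence band
#' @param object An `rcs_curve` from [fit_rcs_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcs_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble(x = object$knots),
                      ggplot2::aes(x = .data$x), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.05, "npc")) +
    ggplot2::labs(x = "Covariate",
                  y = if (object$family == "logistic")
                    "Estimated probability" else "Estimated outcome") +
    ggplot2::theme_minimal()
}
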