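#' Step-down min-P permutation adjustment for correlated outcomes
#'
#' Westfall-Young familywise-error control that exploits the correlation
#' between outcomes. Group labels are permuted at the subject level; for
#' each permutation the per-outcome p values are recomputed from the same
#' permuted labels (rows stay intact, preserving the joint distribution of
#' the outcomes). The adjusted p for the outcome with the i-th smallest
#' observed p is
#' `(1 + #\{b : min over not-yet-rejected outcomes of p_b <= p_(i)\}) / (B + 1)`,
#' with monotonicity enforced along the step-down path. The smallest
#' attainable value is `1/(B+1)`.
#'
#' Inside the permutation loop the Mann-Whitney p uses the normal
#' approximation with tie and continuity correction (identical to
#' `wilcox.test(exact = FALSE, correct = TRUE)`), and the binary test is the
#' Yates-corrected chi-squared for a 2x2 table; the observed p values are
#' computed by the same routine, so observed and permuted values are
#' exchangeable. A constant outcome column gets raw p 1 and the adjustment
#' proceeds.
#'
#' @param outcome_matrix Numeric matrix, subjects in rows, outcomes in
#'   columns.
#' @param groups Logical or two-level vector of group membership, one per
#'   subject.
#' @param B Number of random permutations (at least 100).
#' @param test `"mann_whitney"` for numeric outcomes, `"prop_cc"` for
#'   binary (0/1) outcomes.
#' @param variant `"step-down"` (default; uniformly more powerful) or
#'   `"single-step"`, which compares every observed p against the
#'   permutation distribution of the overall minimum.
#' @param seed Integer seed making the permutation draw reproducible.
#' @return A list with `raw_p`, `perm_p` (both in input column order) and
#'   `B`.
#' @export
minp_adjust <- function(outcome_matrix, groups, B = 999,
                        test = c("mann_whitney", "prop_cc"),
                        variant = c("step-down", "single-step"),
                        seed = NULL) {
  test <- arg_match(test)
  variant <- arg_match(variant)
  Y <- as.matrix(outcome_matrix)
  if (is.logical(groups)) {
    in2 <- groups
  } else {
    lev <- sort(unique(as.character(groups[!is.na(groups)])))
    if (length(lev) != 2) {
      abort("`groups` must have exactly two levels.", class = "longmed_role_error")
    }
    in2 <- as.character(groups) == lev[2]
  }
  if (length(in2) != nrow(Y)) {
    abort("`groups` length must match the number of rows.",
          class = "longmed_validation_error")
  }
  n1 <- sum(!in2); n2 <- sum(in2)
  if (n1 < 2 || n2 < 2) {
    abort("Need at least 2 subjects per group.", class = "longmed_validation_error")
  }
  if (B < 100) abort("B must be at least 100.", class = "longmed_domain_error")

  pfun <- switch(test, mann_whitney = mw_pvalues, prop_cc = prop_pvalues)
  fast_mw <- test == "mann_whitney" && !anyNA(Y)
  run <- function() {
    obs <- pfun(Y, in2)
    n <- nrow(Y)
    # permutation indicator matrix: column b marks the permuted group 2
    G <- matrix(FALSE, n, B)
    for (b in seq_len(B)) G[sample.int(n, n2), b] <- TRUE
    if (fast_mw) {
      # ranks and tie variances do not depend on the labels: one matrix
      # product gives the rank sums of all permutations at once
      R <- apply(Y, 2, rank)
      tie_terms <- apply(Y, 2, function(v) {
        if (!anyDuplicated(v)) return(0)
        t <- tabulate(match(v, v)); t <- t[t > 0]
        sum(t^3 - t)
      })
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_terms / (n * (n - 1)))
      S <- crossprod(!G, R)                       # B x k rank sums, group 1
      U <- sweep(S, 2, rep(n1 * (n1 + 1) / 2, ncol(Y))) - n1 * n2 / 2
      U <- U - sign(U) * 0.5
      Z <- sweep(U, 2, sqrt(pmax(sigma2, .Machine$double.eps)), "/")
      P <- pmin(2 * pnorm(-abs(Z)), 1)
      P[, sigma2 <= 0] <- 1
    } else {
      P <- matrix(NA_real_, B, ncol(Y))
      for (b in seq_len(B)) P[b, ] <- pfun(Y, G[, b])
    }
    list(obs = obs, P = P)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  obs <- res$obs
  P <- res$P
  k <- length(obs)
  ord <- order(obs)                      # ascending observed p
  # successive minima: q[, i] = min over outcomes with step-down rank >= i
  Psort <- P[, ord, drop = FALSE]
  Q <- Psort
  if (k > 1) for (i in (k - 1):1) Q[, i] <- pmin(Q[, i], Q[, i + 1])
  if (variant == "single-step") Q[] <- Q[, 1]  # min over all outcomes
  adj_sorted <- vapply(seq_len(k), function(i) {
    (1 + sum(Q[, i] <= obs[ord[i]])) / (B + 1)
  }, numeric(1))
  adj_sorted <- cummax(adj_sorted)
  adj <- numeric(k)
  adj[ord] <- pmin(adj_sorted, 1)
  list(raw_p = unname(obs), perm_p = adj, B = B)
}

# Vectorized Mann-Whitney p over columns: normal approximation with tie
# correction and continuity correction, matching
# wilcox.test(exact = FALSE, correct = TRUE).
mw_pvalues <- function(Y, in2) {
  apply(Y, 2, function(v) mw_p_one(v, in2))
}

mw_p_one <- function(v, in2) {
  keep <- !is.na(v)
  v <- v[keep]; g2 <- in2[keep]
  nx <- sum(!g2); ny <- sum(g2)
  if (nx == 0 || ny == 0) return(1)
  r <- rank(v)
  U <- sum(r[!g2]) - nx * (nx + 1) / 2
  n <- nx + ny
  tie_term <- if (anyDuplicated(v)) {
    ties <- tabulate(match(v, v))
    ties <- ties[ties > 0]
    sum(ties^3 - ties)
  } else 0
  sigma2 <- (nx * ny / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - nx * ny / 2
  corr <- sign(z) * 0.5
  z <- (z - corr) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# Vectorized Yates-corrected 2x2 chi-squared p over binary columns,
# matching prop.test(correct = TRUE).
prop_pvalues <- function(Y, in2) {
  apply(Y, 2, function(v) {
    keep <- !is.na(v)
    v <- v[keep]; g2 <- in2[keep]
    a <- sum(v[!g2] == 1); b <- sum(v[!g2] == 0)
    c_ <- sum(v[g2] == 1); d <- sum(v[g2] == 0)
    n <- a + b + c_ + d
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
    stat <- n * (max(abs(a * d - b * c_) - n / 2, 0))^2 / (r1 * r2 * c1 * c2)
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
}
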