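test_that("Mann-Whitney uses exact enumeration on small tie-free samples", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
})

test_that("the proportion test applies the Yates correction", {
  expect_equal(prop_test_cc(rbind(c(10, 0), c(0, 10)))$statistic, 16.2,
               tolerance = 1e-10)
  even <- prop_test_cc(rbind(c(5, 5), c(5, 5)))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_equal(prop_test_cc(rbind(c(1, 1), c(1, 1)))$statistic, 0)
  expect_true(prop_test_cc(rbind(c(0, 0), c(3, 2)))$flagged)
})

test_that("Holm and BH/BY agree with hand-worked examples", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.02)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(by_qvalues(c(0.01, 0.02, 0.04)),
               c(0.03, 0.03, 0.04) * (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-12)
  expect_equal(by_qvalues(c(1, 1)), c(1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "longmed_domain_error")
})

test_that("adjustments match brute-force definitions on random vectors", {
  for (seed in 1:10) {
    p <- withr::with_seed(seed, round(runif(sample(2:6, 1)), 3))
    expect_equal(holm_adjust(p), holm_brute(p), tolerance = 1e-12)
    expect_equal(bh_qvalues(p), bh_brute(p), tolerance = 1e-12)
    expect_equal(by_qvalues(p), by_brute(p), tolerance = 1e-12)
    expect_true(all(by_qvalues(p) >= bh_qvalues(p) - 1e-12))
    expect_true(all(holm_adjust(p) >= p - 1e-12))
  }
})

test_that("internal permutation p-values match wilcox.test and prop.test", {
  withr::with_seed(31, {
    v <- sample(0:10, 40, replace = TRUE)  # heavy ties
    g2 <- rep(c(FALSE, TRUE), 20)
    expect_equal(longmed:::mw_p_one(v, g2),
                 suppressWarnings(wilcox.test(v[!g2], v[g2], exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-12)
    b <- rbinom(40, 1, 0.4)
    tab <- rbind(c(sum(b[!g2] == 1), sum(b[!g2] == 0)),
                 c(sum(b[g2] == 1), sum(b[g2] == 0)))
    expect_equal(unname(longmed:::prop_pvalues(matrix(b), g2)),
                 suppressWarnings(prop.test(tab, correct = TRUE)$p.value),
                 tolerance = 1e-12)
  })
})

test_that("min-P adjustment pays no penalty for duplicated outcomes", {
  gn <- generate_global_null(n = 12, k = 1, seed = 5)
  y <- as.matrix(gn[, -(1:2)])
  single <- minp_adjust(y, gn$group, B = 499, seed = 77)
  # a single outcome reduces to the plain permutation p: recount the
  # estimator by replaying the same seeded label permutations
  n <- nrow(y); n2 <- sum(gn$group)
  manual <- withr::with_seed(77, {
    obs <- longmed:::mw_p_one(y[, 1], gn$group)
    hits <- vapply(1:499, function(b) {
      g2 <- logical(n); g2[sample.int(n, n2)] <- TRUE
      longmed:::mw_p_one(y[, 1], g2) <= obs
    }, logical(1))
    (1 + sum(hits)) / 500
  })
  expect_equal(single$perm_p, manual, tolerance = 1e-12)
  dup <- minp_adjust(cbind(a = y[, 1], b = y[, 1]), gn$group, B = 499,
                     seed = 77)
  expect_equal(dup$perm_p[1], dup$perm_p[2])
  expect_equal(dup$perm_p[1], single$perm_p, tolerance = 1e-12)
})

test_that("min-P adjusted values respect resolution and column-order invariance", {
  gn <- generate_global_null(n = 10, k = 5, correlation = 0.3, seed = 8)
  y <- as.matrix(gn[, -(1:2)])
  a <- minp_adjust(y, gn$group, B = 199, seed = 12)
  expect_true(all(a$perm_p >= 1 / 200))
  expect_true(all(a$perm_p <= 1))
  perm <- c(3, 1, 5, 2, 4)
  b <- minp_adjust(y[, perm], gn$group, B = 199, seed = 12)
  expect_equal(b$perm_p, a$perm_p[perm], tolerance = 1e-12)
  # single-step variant is never smaller and agrees on the smallest p
  ss <- minp_adjust(y, gn$group, B = 199, variant = "single-step", seed = 12)
  expect_true(all(ss$perm_p >= a$perm_p - 1e-12))
  expect_equal(ss$perm_p[which.min(a$raw_p)], a$perm_p[which.min(a$raw_p)])
  # constant outcome column gets raw p 1 and the adjustment proceeds
  cc <- minp_adjust(cbind(y[, 1:2], const = 5), gn$group, B = 199, seed = 1)
  expect_equal(cc$raw_p[3], 1)
  expect_equal(cc$perm_p[3], 1)
})

test_that("group comparison tables carry summaries and adjustment columns", {
  g <- generate_em_like(
    sim_config(n_subjects = 40, n_outcomes = 5, group_effect = 1.5),
    seed = 14)
  plain <- compare_groups(g, occasion = "0", B = 199, seed = 3)
  expect_false(any(c("holm_p", "perm_p", "q_bh", "q_by") %in% names(plain)))
  adj <- compare_groups(g, occasion = "0", adjust = TRUE, B = 199, seed = 3)
  expect_equal(setdiff(names(adj), names(plain)),
               c("holm_p", "perm_p", "q_bh", "q_by"))
  expect_true(all(adj$holm_p >= adj$raw_p - 1e-12))
  expect_true(all(adj$q_by >= adj$q_bh - 1e-12))
  expect_true(all(adj$perm_p >= 1 / 200))

  binadj <- compare_groups(g, occasion = "0", binary = TRUE, threshold = 2,
                           adjust = TRUE, B = 199, seed = 3)
  expect_true(all(c("positive_1", "prop_2", "perm_p") %in% names(binadj)))

  # rows with a missing group label are dropped with a message
  g2 <- g
  g2$group[g2$subject == "S001"] <- NA
  g2 <- validate_roles(as_tibble(g2), roles_of(g))
  expect_message(compare_groups(g2, occasion = "0", B = 199, seed = 1),
                 "missing group label")
})

test_that("independent-test FWER arithmetic crosses one half above 13 tests", {
  expect_lt(fwer_independent(13), 0.5)
  expect_gt(fwer_independent(14), 0.5)
  expect_equal(fwer_independent(1), 0.05)
})
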