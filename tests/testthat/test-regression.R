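test_that("linear fit with a binary covariate reproduces the equal-variance t-test", {
  withr::with_seed(101, {
    y <- rnorm(40, mean = rep(c(0, 1), each = 20))
    x <- rep(c("responder", "nonresponder"), each = 20)
  })
  fit <- fit_linear(y, factor(x, levels = c("responder", "nonresponder")))
  tt <- t.test(y[x == "nonresponder"], y[x == "responder"], var.equal = TRUE)
  slope <- fit$terms[fit$terms$term != "(Intercept)", ]
  expect_equal(slope$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(slope$estimate,
               mean(y[x == "nonresponder"]) - mean(y[x == "responder"]),
               tolerance = 1e-12)
  expect_equal(unlist(slope[c("ci_low", "ci_high")], use.names = FALSE),
               as.numeric(tt$conf.int), tolerance = 1e-9)
})

test_that("noise-free linear data is recovered exactly", {
  x <- 1:20
  fit <- suppressWarnings(fit_linear(3 + 2 * x, x))  # perfect-fit warning
  expect_equal(fit$terms$estimate, c(3, 2), tolerance = 1e-10)
  expect_lt(suppressWarnings(summary(fit$fit))$sigma, 1e-10)
  expect_error(fit_linear(rnorm(10), rep(1, 10)),
               class = "longmed_singularity_error")
})

test_that("slope CIs bracket the estimate on the estimation scale", {
  withr::with_seed(7, {
    y <- rnorm(50); x <- rnorm(50)
    yb <- rbinom(50, 1, plogis(x))
  })
  lin <- tidy(fit_linear(y, x))
  expect_true(all(lin$ci_low <= lin$estimate & lin$estimate <= lin$ci_high))
  logi <- tidy(fit_logistic(yb, x))
  expect_true(all(logi$estimate > 0))
  expect_true(all(logi$ci_low <= logi$estimate & logi$estimate <= logi$ci_high))
})

test_that("Firth's penalization keeps separated fits finite", {
  sep <- generate_separable(4)
  firth <- fit_logistic(sep$y, sep$x, firth = TRUE)
  slope_or <- firth$terms$estimate[firth$terms$term != "(Intercept)"]
  expect_equal(log(slope_or), log(25), tolerance = 1e-4)

  plain <- fit_logistic(sep$y, sep$x, firth = FALSE)
  expect_true(plain$diverged)
  expect_false(firth$diverged)

  big <- generate_separable(40)
  ml <- logistic_ml(cbind(1, big$x), big$y)
  expect_true(ml$diverged)
  ff <- firth_logistic(cbind(`(Intercept)` = 1, x = big$x), big$y)
  expect_true(all(is.finite(ff$coefficients)))
  expect_true(ff$converged)
})

test_that("a balanced non-separated 2x2 table gives odds ratio one", {
  y <- rep(c(1, 0, 1, 0), each = 10)
  x <- rep(c(0, 0, 1, 1), each = 10)
  for (firth in c(FALSE, TRUE)) {
    fit <- fit_logistic(y, x, firth = firth)
    or <- fit$terms$estimate[fit$terms$term != "(Intercept)"]
    expect_equal(log(or), 0, tolerance = 1e-8)
  }
})

test_that("logistic coefficients are recovered on simulated data", {
  withr::with_seed(202, {
    x <- rnorm(500)
    y <- rbinom(500, 1, plogis(-0.5 + 0.8 * x))
  })
  for (firth in c(FALSE, TRUE)) {
    fit <- fit_logistic(y, x, firth = firth)
    row <- fit$terms[fit$terms$term != "(Intercept)", ]
    se <- (log(row$ci_high) - log(row$ci_low)) / (2 * qnorm(0.975))
    expect_lt(abs(log(row$estimate) - 0.8), 3 * se)
  }
})

test_that("degenerate logistic inputs are rejected", {
  expect_error(fit_logistic(rep(1, 20), rnorm(20)),
               class = "longmed_degenerate_error")
  expect_error(fit_logistic(c(0.2, 0.8, rep(0:1, 9)), rnorm(20)),
               class = "longmed_type_error")
})

test_that("default knots sit at the standard quantiles", {
  x <- 0:100
  expect_equal(default_knots(x, 3), c(10, 50, 90), tolerance = 0.02)
  expect_equal(length(default_knots(x, 4)), 4)
  expect_equal(default_knots(c(1, 5, 9), 3), c(1, 5, 9))
  expect_error(default_knots(rep(2, 10), 3), class = "longmed_knot_error")
  expect_error(default_knots(x, 6), class = "longmed_domain_error")
})

test_that("the restricted basis is truncated below and linear beyond the knots", {
  knots <- c(2, 5, 8)
  x <- seq(0, 12, by = 0.05)
  b <- rcs_basis(x, knots)
  expect_equal(ncol(b), 2)  # k - 2 = 1 nonlinear column plus x
  expect_true(all(b[x <= 2, -1] == 0))

  # second differences of every column vanish beyond the boundary knots
  for (kn in list(c(2, 5, 8), c(1, 3, 6, 9), c(0, 2, 5, 8, 10))) {
    right <- seq(max(kn) + 0.5, max(kn) + 12, by = 0.1)
    bb <- rcs_basis(right, kn)
    d2 <- diff(bb, differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
  }
  expect_error(rcs_basis(x, c(5, 2, 8)), class = "longmed_domain_error")
})

test_that("spline curves find planted shapes and stay honest under linearity", {
  withr::with_seed(77, {
    x <- runif(300, 0, 10)
    yu <- (x - 5)^2 / 5 + rnorm(300, sd = 0.5)
  })
  ufit <- fit_rcs_curve(yu, x, k = 4)
  expect_lt(ufit$p_nonlinear, 1e-4)
  interior <- ufit$curve[ufit$curve$x > min(x) + 1 &
                           ufit$curve$x < max(x) - 1, ]
  expect_lt(min(interior$fit), ufit$curve$fit[1])
  expect_lt(min(interior$fit),
            ufit$curve$fit[nrow(ufit$curve)])
  expect_true(all(ufit$curve$ci_low <= ufit$curve$fit &
                    ufit$curve$fit <= ufit$curve$ci_high))

  # size of the nonlinearity test under a truly linear signal
  rejections <- vapply(1:100, function(i) {
    withr::with_seed(1000 + i, {
      x <- runif(100, 0, 10)
      y <- 1 + 0.3 * x + rnorm(100)
    })
    fit_rcs_curve(y, x, k = 3)$p_nonlinear < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.12)
  expect_error(fit_rcs_curve(rnorm(10), rep(3, 10)),
               class = "longmed_knot_error")
})

test_that("per-outcome regression tables cover every declared outcome", {
  g <- generate_em_like(
    sim_config(n_subjects = 50, n_outcomes = 3, group_effect = 1),
    seed = 31)
  rt <- regress_outcomes(g, covariate = "group", occasion = "0")
  expect_setequal(unique(rt$outcome), roles_of(g)$outcomes)
  expect_true(all(rt$family == "linear"))
  expect_true(all(table(rt$outcome) == 2))  # intercept + slope

  rtb <- regress_outcomes(g, covariate = "group", occasion = "0",
                          binary = TRUE, threshold = 2, firth = TRUE)
  expect_true(all(rtb$family == "logistic"))
  expect_true(all(rtb$penalized))
  expect_true(all(rtb$estimate[rtb$term != "(Intercept)"] > 0, na.rm = TRUE))
})
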