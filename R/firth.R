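#' Firth penalized-likelihood logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by Newton iteration on the
#' hat-value-modified score
#' `U*_j = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ij`,
#' with step-halving on the penalized likelihood. The penalty keeps the
#' estimates finite even under complete separation, where ordinary maximum
#' likelihood diverges to infinity. Wald 95% confidence intervals on the
#' log-odds scale use the inverse Fisher information at convergence.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary 0/1 response vector.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the max-norm of the modified score.
#' @param level Confidence level for the Wald intervals.
#' @return An object of class `firth_fit`: list with `coefficients`, `se`,
#'   `vcov`, `ci_low`, `ci_high`, `p_value`, `loglik` (penalized),
#'   `iterations`, `converged`.
#' @export
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8, level = 0.95) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary 0/1.", class = "longmed_type_error")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient.", class = "longmed_singularity_error")
  }
  p <- ncol(X)

  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    w <- plogis(eta) * (1 - plogis(eta))
    ll <- sum(y * eta - log1p(exp(eta)))
    I <- crossprod(X * w, X)
    ll + 0.5 * determinant(I, logarithm = TRUE)$modulus
  }

  beta <- rep(0, p)
  ll_old <- pen_loglik(beta)
  converged <- FALSE
  iter <- 0
  grad_norm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    pi_ <- plogis(eta)
    w <- pi_ * (1 - pi_)
    I <- crossprod(X * w, X)
    Ichol <- tryCatch(chol(I), error = function(e)
      abort("Fisher information is singular.", class = "longmed_singularity_error"))
    XWhalf <- X * sqrt(w)
    H <- XWhalf %*% chol2inv(Ichol)
    h <- rowSums(H * XWhalf)
    U <- drop(crossprod(X, y - pi_ + h * (0.5 - pi_)))
    grad_norm <- max(abs(U))
    if (grad_norm < tol) { converged <- TRUE; break }
    delta <- drop(chol2inv(Ichol) %*% U)
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- pen_loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; ll_new <- ll_old; break }
    }
    beta <- beta_new
    ll_old <- ll_new
  }
  if (!converged && grad_norm >= tol) {
    abort(sprintf(
      "Firth fit did not converge in %d iterations (gradient max-norm %.3g).",
      max_iter, grad_norm), class = "longmed_convergence_error")
  }

  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  I <- crossprod(X * w, X)
  V <- chol2inv(chol(I))
  se <- sqrt(diag(V))
  z <- qnorm(1 - (1 - level) / 2)
  names(beta) <- names(se) <- colnames(X)
  structure(
    list(coefficients = beta, se = se, vcov = V,
         ci_low = beta - z * se, ci_high = beta + z * se,
         p_value = 2 * pnorm(-abs(beta / se)),
         loglik = as.numeric(ll_old), iterations = iter,
         converged = converged),
    class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic regression (", x$iterations, " iterations)\n",
      sep = "")
  print(tidy.firth_fit(x))
  invisible(x)
}

#' @rdname firth_logistic
#' @param x A `firth_fit`.
#' @param ... Unused.
#' @export
tidy.firth_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std_error = unname(x$se),
         ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
         p_value = unname(x$p_value))
}

#' @rdname firth_logistic
#' @export
glance.firth_fit <- function(x, ...) {
  tibble(logLik_penalized = x$loglik, iterations = x$iterations,
         converged = x$converged)
}

#' Detect divergence of the unpenalized logistic fit
#'
#' Runs ordinary maximum-likelihood logistic regression and flags the
#' separation failure mode: fitted probabilities numerically at 0 or 1, or a
#' coefficient norm that keeps growing with the iteration budget (the
#' estimate diverges to infinity under complete separation).
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary 0/1 response.
#' @return A list with `coefficients`, `diverged` (logical) and
#'   `max_abs_coef`.
#' @export
logistic_ml <- function(X, y) {
  X <- as.matrix(X)
  warned <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  eps <- 1e-8
  boundary <- any(mu < eps | mu > 1 - eps)
  big <- max(abs(fit$coefficients), na.rm = TRUE) > 10
  list(coefficients = fit$coefficients,
       diverged = warned || (boundary && big),
       max_abs_coef = max(abs(fit$coefficients), na.rm = TRUE))
}
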