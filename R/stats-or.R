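#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' For counts `a` (exposed, outcome-positive), `b` (exposed, negative),
#' `c` (reference, positive), `d` (reference, negative):
#' OR = (a d) / (b c), with a Wald interval
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to every cell and the result is
#' flagged `continuity_corrected`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param ci_level Confidence level (default 0.95).
#' @return An object of class `bf_or` with fields `odds_ratio`, `ci_low`,
#'   `ci_high`, `ci_level`, `continuity_corrected`.
#' @examples
#' odds_ratio_2x2(65, 49, 10, 145)  # ~19.2, IBS vs healthy controls
#' @export
odds_ratio_2x2 <- function(a, b, c, d, ci_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, ci_level > 0, ci_level < 1)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("odds ratio undefined: an entire row or column of the table is zero")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 ci_level = ci_level,
                 continuity_corrected = corrected),
            class = "bf_or")
}

#' @export
print.bf_or <- function(x, ...) {
  cat(sprintf("OR %.2f (%d%% CI %.2f-%.2f)%s\n", x$odds_ratio,
              round(100 * x$ci_level), x$ci_low, x$ci_high,
              if (x$continuity_corrected) " [Haldane-Anscombe corrected]"
              else ""))
  invisible(x)
}

#' Grouped-binomial logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression on grouped binomial data
#' (successes out of totals per covariate row), fitted by iteratively
#' reweighted least squares. Used for the center-adjusted cohort odds
#' ratios. Declares an explicit error on non-convergence or separation
#' (diverging linear predictor).
#'
#' @param design Numeric model matrix (rows = groups; include an intercept
#'   column), or a data frame of factors/numerics which is passed through
#'   [stats::model.matrix()] with an intercept.
#' @param successes,totals Integer vectors, one entry per design row,
#'   `0 <= successes <= totals`.
#' @param tol Convergence tolerance on the coefficient step (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param ci_level Confidence level for the Wald intervals on exp(coef).
#' @return An object of class `grouped_logit`: `coefficients`, `se`,
#'   `odds_ratio` (= exp(coef)), `ci_low`, `ci_high`, `iterations`,
#'   `converged`, `vcov`.
#' @export
fit_grouped_logistic <- function(design, successes, totals, tol = 1e-8,
                                 max_iter = 50, ci_level = 0.95) {
  if (is.data.frame(design))
    design <- stats::model.matrix(~ ., data = design)
  X <- as.matrix(design)
  s <- as.numeric(successes)
  n <- as.numeric(totals)
  stopifnot(nrow(X) == length(s), length(s) == length(n),
            all(s >= 0), all(n >= s))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (any(abs(eta) > 30))
      stop("separation detected: linear predictor diverging")
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    z <- eta + (s - n * mu) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("IRLS did not converge in ", max_iter, " iterations")
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- n * mu * (1 - mu)
  vcov <- solve(t(X * w) %*% X)
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  names(beta) <- names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se,
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 iterations = iter, converged = converged, vcov = vcov),
            class = "grouped_logit")
}

#' @export
coef.grouped_logit <- function(object, ...) object$coefficients

#' @export
print.grouped_logit <- function(x, ...) {
  cat("Grouped binomial logistic fit (IRLS,",
      x$iterations, "iterations)\n")
  print(data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratio,
                   ci_low = x$ci_low, ci_high = x$ci_high))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity from a 2x2 confusion table.
#' A zero denominator makes the corresponding field `NA` (undefined),
#' never an error.
#'
#' @param tp,fn,fp,tn Non-negative integer counts (true positive, false
#'   negative, false positive, true negative).
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `n`.
#' @examples
#' confusion_metrics(33, 4, 19, 28)$accuracy  # 61/84
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty confusion table")
  list(accuracy = (tp + tn) / n,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n = n)
}
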