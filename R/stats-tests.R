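# Hypothesis-test wrappers. The tests themselves are standard and are
# delegated to base R; the wrappers fix the conventions used throughout the
# analysis (two-sided Fisher by the minimum-likelihood rule, Mann-Whitney U
# exact only for small untied samples, Kruskal-Wallis with tie correction)
# and return a uniform result object.

.bf_test <- function(statistic, p_value, method, sidedness) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, sidedness = sidedness),
            class = "bf_htest")
}

#' @export
print.bf_htest <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$sidedness, x$statistic, x$p_value))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. `method = "doubling"` instead doubles the smaller one-sided
#' tail (capped at 1).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param method `"min-likelihood"` (default) or `"doubling"`.
#' @return A `bf_htest` (statistic = the observed table probability).
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             method = c("min-likelihood", "doubling")) {
  method <- match.arg(method)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, c, b, d), 2)
  p_obs <- stats::dhyper(a, a + b, c + d, a + c)
  if (method == "min-likelihood") {
    p <- stats::fisher.test(m)$p.value
  } else {
    p_lo <- stats::phyper(a, a + b, c + d, a + c)
    p_hi <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  .bf_test(p_obs, min(p, 1), paste0("Fisher exact (", method, ")"),
           "two-sided")
}

#' Mann-Whitney U test
#'
#' U computed from midranks. The p-value is exact (enumeration) when the
#' pooled sample size is at most 16 and there are no ties, otherwise a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `bf_htest` with `statistic` = U for `x`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 16 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  .bf_test(unname(ht$statistic), ht$p.value,
           paste0("Mann-Whitney U (",
                  if (exact) "exact" else "normal approximation", ")"),
           alternative)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction; p from a chi-square with k - 1 degrees
#' of freedom. All-identical values give H = 0, p = 1.
#'
#' @param groups A list of at least two non-empty numeric vectors.
#' @return A `bf_htest` with `statistic` = H.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1)
    return(.bf_test(0, 1, "Kruskal-Wallis", "two-sided"))
  ht <- stats::kruskal.test(groups)
  .bf_test(unname(ht$statistic), ht$p.value, "Kruskal-Wallis", "two-sided")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, clipped at 1, original
#' order preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample t test on log-transformed data
#'
#' Welch t test of `log(x)` vs `log(y)`; the convention used for strictly
#' positive, right-skewed quantities such as 16S gene-copy ratios.
#'
#' @param x,y Strictly positive numeric samples.
#' @return A `bf_htest`.
#' @export
log_t_test <- function(x, y) {
  stopifnot(all(x > 0), all(y > 0))
  ht <- stats::t.test(log(x), log(y))
  .bf_test(unname(ht$statistic), ht$p.value, "Welch t on log data",
           "two-sided")
}
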