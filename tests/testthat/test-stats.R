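test_that("2x2 odds ratios match hand arithmetic", {
  expect_equal(round(odds_ratio_2x2(65, 49, 10, 145)$odds_ratio, 1), 19.2)
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$odds_ratio, 1)
  expect_equal(odds_ratio_2x2(10, 10, 5, 20)$odds_ratio, 4)
  r <- odds_ratio_2x2(10, 10, 5, 20)
  expect_lte(r$ci_low, r$odds_ratio)
  expect_gte(r$ci_high, r$odds_ratio)
  expect_false(r$continuity_corrected)
})

test_that("odds ratios obey reciprocal symmetry and zero-cell handling", {
  a <- odds_ratio_2x2(12, 7, 5, 19)$odds_ratio
  b <- odds_ratio_2x2(5, 19, 12, 7)$odds_ratio
  expect_equal(a, 1 / b)
  z <- odds_ratio_2x2(0, 10, 5, 20)
  expect_true(z$continuity_corrected)
  expect_equal(z$odds_ratio, (0.5 * 20.5) / (10.5 * 5.5))
  expect_error(odds_ratio_2x2(0, 0, 5, 20), "undefined")
})

test_that("Fisher exact matches enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3)$p_value, 0.1)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3, method = "doubling")$p_value,
               0.1)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.1, 1)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_equal(p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                       cells[4]),
                 tolerance = 1e-7)
    pt <- fisher_exact_2x2(cells[1], cells[3], cells[2], cells[4])$p_value
    expect_equal(p, pt, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U has exact small-sample behaviour", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 9 / 2)
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney U statistics conserve U_x + U_y = n_x n_y", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), 0.5)
    ux <- mann_whitney_u(x, y)$statistic
    uy <- mann_whitney_u(y, x)$statistic
    expect_equal(ux + uy, length(x) * length(y))
  }
})

test_that("Kruskal-Wallis agrees with Mann-Whitney asymptotics", {
  set.seed(44)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  p_kw <- kruskal_wallis(list(x, y))$p_value
  p_mw <- mann_whitney_u(x, y)$p_value
  expect_lt(abs(p_kw - p_mw), 0.02)
  ident <- kruskal_wallis(list(rep(2, 5), rep(2, 7)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(55)
  rej <- mean(vapply(seq_len(500), function(i) {
    g <- list(runif(50), runif(50), runif(50))
    kruskal_wallis(g)$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(66)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    # re-adjusting never shrinks a value; constants are fixed points
    expect_true(all(bh_adjust(adj) >= adj))
  }
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("IRLS logistic on a saturated 2x2 equals the crude odds ratio", {
  X <- cbind(1, c(1, 0))
  fit <- fit_grouped_logistic(X, successes = c(10, 5), totals = c(20, 25))
  or <- odds_ratio_2x2(10, 10, 5, 20)$odds_ratio
  expect_equal(unname(exp(fit$coefficients[2])), or, tolerance = 1e-10)
})

test_that("IRLS logistic matches glm on grouped data", {
  set.seed(77)
  df <- data.frame(x = c(0, 0, 1, 1), z = c(0, 1, 0, 1))
  n <- c(50, 60, 55, 45)
  p_true <- plogis(-0.5 + 1.2 * df$x + 0.3 * df$z)
  s <- rbinom(4, n, p_true)
  X <- cbind(1, df$x, df$z)
  fit <- fit_grouped_logistic(X, s, n)
  g <- glm(cbind(s, n - s) ~ x + z, family = binomial, data = df)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
})

test_that("IRLS logistic recovers a planted odds ratio", {
  set.seed(88)
  est <- vapply(seq_len(200), function(i) {
    n <- c(2500, 2500)
    s <- rbinom(2, n, plogis(c(-1, -1 + log(3))))
    fit <- fit_grouped_logistic(cbind(1, c(0, 1)), s, n)
    fit$coefficients[2]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(3)), 3 * se + 1e-12)
})

test_that("IRLS logistic reports separation explicitly", {
  X <- cbind(1, c(0, 1))
  expect_error(fit_grouped_logistic(X, c(0, 30), c(30, 30)),
               "separation|converge")
  expect_error(fit_grouped_logistic(cbind(1, c(1, 1)), c(5, 5),
                                    c(10, 10)), "rank")
})

test_that("confusion metrics handle counts and undefined denominators", {
  expect_equal(confusion_metrics(10, 0, 0, 10)$accuracy, 1)
  m <- confusion_metrics(33, 4, 19, 28)
  expect_equal(m$accuracy, 61 / 84)
  expect_equal(m$sensitivity, 33 / 37)
  expect_equal(m$specificity, 28 / 47)
  expect_true(is.na(confusion_metrics(0, 0, 3, 5)$sensitivity))
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("the log-scale t test matches t.test on transformed data", {
  set.seed(99)
  x <- rlnorm(20); y <- rlnorm(25, 0.5)
  r <- log_t_test(x, y)
  ref <- t.test(log(x), log(y))
  expect_equal(r$p_value, ref$p.value)
  expect_error(log_t_test(c(1, -1), y))
})
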