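test_that("welch_t matches the textbook formula and stats::t.test", {
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  res <- welch_t(x, y)
  ora <- oracle_welch(x, y)
  ref <- t.test(x, y)
  expect_equal(res$statistic, ora$statistic, tolerance = 1e-12)
  expect_equal(res$df, ora$df, tolerance = 1e-12)
  expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  z <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)

  # equal-variance balanced design: Welch df equals pooled df
  a <- c(0, 1, 2, 3); b <- c(10, 11, 12, 13)
  expect_equal(welch_t(a, b)$df, length(a) + length(b) - 2)

  # degenerate variances
  expect_equal(welch_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("holm_adjust implements the step-down definition", {
  expect_equal(holm_adjust(0.05), 0.05)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-14)
    expect_equal(adj, p.adjust(p, method = "holm"), tolerance = 1e-14)
    expect_true(all(adj >= p))            # never below the raw p
    expect_true(all(adj <= 1))
  }
})

test_that("one_way_anova matches sums-of-squares oracle and stats::aov", {
  set.seed(5)
  groups <- lapply(1:4, function(i) rnorm(5, mean = i / 2))
  res <- one_way_anova(groups)
  ora <- oracle_anova(groups)
  expect_equal(res$statistic, ora$f, tolerance = 1e-12)
  expect_equal(res$df, ora$df)
  expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), times = lengths(groups))))
  ref <- summary(aov(y ~ g, data = df))[[1]]
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)

  # two groups: F equals the square of the pooled t statistic
  x <- rnorm(6); y <- rnorm(7, 1)
  f2 <- one_way_anova(list(x, y))
  tp <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tp$statistic)^2, tolerance = 1e-10)
  expect_equal(f2$p_value, tp$p.value, tolerance = 1e-10)

  # the titer design: 6 treatments x 3 line means -> df (5, 12)
  g6 <- lapply(1:6, function(i) rnorm(3, i))
  expect_equal(one_way_anova(g6)$df, c(5L, 12L))

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(rnorm(3))), "at least 2 groups")
})

test_that("one_way_anova F is near its null expectation under the null", {
  set.seed(88)
  k <- 4; n <- 5
  f <- replicate(400, one_way_anova(
    split(rnorm(k * n), rep(1:k, each = n)))$statistic)
  df2 <- k * (n - 1)
  expect_lt(abs(mean(f) - df2 / (df2 - 2)), 3 * sd(f) / sqrt(length(f)))
})

test_that("tukey_hsd reduces to the pooled t-test for two groups", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6, 0.8)
    tk <- tukey_hsd(list(a = x, b = y))
    tp <- t.test(x, y, var.equal = TRUE)
    expect_equal(tk$q, abs(unname(tp$statistic)) * sqrt(2), tolerance = 1e-10)
    expect_equal(tk$p_value, tp$p.value, tolerance = 1e-9)
  }
})

test_that("tukey_hsd agrees with TukeyHSD on a balanced design and flags the shifted group", {
  set.seed(10)
  k <- 5; n <- 4
  groups <- split(rnorm(k * n, sd = 0.3), rep(1:k, each = n))
  groups[[3]] <- groups[[3]] + 5          # planted shift >> noise
  names(groups) <- paste0("g", 1:k)
  tk <- tukey_hsd(groups)
  involves3 <- tk$group_i == "g3" | tk$group_j == "g3"
  expect_true(all(tk$p_value[involves3] < 1e-4))
  expect_true(all(tk$p_value[!involves3] > 0.05))

  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), times = lengths(groups))))
  ref <- TukeyHSD(aov(y ~ g, data = df))$g
  # match pairs by label; base R uses ptukey (accuracy ~1e-7)
  for (r in seq_len(nrow(tk))) {
    lab <- paste0(tk$group_j[r], "-", tk$group_i[r])
    expect_equal(tk$p_value[r], ref[lab, "p adj"], tolerance = 1e-5)
  }

  # identical group means -> all pairwise p near 1
  same <- lapply(1:3, function(i) c(-1, 0, 1) + i * 0)
  expect_error(one_way_anova(lapply(1:3, function(i) rep(0, 3))), "degenerate")
  tk1 <- tukey_hsd(same)
  expect_true(all(tk1$p_value > 1 - 1e-6))
})

test_that("studentized_range_cdf matches the k = 2 Student-t reduction", {
  set.seed(12)
  for (i in 1:10) {
    t <- runif(1, 0.1, 5); df <- sample(c(3, 8, 12, 40), 1)
    expect_equal(1 - studentized_range_cdf(abs(t) * sqrt(2), 2, df),
                 2 * pt(-abs(t), df), tolerance = 1e-9)
  }
  expect_equal(studentized_range_cdf(0, 3, 10), 0)
  # secondary check against base ptukey (its own accuracy ~1e-7)
  expect_equal(studentized_range_cdf(3.5, 4, 12), ptukey(3.5, 4, 12),
               tolerance = 1e-5)
})

test_that("linear_fit matches the closed-form normal equations and lm", {
  x <- 1:6; y <- 2 * x
  fit <- linear_fit(x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    fit <- linear_fit(x, y)
    ora <- oracle_linfit(x, y)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-12)
    expect_equal(fit$r_squared, ora$r2, tolerance = 1e-12)
    expect_equal(fit$p_value, ora$p, tolerance = 1e-12)
    ref <- summary(lm(y ~ x))
    expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-10)
    expect_equal(fit$f_statistic, unname(ref$fstatistic[1]), tolerance = 1e-9)
    # internal identity: F = r^2 df2 / (1 - r^2)
    expect_equal(fit$f_statistic,
                 fit$r_squared * fit$df[2] / (1 - fit$r_squared),
                 tolerance = 1e-9)
  }

  # the 9-strain correlation design: n = 9 -> df (1, 7)
  set.seed(14)
  expect_equal(linear_fit(rnorm(9), rnorm(9))$df, c(1L, 7L))
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "constant predictor")
  expect_error(linear_fit(1:2, 1:2), "n >= 3")
})
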