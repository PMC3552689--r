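test_that("worked examples give the hand-computed statistics", {
  # balanced rank sums force H = 0
  r <- kruskal_wallis(list(c(1, 4), c(2, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$df1, 2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  r <- oneway_anova(list(c(1, 3), c(1, 3), c(1, 3)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- oneway_anova(list(1:3, 2:4, 3:5))  # SSB = 6, SSW = 6
  expect_equal(r$statistic, 3)
  expect_equal(c(r$df1, r$df2), c(2, 6))
  expect_equal(r$p_value, pf(3, 2, 6, lower.tail = FALSE))

  # groups split evenly around the pooled median: M's zero point
  r <- median_test(list(c(1, 10), c(2, 9)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- median_test(list(1:4, 5:8))  # pooled median 4.5, A = (0, 4)
  expect_equal(r$statistic, 8)
  expect_equal(r$df1, 1)
  expect_equal(r$p_value, pchisq(8, 1, lower.tail = FALSE))

  # equal group means annihilate the Welch numerator
  r <- welch_test(list(c(0, 2), c(-1, 3), c(0.5, 1.5)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("statistics agree with the reference implementations", {
  set.seed(101)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    g <- random_beta_groups(K)
    y <- unlist(g)
    grp <- factor(rep(seq_len(K), lengths(g)))

    kt <- suppressWarnings(kruskal.test(y, grp))
    kw <- kruskal_wallis(g)
    expect_equal(kw$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, kt$p.value, tolerance = 1e-12)

    ow <- oneway.test(y ~ grp, var.equal = TRUE)
    an <- oneway_anova(g)
    expect_equal(an$statistic, unname(ow$statistic), tolerance = 1e-12)
    expect_equal(an$p_value, ow$p.value, tolerance = 1e-12)

    wt <- oneway.test(y ~ grp, var.equal = FALSE)
    we <- welch_test(g)
    expect_equal(we$statistic, unname(wt$statistic), tolerance = 1e-10)
    expect_equal(we$df2, unname(wt$parameter[["denom df"]]), tolerance = 1e-10)
    expect_equal(we$p_value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis applies the tie correction", {
  set.seed(7)
  for (i in 1:10) {
    g <- lapply(c(6, 8, 7), function(m) sample(1:4, m, replace = TRUE))
    if (length(unique(unlist(g))) < 2) next
    kt <- suppressWarnings(kruskal.test(unlist(g), rep(1:3, lengths(g))))
    kw <- kruskal_wallis(g)
    expect_equal(kw$statistic, unname(kt$statistic), tolerance = 1e-12)
  }
})

test_that("rank and location-scale invariances hold", {
  set.seed(11)
  g <- random_beta_groups(3)
  kw1 <- kruskal_wallis(g)
  kw2 <- kruskal_wallis(lapply(g, function(v) exp(5 * v) - 2))  # monotone
  expect_equal(kw1$statistic, kw2$statistic)
  expect_equal(kw1$p_value, kw2$p_value)

  an1 <- oneway_anova(g)
  an2 <- oneway_anova(lapply(g, function(v) 3.7 * v - 1.2))
  expect_equal(an1$statistic, an2$statistic, tolerance = 1e-12)
})

test_that("Welch at K = 2 is the squared Welch t with its df", {
  set.seed(12)
  for (i in 1:20) {
    g <- list(rnorm(sample(3:15, 1)), rnorm(sample(3:15, 1), sd = 3))
    tt <- t.test(g[[1]], g[[2]])
    we <- welch_test(g)
    expect_equal(we$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(we$df2, unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("median M is zero iff every group splits evenly, and matches the
           contingency-table chi-square", {
  set.seed(13)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    n <- 2 * sample(2:6, K, replace = TRUE)  # even N guaranteed? no: even n_k
    g <- lapply(n, function(m) rbeta(m, 2, 2))
    r <- median_test(g)
    m <- median(unlist(g))
    A <- vapply(g, function(v) sum(v > m), 0)
    expect_equal(r$statistic == 0, all(A == n / 2))
    # with continuous data and even N, M equals the Pearson chi-square of
    # the 2 x K median-split table
    expect_equal(r$statistic, contingency_median_chisq(g), tolerance = 1e-10)
  }
})

test_that("degenerate and invalid inputs follow the contract", {
  const <- list(c(0.3, 0.3), c(0.3, 0.3, 0.3))
  for (f in list(kruskal_wallis, oneway_anova, median_test, welch_test)) {
    expect_warning(r <- f(const))
    expect_equal(r$p_value, 1)
  }
  # zero within-group variance with unequal means: p = 0 with warning
  expect_warning(r <- oneway_anova(list(c(1, 1), c(2, 2))))
  expect_equal(r$p_value, 0)
  # a zero-variance group makes the Welch weights infinite
  expect_error(welch_test(list(c(1, 1), c(2, 3))), "zero variance")
  expect_error(welch_test(list(1, 2:3)), "at least two")
  expect_error(grouped_samples(list(1:3)), "K >= 2")
  expect_error(grouped_samples(list(1:3, numeric(0))), "at least one")
  expect_error(grouped_samples(list(1:3, c(1, NA))), "finite")
  expect_error(grouped_samples(list(c(.1, .2), c(.3, 1.4)), check_range = TRUE),
               "\\[0, 1\\]")
})

test_that("p-values stay in [0, 1] under fuzzed group configurations", {
  set.seed(14)
  for (i in 1:60) {
    K <- sample(2:6, 1)
    g <- lapply(sample(2:10, K, replace = TRUE),
                function(m) rnorm(m, sd = runif(1, .01, 10)))
    for (f in list(kruskal_wallis, oneway_anova, median_test, welch_test)) {
      p <- suppressWarnings(f(g)$p_value)
      expect_true(p >= 0 && p <= 1)
    }
  }
})
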