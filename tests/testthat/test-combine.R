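test_that("Fisher combination matches the chi-square oracle", {
  # one p-value: identity
  for (p in c(1e-8, .01, .2, .5, .9, 1))
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  # frozen worked example: X = -2 * 2 * log(.05) = 11.983
  expect_equal(fisher_combine(c(.05, .05)),
               pchisq(-4 * log(.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(fisher_combine(c(.05, .05)), 4), 0.0175)
  # upper boundary
  expect_equal(fisher_combine(rep(1, 6)), 1)
})

test_that("weighted Z combination matches the normal oracle", {
  # Phi^-1(0.5) = 0 regardless of weights
  expect_equal(weighted_z_combine(rep(.5, 4), c(1, 10, 100, 3)), .5)
  # G = 1: identity
  for (p in c(1e-8, .01, .2, .5, .9))
    expect_equal(weighted_z_combine(p, 17), p, tolerance = 1e-12)
  # frozen worked example: Z = 2*10*qnorm(.95)/sqrt(200) = 2.3262
  z <- 20 * qnorm(.95) / sqrt(200)
  expect_equal(weighted_z_combine(c(.05, .05), c(10, 10)),
               pnorm(z, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(weighted_z_combine(c(.05, .05), c(10, 10)), 4), 0.0100)
  # equal p, equal n closed form: Z = sqrt(G) * qnorm(1 - p)
  for (G in c(2, 4, 6))
    expect_equal(weighted_z_combine(rep(.1, G), rep(30, G)),
                 pnorm(sqrt(G) * qnorm(.9), lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("both combiners are monotone and permutation-invariant", {
  set.seed(21)
  for (i in 1:30) {
    G <- sample(2:8, 1)
    p <- runif(G)
    n <- sample(10:100, G)
    for (cb in c("fisher", "z")) {
      base <- combine_pvalues(p, n, cb)
      j <- sample(G, 1)
      p2 <- p
      p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
      expect_gte(combine_pvalues(p2, n, cb) - base, -1e-12)
      perm <- sample(G)
      expect_equal(combine_pvalues(p[perm], n[perm], cb), base,
                   tolerance = 1e-12)
    }
  }
})

test_that("combined p is uniform under the uniform null (G = 6)", {
  set.seed(22)
  B <- 10000
  pf_ <- numeric(B); pz <- numeric(B)
  n <- c(45, 103, 103, 73, 109, 47)  # unequal stratum occupancy
  for (b in seq_len(B)) {
    p <- runif(6)
    pf_[b] <- fisher_combine(p)
    pz[b] <- weighted_z_combine(p, n)
  }
  ks <- function(x) max(abs(sort(x) - (seq_along(x) - 0.5) / length(x)))
  expect_lt(ks(pf_), 0.02)
  expect_lt(ks(pz), 0.02)
})

test_that("missing strata and boundary p-values follow the contract", {
  # NA strata are dropped: effective G
  expect_equal(fisher_combine(c(.05, NA, .05)), fisher_combine(c(.05, .05)))
  expect_equal(weighted_z_combine(c(.05, NA, .05), c(10, 99, 10)),
               weighted_z_combine(c(.05, .05), c(10, 10)))
  # no combinable stratum: missing, not 1
  expect_true(is.na(fisher_combine(c(NA_real_, NA_real_))))
  expect_true(is.na(weighted_z_combine(NA_real_, 10)))
  # boundaries are clamped, not an error
  expect_gte(fisher_combine(c(0, .5)), 0)
  expect_lte(weighted_z_combine(c(0, 1), c(5, 5)), 1)
  expect_error(fisher_combine(c(.5, 1.2)), "\\[0, 1\\]")
  expect_error(weighted_z_combine(.5, -3), "positive")
  expect_error(weighted_z_combine(c(.5, .5), 3), "same length")
})
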