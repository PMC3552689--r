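test_that("scenario validation enforces the preconditions", {
  expect_error(sim_scenario("beta", n = 30, a = 1, b = 2), "K >= 2")
  expect_error(sim_scenario("beta", n = c(30, 30), a = c(1, 1), b = c(2, 2),
                            R = 0), "positive")
  expect_error(sim_scenario("beta", n = c(30, 30), a = c(1, 1), b = c(2, 2),
                            alpha = 0), "alpha")
  expect_error(sim_scenario("beta", n = c(30, 30), a = c(1, -1), b = c(2, 2)),
               "positive")
  expect_error(sim_scenario("truncnorm", n = c(30, 30), mu = c(.5, .5),
                            sigma2 = c(.1, 0)), "sigma2")
  expect_error(sim_scenario("censnorm", n = c(30, 30), mu = c(.5, .5)),
               "censnorm")
  expect_error(sample_group("beta", list(a = 2, b = 5), 0), "at least 1")
})

test_that("samplers are symmetric where they should be and stay in range", {
  set.seed(41)
  x <- sample_group("beta", list(a = 3, b = 3), 10000)
  se <- sd(x) / 100
  expect_lt(abs(mean(x) - 0.5), 3 * se)

  y <- sample_group("truncnorm", list(mu = .5, sigma2 = .2), 10000)
  expect_lt(abs(mean(y) - 0.5), 3 * sd(y) / 100)
  expect_true(all(y > 0 & y < 1))

  z <- sample_group("censnorm", list(mu = .5, sd = .3), 10000)
  expect_lt(abs(mean(z) - 0.5), 3 * sd(z) / 100)
  expect_true(all(z >= 0 & z <= 1))
  expect_gt(sum(z == 0 | z == 1), 0)  # censoring leaves boundary mass
})

test_that("truncated-normal moments match the quadrature oracle", {
  mu <- 0.3; s2 <- 0.15; s <- sqrt(s2)
  Zc <- pnorm(1, mu, s) - pnorm(0, mu, s)
  m1 <- integrate(function(x) x * dnorm(x, mu, s) / Zc, 0, 1)$value
  m2 <- integrate(function(x) x^2 * dnorm(x, mu, s) / Zc, 0, 1)$value
  set.seed(42)
  x <- sample_group("truncnorm", list(mu = mu, sigma2 = s2), 1e5)
  expect_lt(abs(mean(x) - m1), 3 * sd(x) / sqrt(1e5))
  expect_lt(abs(mean(x^2) - m2), 3 * sd(x^2) / sqrt(1e5))
})

test_that("run_scenario is reproducible and respects alpha conventions", {
  sc <- sim_scenario("beta", n = c(8, 8, 8), a = c(2, 2, 2), b = c(5, 5, 5),
                     R = 50, seed = 99)
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$rejection, r2$rejection)
  expect_equal(r1$se, sqrt(r1$rejection * (1 - r1$rejection) / 50))

  # R = 1: result in {0, 1}, reproducible
  sc1 <- sim_scenario("beta", n = c(5, 5), a = c(1, 1), b = c(2, 2),
                      R = 1, seed = 3)
  r <- run_scenario(sc1, methods = "kw")
  expect_true(r$rejection %in% c(0, 1))
  expect_identical(run_scenario(sc1, methods = "kw")$rejection, r$rejection)

  # alpha = 1: every continuous-data p is < 1, so all replicates reject
  scA <- sim_scenario("beta", n = c(5, 5), a = c(1, 1), b = c(2, 2),
                      R = 20, alpha = 1, seed = 4)
  expect_equal(unname(run_scenario(scA, methods = "anova")$rejection), 1)
})

test_that("run_table derives reproducible child seeds and keeps table shape", {
  scs <- table1_scenarios()[1:3]
  t1 <- run_table(scs, methods = c("kw", "anova"), R = 100, seed = 17)
  t2 <- run_table(scs, methods = c("kw", "anova"), R = 100, seed = 17)
  expect_identical(t1[c("kw", "anova")], t2[c("kw", "anova")])
  expect_equal(dim(t1), c(3, 5))
  t3 <- run_table(scs, methods = c("kw", "anova"), R = 100, seed = 18)
  expect_false(identical(t1$kw, t3$kw))
  expect_error(run_table(list()), "at least one")
})

test_that("presets carry the benchmark's shapes and sizes", {
  t1 <- table1_scenarios()
  t2 <- table2_scenarios()
  expect_length(t1, 12)
  expect_length(t2, 10)
  expect_true(all(vapply(t1, function(s) s$K, 0) == 3))
  expect_true(all(vapply(t1, function(s) s$R, 0L) == 10000L))
  expect_equal(sum(vapply(t1, function(s) s$family == "beta", NA)), 8)
  expect_equal(t2[[4]]$n, c(20L, 30L, 40L))
  expect_equal(t2[[1]]$params$b, c(20, 25, 30))
})

test_that("every test holds its level under a null with n_k = 30", {
  # calibration at a symmetric beta null; the rejection rate at alpha = 0.05
  # must sit within +/-0.01 for all four tests. R = 30000 keeps the MC
  # standard error (~0.0012) well inside the band: the median test's true
  # level here is ~0.044 (its chi-square reference is conservative at
  # n = 30), leaving only ~0.006 of slack.
  sc <- sim_scenario("beta", n = c(30, 30, 30), a = c(10, 10, 10),
                     b = c(10, 10, 10), R = 30000, seed = 271)
  r <- run_scenario(sc)
  expect_true(all(abs(r$rejection - 0.05) <= 0.01))
})

test_that("power is monotone in effect size", {
  base <- c(0, .025, .05)
  rej <- vapply(c(1, 2), function(f) {
    sc <- sim_scenario("censnorm", n = c(30, 30, 30), mu = 0.45 + f * base,
                       sd = rep(.2, 3), R = 1000, seed = 55)
    run_scenario(sc, methods = "kw")$rejection
  }, 0)
  # doubling the spread of the group means must not reduce power (MC slack)
  expect_gt(rej[2], rej[1] - 0.03)
})
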