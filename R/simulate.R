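# Monte-Carlo harness for type-I-error and power studies of the four base
# tests under beta, truncated-normal and censored-normal beta-value models.

#' Define a simulation scenario
#'
#' A scenario fixes the data-generating family and per-group parameters for K
#' treatment groups, the group sizes, the replicate count, the significance
#' level and an optional seed.
#'
#' For `family = "beta"` give shape vectors `a` and `b` (one entry per
#' group). For `family = "truncnorm"` give `mu` and `sigma2`: the mean and
#' variance of the PARENT normal distribution, which is then truncated to
#' (0, 1) — the conventional TN(mu, sigma^2) parameterization. For
#' `family = "censnorm"` give `mu` and `sd`: a Normal(mu, sd^2) draw clipped
#' (censored) to `[0, 1]`, leaving point masses at the boundaries — the
#' variant the built-in benchmark presets use (see the package vignette for
#' why).
#'
#' @param family `"beta"`, `"truncnorm"` or `"censnorm"`.
#' @param n Integer vector of group sizes (length K >= 2).
#' @param a,b Beta shape parameters per group (family `"beta"`).
#' @param mu,sigma2 Parent-normal mean and variance per group (family
#'   `"truncnorm"`); `mu` is shared with `"censnorm"`.
#' @param sd Parent-normal standard deviation per group (family
#'   `"censnorm"`).
#' @param R Number of Monte-Carlo replicates (default 10000).
#' @param alpha Significance level in `(0, 1]` (default 0.05).
#' @param seed Optional RNG seed for reproducibility.
#' @param label Optional scenario label for tables.
#' @return An object of class `sim_scenario`.
#' @examples
#' sim_scenario("beta", n = c(30, 30, 30), a = c(1, 1, 1), b = c(2, 2, 2),
#'              R = 100, seed = 1)
#' @export
sim_scenario <- function(family = c("beta", "truncnorm", "censnorm"), n,
                         a = NULL, b = NULL, mu = NULL, sigma2 = NULL,
                         sd = NULL, R = 10000, alpha = 0.05, seed = NULL,
                         label = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  K <- length(n)
  if (K < 2L || any(n < 1L)) stop("need K >= 2 groups with n_k >= 1")
  if (length(R) != 1L || is.na(R) || R < 1) stop("'R' must be a positive integer")
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  if (family == "beta") {
    if (is.null(a) || is.null(b) || length(a) != K || length(b) != K)
      stop("beta family needs shape vectors 'a' and 'b' of length K")
    if (any(a <= 0) || any(b <= 0)) stop("beta shapes must be positive")
    params <- list(a = as.numeric(a), b = as.numeric(b))
  } else if (family == "truncnorm") {
    if (is.null(mu) || is.null(sigma2) || length(mu) != K ||
        length(sigma2) != K)
      stop("truncnorm family needs 'mu' and 'sigma2' of length K")
    if (any(sigma2 <= 0)) stop("sigma2 must be positive")
    params <- list(mu = as.numeric(mu), sigma2 = as.numeric(sigma2))
  } else {
    if (is.null(mu) || is.null(sd) || length(mu) != K || length(sd) != K)
      stop("censnorm family needs 'mu' and 'sd' of length K")
    if (any(sd <= 0)) stop("sd must be positive")
    params <- list(mu = as.numeric(mu), sd = as.numeric(sd))
  }
  if (is.null(label)) {
    pstr <- paste(vapply(params, function(v) paste(v, collapse = ","), ""),
                  collapse = "; ")
    label <- sprintf("%s(n=%s; %s)", family, paste(n, collapse = ","), pstr)
  }
  structure(list(family = family, n = n, K = K, params = params,
                 R = as.integer(R), alpha = alpha, seed = seed,
                 label = label),
            class = "sim_scenario")
}

# inverse-CDF sampler for the parent normal N(mean, sd^2) truncated to (0, 1)
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  u <- lo + stats::runif(n) * (hi - lo)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

# normal draw censored (clipped) to [0,1]; boundary point masses remain
rcensnorm01 <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
}

#' Draw one group of simulated beta-values
#'
#' @param family `"beta"`, `"truncnorm"` or `"censnorm"`.
#' @param params For `"beta"`, a list with scalars `a`, `b`; for
#'   `"truncnorm"`, scalars `mu`, `sigma2` of the parent normal truncated to
#'   (0, 1) (inverse-CDF sampling); for `"censnorm"`, scalars `mu`, `sd` of
#'   a normal clipped to `[0, 1]`.
#' @param n Number of draws.
#' @return Numeric vector of length `n` with values in (0, 1) (`[0, 1]` for
#'   `"censnorm"`).
#' @examples
#' set.seed(1); mean(sample_group("beta", list(a = 2, b = 2), 1000))
#' @export
sample_group <- function(family = c("beta", "truncnorm", "censnorm"),
                         params, n) {
  family <- match.arg(family)
  if (n < 1) stop("'n' must be at least 1")
  switch(family,
    beta = {
      if (is.null(params$a) || is.null(params$b) || params$a <= 0 ||
          params$b <= 0)
        stop("beta family requires positive 'a' and 'b'")
      stats::rbeta(n, params$a, params$b)
    },
    truncnorm = {
      if (is.null(params$mu) || is.null(params$sigma2) || params$sigma2 <= 0)
        stop("truncnorm family requires 'mu' and positive 'sigma2'")
      rtruncnorm01(n, params$mu, sqrt(params$sigma2))
    },
    censnorm = {
      if (is.null(params$mu) || is.null(params$sd) || params$sd <= 0)
        stop("censnorm family requires 'mu' and positive 'sd'")
      rcensnorm01(n, params$mu, params$sd)
    })
}

draw_scenario_groups <- function(sc) {
  switch(sc$family,
    beta = lapply(seq_len(sc$K), function(k)
      stats::rbeta(sc$n[k], sc$params$a[k], sc$params$b[k])),
    truncnorm = lapply(seq_len(sc$K), function(k)
      rtruncnorm01(sc$n[k], sc$params$mu[k], sqrt(sc$params$sigma2[k]))),
    censnorm = lapply(seq_len(sc$K), function(k)
      rcensnorm01(sc$n[k], sc$params$mu[k], sc$params$sd[k])))
}

#' Run one simulation scenario
#'
#' For each of R replicates, draws the K groups once and applies every
#' requested base test to the SAME draw (common random numbers, so method
#' differences are compared fairly), recording a rejection when p < alpha
#' (strict). Fully reproducible given the scenario's seed.
#'
#' @param sc A [sim_scenario()].
#' @param methods Base tests to evaluate, subset of
#'   `c("kw", "anova", "median", "welch")`.
#' @return An object of class `sim_result`: list with `rejection` (named
#'   proportions), `se` (Monte-Carlo standard errors
#'   `sqrt(p*(1-p)/R)`), `R`, and the scenario.
#' @examples
#' sc <- sim_scenario("beta", n = c(10, 10), a = c(2, 2), b = c(5, 5),
#'                    R = 200, seed = 42)
#' run_scenario(sc, methods = "kw")
#' @export
run_scenario <- function(sc, methods = c("kw", "anova", "median", "welch")) {
  stopifnot(inherits(sc, "sim_scenario"))
  methods <- match.arg(methods, BASE_METHODS, several.ok = TRUE)
  if (!is.null(sc$seed)) set.seed(sc$seed)
  nrej <- stats::setNames(numeric(length(methods)), methods)
  for (r in seq_len(sc$R)) {
    groups <- draw_scenario_groups(sc)
    for (m in methods)
      if (base_p(groups, m) < sc$alpha) nrej[m] <- nrej[m] + 1
  }
  prop <- nrej / sc$R
  structure(list(rejection = prop,
                 se = sqrt(prop * (1 - prop) / sc$R),
                 R = sc$R, alpha = sc$alpha, scenario = sc),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Scenario:", x$scenario$label, "\n")
  cat(sprintf("R = %d, alpha = %g\n", x$R, x$alpha))
  print(round(x$rejection, 4))
  invisible(x)
}

#' Run a list of scenarios into a results table
#'
#' One row per scenario, one rejection-proportion column per method —
#' the layout of a type-I-error or power table. Per-scenario child seeds are
#' derived from `seed` by `set.seed(seed); sample.int(2^31 - 2, #scenarios)`,
#' so rows are individually reproducible.
#'
#' @param scenarios List of [sim_scenario()] objects.
#' @param methods Base tests to evaluate.
#' @param R Optional replicate-count override applied to every scenario.
#' @param seed Optional master seed; overrides per-scenario seeds.
#' @return Data frame with columns `label`, `family`, `R`, then one column
#'   per method; the full `sim_result` list is attached as attribute
#'   `"results"`.
#' @examples
#' tab <- run_table(table1_scenarios()[1:2], methods = "anova", R = 100,
#'                  seed = 7)
#' tab
#' @export
run_table <- function(scenarios, methods = c("kw", "anova", "median", "welch"),
                      R = NULL, seed = NULL) {
  if (length(scenarios) < 1L) stop("need at least one scenario")
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  methods <- match.arg(methods, BASE_METHODS, several.ok = TRUE)
  if (!is.null(seed)) {
    set.seed(seed)
    child <- sample.int(2^31 - 2, length(scenarios))
  }
  results <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (!is.null(R)) sc$R <- as.integer(R)
    if (!is.null(seed)) sc$seed <- child[i]
    results[[i]] <- run_scenario(sc, methods = methods)
  }
  tab <- data.frame(
    label = vapply(results, function(r) r$scenario$label, ""),
    family = vapply(results, function(r) r$scenario$family, ""),
    R = vapply(results, function(r) r$R, 0L),
    stringsAsFactors = FALSE
  )
  for (m in methods)
    tab[[m]] <- vapply(results, function(r) r$rejection[[m]], 0)
  attr(tab, "results") <- results
  tab
}
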