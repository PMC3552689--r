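# K-sample location tests applied within one age stratum.
#
# All four tests share the same contract: a grouped_samples (or bare list of
# numeric vectors) in, a dml_test out, with the omnibus p-value referred to a
# chi-square (KW, median) or F (ANOVA, Welch) distribution. Degenerate input
# (every value identical) yields p = 1 with a warning rather than an error so
# that genome-scale runs do not abort on invariant loci.

new_dml_test <- function(statistic, df1, df2, p_value, method) {
  structure(
    list(statistic = statistic, df1 = df1, df2 = df2,
         p_value = p_value, method = method),
    class = "dml_test"
  )
}

#' @export
print.dml_test <- function(x, ...) {
  lbl <- c(kw = "Kruskal-Wallis rank sum test",
           anova = "One-way analysis of variance",
           median = "Mood's median test",
           welch = "Welch heteroscedastic F test")[[x$method]]
  cat(lbl, "\n")
  df <- if (is.null(x$df2) || is.na(x$df2)) sprintf("df = %g", x$df1)
        else sprintf("df1 = %g, df2 = %.4g", x$df1, x$df2)
  cat(sprintf("statistic = %.6g, %s, p-value = %.6g\n", x$statistic, df, x$p_value))
  invisible(x)
}

all_identical_values <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  all(x == x[1L])
}

degenerate_result <- function(method, df1, msg) {
  warning(msg, call. = FALSE)
  new_dml_test(0, df1, if (method %in% c("anova", "welch")) NA_real_ else NULL,
               1, method)
}

# ---- statistic cores (fast paths shared with the simulation harness) -------
# Each takes a bare list of numeric vectors assumed valid and non-degenerate,
# and returns list(stat, df1, df2, p).

kw_core <- function(groups) {
  K <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  ends <- cumsum(n)
  cs <- cumsum(r)
  Rk <- cs[ends] - c(0, cs[ends[-K]])
  H <- 12 / (N * (N + 1)) * sum(Rk * Rk / n) - 3 * (N + 1)
  if (anyDuplicated(x)) {
    t <- rle(sort(x))$lengths
    corr <- 1 - sum(t^3 - t) / (N^3 - N)
    if (corr <= 0) return(list(stat = 0, df1 = K - 1, df2 = NULL, p = 1))
    H <- H / corr
  }
  H <- max(H, 0)  # guard tiny negative rounding
  list(stat = H, df1 = K - 1, df2 = NULL,
       p = stats::pchisq(H, K - 1, lower.tail = FALSE))
}

anova_core <- function(groups) {
  K <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 0)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(K), function(k) sum((groups[[k]] - means[k])^2), 0))
  df1 <- K - 1
  df2 <- N - K
  if (ssw == 0) {
    # zero within-group variance: unequal means are then infinitely significant
    if (ssb > 0) {
      warning("zero within-group variance with unequal means; p = 0",
              call. = FALSE)
      return(list(stat = Inf, df1 = df1, df2 = df2, p = 0))
    }
    return(list(stat = 0, df1 = df1, df2 = df2, p = 1))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(stat = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

median_core <- function(groups) {
  K <- length(groups)
  n <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  m <- stats::median(x)
  A <- vapply(groups, function(g) sum(g > m), 0)
  M <- 4 * sum((A - n / 2)^2 / n)
  list(stat = M, df1 = K - 1, df2 = NULL,
       p = stats::pchisq(M, K - 1, lower.tail = FALSE))
}

welch_core <- function(groups) {
  K <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  wk <- n / v
  w <- sum(wk)
  mu <- sum(wk * means) / w
  hk <- (1 - wk / w)^2 / (n - 1)
  sh <- sum(hk)
  W <- (sum(wk * (means - mu)^2) / (K - 1)) /
       (1 + 2 * (K - 2) / (K^2 - 1) * sh)
  f <- (K^2 - 1) / (3 * sh)
  list(stat = W, df1 = K - 1, df2 = f,
       p = stats::pf(W, K - 1, f, lower.tail = FALSE))
}

# ---- exported tests ---------------------------------------------------------

#' Kruskal-Wallis rank test within one stratum
#'
#' Rank-based K-sample omnibus test with the standard tie correction; the H
#' statistic is referred to a chi-square distribution with K - 1 degrees of
#' freedom. Monotone transforms of the data leave the result unchanged.
#'
#' @param samples A [grouped_samples] object or a bare list of K >= 2 numeric
#'   vectors.
#' @return A `dml_test` with elements `statistic`, `df1`, `p_value`, and
#'   `method = "kw"`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskal_wallis <- function(samples) {
  gs <- as_grouped_samples(samples)
  if (all_identical_values(gs$groups))
    return(degenerate_result("kw", gs$K - 1,
                             "all values identical; Kruskal-Wallis p set to 1"))
  r <- kw_core(gs$groups)
  new_dml_test(r$stat, r$df1, NULL, r$p, "kw")
}

#' One-way ANOVA within one stratum
#'
#' Classical one-way F test with df1 = K - 1 and df2 = N - K.
#'
#' @inheritParams kruskal_wallis
#' @return A `dml_test` with `method = "anova"`.
#' @examples
#' oneway_anova(list(1:3, 2:4, 3:5))  # F = 3 on (2, 6) df
#' @export
oneway_anova <- function(samples) {
  gs <- as_grouped_samples(samples)
  if (gs$N <= gs$K)
    stop("one-way ANOVA requires N > K (positive residual df)")
  if (all_identical_values(gs$groups))
    return(degenerate_result("anova", gs$K - 1,
                             "all values identical; ANOVA p set to 1"))
  r <- anova_core(gs$groups)
  new_dml_test(r$stat, r$df1, r$df2, r$p, "anova")
}

#' Mood's median test within one stratum
#'
#' Counts, per condition group, the observations strictly exceeding the pooled
#' median (A_k) and forms M = 4 * sum((A_k - n_k/2)^2 / n_k), referred to a
#' chi-square distribution with K - 1 degrees of freedom (large-sample
#' approximation). Beta-values are effectively continuous, so ties at the
#' pooled median are rare; ties count as not exceeding.
#'
#' @inheritParams kruskal_wallis
#' @return A `dml_test` with `method = "median"`.
#' @examples
#' median_test(list(1:4, 5:8))  # M = 8 on 1 df
#' @export
median_test <- function(samples) {
  gs <- as_grouped_samples(samples)
  if (all_identical_values(gs$groups))
    return(degenerate_result("median", gs$K - 1,
                             "all values equal the pooled median; p set to 1"))
  r <- median_core(gs$groups)
  new_dml_test(r$stat, r$df1, NULL, r$p, "median")
}

#' Welch's heteroscedastic one-way test within one stratum
#'
#' Precision-weighted one-way test robust to unequal group variances:
#' with weights w_k = n_k / s_k^2, w = sum(w_k), weighted grand mean mu,
#' and h_k = (1 - w_k/w)^2 / (n_k - 1),
#' \deqn{W = \frac{\sum_k w_k (\bar x_k - \hat\mu)^2 / (K-1)}
#'            {1 + [2(K-2)/(K^2-1)] \sum_k h_k}}
#' is referred to an F distribution with K - 1 and
#' f = (K^2 - 1) / (3 sum(h_k)) degrees of freedom. At K = 2 this is exactly
#' the squared two-sample Welch t statistic with the Welch-Satterthwaite df.
#'
#' @inheritParams kruskal_wallis
#' @return A `dml_test` with `method = "welch"`, `df2` holding f.
#' @examples
#' welch_test(list(c(0, 2), c(-1, 3), c(1, 1.5)))
#' @export
welch_test <- function(samples) {
  gs <- as_grouped_samples(samples)
  if (any(gs$n < 2L))
    stop("Welch test requires every group to have at least two observations")
  if (all_identical_values(gs$groups))
    return(degenerate_result("welch", gs$K - 1,
                             "all values identical; Welch p set to 1"))
  v <- vapply(gs$groups, stats::var, 0)
  if (any(v == 0))
    stop("Welch test undefined when a group has zero variance ",
         "(infinite precision weight)")
  r <- welch_core(gs$groups)
  new_dml_test(r$stat, r$df1, r$df2, r$p, "welch")
}

# ---- dispatch used by pipeline and simulation -------------------------------

BASE_METHODS <- c("kw", "anova", "median", "welch")

# p-value-only fast path for valid, non-degenerate groups (simulation loop).
base_p <- function(groups, method) {
  switch(method,
         kw = kw_core(groups)$p,
         anova = anova_core(groups)$p,
         median = median_core(groups)$p,
         welch = welch_core(groups)$p,
         stop("unknown method: ", method))
}

# Pipeline-safe p-value: returns NA_real_ for untestable strata instead of
# erroring, and 1 for degenerate (constant) data. `groups` is a bare list
# already stripped of missing values; empty groups must be dropped upstream.
safe_base_p <- function(groups, method) {
  if (length(groups) < 2L) return(NA_real_)
  if (method == "welch") {
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) return(NA_real_)
    if (all_identical_values(groups)) return(1)
    if (any(vapply(groups, stats::var, 0) == 0)) return(NA_real_)
    return(welch_core(groups)$p)
  }
  if (all_identical_values(groups)) return(1)
  if (method == "anova") {
    if (sum(lengths(groups)) <= length(groups)) return(NA_real_)
    return(anova_core(groups)$p)
  }
  base_p(groups, method)
}
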