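# Independent oracles used across the suite. None of these call dmstrat's
# own statistic code.

# Exact permutation p-value for the Kruskal-Wallis test, using
# stats::kruskal.test as the statistic engine and full enumeration of the
# distinct group assignments (feasible for K = 3, n_k = 3: 1680 splits).
perm_kw_p <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  stopifnot(length(groups) == 3L)
  idx <- seq_along(x)
  h_of <- function(assign)
    unname(suppressWarnings(stats::kruskal.test(x, factor(assign))$statistic))
  h_obs <- h_of(rep(seq_len(3), n))
  total <- 0L; count <- 0L
  for (c1 in utils::combn(idx, n[1], simplify = FALSE)) {
    rest <- setdiff(idx, c1)
    for (c2 in utils::combn(rest, n[2], simplify = FALSE)) {
      assign <- integer(length(x))
      assign[c1] <- 1L; assign[c2] <- 2L
      assign[setdiff(rest, c2)] <- 3L
      total <- total + 1L
      if (h_of(assign) >= h_obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# Pearson chi-square statistic of the 2 x K median-split contingency table
# (counts above / not-above the pooled median), built from scratch.
contingency_median_chisq <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  m <- stats::median(x)
  above <- vapply(groups, function(g) sum(g > m), 0)
  tab <- rbind(above, lengths(groups) - above)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

random_beta_groups <- function(K, nmin = 3, nmax = 12) {
  n <- sample(nmin:nmax, K, replace = TRUE)
  lapply(n, function(m) stats::rbeta(m, 2, 5))
}
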