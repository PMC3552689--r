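# Combining G independent per-stratum p-values into one per-locus p-value.
#
# Missing entries (untestable strata) are dropped before combination, so the
# effective G counts only the strata that produced a p-value. If no stratum
# is combinable the result is NA, not 1.

# clamp away the boundaries where log / Phi^-1 are undefined
clamp_p <- function(p, upper = FALSE) {
  p <- pmax(p, .Machine$double.xmin)
  if (upper) p <- pmin(p, 1 - .Machine$double.eps / 2)
  p
}

drop_missing_strata <- function(p, n = NULL) {
  keep <- !is.na(p)
  if (!is.null(n)) {
    if (length(n) != length(p))
      stop("'p' and 'n' must have the same length (one entry per stratum)")
    keep <- keep & !is.na(n)
  }
  list(p = p[keep], n = if (is.null(n)) NULL else n[keep])
}

#' Fisher's method for combining p-values
#'
#' Combines G independent p-values through X = -2 * sum(log(p_g)), referred
#' to a chi-square distribution with 2G degrees of freedom. With G = 1 this
#' is the identity map. Missing entries are dropped first (effective-G
#' convention); an all-missing input returns `NA`.
#'
#' @param p Numeric vector of per-stratum p-values in `(0, 1]`; `NA` entries
#'   mark untestable strata and are ignored. Zeros are clamped to the
#'   smallest positive double before taking logs.
#' @return A single combined p-value in `[0, 1]`, or `NA` if no stratum is
#'   combinable.
#' @examples
#' fisher_combine(c(0.05, 0.05))   # ~0.0175
#' fisher_combine(0.2)             # identity at G = 1
#' @seealso [weighted_z_combine()]
#' @export
fisher_combine <- function(p) {
  p <- drop_missing_strata(as.numeric(p))$p
  G <- length(p)
  if (G == 0L) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  X <- -2 * sum(log(clamp_p(p)))
  stats::pchisq(X, df = 2 * G, lower.tail = FALSE)
}

#' Sample-size-weighted Z (Stouffer) combination of p-values
#'
#' Combines G independent one-sided p-values through
#' Z = sum(n_g * qnorm(1 - p_g)) / sqrt(sum(n_g^2)), which is standard normal
#' under the null; the combined p-value is 1 - Phi(Z) (one-sided — the
#' per-stratum tests are omnibus, so small p always means evidence against
#' the null). Weights n_g are the stratum sample sizes actually used.
#'
#' @inheritParams fisher_combine
#' @param n Positive numeric vector of stratum sample sizes, same length as
#'   `p`.
#' @return A single combined p-value in `[0, 1]`, or `NA` if no stratum is
#'   combinable.
#' @examples
#' weighted_z_combine(c(0.05, 0.05), n = c(10, 10))  # ~0.0100
#' @export
weighted_z_combine <- function(p, n) {
  d <- drop_missing_strata(as.numeric(p), as.numeric(n))
  G <- length(d$p)
  if (G == 0L) return(NA_real_)
  if (any(d$p < 0 | d$p > 1)) stop("p-values must lie in [0, 1]")
  if (any(d$n <= 0)) stop("stratum sizes 'n' must be positive")
  pg <- clamp_p(d$p, upper = TRUE)
  z <- sum(d$n * stats::qnorm(pg, lower.tail = FALSE)) / sqrt(sum(d$n^2))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Combine per-stratum p-values
#'
#' Thin dispatcher over [fisher_combine()] and [weighted_z_combine()].
#'
#' @inheritParams weighted_z_combine
#' @param method `"fisher"` or `"z"`.
#' @return Combined p-value (scalar).
#' @export
combine_pvalues <- function(p, n = NULL, method = c("fisher", "z")) {
  method <- match.arg(method)
  if (method == "fisher") fisher_combine(p)
  else {
    if (is.null(n)) stop("the weighted Z combiner requires stratum sizes 'n'")
    weighted_z_combine(p, n)
  }
}

COMBINERS <- c("fisher", "z")
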