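#' Group observations by condition
#'
#' Container for the per-condition samples tested within one age stratum:
#' an ordered list of K numeric vectors of beta-values (or, for simulation
#' inputs, arbitrary finite reals).
#'
#' @param groups A list of K >= 2 numeric vectors, one per condition, each
#'   with at least one finite observation.
#' @param check_range If `TRUE`, require all values to lie in `[0, 1]`
#'   (beta-value data). Defaults to `FALSE` so simulation and unit-test
#'   inputs may be any reals.
#'
#' @return An object of class `grouped_samples` with elements `groups`
#'   (the list), `n` (group sizes), `N` (total) and `K`.
#' @examples
#' gs <- grouped_samples(list(c(.1, .2, .3), c(.4, .5, .6)))
#' gs$n
#' @export
grouped_samples <- function(groups, check_range = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two (K >= 2) numeric vectors")
  groups <- lapply(groups, function(g) as.numeric(g))
  n <- lengths(groups)
  if (any(n < 1L))
    stop("every condition group must contain at least one observation")
  vals <- unlist(groups, use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("all values must be finite; drop missing values before grouping")
  if (check_range && any(vals < 0 | vals > 1))
    stop("beta-values must lie in [0, 1]")
  structure(
    list(groups = groups, n = as.integer(n), N = sum(n), K = length(groups)),
    class = "grouped_samples"
  )
}

#' @export
print.grouped_samples <- function(x, ...) {
  cat("Grouped samples: K =", x$K, "conditions, n =",
      paste(x$n, collapse = ", "), "(N =", paste0(x$N, ")\n"))
  invisible(x)
}

# Coerce a list or grouped_samples to a validated grouped_samples.
as_grouped_samples <- function(samples, check_range = FALSE) {
  if (inherits(samples, "grouped_samples")) samples
  else grouped_samples(samples, check_range = check_range)
}
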