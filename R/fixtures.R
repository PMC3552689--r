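# Synthetic fixture generator: emulates the structure of an Illumina-array
# study (beta matrix + sample annotation) with planted differential loci, so
# every test and example can build its data in code.

#' Specify a synthetic methylation fixture
#'
#' Describes a cohort of K condition groups observed in G age strata and a
#' beta-value matrix whose null loci are i.i.d. across conditions and whose
#' differential loci get per-condition parameter offsets, constant across
#' strata. Ages are drawn uniformly within each stratum's bin.
#'
#' @param n_loci Total number of loci.
#' @param n_differential Number of planted differential loci
#'   (`<= n_loci`).
#' @param conditions Character vector of K >= 2 condition labels.
#' @param n_per_group Samples per condition per stratum: a scalar, or a
#'   K x G matrix for unequal occupancy.
#' @param age_edges,age_max Stratum bin edges and final right closure (G =
#'   `length(age_edges)` strata; defaults give three strata 50-55, 55-60,
#'   60-and-over capped at 65).
#' @param family Null distribution family: `"beta"`, `"truncnorm"` or
#'   `"censnorm"` (see [sample_group()]).
#' @param null_params Family parameters of null loci: list with scalars
#'   `a`, `b` (beta), `mu`, `sigma2` (truncated normal) or `mu`, `sd`
#'   (censored normal). Default
#'   Beta(5, 20): a right-skewed, mostly-unmethylated locus (mean 0.2),
#'   typical of array beta-values.
#' @param effect Per-condition parameter offsets applied to differential
#'   loci: list with vectors `da`, `db` (or `dmu`, `dsigma2` / `dmu`, `dsd`)
#'   of length K.
#'   Default `db = c(0, 5, 10)` shifts group means downward, mirroring the
#'   benchmark power settings.
#' @param effect_scales Optional numeric vector (length `n_differential`)
#'   multiplying the offsets per differential locus, for graded effect
#'   sizes. Default all 1.
#' @param seed RNG seed; fixtures are fully reproducible.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_loci = 1000, n_differential = 50,
                         conditions = c("control", "pre_treat", "post_treat"),
                         n_per_group = 10,
                         age_edges = c(50, 55, 60), age_max = 65,
                         family = c("beta", "truncnorm", "censnorm"),
                         null_params = list(a = 5, b = 20),
                         effect = list(da = c(0, 0, 0), db = c(0, 5, 10)),
                         effect_scales = NULL,
                         seed = 1L) {
  family <- match.arg(family)
  K <- length(conditions)
  G <- length(age_edges)
  if (K < 2L) stop("need at least two conditions")
  if (n_differential > n_loci) stop("n_differential must not exceed n_loci")
  if (is.matrix(n_per_group)) {
    if (!all(dim(n_per_group) == c(K, G)))
      stop("'n_per_group' matrix must be K x G")
  } else {
    n_per_group <- matrix(n_per_group, K, G)
  }
  if (any(n_per_group < 1)) stop("all group sizes must be >= 1")
  if (is.null(effect_scales)) effect_scales <- rep(1, n_differential)
  if (length(effect_scales) != n_differential)
    stop("'effect_scales' must have length n_differential")
  eff_names <- switch(family, beta = c("da", "db"),
                      truncnorm = c("dmu", "dsigma2"),
                      censnorm = c("dmu", "dsd"))
  for (nm in eff_names) {
    if (is.null(effect[[nm]])) effect[[nm]] <- rep(0, K)
    if (length(effect[[nm]]) != K)
      stop("'effect$", nm, "' must have length K")
  }
  structure(list(n_loci = as.integer(n_loci),
                 n_differential = as.integer(n_differential),
                 conditions = conditions, K = K, G = G,
                 n_per_group = n_per_group,
                 age_edges = age_edges, age_max = age_max,
                 family = family, null_params = null_params,
                 effect = effect, effect_scales = effect_scales,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_group_params <- function(spec, k, scale) {
  np <- spec$null_params
  if (spec$family == "beta") {
    a <- np$a + scale * spec$effect$da[k]
    b <- np$b + scale * spec$effect$db[k]
    if (a <= 0 || b <= 0) stop("effect offsets drive beta shapes non-positive")
    list(a = a, b = b)
  } else if (spec$family == "truncnorm") {
    s2 <- np$sigma2 + scale * spec$effect$dsigma2[k]
    if (s2 <= 0) stop("effect offsets drive sigma2 non-positive")
    list(mu = np$mu + scale * spec$effect$dmu[k], sigma2 = s2)
  } else {
    s <- np$sd + scale * spec$effect$dsd[k]
    if (s <= 0) stop("effect offsets drive sd non-positive")
    list(mu = np$mu + scale * spec$effect$dmu[k], sd = s)
  }
}

#' Generate a synthetic methylation fixture
#'
#' Materialises a [fixture_spec()] into a beta-value matrix, a sample
#' annotation table and a truth table marking the planted differential loci.
#' Same seed, same files, bit for bit.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `beta` (loci x samples matrix), `annotation`
#'   (data frame: sample_id, condition, age), and `truth` (data frame:
#'   locus, differential flag, effect scale).
#' @examples
#' fix <- generate_fixture(fixture_spec(n_loci = 50, n_differential = 5,
#'                                      seed = 9))
#' dim(fix$beta); table(fix$truth$differential)
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  K <- spec$K; G <- spec$G
  edges <- spec$age_edges
  hi <- c(edges[-1], spec$age_max)

  # annotation: samples blocked by stratum then condition
  cond <- integer(0); strat <- integer(0)
  for (g in seq_len(G))
    for (k in seq_len(K)) {
      cond <- c(cond, rep(k, spec$n_per_group[k, g]))
      strat <- c(strat, rep(g, spec$n_per_group[k, g]))
    }
  N <- length(cond)
  age <- stats::runif(N, edges[strat], hi[strat])
  annotation <- data.frame(
    sample_id = sprintf("S%04d", seq_len(N)),
    condition = spec$conditions[cond],
    age = round(age, 2),
    stringsAsFactors = FALSE
  )

  loci <- sprintf("cg%05d", seq_len(spec$n_loci))
  is_diff <- rep(FALSE, spec$n_loci)
  if (spec$n_differential > 0) is_diff[seq_len(spec$n_differential)] <- TRUE
  scales <- rep(0, spec$n_loci)
  scales[is_diff] <- spec$effect_scales

  beta <- matrix(NA_real_, spec$n_loci, N,
                 dimnames = list(loci, annotation$sample_id))
  n_null <- sum(!is_diff)
  if (n_null > 0)
    beta[!is_diff, ] <- matrix(
      sample_group(spec$family, spec$null_params, n_null * N), n_null, N)
  for (i in which(is_diff))
    for (k in seq_len(K)) {
      cols <- which(cond == k)
      beta[i, cols] <- sample_group(
        spec$family, fixture_group_params(spec, k, scales[i]), length(cols))
    }

  truth <- data.frame(locus = loci, differential = is_diff,
                      effect_scale = scales, stringsAsFactors = FALSE)
  list(beta = beta, annotation = annotation, truth = truth)
}

#' Write a generated fixture to a directory
#'
#' Emits `matrix.tsv`, `annotation.tsv` and `truth.tsv`.
#'
#' @param fix List from [generate_fixture()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_beta_matrix(fix$beta, paths[["matrix"]])
  write_annotation(fix$annotation, paths[["annotation"]])
  utils::write.table(fix$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
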