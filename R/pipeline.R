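# Genome-scale stratified testing: QC-filter samples, bin ages, run a base
# test within each age stratum per locus, combine per-stratum p-values, count
# significant loci at cutoffs.

DEFAULT_AGE_EDGES <- c(50, 55, 60, 65, 70, 75)

#' Quality-control filter on the sample annotation
#'
#' Retains samples with bisulfite-conversion intensity `bs_value >= bs_min`,
#' `coverage >= coverage_min` and `age <= age_max`. A sample lacking an
#' optional QC column (or with `NA` there) passes that criterion. Removals
#' and their reasons are attached as the `"removed"` attribute and reported
#' via `message()`.
#'
#' @param annot Data frame with columns `sample_id`, `condition`, `age` and
#'   optionally `bs_value`, `coverage`.
#' @param bs_min Minimum bisulfite-conversion intensity (default 4000;
#'   samples strictly below are removed).
#' @param coverage_min Minimum coverage rate as a fraction (default 0.95;
#'   strictly below removed).
#' @param age_max Maximum age in years (default 80; strictly above removed).
#' @param quiet Suppress the removal message.
#' @return The filtered annotation, with attribute `removed`: a data frame of
#'   `sample_id` and `reason`.
#' @examples
#' ann <- data.frame(sample_id = c("a", "b"), condition = c("x", "y"),
#'                   age = c(60, 81), bs_value = c(5000, 5000),
#'                   coverage = c(0.99, 0.99))
#' qc_filter(ann)   # drops "b" (age > 80)
#' @export
qc_filter <- function(annot, bs_min = 4000, coverage_min = 0.95,
                      age_max = 80, quiet = FALSE) {
  stopifnot(is.data.frame(annot), "sample_id" %in% names(annot),
            "age" %in% names(annot))
  if (!all(is.finite(c(bs_min, coverage_min, age_max))))
    stop("QC thresholds must be finite")
  n <- nrow(annot)
  pass_opt <- function(col, thr) {
    if (!col %in% names(annot)) return(rep(TRUE, n))
    v <- annot[[col]]
    is.na(v) | v >= thr
  }
  ok_bs <- pass_opt("bs_value", bs_min)
  ok_cov <- pass_opt("coverage", coverage_min)
  ok_age <- !is.na(annot$age) & annot$age <= age_max
  keep <- ok_bs & ok_cov & ok_age
  reason <- character(0)
  if (any(!keep)) {
    reason <- vapply(which(!keep), function(i) {
      paste(c(if (!ok_bs[i]) sprintf("bs_value < %g", bs_min),
              if (!ok_cov[i]) sprintf("coverage < %g", coverage_min),
              if (!ok_age[i]) sprintf("age > %g (or missing)", age_max)),
            collapse = "; ")
    }, "")
  }
  removed <- data.frame(sample_id = annot$sample_id[!keep], reason = reason,
                        stringsAsFactors = FALSE)
  if (!quiet && nrow(removed) > 0)
    message("qc_filter: removed ", nrow(removed), " of ", n, " samples")
  out <- annot[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no samples survive QC filtering (empty cohort)")
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Assign samples to age strata
#'
#' Bins ages by half-open intervals `[edge_i, edge_{i+1})`; the last bin is
#' closed on the right at `age_max` and labelled `"<last edge>_over"`. Ages
#' below the first edge or above `age_max` are unassignable and yield `NA`
#' with a warning (drop them upstream) or an error, per `on_unassigned`.
#'
#' @param age Numeric vector of ages in years.
#' @param edges Strictly increasing bin edges; the default reproduces the
#'   six groups 50-55, 55-60, 60-65, 65-70, 70-75, 75-and-over.
#' @param age_max Right closure of the final bin (default 80).
#' @param on_unassigned `"warn"` (default) marks unassignable ages `NA`;
#'   `"error"` aborts.
#' @return Factor of stratum labels, levels ordered by age.
#' @examples
#' assign_age_groups(c(54.9, 55, 80))
#' @export
assign_age_groups <- function(age, edges = DEFAULT_AGE_EDGES, age_max = 80,
                              on_unassigned = c("warn", "error")) {
  on_unassigned <- match.arg(on_unassigned)
  if (is.unsorted(edges, strictly = TRUE))
    stop("age bin edges must be strictly increasing")
  if (age_max <= edges[length(edges)])
    stop("'age_max' must exceed the last bin edge")
  nb <- length(edges)
  labels <- c(paste0(edges[-nb], "_", edges[-1]), paste0(edges[nb], "_over"))
  idx <- findInterval(age, edges)           # 0 = below first edge
  idx[!is.na(age) & age > age_max] <- 0L
  idx[is.na(age)] <- 0L
  if (any(idx == 0L)) {
    bad <- which(idx == 0L)
    msg <- paste0(length(bad), " sample(s) outside [",
                  edges[1], ", ", age_max, "] cannot be assigned to a stratum")
    if (on_unassigned == "error") stop(msg)
    warning(msg, call. = FALSE)
  }
  factor(labels[ifelse(idx == 0L, NA, idx)], levels = labels)
}

# split one locus's values by condition within a stratum, dropping missing
# values and empty groups; returns list(groups, n_used)
stratum_groups <- function(values, condition) {
  ok <- is.finite(values)
  g <- split(values[ok], condition[ok], drop = TRUE)
  g <- g[lengths(g) > 0L]
  list(groups = unname(g), n_used = sum(ok))
}

#' Stratified test of a single locus
#'
#' Runs the chosen base test within each age stratum on one locus's
#' beta-values and combines the per-stratum p-values with each requested
#' combiner. Missing beta-values are dropped per stratum; untestable strata
#' (fewer than two non-empty condition groups, or the Welch variance
#' requirements unmet) contribute a missing p and are excluded from the
#' combination (effective-G). The Z combiner is weighted by each stratum's
#' retained sample count for this locus.
#'
#' @param values Numeric vector of beta-values, one per sample (`NA`
#'   allowed).
#' @param condition Factor or character vector of condition labels, aligned
#'   with `values`.
#' @param stratum Factor of age-stratum labels, aligned with `values`.
#' @param method One of `"kw"`, `"anova"`, `"median"`, `"welch"`.
#' @param combiners Character vector among `"fisher"`, `"z"`.
#' @return A list with `p_strata` (named per-stratum p-values), `n_strata`
#'   (retained sample counts), and `combined` (named per-combiner p-values;
#'   `NA` when no stratum was testable).
#' @export
stratified_locus_test <- function(values, condition, stratum,
                                  method = "kw",
                                  combiners = c("fisher", "z")) {
  method <- match.arg(method, BASE_METHODS)
  combiners <- match.arg(combiners, COMBINERS, several.ok = TRUE)
  stopifnot(length(values) == length(condition),
            length(values) == length(stratum))
  stratum <- as.factor(stratum)
  levs <- levels(stratum)
  p_g <- stats::setNames(rep(NA_real_, length(levs)), levs)
  n_g <- stats::setNames(rep(0L, length(levs)), levs)
  for (s in levs) {
    in_s <- which(stratum == s)
    if (length(in_s) == 0L) next
    sg <- stratum_groups(values[in_s], condition[in_s])
    n_g[s] <- sg$n_used
    p_g[s] <- suppressWarnings(safe_base_p(sg$groups, method))
  }
  combined <- vapply(combiners, function(cb)
    combine_pvalues(p_g, n_g, method = cb), 0)
  list(p_strata = p_g, n_strata = n_g, combined = combined)
}

#' Stratified differential-methylation testing of a beta-value matrix
#'
#' The full pipeline: intersects matrix and annotation sample ids, applies
#' the QC filter, bins ages into strata, then for every locus runs each
#' requested base test within each stratum and combines per-stratum p-values
#' with each requested combiner. Deterministic given its inputs and
#' invariant to sample/locus ordering.
#'
#' @param beta Numeric matrix, loci x samples, values in `[0, 1]` or `NA`;
#'   rownames are locus ids, colnames sample ids (see
#'   [read_beta_matrix()]).
#' @param annot Sample annotation data frame (see [read_annotation()]).
#' @param methods Base tests to run, subset of
#'   `c("kw", "anova", "median", "welch")`.
#' @param combiners Combiners to apply, subset of `c("fisher", "z")`.
#' @param age_edges,age_max Passed to [assign_age_groups()].
#' @param bs_min,coverage_min QC thresholds passed to [qc_filter()];
#'   `age_max` doubles as the QC age cutoff.
#' @param qc Apply the QC filter (default `TRUE`).
#' @param keep_stratum_p Also return per-stratum p-value columns
#'   (`p_<method>_s_<stratum>`).
#' @param quiet Suppress progress messages.
#' @return Data frame with one row per locus: `locus`, then
#'   `p_<method>_<combiner>` columns (and per-stratum columns if requested).
#' @examples
#' fix <- generate_fixture(fixture_spec(n_loci = 20, n_differential = 5,
#'                                      seed = 1))
#' res <- run_all(fix$beta, fix$annotation, methods = "kw", quiet = TRUE)
#' head(res)
#' @export
run_all <- function(beta, annot,
                    methods = c("kw", "anova", "median", "welch"),
                    combiners = c("fisher", "z"),
                    age_edges = DEFAULT_AGE_EDGES, age_max = 80,
                    bs_min = 4000, coverage_min = 0.95,
                    qc = TRUE, keep_stratum_p = FALSE, quiet = FALSE) {
  methods <- match.arg(methods, BASE_METHODS, several.ok = TRUE)
  combiners <- match.arg(combiners, COMBINERS, several.ok = TRUE)
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))

  common <- intersect(colnames(beta), annot$sample_id)
  if (length(common) == 0L)
    stop("matrix and annotation share no sample ids (empty cohort)")
  dropped <- (ncol(beta) - length(common)) + (nrow(annot) - length(common))
  if (!quiet && dropped > 0)
    message("run_all: ", dropped, " sample id(s) present in only one input; ",
            "using the intersection of ", length(common))
  annot <- annot[match(common, annot$sample_id), , drop = FALSE]
  if (qc) {
    annot <- qc_filter(annot, bs_min = bs_min, coverage_min = coverage_min,
                       age_max = age_max, quiet = quiet)
  }
  # deterministic sample order regardless of input ordering
  annot <- annot[order(annot$sample_id), , drop = FALSE]
  beta <- beta[, annot$sample_id, drop = FALSE]

  condition <- as.factor(annot$condition)
  if (nlevels(droplevels(condition)) < 2L)
    stop("fewer than two condition levels after filtering")
  stratum <- assign_age_groups(annot$age, edges = age_edges, age_max = age_max)
  usable <- !is.na(stratum)
  if (!all(usable)) {
    beta <- beta[, usable, drop = FALSE]
    condition <- condition[usable]
    stratum <- droplevels(stratum[usable])
  } else {
    stratum <- droplevels(stratum)
  }

  loci <- sort(rownames(beta))
  beta <- beta[loci, , drop = FALSE]
  strat_idx <- split(seq_len(ncol(beta)), stratum)
  levs <- names(strat_idx)
  G <- length(levs)

  out <- data.frame(locus = loci, stringsAsFactors = FALSE)
  n_untestable <- 0L
  for (m in methods) {
    pg_mat <- matrix(NA_real_, nrow = length(loci), ncol = G,
                     dimnames = list(loci, levs))
    ng_mat <- matrix(0L, nrow = length(loci), ncol = G)
    for (j in seq_len(G)) {
      idx <- strat_idx[[j]]
      cond_s <- condition[idx]
      for (i in seq_along(loci)) {
        sg <- stratum_groups(beta[i, idx], cond_s)
        ng_mat[i, j] <- sg$n_used
        pg_mat[i, j] <- suppressWarnings(safe_base_p(sg$groups, m))
      }
    }
    n_untestable <- n_untestable + sum(is.na(pg_mat))
    for (cb in combiners) {
      out[[paste0("p_", m, "_", cb)]] <- vapply(seq_along(loci), function(i)
        combine_pvalues(pg_mat[i, ], ng_mat[i, ], method = cb), 0)
    }
    if (keep_stratum_p)
      for (j in seq_len(G))
        out[[paste0("p_", m, "_s_", levs[j])]] <- pg_mat[, j]
  }
  if (!quiet && n_untestable > 0)
    message("run_all: ", n_untestable,
            " locus-stratum combinations were untestable (missing p)")
  rownames(out) <- NULL
  out
}

#' Count loci significant at p-value cutoffs
#'
#' For each cutoff c, counts the loci with p strictly below c (missing p's
#' never count).
#'
#' @param p Numeric vector of per-locus p-values (`NA` allowed).
#' @param cutoffs Positive cutoff values; default the conventional
#'   `1e-3 ... 1e-6` grid.
#' @return Named integer vector of counts, one per cutoff.
#' @examples
#' count_significant(c(1e-7, 5e-4, 0.01))
#' @export
count_significant <- function(p, cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6)) {
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("cutoffs must be positive")
  vapply(cutoffs, function(cc) sum(p < cc, na.rm = TRUE), 0L,
         USE.NAMES = FALSE) |>
    stats::setNames(format(cutoffs, scientific = TRUE, trim = TRUE))
}

#' Summarise significant-locus counts per method and combiner
#'
#' Builds the methods-by-cutoffs count table from a [run_all()] result.
#'
#' @param results Data frame from [run_all()].
#' @param cutoffs Passed to [count_significant()].
#' @return Data frame with columns `method`, `combiner`, and one count column
#'   per cutoff.
#' @export
significance_summary <- function(results,
                                 cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6)) {
  pcols <- grep("^p_(kw|anova|median|welch)_(fisher|z)$", names(results),
                value = TRUE)
  if (length(pcols) == 0L) stop("no p_<method>_<combiner> columns found")
  parts <- strsplit(sub("^p_", "", pcols), "_", fixed = TRUE)
  tab <- do.call(rbind, lapply(seq_along(pcols), function(i) {
    counts <- count_significant(results[[pcols[i]]], cutoffs)
    cbind(data.frame(method = parts[[i]][1], combiner = parts[[i]][2],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  }))
  rownames(tab) <- NULL
  tab
}
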