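# TSV readers/writers for the beta-value matrix and sample annotation.
# TSV (not CSV) is the primary dialect, matching GEO-style matrix text
# conventions; "NA" is the canonical missing token, "" is accepted on read.

#' Read a beta-value matrix from TSV
#'
#' Expects loci as rows and samples as columns: first column the locus id,
#' header row the sample ids, cells decimal numbers in `[0, 1]` or missing
#' (`NA` or empty). With `transpose = TRUE` the file is samples x loci and
#' is transposed after reading.
#'
#' @param path Path to a tab-delimited text file.
#' @param transpose File is samples x loci; transpose to loci x samples.
#' @return Numeric matrix, loci x samples, with locus ids as rownames and
#'   sample ids as colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.1, 0.9, NA, 0.5), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' write_beta_matrix(m, f)
#' read_beta_matrix(f)
#' @export
read_beta_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1L)
    stop("ragged TSV: line(s) ",
         paste(which(nf != nf[1])[1], collapse = ", "),
         " have a different number of fields than the header")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column id(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                dimnames = list(ids, cn))
  for (j in seq_along(cn)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' (line %d)",
                   raw[bad[1]], ids[bad[1]], cn[j], bad[1] + 1L))
    mat[, j] <- val
  }
  if (transpose) mat <- t(mat)
  oob <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(oob) > 0)
    stop(sprintf(
      "beta-value %g out of [0, 1] at locus '%s', sample '%s'",
      mat[oob[1, 1], oob[1, 2]],
      rownames(mat)[oob[1, 1]], colnames(mat)[oob[1, 2]]))
  mat
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: first column `locus_id`, then one column
#' per sample; missing values written as `NA`.
#'
#' @param beta Numeric matrix, loci x samples, with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- data.frame(locus_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Requires columns `sample_id`, `condition`, `age`; optional numeric QC
#' columns `bs_value` and `coverage` and any extra columns are preserved.
#' Validates unique sample ids, numeric ages, and at least two condition
#' levels.
#'
#' @param path Path to a tab-delimited text file.
#' @return Data frame of per-sample annotation.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "condition", "age")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("annotation is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$age <- as.numeric(df$age)
  if (anyNA(df$age)) stop("column 'age' must be numeric and non-missing")
  for (col in intersect(c("bs_value", "coverage"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if (length(unique(df$condition)) < 2L)
    stop("column 'condition' must have at least two levels (K >= 2)")
  df
}

#' Write a sample annotation table to TSV
#'
#' @param annot Data frame as returned by [read_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write pipeline results and the cutoff-count summary
#'
#' Emits `results.tsv` (one row per locus) and `summary.tsv` (the
#' methods-by-cutoffs count table) into `dir`.
#'
#' @param results Data frame from [run_all()].
#' @param dir Output directory (created if absent).
#' @param cutoffs Cutoff grid for [significance_summary()].
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_results <- function(results, dir,
                          cutoffs = c(1e-3, 1e-4, 1e-5, 1e-6)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(dir, "results.tsv")
  sum_path <- file.path(dir, "summary.tsv")
  utils::write.table(results, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(significance_summary(results, cutoffs), sum_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(results = res_path, summary = sum_path))
}
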