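#' Construct a beta-value matrix
#'
#' A `beta_matrix` is the universal currency of the pipeline: a numeric
#' matrix of methylation fractions with samples as rows and CpG loci as
#' columns. Missing measurements are `NA`. Every present value must lie in
#' \eqn{[0, 1]} and row/column identifiers must be unique.
#'
#' @param values numeric matrix, samples x loci.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames.
#' @param locus_ids character vector of unique locus identifiers; defaults
#'   to existing colnames.
#' @return a numeric matrix of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        locus_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(sample_ids) || is.null(locus_ids))
    stop("sample and locus identifiers are required")
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(values) || length(locus_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("beta value out of [0,1] at sample '%s', locus '%s': %g",
                 sample_ids[i], locus_ids[j], values[bad[1L]]))
  }
  dimnames(values) <- list(sample_ids, locus_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

## strip the class for raw matrix algebra
unclass_beta <- function(x) {
  class(x) <- "matrix"
  x
}

#' Read a beta-value matrix from TSV
#'
#' Expects the dialect written by [write_beta_tsv()]: tab-separated, UTF-8,
#' first column `sample_id`, remaining header fields are locus ids, empty
#' fields are missing values. Values outside \eqn{[0,1]} or non-numeric
#' fields raise an error naming the offending row and column.
#'
#' @param path file path.
#' @return a [beta_matrix()].
#' @export
read_beta_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L) stop("beta TSV needs a sample_id column plus loci")
  sample_ids <- df[[1L]]
  locus_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(locus_ids))
  for (j in seq_along(locus_ids)) {
    raw <- df[[j + 1L]]
    empty <- raw == "" | is.na(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric beta value at line %d, column '%s': '%s'",
                   bad[1L] + 1L, locus_ids[j], raw[bad[1L]]))
    out <- which(!empty & (num < 0 | num > 1))
    if (length(out))
      stop(sprintf("beta value out of [0,1] at line %d, column '%s': %s",
                   out[1L] + 1L, locus_ids[j], raw[out[1L]]))
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  beta_matrix(vals, sample_ids, locus_ids)
}

#' Write a beta-value matrix to TSV
#'
#' Samples as rows, header row of locus ids, missing values as empty
#' fields, beta printed with four decimals.
#'
#' @param beta a [beta_matrix()] or compatible named matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_tsv <- function(beta, path) {
  chr <- ifelse(is.na(beta), "", formatC(beta, digits = 4, format = "f"))
  df <- data.frame(sample_id = rownames(beta), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Median-impute missing beta values by locus
#'
#' Replaces each missing entry with the median of its locus (column);
#' loci that are entirely missing fall back to the global median. This is
#' the pre-factorisation fill used for near-complete array-grade matrices.
#'
#' @param beta a [beta_matrix()] or numeric matrix.
#' @return a plain numeric matrix without missing values.
#' @export
impute_locus_median <- function(beta) {
  x <- unclass_beta(beta)
  med <- apply(x, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- median(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- med[idx[, 2L]]
  x
}

#' Most variably methylated loci
#'
#' The genome-scale pre-filter used before clustering and for the full
#' classifier: the `n` loci with the largest beta variance.
#'
#' @param beta a [beta_matrix()].
#' @param n number of loci to keep.
#' @return character vector of locus ids, by decreasing variance.
#' @export
top_variable_loci <- function(beta, n = 10000L) {
  v <- apply(unclass_beta(beta), 2L, var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  ord <- order(v, decreasing = TRUE)
  colnames(beta)[ord[seq_len(min(n, ncol(beta)))]]
}
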