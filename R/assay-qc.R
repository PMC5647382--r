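#' Construct a primer-extension assay record
#'
#' One sample's multiplexed extension readout: per signature locus a
#' methylated/unmethylated intensity pair and a call status, plus the
#' apparent beta of the bisulfite conversion control (an invariably
#' unmethylated locus, so residual methylated-like signal indicates
#' incomplete conversion), the source material and optional input DNA
#' mass.
#'
#' @param sample_id sample identifier.
#' @param locus_id signature locus identifiers.
#' @param meth,unmeth non-negative intensity vectors.
#' @param status per-locus call status, `OK` or `NO_CALL`.
#' @param control_beta apparent beta of the conversion control in
#'   \eqn{[0,1]}, or `NA` when the control is absent.
#' @param material source material tag.
#' @param input_ng input DNA mass in nanograms (optional metadata).
#' @return a list of class `assay_record`.
#' @export
assay_record <- function(sample_id, locus_id, meth, unmeth,
                         status = NULL, control_beta = NA_real_,
                         material = NA_character_, input_ng = NA_real_) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) stop("duplicate loci in assay record")
  if (length(meth) != length(locus_id) || length(unmeth) != length(locus_id))
    stop("intensity vectors must match the locus list")
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be >= 0")
  if (is.null(status)) status <- ifelse(meth + unmeth > 0, "OK", "NO_CALL")
  if (!all(status %in% c("OK", "NO_CALL"))) stop("bad call status")
  if (!is.na(control_beta) && (control_beta < 0 || control_beta > 1))
    stop("control beta must lie in [0,1]")
  out <- list(sample_id = as.character(sample_id),
              loci = data.frame(locus_id = locus_id,
                                meth = as.numeric(meth),
                                unmeth = as.numeric(unmeth),
                                status = status,
                                stringsAsFactors = FALSE),
              control_beta = control_beta,
              material = material,
              input_ng = input_ng)
  class(out) <- "assay_record"
  out
}

#' @export
print.assay_record <- function(x, ...) {
  cat(sprintf(
    "assay_record '%s': %d loci (%d failed), control beta = %s\n",
    x$sample_id, nrow(x$loci), sum(x$loci$status == "NO_CALL"),
    ifelse(is.na(x$control_beta), "absent",
           sprintf("%.3f", x$control_beta))))
  invisible(x)
}

#' Beta estimate from an extension intensity pair
#'
#' The methylation fraction is the methylated-allele proportion of total
#' extension signal, \eqn{\beta = m / (m + u)}. A locus with zero total
#' signal has no call and returns `NA`.
#'
#' @param meth,unmeth non-negative intensities (vectorised).
#' @return beta values in \eqn{[0,1]}, `NA` where both intensities are 0.
#' @export
beta_from_extension <- function(meth, unmeth) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  tot <- meth + unmeth
  ifelse(is.na(tot) | tot == 0, NA_real_, meth / tot)
}

#' Partial beta vector of an assay record
#'
#' Converts per-locus intensity pairs to beta estimates via
#' [beta_from_extension()]; failed calls (`NO_CALL`) become `NA`.
#'
#' @param record an [assay_record()].
#' @return named beta vector over the record's loci.
#' @export
assay_record_beta <- function(record) {
  b <- beta_from_extension(record$loci$meth, record$loci$unmeth)
  b[record$loci$status == "NO_CALL"] <- NA_real_
  setNames(b, record$loci$locus_id)
}

#' Bisulfite conversion control check
#'
#' The control targets an invariably unmethylated locus which undergoes
#' complete conversion to uracil; apparent methylation above `cutoff`
#' indicates failed conversion. An absent control is treated as a failure
#' (conservative).
#'
#' @param record an [assay_record()].
#' @param cutoff highest acceptable apparent beta of the control.
#' @return `TRUE` if the control passes.
#' @export
conversion_control_check <- function(record, cutoff = 0.1) {
  cb <- record$control_beta
  !is.na(cb) && cb <= cutoff
}

#' Per-sample assay QC
#'
#' Applies the ordered QC taxonomy: a failed (or absent) bisulfite
#' conversion control dominates and gives `BISULFITE_FAIL`; otherwise more
#' than `max_failed` failed signature loci gives `LOCUS_QC_FAIL`;
#' otherwise the sample is `ANALYZABLE`.
#'
#' @param record an [assay_record()].
#' @param max_failed maximum tolerated failed loci (default 6).
#' @param control_cutoff conversion-control cut-off.
#' @return one-row data.frame: `sample_id`, `n_failed_loci`,
#'   `conversion_pass`, `disposition`, `material`, `input_ng`.
#' @export
sample_qc <- function(record, max_failed = 6L, control_cutoff = 0.1) {
  n_failed <- sum(record$loci$status == "NO_CALL")
  conv <- conversion_control_check(record, cutoff = control_cutoff)
  disposition <- if (!conv) "BISULFITE_FAIL"
                 else if (n_failed > max_failed) "LOCUS_QC_FAIL"
                 else "ANALYZABLE"
  data.frame(sample_id = record$sample_id,
             n_failed_loci = n_failed,
             conversion_pass = conv,
             disposition = disposition,
             material = record$material,
             input_ng = record$input_ng,
             stringsAsFactors = FALSE)
}

#' Cohort-level QC report
#'
#' Runs [sample_qc()] over a list of assay records and tallies the
#' mutually exclusive dispositions (which always sum to the cohort size)
#' overall and per input-DNA bin (`<2`, `2-10`, `10-50`, `50-100`,
#' `>100` ng).
#'
#' @param records list of [assay_record()]s.
#' @param max_failed,control_cutoff passed to [sample_qc()].
#' @return a list of class `qc_report`: `samples` (per-sample rows),
#'   `tally` (disposition counts), `by_input_bin`.
#' @export
qc_report <- function(records, max_failed = 6L, control_cutoff = 0.1) {
  rows <- do.call(rbind, lapply(records, sample_qc,
                                max_failed = max_failed,
                                control_cutoff = control_cutoff))
  dispositions <- c("ANALYZABLE", "BISULFITE_FAIL", "LOCUS_QC_FAIL")
  tally <- table(factor(rows$disposition, levels = dispositions))
  bin <- cut(rows$input_ng, breaks = c(-Inf, 2, 10, 50, 100, Inf),
             labels = c("<2", "2-10", "10-50", "50-100", ">100"))
  by_bin <- if (all(is.na(bin))) NULL else
    as.data.frame.matrix(table(bin, factor(rows$disposition,
                                           levels = dispositions)))
  out <- list(samples = rows, tally = tally, by_input_bin = by_bin)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("qc_report: %d samples\n", n))
  for (d in names(x$tally))
    cat(sprintf("  %-15s %3d (%.0f%%)\n", d, x$tally[[d]],
                100 * x$tally[[d]] / n))
  invisible(x)
}

#' Concordance between paired beta estimate sets
#'
#' Compares paired beta vectors from two sources (e.g. extension assay vs
#' methylation array, or first vs second replicate): coefficient of
#' determination of the pooled paired values, regression slope, per-locus
#' mean absolute difference, and -- when subgroup calls are supplied --
#' the call-level agreement fraction.
#'
#' @param a,b matrices (samples x loci) or vectors of paired beta values;
#'   must share dimensions, pairs with a missing value in either source
#'   are dropped.
#' @param calls_a,calls_b optional paired subgroup calls.
#' @return a list of class `concordance_report`: `r_squared`, `slope`,
#'   `n_pairs`, `per_locus_mad` (when inputs are matrices),
#'   `call_agreement` (when calls are supplied).
#' @export
compare_beta <- function(a, b, calls_a = NULL, calls_b = NULL) {
  if (!all(dim(as.matrix(a)) == dim(as.matrix(b))))
    stop("'a' and 'b' must be paired (same dimensions)")
  av <- as.numeric(as.matrix(a)); bv <- as.numeric(as.matrix(b))
  ok <- !is.na(av) & !is.na(bv)
  if (!any(ok)) stop("no overlapping pairs")
  fit <- lm(bv[ok] ~ av[ok])
  r2 <- suppressWarnings(cor(av[ok], bv[ok]))^2
  if (is.na(r2)) r2 <- 0
  per_locus_mad <- NULL
  if (is.matrix(a) || is.data.frame(a)) {
    am <- as.matrix(a); bm <- as.matrix(b)
    per_locus_mad <- colMeans(abs(am - bm), na.rm = TRUE)
  }
  agreement <- NULL
  if (!is.null(calls_a) && !is.null(calls_b))
    agreement <- mean(as.character(calls_a) == as.character(calls_b))
  out <- list(r_squared = r2,
              slope = unname(coef(fit)[2L]),
              n_pairs = sum(ok),
              per_locus_mad = per_locus_mad,
              call_agreement = agreement)
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: R^2 = %.3f, slope = %.3f over %d pairs\n",
              x$r_squared, x$slope, x$n_pairs))
  if (!is.null(x$call_agreement))
    cat(sprintf("  call agreement: %.1f%%\n", 100 * x$call_agreement))
  invisible(x)
}

#' Read assay records from TSV
#'
#' Long format, one locus per row: columns `sample_id`, `locus_id`,
#' `meth`, `unmeth` and optionally `material`, `input_ng`. Rows whose
#' `locus_id` equals `control_id` carry the conversion control; its
#' apparent beta is `meth / (meth + unmeth)`. Malformed numeric fields
#' raise line-numbered parse errors.
#'
#' @param path file path.
#' @param control_id locus id marking conversion-control rows.
#' @return list of [assay_record()]s, one per sample.
#' @export
read_assay_tsv <- function(path, control_id = "BS_control") {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "locus_id", "meth", "unmeth")
  if (!all(need %in% colnames(df)))
    stop("assay TSV needs columns: ", paste(need, collapse = ", "))
  num <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which((raw != "" & !is.na(raw)) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value at line %d, column '%s': '%s'",
                   bad[1L] + 1L, col, raw[bad[1L]]))
    v
  }
  df$meth <- num("meth"); df$unmeth <- num("unmeth")
  if ("input_ng" %in% colnames(df)) df$input_ng <- num("input_ng")
  lapply(split(df, df$sample_id)[unique(df$sample_id)], function(sd) {
    ctrl <- sd$locus_id == control_id
    cb <- if (any(ctrl))
      beta_from_extension(sd$meth[ctrl][1L], sd$unmeth[ctrl][1L])
    else NA_real_
    sd <- sd[!ctrl, , drop = FALSE]
    if (anyDuplicated(sd$locus_id))
      stop(sprintf("duplicate locus for sample '%s'", sd$sample_id[1L]))
    assay_record(sample_id = sd$sample_id[1L],
                 locus_id = sd$locus_id,
                 meth = ifelse(is.na(sd$meth), 0, sd$meth),
                 unmeth = ifelse(is.na(sd$unmeth), 0, sd$unmeth),
                 control_beta = cb,
                 material = if ("material" %in% colnames(sd))
                   sd$material[1L] else NA_character_,
                 input_ng = if ("input_ng" %in% colnames(sd))
                   sd$input_ng[1L] else NA_real_)
  })
}

#' Write assay records to TSV
#'
#' Inverse of [read_assay_tsv()].
#'
#' @param records list of [assay_record()]s.
#' @param path file path.
#' @param control_id locus id used for conversion-control rows.
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(records, path, control_id = "BS_control") {
  rows <- do.call(rbind, lapply(records, function(r) {
    df <- r$loci[, c("locus_id", "meth", "unmeth")]
    if (!is.na(r$control_beta))
      df <- rbind(df, data.frame(locus_id = control_id,
                                 meth = r$control_beta * 1e4,
                                 unmeth = (1 - r$control_beta) * 1e4))
    df$sample_id <- r$sample_id
    df$material <- r$material
    df$input_ng <- r$input_ng
    df[, c("sample_id", "locus_id", "meth", "unmeth", "material",
           "input_ng")]
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write classification calls to TSV
#'
#' @param calls data.frame as returned by [classify_cohort()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         formatC(out[[j]], digits = 4, format = "fg"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
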