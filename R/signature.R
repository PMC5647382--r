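#' Construct a signature definition
#'
#' An ordered panel of signature CpG loci with per-locus metadata: the
#' multiplex (plex) each locus is assayed in, the one-vs-rest contrast that
#' contributed it, and optional genomic coordinates (hg19, 1-based).
#'
#' @param locus_id character vector of unique locus identifiers, in panel
#'   order.
#' @param contrast subgroup contrast that contributed each locus (or `NA`).
#' @param plex integer multiplex assignment, conventionally in 1..3.
#' @param chrom,pos optional genomic coordinates.
#' @return a data.frame of class `signature_def`.
#' @export
signature_definition <- function(locus_id,
                                 contrast = NA_character_,
                                 plex = rep_len(1:3, length(locus_id)),
                                 chrom = NA_character_,
                                 pos = NA_integer_) {
  locus_id <- as.character(locus_id)
  if (!length(locus_id)) stop("signature must contain at least one locus")
  if (anyDuplicated(locus_id)) stop("duplicate loci in signature")
  df <- data.frame(locus_id = locus_id,
                   contrast = rep_len(as.character(contrast), length(locus_id)),
                   plex = rep_len(as.integer(plex), length(locus_id)),
                   chrom = rep_len(as.character(chrom), length(locus_id)),
                   pos = rep_len(as.integer(pos), length(locus_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("signature_def", "data.frame")
  df
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("signature_def: %d loci over %d multiplexes\n",
              nrow(x), length(unique(x$plex))))
  print.data.frame(x, ...)
  invisible(x)
}

signature_loci <- function(signature) {
  if (inherits(signature, "signature_def")) signature$locus_id
  else as.character(signature)
}

#' Read / write signature definitions as JSON
#'
#' The on-disk form is a versioned JSON object with a `loci` array; each
#' element carries `locus_id`, `contrast`, `plex` and optional `chrom`/`pos`.
#'
#' @param path file path.
#' @return `read_signature_json` returns a [signature_definition()];
#'   `write_signature_json` returns `path` invisibly.
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loci <- obj$loci
  if (is.null(loci)) stop("signature JSON lacks a 'loci' array")
  signature_definition(loci$locus_id,
                       contrast = loci$contrast %||% NA_character_,
                       plex = loci$plex %||% rep_len(1:3, nrow(loci)),
                       chrom = loci$chrom %||% NA_character_,
                       pos = loci$pos %||% NA_integer_)
}

#' @param signature a [signature_definition()].
#' @rdname read_signature_json
#' @export
write_signature_json <- function(signature, path) {
  obj <- list(format = "minsig-signature", version = 1L,
              loci = as.data.frame(signature))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
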