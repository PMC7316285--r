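#' Normalize chromosome names
#'
#' Strips a leading "chr"/"Chr" prefix and upper-cases the remainder so that
#' "chr4", "Chr4" and "4" all compare equal. Coordinates throughout the
#' package are 1-based inclusive (UMD3.1.1 table convention).
#'
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_chrom(c("chr4", "4", "ChrX"))
normalize_chrom <- function(x) {
  toupper(sub("^[Cc][Hh][Rr]", "", as.character(x)))
}

# Deterministic 32-bit sub-seed from a root seed and a stage label, so each
# generator can be re-run independently of the others under one root seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Write a headered, comment-free TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a headered TSV as a tibble
#'
#' @param path input path.
#' @return tibble.
#' @export
read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
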