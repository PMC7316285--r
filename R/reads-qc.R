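#' Read a FASTQ file into a read table
#'
#' Phred+33 encoding is assumed; gzip input is handled transparently. The
#' file structure is validated first so a malformed record is reported by
#' its index.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return tibble with columns `id` (name up to first space), `sequence`,
#'   and `quality` (list-column of integer Phred scores).
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  ln <- readLines(con)
  if (length(ln) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  n <- length(ln) / 4
  hdr <- ln[seq(1, length(ln), 4)]
  seqs <- ln[seq(2, length(ln), 4)]
  plus <- ln[seq(3, length(ln), 4)]
  qual <- ln[seq(4, length(ln), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1], " in ", path)
  # the harmless "metadata columns dropped" notice from Biostrings is muted
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qv <- as.list(methods::as(Biostrings::quality(x), "IntegerList"))
  tibble::tibble(id = sub("\\s.*$", "", names(x)),
                 sequence = as.character(x, use.names = FALSE),
                 quality = lapply(qv, as.integer))
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads read table from [read_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  rec <- character(4L * nrow(reads))
  rec[seq(1, length(rec), 4)] <- paste0("@", reads$id)
  rec[seq(2, length(rec), 4)] <- reads$sequence
  rec[seq(3, length(rec), 4)] <- "+"
  rec[seq(4, length(rec), 4)] <- vapply(reads$quality,
                                        function(q) intToUtf8(q + 33L), "")
  writeLines(rec, path)
  invisible(path)
}

#' Low-quality read flag
#'
#' A read is low quality when the proportion of its bases with Phred score
#' <= 20 is strictly greater than 50%. A read with exactly half of its bases
#' at or below Q20 is kept.
#'
#' @param quality integer vector of per-base Phred scores for one read.
#' @return logical flag.
#' @export
is_low_quality <- function(quality) {
  if (length(quality) == 0) stop("empty read")
  mean(quality <= 20) > 0.5
}

#' Excess-N read flag
#'
#' TRUE when the fraction of N bases is strictly greater than 10%.
#'
#' @param sequence base string for one read.
#' @return logical flag.
#' @export
has_excess_n <- function(sequence) {
  if (nchar(sequence) == 0) stop("empty read")
  n_n <- nchar(gsub("[^Nn]", "", sequence))
  n_n / nchar(sequence) > 0.10
}

#' Adapter-contamination flag
#'
#' Exact substring matching against the configured adapter set; no
#' mismatches are tolerated.
#'
#' @param sequence base string for one read.
#' @param adapters non-empty character vector of adapter sequences.
#' @return logical flag.
#' @export
has_adapter <- function(sequence, adapters = truseq_adapters()) {
  if (length(adapters) == 0) stop("adapter set must be non-empty")
  any(vapply(adapters, function(a) grepl(a, sequence, fixed = TRUE), TRUE))
}

#' Filter reads into clean data with a QC summary
#'
#' Removal reasons are attributed uniquely with priority
#' adapter > excess-N > low-quality, so the removed counts always sum with
#' `n_clean` to `n_raw`. Q20, Q30 and GC are computed on the clean reads.
#'
#' @param reads read table from [read_fastq()].
#' @param adapters adapter set for [has_adapter()].
#' @return list with `clean` (read table) and `summary` (one-row tibble:
#'   n_raw, n_clean, n_adapter, n_highN, n_lowq, q20, q30, gc).
#' @export
filter_reads <- function(reads, adapters = truseq_adapters()) {
  ad <- vapply(reads$sequence, has_adapter, TRUE, adapters = adapters,
               USE.NAMES = FALSE)
  nn <- vapply(reads$sequence, has_excess_n, TRUE, USE.NAMES = FALSE)
  lq <- vapply(reads$quality, is_low_quality, TRUE, USE.NAMES = FALSE)
  reason <- rep("clean", nrow(reads))
  reason[lq] <- "lowq"
  reason[nn] <- "highN"
  reason[ad] <- "adapter"
  clean <- reads[reason == "clean", ]
  qs <- if (nrow(clean) > 0) summarize_quality(clean) else
    list(q20 = NA_real_, q30 = NA_real_, gc = NA_real_)
  summary <- tibble::tibble(
    n_raw = nrow(reads), n_clean = nrow(clean),
    n_adapter = sum(reason == "adapter"), n_highN = sum(reason == "highN"),
    n_lowq = sum(reason == "lowq"),
    q20 = qs$q20, q30 = qs$q30, gc = qs$gc)
  list(clean = clean, summary = summary)
}

#' Base-level quality and composition summary
#'
#' Q20/Q30 are the percentages of bases with Phred score strictly greater
#' than 20/30 (so Q30 <= Q20 always); GC is the percentage of G+C among
#' non-N bases.
#'
#' @param reads read table.
#' @return list with `q20`, `q30`, `gc` (percent).
#' @export
summarize_quality <- function(reads) {
  if (nrow(reads) == 0) stop("empty read set")
  q <- unlist(reads$quality)
  allseq <- paste(reads$sequence, collapse = "")
  n_gc <- nchar(gsub("[^GCgc]", "", allseq))
  n_n <- nchar(gsub("[^Nn]", "", allseq))
  list(q20 = 100 * mean(q > 20), q30 = 100 * mean(q > 30),
       gc = 100 * n_gc / (nchar(allseq) - n_n))
}
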