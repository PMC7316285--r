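#' Default adapter sequences used by the read filter
#'
#' Illumina TruSeq read-1 and read-2 adapter prefixes; the exact-substring
#' adapter filter matches against these unless the caller supplies others.
#'
#' @return named character vector of adapter sequences.
#' @export
truseq_adapters <- function() {
  c(read1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    read2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")
}

#' Generate a synthetic FASTQ file with planted contamination classes
#'
#' Writes Phred+33 single-end reads. A configured fraction of reads carries a
#' verbatim adapter insertion, a fraction has more than 10% N bases, and a
#' fraction has more than half of its bases at quality <= 20; the remainder
#' are clean (all bases Q >= 25, no N). Each read's planted class is recorded
#' in its name and returned as a truth table, so filter counts can be checked
#' exactly.
#'
#' @param n_reads number of reads.
#' @param read_length read length in bp (target platform: 125/150 bp).
#' @param frac_adapter,frac_lowq,frac_highN planted class fractions
#'   (must sum to <= 1).
#' @param seed integer seed.
#' @param path output FASTQ path.
#' @param adapter adapter sequence planted into adapter-class reads.
#' @return list with `path` and `truth` (tibble: id, class).
#' @export
gen_fastq <- function(n_reads, read_length = 125L, frac_adapter = 0,
                      frac_lowq = 0, frac_highN = 0, seed = 1L,
                      path = tempfile(fileext = ".fastq"),
                      adapter = truseq_adapters()[["read1"]]) {
  if (frac_adapter + frac_lowq + frac_highN > 1)
    stop("planted class fractions must sum to <= 1")
  if (read_length < nchar(adapter))
    stop("read_length must be at least the adapter length (",
         nchar(adapter), ")")
  withr::local_seed(derive_seed(seed, "fastq"))

  n_ad <- round(n_reads * frac_adapter)
  n_lq <- round(n_reads * frac_lowq)
  n_hn <- round(n_reads * frac_highN)
  class <- sample(rep(c("adapter", "lowq", "highN", "clean"),
                      c(n_ad, n_lq, n_hn, n_reads - n_ad - n_lq - n_hn)))
  ids <- sprintf("simread%06d", seq_len(n_reads))

  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_reads), function(i)
    paste(sample(bases, read_length, replace = TRUE), collapse = ""), "")
  quals <- matrix(sample(25:40, n_reads * read_length, replace = TRUE),
                  n_reads, read_length)

  for (i in which(class == "adapter")) {
    at <- sample.int(read_length - nchar(adapter) + 1L, 1L)
    substr(seqs[i], at, at + nchar(adapter) - 1L) <- adapter
  }
  for (i in which(class == "highN")) {
    n_n <- sample(seq(floor(0.10 * read_length) + 1L,
                      floor(0.30 * read_length)), 1L)
    pos <- sample.int(read_length, n_n)
    s <- strsplit(seqs[i], "")[[1]]
    s[pos] <- "N"
    seqs[i] <- paste(s, collapse = "")
  }
  for (i in which(class == "lowq")) {
    n_low <- sample(seq(floor(0.5 * read_length) + 1L, read_length), 1L)
    pos <- sample.int(read_length, n_low)
    quals[i, pos] <- sample(2:20, n_low, replace = TRUE)
  }

  qchar <- vapply(seq_len(n_reads), function(i)
    intToUtf8(quals[i, ] + 33L), "")
  rec <- character(4L * n_reads)
  rec[seq(1, length(rec), 4)] <- paste0("@", ids, " class=", class)
  rec[seq(2, length(rec), 4)] <- seqs
  rec[seq(3, length(rec), 4)] <- "+"
  rec[seq(4, length(rec), 4)] <- qchar
  writeLines(rec, path)
  list(path = path, truth = tibble::tibble(id = ids, class = class))
}
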