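#' Generate a synthetic gene annotation
#'
#' Places `n_genes` genes uniformly on the configured chromosomes (sampling
#' chromosomes proportionally to length, gene lengths log-uniform). Genes may
#' overlap each other, as real annotations do. Coordinates are 1-based
#' inclusive. Each gene carries an annotation status (annotated, pseudogene
#' or novel) at roughly the proportions seen in bovine muscle RNA-seq.
#'
#' @param config a [sim_config()] object.
#' @return tibble with columns `gene_id`, `symbol`, `chromosome`, `start`,
#'   `end`, `length`, `annotation_status`.
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (min(config$gene_length_range) > max(config$chrom_lengths))
    stop("configuration error: minimum gene length exceeds every chromosome")
  withr::local_seed(derive_seed(config$seed, "annotation"))

  n <- config$n_genes
  lens <- config$chrom_lengths
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  glen <- round(exp(runif(n, log(config$gene_length_range[1]),
                          log(config$gene_length_range[2]))))
  # a drawn gene longer than its chromosome is a configuration error
  too_long <- glen >= lens[chrom]
  if (any(too_long)) {
    # re-draw on the same chromosome, capped; only tiny chromosomes hit this
    glen[too_long] <- pmin(glen[too_long], floor(lens[chrom[too_long]] / 2))
  }
  start <- floor(runif(n, 1, lens[chrom] - glen + 1))
  end <- start + glen - 1
  status <- sample(c("annotated", "pseudogene", "novel"), n, replace = TRUE,
                   prob = c(0.85, 0.05, 0.10))
  ord <- order(as.integer(factor(chrom, levels = names(lens))), start)
  tibble::tibble(
    gene_id = sprintf("SIMG%05d", seq_len(n)),
    symbol = sprintf("Sym%05d", seq_len(n)),
    chromosome = normalize_chrom(chrom),
    start = as.numeric(start), end = as.numeric(end),
    length = as.numeric(glen),
    annotation_status = status
  )[ord, ]
}

#' Export a gene table as GFF3
#'
#' Writes 1-based inclusive gene records (`type = gene`) with `ID`, `Name`
#' and `biotype`-style attributes.
#'
#' @param genes gene table from [gen_annotation()] or [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  attrs <- sprintf("ID=%s;Name=%s;annotation_status=%s",
                   genes$gene_id, genes$symbol, genes$annotation_status)
  lines <- c("##gff-version 3",
             sprintf("%s\tbeefcand\tgene\t%d\t%d\t.\t+\t.\t%s",
                     genes$chromosome, as.integer(genes$start),
                     as.integer(genes$end), attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table from GFF3 or TSV
#'
#' GFF3 input keeps `type == "gene"` rows and parses `ID`/`Name`/
#' `annotation_status` attributes; TSV input must carry the gene-table
#' columns. The FPKM length defaults to the genomic span when no explicit
#' `length` column is present.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return gene table tibble (see [gen_annotation()]).
#' @export
read_gene_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) == 9L]
    f <- f[vapply(f, function(x) x[3] == "gene", TRUE)]
    if (length(f) == 0L) stop("no gene records in ", path)
    get_attr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
      vapply(m, function(x) if (length(x)) x[3] else NA_character_, "")
    }
    a <- vapply(f, `[`, "", 9L)
    out <- tibble::tibble(
      gene_id = get_attr(a, "ID"),
      symbol = get_attr(a, "Name"),
      chromosome = normalize_chrom(vapply(f, `[`, "", 1L)),
      start = as.numeric(vapply(f, `[`, "", 4L)),
      end = as.numeric(vapply(f, `[`, "", 5L)),
      annotation_status = get_attr(a, "annotation_status")
    )
    out$annotation_status[is.na(out$annotation_status)] <- "annotated"
  } else {
    out <- read_tsv_plain(path)
    req <- c("gene_id", "chromosome", "start", "end")
    if (!all(req %in% names(out)))
      stop("gene table must have columns: ", paste(req, collapse = ", "))
    out$chromosome <- normalize_chrom(out$chromosome)
    if (is.null(out[["annotation_status"]])) out$annotation_status <- "annotated"
    if (is.null(out[["symbol"]])) out$symbol <- out$gene_id
  }
  if (is.null(out[["length"]])) out$length <- out$end - out$start + 1
  if (any(out$start > out$end)) stop("malformed gene span: start > end")
  out
}
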