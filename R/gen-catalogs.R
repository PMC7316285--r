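#' Generate a QTL catalog planted around a known truth
#'
#' Every gene in `truth$qtl_pass_ids` is overlapped by exactly one planted
#' meat-quality QTL; planted QTLs are placed *inside* their target gene, on a
#' stretch not shared with any other gene, and decoy QTLs are placed so they
#' overlap no gene at all. Under this construction the QTL screen's pass set
#' equals the planted one regardless of which non-planted genes a noisy DE
#' caller lets through. A configurable share of decoys is tagged with
#' reproduction traits to exercise trait-class filtering.
#'
#' @param genes gene table from [gen_annotation()].
#' @param truth `planted_truth` from [gen_counts()].
#' @param config a [sim_config()] object.
#' @param frac_other_class fraction of decoys tagged with reproduction traits.
#' @param max_tries bounded retries for decoy placement before erroring.
#' @return QTL catalog tibble: `qtl_id`, `chromosome`, `span_start`,
#'   `span_end`, `peak`, `trait_code`, `trait_class`, `source_ref`.
#' @export
gen_qtl_catalog <- function(genes, truth, config, frac_other_class = 0.2,
                            max_tries = 200L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (!all(truth$qtl_pass_ids %in% truth$deg$gene_id))
    stop("planted QTL-pass genes must be planted DEGs")
  withr::local_seed(derive_seed(config$seed, "qtl_catalog"))
  vocab <- config$trait_vocab
  meat <- vocab$trait_code[vocab$trait_class == "meat_quality"]
  repro <- vocab$trait_code[vocab$trait_class == "reproduction"]

  tg <- genes[match(truth$qtl_pass_ids, genes$gene_id), ]
  planted <- lapply(seq_len(nrow(tg)), function(i) {
    span <- gene_free_subinterval(genes, tg[i, ])
    if (is.null(span))
      stop("impossible placement: gene ", tg$gene_id[i],
           " has no stretch free of other genes for its planted QTL")
    a <- floor(runif(1, span[1], span[2]))
    b <- floor(runif(1, a, span[2]))
    tibble::tibble(chromosome = tg$chromosome[i], span_start = a,
                   span_end = max(b, a), peak = floor(runif(1, a, max(b, a) + 1)),
                   trait_code = sample(meat, 1), trait_class = "meat_quality")
  })
  planted <- dplyr::bind_rows(planted)

  n_decoy <- config$n_qtls - nrow(planted)
  if (n_decoy < 0) stop("n_qtls smaller than the planted QTL-pass set")
  decoys <- place_gene_free_intervals(genes, config, n_decoy,
                                      len_range = c(5e4, 5e5),
                                      max_tries = max_tries)
  if (n_decoy > 0) {
    other <- runif(n_decoy) < frac_other_class
    decoys$trait_code <- ifelse(other, sample(repro, n_decoy, replace = TRUE),
                                sample(meat, n_decoy, replace = TRUE))
    decoys$trait_class <- ifelse(other, "reproduction", "meat_quality")
    decoys$peak <- floor(runif(n_decoy, decoys$span_start,
                               decoys$span_end + 1))
  }
  out <- dplyr::bind_rows(planted, decoys)
  out$qtl_id <- sprintf("SIMQTL%04d", seq_len(nrow(out)))
  out$source_ref <- "synthetic"
  out[, c("qtl_id", "chromosome", "span_start", "span_end", "peak",
          "trait_code", "trait_class", "source_ref")]
}

# Widest stretch of a gene not covered by any other gene (NULL if none).
gene_free_subinterval <- function(genes, gene) {
  same <- genes$chromosome == gene$chromosome & genes$gene_id != gene$gene_id
  others <- genes[same & genes$start <= gene$end & genes$end >= gene$start, ]
  tgt <- IRanges::IRanges(gene$start, gene$end)
  free <- if (nrow(others) == 0) tgt else
    IRanges::setdiff(tgt, IRanges::IRanges(others$start, others$end))
  if (length(free) == 0) return(NULL)
  w <- which.max(IRanges::width(free))
  c(IRanges::start(free)[w], IRanges::end(free)[w])
}

# Rejection-sample intervals overlapping no gene at all.
place_gene_free_intervals <- function(genes, config, n, len_range,
                                      max_tries = 200L) {
  empty <- tibble::tibble(chromosome = character(0), span_start = numeric(0),
                          span_end = numeric(0))
  if (n == 0) return(empty)
  lens <- config$chrom_lengths
  names(lens) <- normalize_chrom(names(lens))
  gr_genes <- GenomicRanges::GRanges(genes$chromosome,
                                     IRanges::IRanges(genes$start, genes$end))
  got <- empty
  for (it in seq_len(max_tries)) {
    need <- n - nrow(got)
    if (need == 0) break
    m <- need * 2L
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
    len <- runif(m, len_range[1], min(len_range[2], min(lens)))
    st <- floor(runif(m, 1, pmax(2, lens[chrom] - len)))
    cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + floor(len) - 1))
    ok <- !IRanges::overlapsAny(cand, gr_genes)
    keep <- utils::head(which(ok), need)
    if (length(keep))
      got <- dplyr::bind_rows(got, tibble::tibble(
        chromosome = chrom[keep], span_start = st[keep],
        span_end = st[keep] + floor(len[keep]) - 1))
  }
  if (nrow(got) < n)
    stop("impossible placement: could not find ", n,
         " gene-free decoy intervals after ", max_tries, " rounds ",
         "(chromosomes too crowded)")
  got
}

#' Generate a SNP catalog planted around a known truth
#'
#' Each gene in `truth$snp_pass_ids` receives one meat-quality SNP at an
#' edge distance strictly below `snp_max_mb - placement_margin_mb`; every
#' annotated planted DEG *not* in the pass set is kept at least
#' `snp_max_mb + placement_margin_mb` away from every SNP in the catalog, so
#' rounding at the threshold can never flip a truth label. Decoy SNPs keep
#' that clearance from all planted DEGs.
#'
#' @inheritParams gen_qtl_catalog
#' @return SNP catalog tibble: `snp_name`, `chromosome`, `position`,
#'   `trait_code`, `trait_class`, `source_ref`.
#' @export
gen_snp_catalog <- function(genes, truth, config, frac_other_class = 0.2,
                            max_tries = 200L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (!all(truth$snp_pass_ids %in% truth$deg$gene_id))
    stop("planted SNP-pass genes must be planted DEGs")
  withr::local_seed(derive_seed(config$seed, "snp_catalog"))
  vocab <- config$trait_vocab
  meat <- vocab$trait_code[vocab$trait_class == "meat_quality"]
  repro <- vocab$trait_code[vocab$trait_class == "reproduction"]
  lens <- config$chrom_lengths
  names(lens) <- normalize_chrom(names(lens))
  near_mb <- config$snp_max_mb - config$placement_margin_mb
  far_mb <- config$snp_max_mb + config$placement_margin_mb

  deg_annot <- truth$deg$gene_id[truth$deg$annotation_status == "annotated"]
  forbidden <- genes[genes$gene_id %in% setdiff(deg_annot, truth$snp_pass_ids), ]
  all_deg_genes <- genes[genes$gene_id %in% truth$deg$gene_id, ]

  tg <- genes[match(truth$snp_pass_ids, genes$gene_id), ]
  pos_planted <- numeric(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      d <- runif(1, 0.01, near_mb) * 1e6
      pos <- if (runif(1) < 0.5) tg$start[i] - d else tg$end[i] + d
      pos <- floor(pos)
      if (pos < 1 || pos > lens[[tg$chromosome[i]]]) next
      if (min_edge_dist_mb(forbidden, tg$chromosome[i], pos) <= far_mb) next
      pos_planted[i] <- pos
      placed <- TRUE
      break
    }
    if (!placed)
      stop("impossible placement: no margin-respecting SNP position near ",
           tg$gene_id[i], " after ", max_tries, " tries")
  }
  planted <- tibble::tibble(
    chromosome = tg$chromosome, position = pos_planted,
    trait_code = sample(meat, nrow(tg), replace = TRUE),
    trait_class = "meat_quality")

  n_decoy <- config$n_snps - nrow(planted)
  if (n_decoy < 0) stop("n_snps smaller than the planted SNP-pass set")
  decoys <- tibble::tibble(chromosome = character(0), position = numeric(0))
  for (it in seq_len(max_tries)) {
    need <- n_decoy - nrow(decoys)
    if (need == 0) break
    m <- need * 2L
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
    pos <- floor(runif(m, 1, lens[chrom]))
    ok <- vapply(seq_len(m), function(k)
      min_edge_dist_mb(all_deg_genes, chrom[k], pos[k]) > far_mb, TRUE)
    keep <- utils::head(which(ok), need)
    if (length(keep))
      decoys <- dplyr::bind_rows(decoys, tibble::tibble(
        chromosome = chrom[keep], position = pos[keep]))
  }
  if (nrow(decoys) < n_decoy)
    stop("impossible placement: could not place ", n_decoy, " decoy SNPs")
  if (n_decoy > 0) {
    other <- runif(n_decoy) < frac_other_class
    decoys$trait_code <- ifelse(other, sample(repro, n_decoy, replace = TRUE),
                                sample(meat, n_decoy, replace = TRUE))
    decoys$trait_class <- ifelse(other, "reproduction", "meat_quality")
  }
  out <- dplyr::bind_rows(planted, decoys)
  out$snp_name <- sprintf("SIMSNP%04d", seq_len(nrow(out)))
  out$source_ref <- "synthetic"
  out[, c("snp_name", "chromosome", "position", "trait_code", "trait_class",
          "source_ref")]
}

# Minimum nearest-edge distance (Mb) from a position to a set of gene spans;
# Inf when no gene shares the chromosome.
min_edge_dist_mb <- function(genes, chromosome, pos) {
  g <- genes[genes$chromosome == chromosome, ]
  if (nrow(g) == 0) return(Inf)
  inside <- pos >= g$start & pos <= g$end
  if (any(inside)) return(0)
  min(pmin(abs(pos - g$start), abs(pos - g$end))) / 1e6
}
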