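#' Restrict a QTL or SNP catalog to one trait class
#'
#' Keeps records whose `trait_class` matches; unknown trait codes (absent
#' from the vocabulary) are a hard error listing the offenders, so typos in
#' hand-built catalogs cannot silently drop records.
#'
#' @param catalog QTL or SNP catalog tibble with `trait_code`, `trait_class`.
#' @param trait_class "meat_quality" or "reproduction".
#' @param vocab trait vocabulary tibble (see [trait_vocabulary()]).
#' @return catalog subset.
#' @export
filter_by_trait_class <- function(catalog, trait_class,
                                  vocab = trait_vocabulary()) {
  bad <- setdiff(unique(catalog$trait_code), vocab$trait_code)
  if (length(bad))
    stop("unknown trait codes: ", paste(bad, collapse = ", "))
  if (!trait_class %in% vocab$trait_class)
    stop("unknown trait class: ", trait_class)
  catalog[catalog$trait_class == trait_class, , drop = FALSE]
}

#' Does a gene span overlap a QTL span?
#'
#' Default mode "any" flags any intersection of the two 1-based inclusive
#' intervals (touching endpoints count); "containment" requires the gene to
#' lie entirely inside the QTL; "midpoint" tests only the gene midpoint.
#' Different chromosomes give FALSE, never an error.
#'
#' @param gene one gene row (`chromosome`, `start`, `end`).
#' @param qtl one QTL row (`chromosome`, `span_start`, `span_end`).
#' @param mode overlap mode.
#' @return logical flag.
#' @export
gene_qtl_overlap <- function(gene, qtl, mode = c("any", "containment",
                                                 "midpoint")) {
  mode <- match.arg(mode)
  if (normalize_chrom(gene$chromosome) != normalize_chrom(qtl$chromosome))
    return(FALSE)
  switch(mode,
         any = gene$start <= qtl$span_end && gene$end >= qtl$span_start,
         containment = gene$start >= qtl$span_start &&
           gene$end <= qtl$span_end,
         midpoint = {
           mid <- (gene$start + gene$end) / 2
           mid >= qtl$span_start && mid <= qtl$span_end
         })
}

#' Signed genetic distance from a gene to a QTL peak
#'
#' `(gene midpoint - peak)` in Mb times a cM-per-Mb conversion; negative
#' means the gene lies left of the peak. The conversion is a reporting
#' annotation only — it is never used as a screening filter.
#'
#' @param gene one gene row.
#' @param qtl one QTL row with `peak` (bp).
#' @param cm_per_mb scalar or per-chromosome named vector of conversions.
#' @return signed distance in cM.
#' @export
distance_to_peak_cm <- function(gene, qtl, cm_per_mb = 1.0) {
  conv <- if (length(cm_per_mb) == 1 && is.null(names(cm_per_mb)))
    cm_per_mb
  else unname(cm_per_mb[normalize_chrom(gene$chromosome)])
  if (length(conv) != 1 || is.null(conv) || is.na(conv))
    stop("no cM-per-Mb conversion for chromosome ", gene$chromosome)
  ((gene$start + gene$end) / 2 - qtl$peak) / 1e6 * conv
}

#' Distance from a gene to a SNP in Mb (nearest edge)
#'
#' 0 when the SNP lies inside the gene span, otherwise the distance from the
#' SNP to the nearest gene edge; `Inf` on different chromosomes.
#'
#' @param gene one gene row.
#' @param snp one SNP row (`chromosome`, `position`).
#' @return distance in Mb, >= 0.
#' @export
gene_snp_distance_mb <- function(gene, snp) {
  if (normalize_chrom(gene$chromosome) != normalize_chrom(snp$chromosome))
    return(Inf)
  if (snp$position >= gene$start && snp$position <= gene$end) return(0)
  min(abs(snp$position - gene$start), abs(snp$position - gene$end)) / 1e6
}

check_chrom_compat <- function(degs, catalog) {
  shared <- intersect(unique(normalize_chrom(degs$chromosome)),
                      unique(normalize_chrom(catalog$chromosome)))
  if (length(shared) == 0)
    stop("no shared chromosome names between DEGs (",
         paste(utils::head(unique(degs$chromosome), 3), collapse = ","),
         "...) and catalog (",
         paste(utils::head(unique(catalog$chromosome), 3), collapse = ","),
         "...). Check the naming scheme (e.g. 'chr4' vs '4'); names are ",
         "normalized by stripping a leading 'chr'.")
}

#' Screen DEGs against a QTL catalog
#'
#' A gene passes when its span overlaps at least one catalog QTL under the
#' chosen overlap mode. Evidence rows list every matched QTL with the signed
#' cM distance from the gene midpoint to the QTL peak.
#'
#' @param degs DEG table with `gene_id`, `chromosome`, `start`, `end`.
#' @param qtl_catalog QTL catalog tibble (pre-filtered by trait class).
#' @param mode overlap mode (see [gene_qtl_overlap()]).
#' @param cm_per_mb cM-per-Mb conversion for the reported peak distances.
#' @return list with `pass` (gene-id vector) and `evidence` (tibble:
#'   gene_id, qtl_id, trait_code, distance_cm).
#' @export
qtl_screen <- function(degs, qtl_catalog, mode = "any", cm_per_mb = 1.0) {
  if (nrow(qtl_catalog) == 0 || nrow(degs) == 0)
    return(list(pass = character(0), evidence = tibble::tibble(
      gene_id = character(0), qtl_id = character(0),
      trait_code = character(0), distance_cm = numeric(0))))
  check_chrom_compat(degs, qtl_catalog)
  g <- GenomicRanges::GRanges(normalize_chrom(degs$chromosome),
                              IRanges::IRanges(degs$start, degs$end))
  q <- GenomicRanges::GRanges(normalize_chrom(qtl_catalog$chromosome),
                              IRanges::IRanges(qtl_catalog$span_start,
                                               qtl_catalog$span_end))
  type <- switch(mode, any = "any", containment = "within",
                 midpoint = "any", stop("unknown overlap mode: ", mode))
  if (mode == "midpoint") {
    mid <- floor((degs$start + degs$end) / 2)
    g <- GenomicRanges::GRanges(normalize_chrom(degs$chromosome),
                                IRanges::IRanges(mid, mid))
  }
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(g, q, type = type))
  gi <- S4Vectors::queryHits(hits)
  qi <- S4Vectors::subjectHits(hits)
  ev <- tibble::tibble(
    gene_id = degs$gene_id[gi],
    qtl_id = qtl_catalog$qtl_id[qi],
    trait_code = qtl_catalog$trait_code[qi],
    distance_cm = vapply(seq_along(gi), function(k)
      distance_to_peak_cm(degs[gi[k], ], qtl_catalog[qi[k], ], cm_per_mb),
      1.0))
  ev <- ev[order(match(ev$gene_id, degs$gene_id), ev$qtl_id), ]
  list(pass = degs$gene_id[sort(unique(gi))], evidence = ev)
}

#' Screen DEGs against a SNP catalog
#'
#' A gene passes when some SNP lies at a nearest-edge distance strictly less
#' than `max_mb` (a SNP at exactly `max_mb` does not qualify). Evidence rows
#' list every qualifying SNP with its distance.
#'
#' @param degs DEG table with `gene_id`, `chromosome`, `start`, `end`.
#' @param snp_catalog SNP catalog tibble (pre-filtered by trait class).
#' @param max_mb distance threshold in Mb (strict), default 5.
#' @return list with `pass` and `evidence` (tibble: gene_id, snp_name,
#'   trait_code, distance_mb).
#' @export
snp_screen <- function(degs, snp_catalog, max_mb = 5) {
  if (max_mb <= 0) stop("max_mb must be > 0")
  if (nrow(snp_catalog) == 0 || nrow(degs) == 0)
    return(list(pass = character(0), evidence = tibble::tibble(
      gene_id = character(0), snp_name = character(0),
      trait_code = character(0), distance_mb = numeric(0))))
  check_chrom_compat(degs, snp_catalog)
  gchr <- normalize_chrom(degs$chromosome)
  schr <- normalize_chrom(snp_catalog$chromosome)
  ev <- lapply(seq_len(nrow(degs)), function(i) {
    j <- which(schr == gchr[i])
    if (!length(j)) return(NULL)
    pos <- snp_catalog$position[j]
    inside <- pos >= degs$start[i] & pos <= degs$end[i]
    d <- ifelse(inside, 0,
                pmin(abs(pos - degs$start[i]), abs(pos - degs$end[i])) / 1e6)
    k <- which(d < max_mb)
    if (!length(k)) return(NULL)
    tibble::tibble(gene_id = degs$gene_id[i],
                   snp_name = snp_catalog$snp_name[j[k]],
                   trait_code = snp_catalog$trait_code[j[k]],
                   distance_mb = d[k])
  })
  ev <- dplyr::bind_rows(ev)
  if (nrow(ev) == 0)
    ev <- tibble::tibble(gene_id = character(0), snp_name = character(0),
                         trait_code = character(0), distance_mb = numeric(0))
  list(pass = degs$gene_id[degs$gene_id %in% unique(ev$gene_id)],
       evidence = ev)
}

#' Intersect the two screens into the candidate set
#'
#' Candidates are the genes passing both the QTL and the SNP screen. The
#' report carries, per candidate, every matched QTL with its signed cM peak
#' distance and every matched SNP with its Mb distance. Trait agreement
#' between a gene's QTL matches and SNP matches is not required.
#'
#' @param qtl_result result of [qtl_screen()].
#' @param snp_result result of [snp_screen()].
#' @param degs optional DEG table used to attach gene coordinates.
#' @return list with `candidates` (gene ids), `report` (tibble with one row
#'   per candidate x evidence pairing), `qtl_pass`, `snp_pass`.
#' @export
intersect_candidates <- function(qtl_result, snp_result, degs = NULL) {
  cand <- intersect(qtl_result$pass, snp_result$pass)
  qe <- qtl_result$evidence[qtl_result$evidence$gene_id %in% cand, ]
  se <- snp_result$evidence[snp_result$evidence$gene_id %in% cand, ]
  report <- dplyr::bind_rows(
    if (nrow(qe)) tibble::tibble(gene_id = qe$gene_id, evidence = "qtl",
                                 feature_id = qe$qtl_id,
                                 trait_code = qe$trait_code,
                                 distance = qe$distance_cm,
                                 unit = "cM"),
    if (nrow(se)) tibble::tibble(gene_id = se$gene_id, evidence = "snp",
                                 feature_id = se$snp_name,
                                 trait_code = se$trait_code,
                                 distance = se$distance_mb,
                                 unit = "Mb"))
  if (is.null(report) || nrow(report) == 0)
    report <- tibble::tibble(gene_id = character(0), evidence = character(0),
                             feature_id = character(0),
                             trait_code = character(0),
                             distance = numeric(0), unit = character(0))
  if (!is.null(degs) && nrow(report) > 0) {
    idx <- match(report$gene_id, degs$gene_id)
    report$chromosome <- degs$chromosome[idx]
    report$start <- degs$start[idx]
    report$end <- degs$end[idx]
  }
  report <- report[order(report$gene_id, report$evidence,
                         report$feature_id), ]
  list(candidates = sort(cand), report = report,
       qtl_pass = qtl_result$pass, snp_pass = snp_result$pass)
}

#' Run the full positional screen
#'
#' Filters both catalogs to a trait class, runs the QTL and SNP screens on
#' the DEG table and intersects them. This is the procedure that turns a DEG
#' list plus public QTL/SNP catalogs into a candidate-gene report.
#'
#' @param degs DEG table (`gene_id`, `chromosome`, `start`, `end`).
#' @param qtl_catalog,snp_catalog catalog tibbles.
#' @param trait_class trait class to screen within.
#' @param max_mb SNP distance threshold (Mb, strict).
#' @param mode QTL overlap mode.
#' @param cm_per_mb cM-per-Mb conversion for reporting.
#' @param vocab trait vocabulary.
#' @return the [intersect_candidates()] result plus `parameters`.
#' @export
screen_candidates <- function(degs, qtl_catalog, snp_catalog,
                              trait_class = "meat_quality", max_mb = 5,
                              mode = "any", cm_per_mb = 1.0,
                              vocab = trait_vocabulary()) {
  qc <- filter_by_trait_class(qtl_catalog, trait_class, vocab)
  sc <- filter_by_trait_class(snp_catalog, trait_class, vocab)
  qr <- qtl_screen(degs, qc, mode = mode, cm_per_mb = cm_per_mb)
  sr <- snp_screen(degs, sc, max_mb = max_mb)
  out <- intersect_candidates(qr, sr, degs = degs)
  out$parameters <- list(trait_class = trait_class, max_mb = max_mb,
                         mode = mode, cm_per_mb = cm_per_mb)
  out
}

#' Read a QTL catalog TSV
#' @param path TSV with columns qtl_id, chromosome (or chr), span_start,
#'   span_end, peak, trait_code, trait_class, source_ref.
#' @return catalog tibble with normalized chromosome names.
#' @export
read_qtl_catalog <- function(path) {
  x <- read_tsv_plain(path)
  if (!is.null(x[["chr"]]) && is.null(x[["chromosome"]]))
    x$chromosome <- x$chr
  req <- c("qtl_id", "chromosome", "span_start", "span_end", "trait_code")
  if (!all(req %in% names(x)))
    stop("QTL catalog must have columns: ", paste(req, collapse = ", "))
  if (any(x$span_start > x$span_end)) stop("QTL span_start > span_end")
  x$chromosome <- normalize_chrom(x$chromosome)
  x
}

#' Read a SNP catalog TSV
#' @param path TSV with columns snp_name, chromosome (or chr), position,
#'   trait_code, trait_class, source_ref.
#' @return catalog tibble with normalized chromosome names.
#' @export
read_snp_catalog <- function(path) {
  x <- read_tsv_plain(path)
  if (!is.null(x[["chr"]]) && is.null(x[["chromosome"]]))
    x$chromosome <- x$chr
  req <- c("snp_name", "chromosome", "position", "trait_code")
  if (!all(req %in% names(x)))
    stop("SNP catalog must have columns: ", paste(req, collapse = ", "))
  if (any(x$position < 1)) stop("SNP positions must be >= 1")
  x$chromosome <- normalize_chrom(x$chromosome)
  x
}

#' Export gene spans as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param genes gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chromosome,
                     as.integer(genes$start) - 1L, as.integer(genes$end),
                     genes$gene_id), path)
  invisible(path)
}
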