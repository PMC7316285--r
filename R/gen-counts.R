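#' Generate a synthetic fragment-count matrix with planted DEGs
#'
#' Draws per-gene counts from a negative-binomial model (variance
#' mu + dispersion * mu^2). Every gene gets a base mean (log-uniform over
#' `base_mean_range`); planted DEGs draw theirs from
#' `planted_base_mean_range` and have their case-group ("steer") means scaled
#' by 2^log2FC relative to the calibrator group ("bull"). Per-sample expected
#' totals are drawn uniformly from `library_size_range`.
#'
#' The planted truth returned alongside the matrix also fixes, among the
#' annotated planted DEGs, which genes the catalog generators will plant to
#' pass the QTL screen, the SNP screen, and both (the candidate set) —
#' candidates are a subset of both pass sets by construction.
#'
#' @param genes gene table from [gen_annotation()].
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix genes x samples), `samples`
#'   (tibble: sample, group), and `truth` (class `planted_truth`: `deg` table
#'   with true log2FC, `qtl_pass_ids`, `snp_pass_ids`, `candidate_gene_ids`).
#' @export
gen_counts <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) stop("dispersion must be > 0")
  if (config$n_planted_degs > nrow(genes))
    stop("n_planted_degs cannot exceed the number of genes")
  withr::local_seed(derive_seed(config$seed, "counts"))

  n <- nrow(genes)
  npg <- config$n_samples_per_group
  split <- planted_status_split(config$n_planted_degs)
  planted_idx <- integer(0)
  for (st in names(split)) {
    pool <- setdiff(which(genes$annotation_status == st), planted_idx)
    if (length(pool) < split[[st]])
      stop("not enough '", st, "' genes to plant ", split[[st]], " DEGs")
    planted_idx <- c(planted_idx, sample(pool, split[[st]]))
  }
  lfc <- numeric(n)
  mag <- runif(length(planted_idx), config$log2fc_range[1],
               config$log2fc_range[2])
  sgn <- ifelse(runif(length(planted_idx)) < config$prob_up, 1, -1)
  lfc[planted_idx] <- mag * sgn

  base <- exp(runif(n, log(config$base_mean_range[1]),
                    log(config$base_mean_range[2])))
  base[planted_idx] <- exp(runif(length(planted_idx),
                                 log(config$planted_base_mean_range[1]),
                                 log(config$planted_base_mean_range[2])))

  samples <- tibble::tibble(
    sample = c(sprintf("bull_%d", seq_len(npg)),
               sprintf("steer_%d", seq_len(npg))),
    group = rep(c("bull", "steer"), each = npg)
  )
  lib <- runif(nrow(samples), config$library_size_range[1],
               config$library_size_range[2])
  rel_bull <- base
  rel_steer <- base * 2^lfc
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(samples))) {
    rel <- if (samples$group[j] == "steer") rel_steer else rel_bull
    mu <- rel / sum(rel) * lib[j]
    counts[, j] <- as.integer(rnbinom(n, mu = mu, size = size))
  }

  truth <- make_planted_truth(genes, planted_idx, lfc, config)
  list(counts = counts, samples = samples, truth = truth)
}

make_planted_truth <- function(genes, planted_idx, lfc, config) {
  deg <- tibble::tibble(
    gene_id = genes$gene_id[planted_idx],
    annotation_status = genes$annotation_status[planted_idx],
    true_log2fc = lfc[planted_idx],
    base_mean = NA_real_
  )
  annotated <- deg$gene_id[deg$annotation_status == "annotated"]
  n_cand <- n_planted_candidates(config)
  n_qtl_only <- config$n_qtl_pass - n_cand
  n_snp_only <- config$n_snp_pass - n_cand
  need <- n_cand + n_qtl_only + n_snp_only
  if (length(annotated) < need)
    stop("planted pass sets need ", need, " annotated planted DEGs, have ",
         length(annotated),
         " (qtl_pass + snp_pass - candidates must fit in the annotated set)")
  # Margin-respecting catalogs need two geometric guarantees:
  #  * QTL-pass genes (candidates + qtl-only) own a stretch not shared with
  #    any other gene, where their planted QTL will sit;
  #  * SNP-pass labels are constant within proximity clusters of annotated
  #    planted DEGs. Genes in different single-linkage components at the
  #    2 * (snp_max_mb + margin) threshold are farther apart than that, so a
  #    SNP planted within snp_max - margin of a pass gene always stays more
  #    than snp_max + margin away from every non-pass gene.
  g <- genes[match(annotated, genes$gene_id), ]
  n_a <- nrow(g)
  need_sep <- 2 * (config$snp_max_mb + config$placement_margin_mb)
  dist_mb <- matrix(Inf, n_a, n_a)
  for (i in seq_len(n_a)) {
    same <- which(g$chromosome == g$chromosome[i])
    dist_mb[i, same] <- pmax(0, pmax(g$start[i], g$start[same]) -
                                pmin(g$end[i], g$end[same])) / 1e6
  }
  diag(dist_mb) <- Inf
  comp <- seq_len(n_a)
  repeat {
    changed <- FALSE
    for (i in seq_len(n_a)) {
      link <- c(i, which(dist_mb[i, ] < need_sep))
      m <- min(comp[link])
      if (any(comp[link] != m)) {
        comp[link] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  free_ok <- vapply(seq_len(n_a), function(i)
    !is.null(gene_free_subinterval(genes, g[i, ])), TRUE)

  # QTL-only genes: free-stretch singletons (isolated from every other
  # annotated planted DEG by construction of the components)
  singleton <- vapply(seq_len(n_a), function(i) sum(comp == comp[i]) == 1,
                      TRUE)
  elig <- which(singleton & free_ok)
  elig <- elig[sample.int(length(elig))]
  if (length(elig) < n_qtl_only)
    stop("not enough isolated planted DEGs with a gene-free stretch for ",
         "the QTL-only set")
  qtl_only_idx <- utils::head(elig, n_qtl_only)

  # SNP-pass set: whole components assembled to the exact target size
  target <- n_cand + n_snp_only
  comp_ids <- setdiff(unique(comp), comp[qtl_only_idx])
  comp_ids <- comp_ids[sample.int(length(comp_ids))]
  chosen <- integer(0)
  total <- 0L
  for (cid in comp_ids) {
    size <- sum(comp == cid)
    if (total + size <= target) {
      chosen <- c(chosen, cid)
      total <- total + size
    }
    if (total == target) break
  }
  if (total != target)
    stop("cannot assemble a SNP-pass set of ", target, " genes from the ",
         "proximity clusters of annotated planted DEGs")
  snp_pass_idx <- which(comp %in% chosen)
  cand_pool <- snp_pass_idx[free_ok[snp_pass_idx]]
  if (length(cand_pool) < n_cand)
    stop("not enough SNP-pass planted DEGs with a gene-free stretch for ",
         "the candidate set")
  cand_idx <- cand_pool[sample.int(length(cand_pool), n_cand)]
  cand <- annotated[cand_idx]
  qtl_only <- annotated[qtl_only_idx]
  snp_only <- annotated[setdiff(snp_pass_idx, cand_idx)]
  structure(list(
    deg = deg,
    qtl_pass_ids = sort(c(cand, qtl_only)),
    snp_pass_ids = sort(c(cand, snp_only)),
    candidate_gene_ids = sort(cand)
  ), class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted truth:", nrow(x$deg), "DEGs (",
      sum(x$deg$annotation_status == "annotated"), "annotated );",
      length(x$qtl_pass_ids), "QTL-pass,", length(x$snp_pass_ids),
      "SNP-pass,", length(x$candidate_gene_ids), "candidates\n")
  invisible(x)
}

#' Write a counts matrix as TSV
#'
#' @param counts integer matrix genes x samples.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv_plain(df, path)
}

#' Read a counts matrix from TSV
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}
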