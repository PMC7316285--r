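# Shared test helpers: a small, fast simulation configuration plus
# brute-force oracles written directly from the definitions, independent of
# the package implementations they cross-check.

# Small configuration sized by the same power analysis as the defaults
# (see ?sim_config): 6 animals/group, low dispersion and strong planted
# effects keep every planted DEG detectable at transcriptome-wide FDR.
small_config <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 1200L, n_samples_per_group = 6L,
             n_planted_degs = 30L, log2fc_range = c(2.5, 4),
             nb_dispersion = 0.01, planted_base_mean_range = c(500, 5000),
             library_size_range = c(4e6, 6e6), n_qtls = 20L, n_snps = 40L,
             n_qtl_pass = 5L, n_snp_pass = 12L,
             planted_candidate_fraction = 3 / 5, ...)
}

# Benjamini-Hochberg step-up, by definition: sort, multiply by n/rank,
# enforce monotonicity from the largest p down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# QTL screen by definition: a gene passes if any same-chromosome QTL
# satisfies the interval predicate of the chosen mode.
oracle_qtl_pass <- function(degs, qtls, mode = "any") {
  pass <- vapply(seq_len(nrow(degs)), function(i) {
    same <- normalize_chrom(qtls$chromosome) ==
      normalize_chrom(degs$chromosome[i])
    if (!any(same)) return(FALSE)
    qs <- qtls$span_start[same]
    qe <- qtls$span_end[same]
    gs <- degs$start[i]
    ge <- degs$end[i]
    hit <- switch(mode,
                  any = gs <= qe & ge >= qs,
                  containment = gs >= qs & ge <= qe,
                  midpoint = {
                    m <- (gs + ge) / 2
                    m >= qs & m <= qe
                  })
    any(hit)
  }, TRUE)
  degs$gene_id[pass]
}

# SNP screen by definition: nearest-edge distance (0 inside the span),
# strict < max_mb.
oracle_snp_pass <- function(degs, snps, max_mb = 5) {
  pass <- vapply(seq_len(nrow(degs)), function(i) {
    same <- normalize_chrom(snps$chromosome) ==
      normalize_chrom(degs$chromosome[i])
    if (!any(same)) return(FALSE)
    pos <- snps$position[same]
    inside <- pos >= degs$start[i] & pos <= degs$end[i]
    d <- ifelse(inside, 0,
                pmin(abs(pos - degs$start[i]), abs(pos - degs$end[i])) / 1e6)
    any(d < max_mb)
  }, TRUE)
  degs$gene_id[pass]
}

# Random gene/catalog tables for oracle cross-checks.
random_genes <- function(n, n_chrom = 5, max_pos = 5e7) {
  st <- floor(runif(n, 1, max_pos))
  tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(n)),
    chromosome = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = st,
    end = st + floor(runif(n, 1, 2e5)))
}

random_qtls <- function(n, n_chrom = 5, max_pos = 5e7) {
  st <- floor(runif(n, 1, max_pos))
  tibble::tibble(
    qtl_id = sprintf("Q%05d", seq_len(n)),
    chromosome = as.character(sample.int(n_chrom, n, replace = TRUE)),
    span_start = st, span_end = st + floor(runif(n, 1, 2e6)),
    peak = st, trait_code = "CW", trait_class = "meat_quality")
}

random_snps <- function(n, n_chrom = 5, max_pos = 5e7) {
  tibble::tibble(
    snp_name = sprintf("S%05d", seq_len(n)),
    chromosome = as.character(sample.int(n_chrom, n, replace = TRUE)),
    position = floor(runif(n, 1, max_pos)),
    trait_code = "CW", trait_class = "meat_quality")
}
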