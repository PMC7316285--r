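#' Approximate Bos taurus autosome lengths
#'
#' Autosome lengths (bp) rounded to 0.1 Mb, matching the scale of the UMD3.1
#' cattle assembly. Used as the default simulated genome so planted features
#' live at realistic coordinates and densities.
#'
#' @return named numeric vector, names "1".."29".
#' @export
bta_chrom_lengths <- function() {
  mb <- c(158.3, 137.1, 121.4, 120.8, 121.2, 119.5, 112.6, 113.4, 105.7,
          104.3, 107.3, 91.2, 84.2, 84.6, 85.0, 81.7, 75.2, 66.0, 64.1,
          72.0, 71.6, 61.4, 52.5, 62.7, 42.9, 51.7, 45.4, 46.3, 51.5)
  setNames(mb * 1e6, as.character(seq_along(mb)))
}

#' Controlled vocabulary of trait codes
#'
#' Trait codes used to tag QTL and SNP catalog entries, split into the two
#' trait classes the screening stage distinguishes: meat/carcass quality and
#' reproduction.
#'
#' @return tibble with columns `trait_code`, `trait_class`, `description`.
#' @export
trait_vocabulary <- function() {
  tibble::tribble(
    ~trait_code, ~trait_class,   ~description,
    "CW",        "meat_quality", "carcass weight",
    "IMF",       "meat_quality", "intramuscular fat",
    "FT12R",     "meat_quality", "fat thickness at the 12th rib",
    "LMY",       "meat_quality", "lean meat yield",
    "SF",        "meat_quality", "shear force",
    "CC",        "meat_quality", "carcass conformation",
    "IMFP",      "meat_quality", "intramuscular fat percentage",
    "LDMA",      "meat_quality", "loin muscle area",
    "MS",        "meat_quality", "marbling score",
    "SC",        "reproduction", "scrotal circumference",
    "GL",        "reproduction", "gestation length",
    "SM",        "reproduction", "sperm motility",
    "CCR",       "reproduction", "cow conception rate"
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate the
#' shape of the study design the package targets: two groups of cattle,
#' roughly 11,500 expressed genes, 57 planted differentially expressed genes
#' (41 annotated, 4 pseudogenes, 12 novel) with |log2 fold change| between
#' 1.2 and 4, and QTL/SNP catalogs planted so that 9 annotated DEGs fall
#' inside a meat-quality QTL, 39 lie within 5 Mb of a meat-quality SNP, and
#' exactly 7 do both.
#'
#' Sample size, dispersion and planted base means are set from an a-priori
#' power analysis of the per-gene Welch test on log2 FPKM, not from the
#' emulated study. With g genes and k planted DEGs the Benjamini-Hochberg
#' step-up can only recover all k if every planted raw p-value falls below
#' alpha * k / g (about 2.5e-4 at the defaults). A planted gene's log2
#' expression has per-sample variance close to (dispersion + 1/mu) / ln(2)^2,
#' so the expected t statistic at the weakest planted corner
#' (|log2FC| = 1.2, mu = 200, dispersion = 0.02) is about 9 — which clears
#' the step-up bound at df = 2n-2 = 10 (p ~ 4e-6) but not at the df = 4 of
#' three animals per group, where even t = 15 only reaches p ~ 1e-4.
#' Hence the defaults use six animals per group; three-per-group designs
#' remain fully supported but need either fewer genes tested or stronger
#' planted effects to yield discoveries at transcriptome-wide FDR.
#'
#' @param seed integer root seed; every generator derives its own sub-seed
#'   from it, so outputs are reproducible jointly and per stage.
#' @param n_genes number of genes to simulate.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_samples_per_group RNA-seq animals per group.
#' @param n_planted_degs number of genes given a non-zero planted log2FC.
#' @param log2fc_range magnitude range of planted |log2FC|.
#' @param prob_up probability a planted DEG is up-regulated in the case group.
#' @param nb_dispersion negative-binomial dispersion (variance = mu + d*mu^2).
#' @param base_mean_range log-uniform range of per-gene expected fragments.
#' @param planted_base_mean_range base-mean range for planted DEGs.
#' @param library_size_range per-sample total-fragment target range.
#' @param gene_length_range log-uniform range of simulated gene lengths (bp).
#' @param n_qtls,n_snps catalog sizes (planted passes + decoys).
#' @param n_qtl_pass,n_snp_pass number of annotated planted DEGs planted to
#'   pass the QTL screen / the SNP screen.
#' @param planted_candidate_fraction fraction of `n_qtl_pass` genes that are
#'   also planted to pass the SNP screen; the candidate count is
#'   `round(planted_candidate_fraction * n_qtl_pass)`.
#' @param snp_max_mb SNP-screen distance threshold the catalogs are planted
#'   against (Mb).
#' @param placement_margin_mb clearance (Mb) kept between planted non-pass
#'   genes and the SNP distance threshold so rounding cannot flip labels.
#' @param trait_vocab trait vocabulary tibble (see [trait_vocabulary()]).
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 11500L,
                       chrom_lengths = bta_chrom_lengths(),
                       n_samples_per_group = 6L,
                       n_planted_degs = 57L,
                       log2fc_range = c(1.2, 4),
                       prob_up = 0.66,
                       nb_dispersion = 0.02,
                       base_mean_range = c(5, 5000),
                       planted_base_mean_range = c(200, 5000),
                       library_size_range = c(45e6, 55e6),
                       gene_length_range = c(1e3, 2e5),
                       n_qtls = 60L,
                       n_snps = 120L,
                       n_qtl_pass = 9L,
                       n_snp_pass = 39L,
                       planted_candidate_fraction = 7 / 9,
                       snp_max_mb = 5,
                       placement_margin_mb = 1,
                       trait_vocab = trait_vocabulary()) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom_lengths = chrom_lengths,
              n_samples_per_group = as.integer(n_samples_per_group),
              n_planted_degs = as.integer(n_planted_degs),
              log2fc_range = as.numeric(log2fc_range), prob_up = prob_up,
              nb_dispersion = nb_dispersion,
              base_mean_range = as.numeric(base_mean_range),
              planted_base_mean_range = as.numeric(planted_base_mean_range),
              library_size_range = as.numeric(library_size_range),
              gene_length_range = as.numeric(gene_length_range),
              n_qtls = as.integer(n_qtls), n_snps = as.integer(n_snps),
              n_qtl_pass = as.integer(n_qtl_pass),
              n_snp_pass = as.integer(n_snp_pass),
              planted_candidate_fraction = planted_candidate_fraction,
              snp_max_mb = snp_max_mb,
              placement_margin_mb = placement_margin_mb,
              trait_vocab = trait_vocab)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (length(cfg$chrom_lengths) == 0L || any(cfg$chrom_lengths <= 0))
    stop("chrom_lengths must be a non-empty vector of positive lengths")
  if (is.null(names(cfg$chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  if (cfg$n_planted_degs > cfg$n_genes)
    stop("n_planted_degs cannot exceed n_genes")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (diff(cfg$log2fc_range) < 0 || any(cfg$log2fc_range < 0))
    stop("log2fc_range must be non-negative magnitudes, low <= high")
  if (cfg$planted_candidate_fraction < 0 || cfg$planted_candidate_fraction > 1)
    stop("planted_candidate_fraction must lie in [0, 1]")
  if (cfg$n_samples_per_group < 2L)
    stop("n_samples_per_group must be >= 2")
  n_cand <- round(cfg$planted_candidate_fraction * cfg$n_qtl_pass)
  if (cfg$n_snp_pass < n_cand)
    stop("n_snp_pass must be at least the planted candidate count")
  invisible(cfg)
}

#' Number of planted candidate genes implied by a configuration
#' @param config a [sim_config()] object.
#' @return integer count.
#' @export
n_planted_candidates <- function(config) {
  as.integer(round(config$planted_candidate_fraction * config$n_qtl_pass))
}

# Split of planted DEGs across annotation classes. Mirrors the target study
# shape 41 annotated : 4 pseudogene : 12 novel, rescaled to n_planted_degs.
planted_status_split <- function(n_planted) {
  props <- c(annotated = 41, pseudogene = 4, novel = 12) / 57
  n <- floor(props * n_planted)
  rem <- n_planted - sum(n)
  if (rem > 0) n["annotated"] <- n["annotated"] + rem
  n
}
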