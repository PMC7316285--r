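#' Generate a synthetic qPCR Ct plate consistent with planted fold changes
#'
#' Emulates a triplicate SYBR-green validation plate: for each target gene
#' the case-group ("steer") Ct is shifted by minus the planted log2 fold
#' change relative to the calibrator group ("bull"), reference genes have
#' identical group means, and a per-animal offset (pipetting / input amount)
#' is shared by all genes of that animal, so it cancels in reference
#' normalization. Replicate-level noise is normal with SD `noise_sd` cycles.
#'
#' @param truth `planted_truth` from [gen_counts()], supplying target genes
#'   and their true log2FC; targets are drawn from the annotated planted DEGs.
#' @param reference_genes character vector of reference gene names.
#' @param noise_sd replicate noise SD in cycles (>= 0).
#' @param seed integer seed.
#' @param n_targets number of target genes to draw from the truth.
#' @param n_per_group animals per group on the plate.
#' @param n_replicates technical replicates per gene x animal.
#' @return list with `plate` (tibble: gene, sample, group, replicate, ct),
#'   `reference_genes`, and `targets` (tibble: gene, true_log2fc).
#' @export
gen_qpcr <- function(truth, reference_genes = c("ACTB", "GAPDH"),
                     noise_sd = 0.2, seed = 1L, n_targets = 9L,
                     n_per_group = 3L, n_replicates = 3L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  withr::local_seed(derive_seed(seed, "qpcr"))
  pool <- truth$deg[truth$deg$annotation_status == "annotated", ]
  n_targets <- min(n_targets, nrow(pool))
  tgt <- pool[sample(nrow(pool), n_targets), ]
  targets <- tibble::tibble(gene = tgt$gene_id, true_log2fc = tgt$true_log2fc)

  samples <- tibble::tibble(
    sample = c(sprintf("bull_%d", seq_len(n_per_group)),
               sprintf("steer_%d", seq_len(n_per_group))),
    group = rep(c("bull", "steer"), each = n_per_group),
    offset = rnorm(2 * n_per_group, 0, 0.5))

  base_ct <- c(setNames(runif(n_targets, 22, 30), targets$gene),
               setNames(runif(length(reference_genes), 16, 20),
                        reference_genes))
  shift <- c(setNames(-targets$true_log2fc, targets$gene),
             setNames(rep(0, length(reference_genes)), reference_genes))

  grid <- expand.grid(gene = names(base_ct), si = seq_len(nrow(samples)),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  is_steer <- samples$group[grid$si] == "steer"
  ct <- base_ct[grid$gene] + ifelse(is_steer, shift[grid$gene], 0) +
    samples$offset[grid$si] + rnorm(nrow(grid), 0, noise_sd)
  plate <- tibble::tibble(
    gene = grid$gene, sample = samples$sample[grid$si],
    group = samples$group[grid$si], replicate = grid$replicate, ct = ct)
  list(plate = plate, reference_genes = reference_genes, targets = targets)
}
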