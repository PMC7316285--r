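#' Run the full synthetic pipeline end to end
#'
#' Generates annotation, counts, catalogs, phenotypes and a qPCR plate from
#' one configuration, then runs every analysis stage: differential
#' expression (log2-FPKM Welch test, BH adjustment, strict padj < alpha
#' call), positional QTL/SNP screening of the annotated called DEGs, trait
#' comparisons, and ddCt validation of the planted candidates. The planted
#' truth is carried through so recovery can be checked.
#'
#' @param config a [sim_config()] object.
#' @param alpha adjusted-p DEG threshold (strict).
#' @param max_mb SNP screen distance threshold (Mb, strict).
#' @param mode QTL overlap mode.
#' @param trait_specs optional phenotype specifications for the trait stage
#'   (default: the packaged trait summaries at n = 10).
#' @param qpcr_noise_sd replicate noise for the simulated validation plate.
#' @param out_dir optional directory; when given, every stage table is
#'   written there as TSV together with a JSON run manifest.
#' @return list with the stage outputs: `genes`, `samples`, `truth`, `de`,
#'   `degs`, `screen`, `traits`, `qpcr` (fold changes + correlation), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), alpha = 0.05, max_mb = 5,
                         mode = "any", trait_specs = NULL,
                         qpcr_noise_sd = 0.2, out_dir = NULL) {
  genes <- gen_annotation(config)
  cc <- gen_counts(genes, config)
  qtl_cat <- gen_qtl_catalog(genes, cc$truth, config)
  snp_cat <- gen_snp_catalog(genes, cc$truth, config)

  de <- de_test(cc$counts, cc$samples, genes$length)
  de$chromosome <- genes$chromosome[match(de$gene_id, genes$gene_id)]
  de$start <- genes$start[match(de$gene_id, genes$gene_id)]
  de$end <- genes$end[match(de$gene_id, genes$gene_id)]
  de$annotation_status <-
    genes$annotation_status[match(de$gene_id, genes$gene_id)]
  de$padj <- bh_adjust(de$pvalue)
  called <- call_degs(de, alpha = alpha)
  deg_annot <- called$degs[called$degs$annotation_status == "annotated", ]

  screen <- screen_candidates(deg_annot, qtl_cat, snp_cat,
                              trait_class = "meat_quality", max_mb = max_mb,
                              mode = mode)

  if (is.null(trait_specs)) trait_specs <- table1_trait_specs()
  phen <- gen_phenotypes(trait_specs, n_per_group = 10L, seed = config$seed)
  traits <- compare_traits(phen, mode = "raw")

  qp <- gen_qpcr(cc$truth, noise_sd = qpcr_noise_sd, seed = config$seed)
  fc <- qpcr_fold_changes(qp$plate, qp$reference_genes)
  rnaseq_fc <- de[, c("gene_id", "log2fc")]
  corr <- correlate_with_rnaseq(fc, rnaseq_fc)

  manifest <- list(
    package_version = as.character(utils::packageVersion("beefcand")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_genes = nrow(genes),
    n_called_degs = nrow(called$degs),
    n_annotated_degs = nrow(deg_annot),
    n_qtl_pass = length(screen$qtl_pass),
    n_snp_pass = length(screen$snp_pass),
    n_candidates = length(screen$candidates))

  result <- list(genes = genes, samples = cc$samples, truth = cc$truth,
                 de = de, degs = called, screen = screen, traits = traits,
                 qpcr = list(plate = qp$plate, targets = qp$targets,
                             fold_changes = fc, correlation = corr),
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(result$de, file.path(out_dir, "de_table.tsv"))
  write_tsv_plain(result$degs$degs, file.path(out_dir, "degs.tsv"))
  write_tsv_plain(result$screen$report,
                  file.path(out_dir, "candidate_report.tsv"))
  write_tsv_plain(result$traits, file.path(out_dir, "trait_comparisons.tsv"))
  write_tsv_plain(result$qpcr$fold_changes,
                  file.path(out_dir, "qpcr_fold_changes.tsv"))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a candidate-gene report
#'
#' Deterministic markdown plus TSV rendering of a screening result, with
#' optional trait comparisons and qPCR fold changes appended. Rendering the
#' same result twice produces identical bytes.
#'
#' @param screen result of [screen_candidates()] (or
#'   [intersect_candidates()]).
#' @param traits optional trait comparison tibble from [compare_traits()].
#' @param fold_changes optional qPCR fold-change tibble.
#' @param path optional file to write the markdown to.
#' @return the markdown lines, invisibly when `path` is given.
#' @export
render_report <- function(screen, traits = NULL, fold_changes = NULL,
                          path = NULL) {
  md <- c("# Candidate-gene screening report", "",
          sprintf("- QTL screen pass: %d genes", length(screen$qtl_pass)),
          sprintf("- SNP screen pass: %d genes", length(screen$snp_pass)),
          sprintf("- Candidates (both screens): %d genes",
                  length(screen$candidates)), "")
  if (length(screen$candidates)) {
    md <- c(md, "## Candidates", "",
            paste0("- ", screen$candidates), "")
  }
  if (nrow(screen$report)) {
    md <- c(md, "## Evidence", "",
            "| gene | evidence | feature | trait | distance | unit |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %s | %.3g | %s |",
                    screen$report$gene_id, screen$report$evidence,
                    screen$report$feature_id, screen$report$trait_code,
                    screen$report$distance, screen$report$unit), "")
  }
  if (!is.null(traits) && nrow(traits)) {
    md <- c(md, "## Trait comparisons", "",
            "| trait | diff | SED | t | p | tier |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %.3f | %.3f | %.3f | %.3f | %s |",
                    traits$trait, traits$mean_diff, traits$sed,
                    traits$t_stat, traits$pvalue, traits$tier), "")
  }
  if (!is.null(fold_changes) && nrow(fold_changes)) {
    md <- c(md, "## qPCR fold changes", "",
            "| gene | fold change | log2 |", "|---|---|---|",
            sprintf("| %s | %.3f | %.3f |", fold_changes$gene,
                    fold_changes$fold_change,
                    fold_changes$log2_fold_change), "")
  }
  if (!is.null(path)) {
    writeLines(md, path)
    return(invisible(md))
  }
  md
}

#' Volcano-plot data for a DE table
#'
#' Returns the (log2FC, -log10 p) coordinates with DEG status, ready for
#' plotting; when ggplot2 is available a plot object is attached.
#'
#' @param de DE table with `log2fc` and `padj` (or `pvalue`).
#' @param alpha DEG threshold on `padj`.
#' @return tibble with `log2fc`, `neg_log10_p`, `status`; attribute `plot`
#'   holds a ggplot when ggplot2 is installed.
#' @export
volcano_data <- function(de, alpha = 0.05) {
  p <- de[["padj"]] %||% bh_adjust(de$pvalue)
  d <- tibble::tibble(
    log2fc = de$log2fc, neg_log10_p = -log10(de$pvalue),
    status = ifelse(p >= alpha, "ns", ifelse(de$log2fc > 0, "up", "down")))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    attr(d, "plot") <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                      colour = .data$status)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(up = "red", down = "green4", ns = "blue")) +
      ggplot2::labs(x = "log2 fold change", y = "-log10 p")
  }
  d
}
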