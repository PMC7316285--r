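#' Mean Ct over technical replicates
#'
#' @param plate Ct plate tibble (`gene`, `sample`, `group`, `replicate`,
#'   `ct`).
#' @param gene,sample the well to average.
#' @return mean Ct (cycles).
#' @export
mean_ct <- function(plate, gene, sample) {
  ct <- plate$ct[plate$gene == gene & plate$sample == sample]
  if (length(ct) == 0)
    stop("no Ct values for gene ", gene, " in sample ", sample)
  mean(ct)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - mean(Ct over reference genes)` (arithmetic
#' mean of reference Cts, i.e. geometric mean of their linear quantities);
#' `ddCt = mean dCt(case) - mean dCt(calibrator)`; the fold change is
#' `2^-ddCt`. Adding a constant to every Ct on the plate leaves the result
#' unchanged.
#'
#' @param plate Ct plate tibble.
#' @param target_gene gene to quantify.
#' @param reference_genes reference gene names; every one must be measured
#'   in every sample where the target is measured.
#' @param case,calibrator group labels; the fold change is case relative to
#'   calibrator.
#' @return list with `fold_change`, `log2_fold_change`, `ddct`, and the
#'   per-sample `dct` table.
#' @export
delta_delta_ct <- function(plate, target_gene,
                           reference_genes = c("ACTB", "GAPDH"),
                           case = "steer", calibrator = "bull") {
  if (!target_gene %in% plate$gene)
    stop("target gene ", target_gene, " not on the plate")
  samp <- unique(plate[plate$gene == target_gene, c("sample", "group")])
  dct <- vapply(seq_len(nrow(samp)), function(i) {
    s <- samp$sample[i]
    ref_ct <- vapply(reference_genes, function(rg) {
      sub <- plate[plate$gene == rg & plate$sample == s, ]
      if (nrow(sub) == 0)
        stop("reference gene ", rg, " missing in sample ", s)
      mean(sub$ct)
    }, 1.0)
    mean_ct(plate, target_gene, s) - mean(ref_ct)
  }, 1.0)
  for (g in c(case, calibrator))
    if (!any(samp$group == g)) stop("group '", g, "' not on the plate")
  ddct <- mean(dct[samp$group == case]) - mean(dct[samp$group == calibrator])
  list(fold_change = 2^(-ddct), log2_fold_change = -ddct, ddct = ddct,
       dct = tibble::tibble(sample = samp$sample, group = samp$group,
                            dct = dct))
}

#' qPCR fold changes for a set of target genes
#'
#' @inheritParams delta_delta_ct
#' @param target_genes genes to quantify (default: every non-reference gene
#'   on the plate).
#' @return tibble with `gene`, `fold_change`, `log2_fold_change`.
#' @export
qpcr_fold_changes <- function(plate, reference_genes = c("ACTB", "GAPDH"),
                              target_genes = NULL, case = "steer",
                              calibrator = "bull") {
  targets <- target_genes %||% setdiff(unique(plate$gene), reference_genes)
  rows <- lapply(targets, function(g) {
    r <- delta_delta_ct(plate, g, reference_genes, case, calibrator)
    tibble::tibble(gene = g, fold_change = r$fold_change,
                   log2_fold_change = r$log2_fold_change)
  })
  dplyr::bind_rows(rows)
}

#' Correlate qPCR and RNA-seq log2 fold changes
#'
#' Pearson correlation over the genes shared between a qPCR fold-change
#' table and an RNA-seq log2FC table, with the fitted least-squares line for
#' plotting.
#'
#' @param qpcr_fc tibble from [qpcr_fold_changes()].
#' @param rnaseq tibble with `gene_id` (or `gene`) and `log2fc`.
#' @return list with `r`, `n_genes`, `intercept`, `slope`, and the paired
#'   `data` tibble.
#' @export
correlate_with_rnaseq <- function(qpcr_fc, rnaseq) {
  key <- if (!is.null(rnaseq[["gene_id"]])) rnaseq$gene_id else rnaseq$gene
  idx <- match(qpcr_fc$gene, key)
  ok <- !is.na(idx)
  if (sum(ok) < 3) stop("need at least 3 shared genes to correlate")
  d <- tibble::tibble(gene = qpcr_fc$gene[ok],
                      log2_qpcr = qpcr_fc$log2_fold_change[ok],
                      log2_rnaseq = rnaseq$log2fc[idx[ok]])
  fit <- lm(log2_qpcr ~ log2_rnaseq, data = d)
  list(r = cor(d$log2_qpcr, d$log2_rnaseq), n_genes = nrow(d),
       intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       data = d)
}

#' Read a Ct plate TSV
#' @param path TSV with columns gene, sample, group, replicate, ct.
#' @return plate tibble.
#' @export
read_ct_plate <- function(path) {
  x <- read_tsv_plain(path)
  req <- c("gene", "sample", "group", "replicate", "ct")
  if (!all(req %in% names(x)))
    stop("Ct plate must have columns: ", paste(req, collapse = ", "))
  if (any(x$ct <= 0)) stop("Ct values must be > 0")
  x
}
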