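#' Plumbing differential-expression test on log2 FPKM
#'
#' A deliberately simple two-group test used to exercise the downstream
#' screening machinery: per-gene log2 fold change is
#' `log2((mean FPKM case + c) / (mean FPKM calibrator + c))` with
#' pseudo-count `c`, and the p-value comes from a two-sided Welch
#' (unequal-variance) t-test on `log2(FPKM + c)`. It is not a replacement
#' for a count-model DE package; an externally produced DE table can be fed
#' straight into [call_degs()] and the screening stage instead.
#'
#' Like any per-sample-total normalization, FPKM is only calibrated when
#' differentially expressed genes carry a small share of the total
#' expression mass. A strong, directionally imbalanced global signal shifts
#' every null gene's FPKM in the opposite direction (compositional bias),
#' inflating the false discovery rate — the situation dedicated count-model
#' normalizations (median-of-ratios, TMM) exist to repair.
#'
#' @param counts integer matrix genes x samples.
#' @param samples tibble with columns `sample`, `group` (two groups).
#' @param gene_lengths per-gene lengths (bp) aligned with rows.
#' @param case,calibrator group labels; log2FC is case over calibrator.
#' @param pseudo_count FPKM pseudo-count `c` for the log transform.
#' @param total_fragments optional per-sample totals for FPKM.
#' @return tibble with `gene_id`, `log2fc`, `pvalue`, plus the group mean
#'   FPKMs `mean_fpkm_case` / `mean_fpkm_calibrator`.
#' @export
de_test <- function(counts, samples, gene_lengths, case = "steer",
                    calibrator = "bull", pseudo_count = 0.25,
                    total_fragments = NULL) {
  for (g in c(case, calibrator)) {
    if (sum(samples$group == g) < 2)
      stop("group '", g, "' needs at least 2 samples")
  }
  fp <- fpkm_matrix(counts, gene_lengths, total_fragments)
  lf <- log2(fp + pseudo_count)
  a <- lf[, samples$sample[samples$group == case], drop = FALSE]
  b <- lf[, samples$sample[samples$group == calibrator], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate: both groups constant and equal -> no evidence
  p[se2 == 0 & ma == mb] <- 1
  mfa <- rowMeans(fp[, samples$sample[samples$group == case], drop = FALSE])
  mfb <- rowMeans(fp[, samples$sample[samples$group == calibrator],
                     drop = FALSE])
  tibble::tibble(gene_id = rownames(counts),
                 log2fc = unname(log2((mfa + pseudo_count) /
                                        (mfb + pseudo_count))),
                 pvalue = as.numeric(p),
                 mean_fpkm_case = unname(mfa),
                 mean_fpkm_calibrator = unname(mfb))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone in rank, capped at 1), with
#' input validation: p-values must lie in (0, 1].
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes at an adjusted-p threshold
#'
#' A gene is a DEG iff its BH-adjusted p-value is strictly below `alpha`.
#' Direction is the sign of the log2 fold change; a called DEG with log2FC
#' exactly 0 is flagged as a tie (`direction = "tie"`). When the DE table
#' carries gene annotation status the up/down and annotation partitions are
#' tallied.
#'
#' @param de_table tibble with `gene_id`, `log2fc` and either `padj` or
#'   `pvalue` (in which case BH adjustment is applied here).
#' @param alpha adjusted-p threshold (strict), default 0.05.
#' @return list with `degs` (DEG rows with `padj` and `direction`),
#'   `n_up`, `n_down`, and `by_status` (named counts, when annotation
#'   status is available).
#' @export
call_degs <- function(de_table, alpha = 0.05) {
  if (nrow(de_table) == 0)
    return(list(degs = de_table, n_up = 0L, n_down = 0L, by_status = NULL))
  if (is.null(de_table[["padj"]])) de_table$padj <- bh_adjust(de_table$pvalue)
  deg <- de_table[de_table$padj < alpha, , drop = FALSE]
  deg$direction <- ifelse(deg$log2fc > 0, "up",
                          ifelse(deg$log2fc < 0, "down", "tie"))
  by_status <- if (!is.null(deg[["annotation_status"]]) && nrow(deg) > 0)
    table(deg$annotation_status) else NULL
  list(degs = deg, n_up = sum(deg$direction == "up"),
       n_down = sum(deg$direction == "down"), by_status = by_status)
}

#' Read an externally produced DE table
#'
#' Accepts the minimal contract `gene_id`, `log2fc`, `pvalue` with optional
#' `padj` and gene columns (`chromosome`, `start`, `end`,
#' `annotation_status`), so a published DEG list can enter the screening
#' stage directly.
#'
#' @param path TSV file.
#' @return tibble.
#' @export
read_de_table <- function(path) {
  x <- read_tsv_plain(path)
  req <- c("gene_id", "log2fc", "pvalue")
  if (!all(req %in% names(x)))
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  if (!is.null(x[["chromosome"]]))
    x$chromosome <- normalize_chrom(x$chromosome)
  x
}
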