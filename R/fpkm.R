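#' FPKM from a fragment count
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `count * 1e9 / (gene_length * total_fragments)`. All three arguments
#' recycle, so the function serves both scalars and whole columns.
#'
#' @param count non-negative fragment count(s).
#' @param gene_length gene length(s) in bp, > 0.
#' @param total_fragments per-sample total mapped fragments, > 0.
#' @return FPKM value(s).
#' @export
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
fpkm <- function(count, gene_length, total_fragments) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(total_fragments <= 0)) stop("total_fragments must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e9 / (gene_length * total_fragments)
}

#' FPKM matrix from a counts matrix
#'
#' By default the per-sample denominator is the column sum of the counts
#' matrix (fragments assigned to genes); a vector of externally counted
#' totals may be supplied instead.
#'
#' @param counts integer matrix genes x samples.
#' @param gene_lengths lengths (bp) aligned with the rows of `counts`.
#' @param total_fragments optional per-sample totals (defaults to column
#'   sums).
#' @return numeric matrix of FPKM values with the same dimnames.
#' @export
fpkm_matrix <- function(counts, gene_lengths, total_fragments = NULL) {
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must align with the rows of counts")
  totals <- total_fragments %||% colSums(counts)
  if (length(totals) != ncol(counts))
    stop("total_fragments must align with the columns of counts")
  sweep(counts / gene_lengths, 2, totals, "/") * 1e9
}

#' Assign FPKM values to five ordered expression levels
#'
#' Splits expressed genes into five levels from lowest to highest using four
#' strictly increasing FPKM cut points. The default cut points
#' (0.1, 1, 10, 100) are configuration stand-ins, not published values.
#' Values at a boundary fall in the lower level.
#'
#' @param fpkm_values numeric vector of FPKM values.
#' @param boundaries four strictly increasing cut points.
#' @return list with `levels` (integer 1-5 per gene) and `counts`
#'   (named count per level).
#' @export
bin_expression_levels <- function(fpkm_values, boundaries = c(0.1, 1, 10, 100)) {
  if (length(boundaries) != 4 || any(diff(boundaries) <= 0))
    stop("boundaries must be 4 strictly increasing cut points")
  lev <- findInterval(fpkm_values, boundaries, left.open = TRUE) + 1L
  counts <- setNames(tabulate(lev, nbins = 5L), paste0("level", 1:5))
  list(levels = lev, counts = counts)
}

#' Per-group expressed-gene sets and their intersection
#'
#' A gene counts as expressed in a group when its mean FPKM over that
#' group's samples is strictly greater than `threshold`.
#'
#' @param fpkm_mat FPKM matrix genes x samples (rownames = gene ids).
#' @param group_map named character vector mapping sample -> group, or a
#'   tibble with columns `sample` and `group`.
#' @param threshold expression threshold (FPKM), >= 0.
#' @return list with `sets` (named list of gene-id vectors per group),
#'   `sizes`, and `n_common` (size of the intersection across all groups).
#' @export
expressed_sets <- function(fpkm_mat, group_map, threshold = 0.1) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (is.data.frame(group_map))
    group_map <- setNames(group_map$group, group_map$sample)
  if (!all(colnames(fpkm_mat) %in% names(group_map)))
    stop("unknown group label: samples ",
         paste(setdiff(colnames(fpkm_mat), names(group_map)), collapse = ", "),
         " missing from group_map")
  groups <- unique(group_map[colnames(fpkm_mat)])
  sets <- lapply(groups, function(g) {
    cols <- colnames(fpkm_mat)[group_map[colnames(fpkm_mat)] == g]
    rownames(fpkm_mat)[rowMeans(fpkm_mat[, cols, drop = FALSE]) > threshold]
  })
  names(sets) <- groups
  list(sets = sets,
       sizes = vapply(sets, length, 1L),
       n_common = length(Reduce(intersect, sets)))
}
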