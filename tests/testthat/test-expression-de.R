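test_that("fpkm matches its closed form and validates input", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(c(5, 50), 2500, 2e7), c(5, 50) * 1e9 / (2500 * 2e7))
  expect_error(fpkm(1, 0, 1e6), "gene_length")
  expect_error(fpkm(1, 1000, 0), "total_fragments")
  expect_error(fpkm(-1, 1000, 1e6), "count")
})

test_that("fpkm_matrix agrees with the scalar formula element-wise", {
  withr::local_seed(101)
  counts <- matrix(rpois(30, 50), 6, 5,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  lens <- c(500, 1500, 3000, 800, 10000, 1200)
  fm <- fpkm_matrix(counts, lens)
  tot <- unname(colSums(counts))
  for (i in 1:6) for (j in 1:5)
    expect_equal(fm[i, j], fpkm(counts[i, j], lens[i], tot[j]))
  fixed <- fpkm_matrix(counts, lens, total_fragments = rep(1e6, 5))
  expect_equal(fixed[2, 3], fpkm(counts[2, 3], lens[2], 1e6))
  expect_error(fpkm_matrix(counts, lens[-1]), "align")
  expect_error(fpkm_matrix(counts, lens, total_fragments = 1e6), "align")
})

test_that("expression levels bin with boundary values in the lower level", {
  b <- c(0.1, 1, 10, 100)
  res <- bin_expression_levels(c(0.05, 0.1, 0.2, 1, 5, 10, 99, 100, 101), b)
  expect_equal(res$levels, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_equal(unname(res$counts), c(2L, 2L, 2L, 2L, 1L))
  expect_error(bin_expression_levels(1, c(1, 2, 2, 3)), "increasing")
})

test_that("expressed_sets applies a strict threshold per group mean", {
  fm <- matrix(c(0.1, 0.1, 0.3, 0.11,
                 5, 5, 0, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  gm <- c(s1 = "bull", s2 = "bull", s3 = "steer", s4 = "steer")
  es <- expressed_sets(fm, gm, threshold = 0.1)
  # gA bull mean exactly 0.1 -> not expressed (strict); steer mean 0.205 -> yes
  expect_setequal(es$sets$bull, "gB")
  expect_setequal(es$sets$steer, "gA")
  expect_equal(es$n_common, 0)
  expect_error(expressed_sets(fm, gm[1:3]), "missing from group_map")
  expect_error(expressed_sets(fm, gm, threshold = -1), ">= 0")
})

test_that("de_test equals per-gene Welch t.test on log2 FPKM", {
  withr::local_seed(202)
  n <- 60
  counts <- matrix(rnbinom(n * 8, mu = 200, size = 20), n, 8)
  rownames(counts) <- sprintf("g%03d", seq_len(n))
  colnames(counts) <- c(paste0("bull_", 1:4), paste0("steer_", 1:4))
  samples <- tibble::tibble(sample = colnames(counts),
                            group = rep(c("bull", "steer"), each = 4))
  lens <- runif(n, 500, 5000)
  de <- de_test(counts, samples, lens)

  fp <- fpkm_matrix(counts, lens)
  lf <- log2(fp + 0.25)
  for (i in c(1, 7, 23, 60)) {
    tt <- t.test(lf[i, 5:8], lf[i, 1:4])
    expect_equal(de$pvalue[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i],
                 log2((mean(fp[i, 5:8]) + 0.25) / (mean(fp[i, 1:4]) + 0.25)),
                 tolerance = 1e-12)
  }
  expect_error(de_test(counts, samples[c(1, 5), ], lens), "at least 2")
})

test_that("bh_adjust matches the step-up oracle and validates input", {
  withr::local_seed(303)
  for (n in c(1, 2, 10, 500)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  p_ties <- c(0.01, 0.01, 0.5, 1, 1)
  expect_equal(bh_adjust(p_ties), oracle_bh(p_ties), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1]")
  expect_error(bh_adjust(c(0.5, NA)), "\\(0, 1]")
})

test_that("call_degs applies a strict threshold and tallies direction", {
  de <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    log2fc = c(2, -1, 0, 3, -2),
    padj = c(0.049999, 0.05, 0.01, 0.2, 0.002),
    annotation_status = c("annotated", "annotated", "novel", "annotated",
                          "pseudogene"))
  res <- call_degs(de, alpha = 0.05)
  expect_setequal(res$degs$gene_id, c("g1", "g3", "g5"))  # g2 at 0.05 excluded
  expect_equal(res$n_up, 1)
  expect_equal(res$n_down, 1)
  expect_equal(res$degs$direction[res$degs$gene_id == "g3"], "tie")
  expect_equal(as.vector(res$by_status[c("annotated", "novel",
                                          "pseudogene")]),
               c(1L, 1L, 1L))
  empty <- call_degs(de[0, ])
  expect_equal(nrow(empty$degs), 0)
})

test_that("read_de_table enforces the minimal contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_plain(tibble::tibble(gene_id = "g1", log2fc = 1.5,
                                 pvalue = 0.01, chromosome = "chr4",
                                 start = 10, end = 20), path)
  x <- read_de_table(path)
  expect_equal(x$chromosome, "4")
  write_tsv_plain(tibble::tibble(gene_id = "g1", log2fc = 1.5), path)
  expect_error(read_de_table(path), "must have columns")
})
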