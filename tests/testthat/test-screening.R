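test_that("gene_qtl_overlap covers all modes and chromosome handling", {
  gene <- list(chromosome = "4", start = 100, end = 200)
  expect_true(gene_qtl_overlap(gene, list(chromosome = "chr4",
                                          span_start = 200, span_end = 300)))
  expect_true(gene_qtl_overlap(gene, list(chromosome = "4",
                                          span_start = 1, span_end = 100)))
  expect_false(gene_qtl_overlap(gene, list(chromosome = "4",
                                           span_start = 201, span_end = 300)))
  expect_false(gene_qtl_overlap(gene, list(chromosome = "5",
                                           span_start = 100, span_end = 200)))
  qtl <- list(chromosome = "4", span_start = 90, span_end = 160)
  expect_true(gene_qtl_overlap(gene, qtl, mode = "any"))
  expect_false(gene_qtl_overlap(gene, qtl, mode = "containment"))
  expect_true(gene_qtl_overlap(gene, list(chromosome = "4", span_start = 90,
                                          span_end = 210),
                               mode = "containment"))
  # midpoint 150
  expect_true(gene_qtl_overlap(gene, qtl, mode = "midpoint"))
  expect_false(gene_qtl_overlap(gene, list(chromosome = "4", span_start = 151,
                                           span_end = 300),
                                mode = "midpoint"))
})

test_that("gene_snp_distance_mb is nearest-edge, zero inside, Inf across", {
  gene <- list(chromosome = "19", start = 1e6, end = 2e6)
  expect_equal(gene_snp_distance_mb(gene, list(chromosome = "19",
                                               position = 1.5e6)), 0)
  expect_equal(gene_snp_distance_mb(gene, list(chromosome = "19",
                                               position = 2e6)), 0)
  expect_equal(gene_snp_distance_mb(gene, list(chromosome = "19",
                                               position = 2.4e6)), 0.4)
  expect_equal(gene_snp_distance_mb(gene, list(chromosome = "chr19",
                                               position = 0.75e6)), 0.25)
  expect_identical(gene_snp_distance_mb(gene, list(chromosome = "1",
                                                   position = 1.5e6)), Inf)
})

test_that("distance_to_peak_cm is signed and conversion-aware", {
  gene <- list(chromosome = "4", start = 2e6, end = 4e6)  # midpoint 3e6
  qtl <- list(peak = 1e6)
  expect_equal(distance_to_peak_cm(gene, qtl), 2)
  expect_equal(distance_to_peak_cm(gene, list(peak = 5e6)), -2)
  expect_equal(distance_to_peak_cm(gene, qtl, cm_per_mb = c("4" = 1.25)), 2.5)
  expect_error(distance_to_peak_cm(gene, qtl, cm_per_mb = c("5" = 1.25)),
               "no cM-per-Mb conversion")
})

test_that("trait-class filtering rejects unknown codes", {
  cat <- tibble::tibble(trait_code = c("CW", "SC"),
                        trait_class = c("meat_quality", "reproduction"))
  expect_equal(filter_by_trait_class(cat, "meat_quality")$trait_code, "CW")
  expect_equal(filter_by_trait_class(cat, "reproduction")$trait_code, "SC")
  expect_error(filter_by_trait_class(
    tibble::tibble(trait_code = "NOPE", trait_class = "meat_quality"),
    "meat_quality"), "unknown trait codes: NOPE")
  expect_error(filter_by_trait_class(cat, "fluffiness"),
               "unknown trait class")
})

test_that("qtl_screen and snp_screen match the brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    withr::local_seed(seed)
    degs <- random_genes(80)
    qtls <- random_qtls(300)
    snps <- random_snps(300)
    for (mode in c("any", "containment", "midpoint")) {
      got <- qtl_screen(degs, qtls, mode = mode)
      expect_setequal(got$pass, oracle_qtl_pass(degs, qtls, mode = mode))
    }
    for (max_mb in c(0.5, 5)) {
      got <- snp_screen(degs, snps, max_mb = max_mb)
      expect_setequal(got$pass, oracle_snp_pass(degs, snps, max_mb = max_mb))
      # every evidence row satisfies the strict threshold
      expect_true(all(got$evidence$distance_mb < max_mb))
    }
  }
})

test_that("qtl evidence lists every matched QTL with its signed distance", {
  degs <- tibble::tibble(gene_id = "g1", chromosome = "4",
                         start = 2e6, end = 4e6)
  qtls <- tibble::tibble(qtl_id = c("q1", "q2", "q3"), chromosome = "4",
                         span_start = c(1e6, 3.5e6, 6e6),
                         span_end = c(2.5e6, 5e6, 7e6),
                         peak = c(2e6, 4e6, 6.5e6),
                         trait_code = "CW", trait_class = "meat_quality")
  res <- qtl_screen(degs, qtls)
  expect_equal(res$pass, "g1")
  expect_equal(res$evidence$qtl_id, c("q1", "q2"))
  expect_equal(res$evidence$distance_cm, c(1, -1))
})

test_that("intersection yields candidates and a well-formed report", {
  withr::local_seed(7)
  degs <- random_genes(60)
  qtls <- random_qtls(150)
  snps <- random_snps(150)
  qr <- qtl_screen(degs, qtls)
  sr <- snp_screen(degs, snps)
  res <- intersect_candidates(qr, sr, degs = degs)
  expect_setequal(res$candidates, intersect(qr$pass, sr$pass))
  expect_setequal(unique(res$report$gene_id), res$candidates)
  expect_true(all(res$report$evidence %in% c("qtl", "snp")))
  expect_true(all(res$report$unit[res$report$evidence == "qtl"] == "cM"))
  expect_true(all(res$report$unit[res$report$evidence == "snp"] == "Mb"))

  # empty screens give a structurally valid zero-row report
  none <- intersect_candidates(
    qtl_screen(degs[0, ], qtls), snp_screen(degs[0, ], snps))
  expect_length(none$candidates, 0)
  expect_equal(nrow(none$report), 0)
  expect_true(all(c("gene_id", "evidence", "feature_id", "trait_code",
                    "distance", "unit") %in% names(none$report)))
})

test_that("screening across naming schemes works or fails loudly", {
  degs <- tibble::tibble(gene_id = "g1", chromosome = "chr4",
                         start = 1e6, end = 2e6)
  qtls <- tibble::tibble(qtl_id = "q1", chromosome = "4", span_start = 1.5e6,
                         span_end = 3e6, peak = 2e6, trait_code = "CW",
                         trait_class = "meat_quality")
  expect_equal(qtl_screen(degs, qtls)$pass, "g1")  # chr4 vs 4 normalized
  qtls$chromosome <- "12"
  expect_error(qtl_screen(degs, qtls), "no shared chromosome names")
})

test_that("catalog readers validate columns; write_bed converts coordinates", {
  qp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_plain(tibble::tibble(qtl_id = "q1", chr = "chr7",
                                 span_start = 10, span_end = 5,
                                 peak = 7, trait_code = "CW",
                                 trait_class = "meat_quality",
                                 source_ref = "x"), qp)
  expect_error(read_qtl_catalog(qp), "span_start > span_end")
  write_tsv_plain(tibble::tibble(qtl_id = "q1", chr = "chr7",
                                 span_start = 5, span_end = 10,
                                 peak = 7, trait_code = "CW",
                                 trait_class = "meat_quality",
                                 source_ref = "x"), qp)
  expect_equal(read_qtl_catalog(qp)$chromosome, "7")
  write_tsv_plain(tibble::tibble(foo = 1), qp)
  expect_error(read_qtl_catalog(qp), "must have columns")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(tibble::tibble(gene_id = "g1", chromosome = "4",
                           start = 100, end = 200), bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.numeric(f[2]), 99)   # 0-based start
  expect_equal(as.numeric(f[3]), 200)  # half-open end
})

test_that("screen_candidates equals its manual composition", {
  cfg <- small_config(seed = 61)
  genes <- gen_annotation(cfg)
  tr <- gen_counts(genes, cfg)$truth
  qtl <- gen_qtl_catalog(genes, tr, cfg)
  snp <- gen_snp_catalog(genes, tr, cfg)
  degs <- genes[genes$gene_id %in% tr$deg$gene_id &
                  genes$annotation_status == "annotated", ]
  res <- screen_candidates(degs, qtl, snp)
  qc <- filter_by_trait_class(qtl, "meat_quality")
  sc <- filter_by_trait_class(snp, "meat_quality")
  manual <- intersect_candidates(qtl_screen(degs, qc),
                                 snp_screen(degs, sc), degs = degs)
  expect_equal(res$candidates, manual$candidates)
  expect_equal(res$report, manual$report)
  # screening the true DEG table recovers the planted pass sets exactly
  expect_setequal(res$qtl_pass, tr$qtl_pass_ids)
  expect_setequal(res$snp_pass, tr$snp_pass_ids)
  expect_setequal(res$candidates, tr$candidate_gene_ids)
})
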