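test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(planted_candidate_fraction = 1.5), "fraction")
  expect_error(sim_config(log2fc_range = c(4, 1.2)), "log2fc_range")
  expect_error(sim_config(n_samples_per_group = 1), "n_samples_per_group")
  expect_error(sim_config(n_planted_degs = 10, n_genes = 5), "exceed")
  expect_error(sim_config(n_qtl_pass = 10, n_snp_pass = 2,
                          planted_candidate_fraction = 1), "n_snp_pass")
  expect_error(sim_config(chrom_lengths = c(1e6, 2e6)), "named")
})

test_that("derived sub-seeds separate stages but stay reproducible", {
  expect_identical(derive_seed(1L, "counts"), derive_seed(1L, "counts"))
  expect_false(derive_seed(1L, "counts") == derive_seed(1L, "annotation"))
  expect_false(derive_seed(1L, "counts") == derive_seed(2L, "counts"))
  expect_true(derive_seed(.Machine$integer.max, "counts") >= 0)
})

test_that("gen_annotation respects chromosome bounds and is reproducible", {
  cfg <- small_config(seed = 11)
  g1 <- gen_annotation(cfg)
  g2 <- gen_annotation(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), cfg$n_genes)
  lens <- cfg$chrom_lengths
  names(lens) <- normalize_chrom(names(lens))
  expect_true(all(g1$start >= 1))
  expect_true(all(g1$end <= lens[g1$chromosome]))
  expect_true(all(g1$start <= g1$end))
  expect_true(all(g1$annotation_status %in%
                    c("annotated", "pseudogene", "novel")))
  expect_false(is.unsorted(match(g1$chromosome,
                                 normalize_chrom(names(cfg$chrom_lengths)))))
})

test_that("gen_counts plants a consistent truth with detectable signal", {
  cfg <- small_config(seed = 21)
  genes <- gen_annotation(cfg)
  cc <- gen_counts(genes, cfg)
  expect_identical(dim(cc$counts), c(cfg$n_genes, 12L))
  expect_identical(cc$counts, gen_counts(genes, cfg)$counts)

  tr <- cc$truth
  expect_s3_class(tr, "planted_truth")
  expect_equal(nrow(tr$deg), cfg$n_planted_degs)
  expect_length(tr$qtl_pass_ids, cfg$n_qtl_pass)
  expect_length(tr$snp_pass_ids, cfg$n_snp_pass)
  expect_length(tr$candidate_gene_ids, n_planted_candidates(cfg))
  expect_true(all(tr$candidate_gene_ids %in% tr$qtl_pass_ids))
  expect_true(all(tr$candidate_gene_ids %in% tr$snp_pass_ids))
  expect_setequal(intersect(tr$qtl_pass_ids, tr$snp_pass_ids),
                  tr$candidate_gene_ids)
  st <- genes$annotation_status[match(
    unique(c(tr$qtl_pass_ids, tr$snp_pass_ids)), genes$gene_id)]
  expect_true(all(st == "annotated"))

  # planted effect direction shows up in the raw group means
  idx <- match(tr$deg$gene_id, genes$gene_id)
  bull <- rowMeans(cc$counts[idx, cc$samples$sample[cc$samples$group == "bull"]])
  steer <- rowMeans(cc$counts[idx, cc$samples$sample[cc$samples$group == "steer"]])
  expect_true(all(sign(log(pmax(steer, 0.5) / pmax(bull, 0.5))) ==
                    sign(tr$deg$true_log2fc)))
})

test_that("planted QTLs overlap only their target gene; decoys overlap none", {
  cfg <- small_config(seed = 31)
  genes <- gen_annotation(cfg)
  tr <- gen_counts(genes, cfg)$truth
  qtl <- gen_qtl_catalog(genes, tr, cfg)
  expect_equal(nrow(qtl), cfg$n_qtls)

  overlapping_genes <- function(q) {
    hit <- genes$chromosome == q$chromosome &
      genes$start <= q$span_end & genes$end >= q$span_start
    genes$gene_id[hit]
  }
  planted <- qtl[seq_along(tr$qtl_pass_ids), ]
  for (i in seq_len(nrow(planted)))
    expect_identical(overlapping_genes(planted[i, ]), tr$qtl_pass_ids[i])
  decoys <- qtl[-seq_along(tr$qtl_pass_ids), ]
  for (i in seq_len(nrow(decoys)))
    expect_length(overlapping_genes(decoys[i, ]), 0)
})

test_that("SNP catalog respects the placement margins", {
  cfg <- small_config(seed = 41)
  genes <- gen_annotation(cfg)
  tr <- gen_counts(genes, cfg)$truth
  snp <- gen_snp_catalog(genes, tr, cfg)
  expect_equal(nrow(snp), cfg$n_snps)

  near <- cfg$snp_max_mb - cfg$placement_margin_mb
  far <- cfg$snp_max_mb + cfg$placement_margin_mb
  pass_genes <- genes[match(tr$snp_pass_ids, genes$gene_id), ]
  planted <- snp[seq_along(tr$snp_pass_ids), ]
  d_pass <- vapply(seq_len(nrow(planted)), function(i)
    gene_snp_distance_mb(pass_genes[i, ], planted[i, ]), 1.0)
  expect_true(all(d_pass > 0 & d_pass <= near))

  annotated <- tr$deg$gene_id[tr$deg$annotation_status == "annotated"]
  non_pass <- genes[match(setdiff(annotated, tr$snp_pass_ids),
                          genes$gene_id), ]
  for (i in seq_len(nrow(non_pass))) {
    d <- vapply(seq_len(nrow(snp)), function(j)
      gene_snp_distance_mb(non_pass[i, ], snp[j, ]), 1.0)
    expect_gt(min(d), far)
  }
})

test_that("gen_fastq plants exactly the requested read classes", {
  path <- withr::local_tempfile(fileext = ".fastq")
  fq <- gen_fastq(200, read_length = 60, frac_adapter = 0.1,
                  frac_lowq = 0.15, frac_highN = 0.05, seed = 5, path = path)
  expect_equal(as.vector(table(fq$truth$class)[c("adapter", "clean",
                                                 "highN", "lowq")]),
               c(20L, 140L, 10L, 30L))
  reads <- read_fastq(path)
  expect_equal(reads$id, fq$truth$id)
  flag <- ifelse(vapply(reads$sequence, has_adapter, TRUE), "adapter",
          ifelse(vapply(reads$sequence, has_excess_n, TRUE), "highN",
          ifelse(vapply(reads$quality, is_low_quality, TRUE), "lowq",
                 "clean")))
  expect_equal(unname(flag), fq$truth$class)
  expect_error(gen_fastq(10, frac_adapter = 0.7, frac_lowq = 0.5), "sum")
  expect_error(gen_fastq(10, read_length = 10), "adapter length")
})

test_that("gen_phenotypes honours the specs, exactly at sd = 0", {
  specs <- tibble::tibble(trait = rep("t1", 2), group = c("bull", "steer"),
                          mean = c(10, 12), sd = c(0, 0))
  ph <- gen_phenotypes(specs, n_per_group = 4, seed = 3)
  expect_equal(nrow(ph), 8)
  expect_true(all(ph$value[ph$group == "bull"] == 10))
  expect_true(all(ph$value[ph$group == "steer"] == 12))
  expect_error(gen_phenotypes(tibble::tibble(trait = "a", group = "b",
                                             mean = 1, sd = -1)), "sd")
  expect_identical(gen_phenotypes(specs, seed = 9),
                   gen_phenotypes(specs, seed = 9))
})

test_that("file round trips preserve the generated tables", {
  cfg <- small_config(seed = 51)
  genes <- gen_annotation(cfg)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, gff)
  back <- read_gene_table(gff)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$annotation_status, genes$annotation_status)

  cc <- gen_counts(genes, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cc$counts, tsv)
  expect_identical(read_counts(tsv), cc$counts)

  tr <- cc$truth
  qtl <- gen_qtl_catalog(genes, tr, cfg)
  snp <- gen_snp_catalog(genes, tr, cfg)
  qp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_plain(qtl, qp)
  write_tsv_plain(snp, sp)
  expect_equal(read_qtl_catalog(qp)$span_start, qtl$span_start)
  expect_equal(read_snp_catalog(sp)$position, snp$position)
})
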