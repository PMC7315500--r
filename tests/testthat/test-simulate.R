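test_that("generation is byte-identical for the same config and seed", {
  cfg <- sim_config(seed = 42, n_genes = 15, n_mirnas = 6)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  c2 <- generate_dataset(sim_config(seed = 43, n_genes = 15, n_mirnas = 6))
  expect_false(identical(a$isoforms$sequence, c2$isoforms$sequence))
})

test_that("truth-table bookkeeping matches the configuration", {
  cfg <- sim_config(seed = 2, n_genes = 50, n_mirnas = 20,
                    isoform_count_probs = c(0, 0, 1)) # 3 isoforms per gene
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$isoforms), 150)
  expect_equal(dplyr::n_distinct(ds$isoforms$gene_id), 50)
  expect_equal(nrow(ds$mirnas), 20)
  expect_equal(nrow(ds$truth$modules), nrow(ds$isoforms))
  expect_equal(sum(ds$mirnas$is_te_related),
               round(cfg$frac_te_mirna * cfg$n_mirnas))
  # every isoform maps to exactly one gene
  expect_equal(anyDuplicated(ds$isoforms$isoform_id), 0)
  # planted targets reference real isoforms
  expect_true(all(ds$truth$targets$isoform_id %in% ds$isoforms$isoform_id))
  # design: 6 tissues, 15 samples (5 + 2x5)
  expect_equal(nrow(ds$design), 15)
  expect_equal(dplyr::n_distinct(ds$design$tissue), 6)
})

test_that("plant_site scores follow the penalty arithmetic", {
  mir <- "UGAGGUAGUAGGUUGUAUAGU" # G at 4, U at 16 etc.
  host <- strrep("C", 80)
  expect_identical(plant_site(host, mir, 10)$expected_score, 0)
  gu16 <- plant_site(host, mir, 10, list(list(type = "gu", mirna_pos = 16)))
  expect_identical(gu16$expected_score, 0.5)
  mm5 <- plant_site(host, mir, 10, list(list(type = "mismatch", mirna_pos = 5)))
  expect_identical(mm5$expected_score, 2)
  bulge <- plant_site(host, mir, 10, list(list(type = "bulge", mirna_pos = 15)))
  expect_identical(bulge$expected_score, 1)
  expect_equal(bulge$length, 22L)
  gap <- plant_site(host, mir, 10, list(list(type = "gap", mirna_pos = 3)))
  expect_identical(gap$expected_score, 2)
  expect_equal(gap$length, 20L)

  expect_error(plant_site(host, mir, 70), "does not fit")
  expect_error(plant_site(host, mir, 10, list(list(type = "gap", mirna_pos = 1))),
               "gap position")
  expect_error(plant_site(host, mir, 10, list(list(type = "gu", mirna_pos = 3))),
               "G:U not possible") # miRNA base at position 3 is A
})

test_that("planted sites score exactly as the scanner computes", {
  demo <- get_demo()
  tr <- demo$ds$truth$targets
  iso <- demo$ds$isoforms
  for (i in seq_len(nrow(tr))) {
    seq_i <- iso$sequence[iso$isoform_id == tr$isoform_id[i]]
    mir_i <- demo$ds$mirnas$sequence[demo$ds$mirnas$mirna_id == tr$mirna_id[i]]
    hits <- find_candidate_sites(mir_i, seq_i)
    match_row <- hits[hits$start == tr$start[i], ]
    expect_equal(nrow(match_row), 1, info = paste("site", i))
    expect_equal(match_row$score, tr$expected_score[i], info = paste("site", i))
    expect_equal(match_row$end, tr$end[i], info = paste("site", i))
  }
})

test_that("planted repression yields negative miRNA-target correlations", {
  cfg <- sim_config(seed = 6, repression_strength = 1, nb_dispersion = 0.01)
  ds <- generate_dataset(cfg)
  mirna_tm <- mirisonet:::tissue_means(expr_to_matrix(ds$mirna_counts),
                                       ds$design)
  iso_tm <- mirisonet:::tissue_means(expr_to_matrix(ds$isoform_counts),
                                     ds$design)
  pairs <- unique(ds$truth$targets[, c("mirna_id", "isoform_id")])
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(mirna_tm[pairs$mirna_id[i], ], iso_tm[pairs$isoform_id[i], ])
  }, numeric(1))
  expect_gte(mean(r < 0), 0.9)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(n_genes = 10), "mandatory")
  expect_error(sim_config(seed = 1, cds_segment_len = 20), "site longer")
  expect_error(sim_config(seed = 1, isoform_count_probs = c(0.5, 0.2)))
})

test_that("written datasets round-trip through the standard readers", {
  ds <- generate_dataset(sim_config(seed = 4, n_genes = 8, n_mirnas = 4))
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  expect_equal(read_fasta(file.path(dir, "mirnas.fa"))$sequence,
               ds$mirnas$sequence)
  iso <- read_fasta(file.path(dir, "isoforms.fa"))
  expect_equal(iso$sequence, ds$isoforms$sequence)
  counts <- read_expression_tsv(file.path(dir, "isoform_counts.tsv"))
  expect_equal(expr_to_matrix(counts), expr_to_matrix(ds$isoform_counts))
  bed <- read_bed_intervals(file.path(dir, "premirna.bed"))
  expect_equal(bed$start, ds$premirna_intervals$start)
})
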