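test_that("a planted perfect complement is found with score 0 at its window", {
  set.seed(11)
  mir <- random_rna_str(21)
  site <- rna_reverse_complement(mir)
  tx <- paste0(random_rna_str(30), site, random_rna_str(25))
  got <- find_candidate_sites(mir, tx)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 30L)
  expect_equal(got$end, 51L)
  expect_identical(got$score, 0)
  expect_equal(got$variant, "gapless")
})

test_that("transcripts with no window at or below the cutoff yield no sites", {
  # poly-A target vs poly-A miRNA: every column is an A:A mismatch
  expect_equal(nrow(find_candidate_sites(strrep("A", 20), strrep("A", 60))), 0)
  # miRNA longer than the transcript
  expect_equal(nrow(find_candidate_sites(strrep("A", 30), strrep("U", 20))), 0)
})

test_that("scanner agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:150) {
    m <- sample(16:21, 1)
    L <- sample((m + 2):60, 1)
    mir <- random_rna_str(m)
    tx <- random_rna_str(L)
    # plant a weak site in half the instances so retained sites are common
    if (i %% 2 == 0) {
      pos <- sample(0:(L - m - 1), 1)
      tx <- plant_site(tx, mir, pos,
                       list(list(type = "mismatch",
                                 mirna_pos = sample(m, 1))))$sequence
    }
    got <- find_candidate_sites(mir, tx)
    exp <- oracle_scan(mir, tx)
    expect_equal(nrow(got), nrow(exp), info = paste("instance", i))
    if (nrow(got)) {
      expect_equal(got$start, exp$start, info = paste("instance", i))
      expect_equal(got$end, exp$end, info = paste("instance", i))
      expect_equal(got$score, exp$score, info = paste("instance", i))
    }
  }
})

test_that("adding a distortion never decreases the planted-site score", {
  set.seed(5)
  mir <- random_rna_str(21)
  host <- random_rna_str(70)
  base <- plant_site(host, mir, 20)
  expect_identical(base$expected_score, 0)
  singles <- list(
    list(type = "mismatch", mirna_pos = 17),
    list(type = "gu", mirna_pos = NA), # filled below
    list(type = "bulge", mirna_pos = 15),
    list(type = "gap", mirna_pos = 16)
  )
  qb <- strsplit(mir, "")[[1]]
  gu_ok <- which(qb %in% c("G", "U"))
  gu_ok <- gu_ok[gu_ok > 2]
  singles[[2]]$mirna_pos <- gu_ok[length(gu_ok)]
  for (d in singles) {
    one <- plant_site(host, mir, 20, list(d))
    expect_gt(one$expected_score, base$expected_score)
    two <- plant_site(host, mir, 20,
                      list(d, list(type = "mismatch", mirna_pos = 1)))
    expect_gt(two$expected_score, one$expected_score)
  }
})

test_that("predict_targets classifies genes and counts regulators", {
  mir1 <- "UGAGGUAGUAGGUUGUAUAGU"
  mir2 <- "ACCCGUAGAUCCGAACUUGUG"
  iso_a1 <- paste0(strrep("A", 10), rna_reverse_complement(mir1),
                   strrep("C", 10), rna_reverse_complement(mir2),
                   strrep("A", 10))
  iso_a2 <- strrep("CA", 40) # no sites
  isoforms <- tibble::tibble(
    isoform_id = c("gA.1", "gA.2", "gB.1"),
    gene_id = c("gA", "gA", "gB"),
    sequence = c(iso_a1, iso_a2, paste0(strrep("G", 12),
                                        rna_reverse_complement(mir1),
                                        strrep("G", 12)))
  )
  mirnas <- tibble::tibble(mirna_id = c("m1", "m2"),
                           sequence = c(mir1, mir2))
  got <- predict_targets(mirnas, isoforms)
  a1 <- got$isoform_summary[got$isoform_summary$isoform_id == "gA.1", ]
  expect_equal(a1$n_sites, 2L)
  expect_equal(a1$n_mirnas, 2L)
  expect_equal(
    got$gene_summary$class[got$gene_summary$gene_id == "gA"],
    "partially_targeted")
  expect_equal(
    got$gene_summary$class[got$gene_summary$gene_id == "gB"],
    "fully_targeted")

  dup <- isoforms; dup$isoform_id[2] <- "gA.1"
  expect_error(predict_targets(mirnas, dup), "duplicate isoform ids")
})

test_that("site regions follow the majority rule with CDS winning ties", {
  iso <- tibble::tibble(
    isoform_id = "t1", gene_id = "g1",
    utr5_start = 0L, utr5_end = 30L, cds_start = 30L, cds_end = 90L,
    utr3_start = 90L, utr3_end = 120L
  )
  sites <- tibble::tibble(
    isoform_id = "t1",
    start = c(35L, 95L, 25L, 5L),
    end = c(56L, 116L, 46L, 26L)
  )
  got <- annotate_site_region(sites, iso)
  # fully inside CDS; fully inside 3'UTR; 5 nt in 5'UTR + 16 in CDS -> CDS;
  # fully inside 5'UTR
  expect_equal(got$region, c("CDS", "3UTR", "CDS", "5UTR"))

  out_of_bounds <- tibble::tibble(isoform_id = "t1", start = 110L, end = 131L)
  expect_error(annotate_site_region(out_of_bounds, iso), "outside transcript")

  props <- site_region_proportions(got)
  expect_equal(sum(props$pct), 100)
  expect_equal(props$n[props$region == "CDS"], 2L)
})
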