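test_that("small-RNA reads are length-filtered and collapsed", {
  r18 <- strrep("AC", 9)   # 18 nt
  r17 <- strrep("A", 17)
  r30 <- strrep("G", 30)
  r21 <- paste0(strrep("U", 20), "A")
  got <- filter_and_collapse(c(r17, r18, r30, r21, r21, r21,
                               paste0(strrep("A", 20), "N")))
  expect_equal(nrow(got), 2)
  expect_equal(got$sequence[1], r21)  # count 3 sorts first
  expect_equal(got$count, c(3L, 1L))
  expect_false(r17 %in% got$sequence)
  expect_false(r30 %in% got$sequence)
  expect_equal(nrow(filter_and_collapse(character(0))), 0)
})

test_that("TE overlap needs >= 1 shared bp on the same chromosome", {
  pre <- tibble::tibble(chrom = c("chr1", "chr1", "chr9"),
                        start = c(100L, 100L, 100L), end = c(180L, 180L, 180L),
                        name = c("p1", "p2", "p3"))
  te <- tibble::tibble(chrom = c("chr1", "chr1"), start = c(150L, 180L),
                       end = c(300L, 300L))
  got <- suppressMessages(annotate_te_overlap(pre[1, ], te[1, ]))
  expect_true(got$te_related)
  # half-open abutment is not an overlap
  got2 <- suppressMessages(annotate_te_overlap(pre[2, ], te[2, ]))
  expect_false(got2$te_related)
  # chromosome absent from the TE set
  got3 <- suppressMessages(annotate_te_overlap(pre[3, ], te))
  expect_false(got3$te_related)
})

test_that("mature miRNAs inherit TE flags from any flagged precursor", {
  map <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
                        premirna_id = c("p1", "p2", "p3"))
  flags <- tibble::tibble(name = c("p1", "p2", "p3"),
                          te_related = c(FALSE, TRUE, FALSE))
  got <- mature_te_flags(map, flags)
  expect_true(got$is_te_related[got$mirna_id == "m1"])
  expect_false(got$is_te_related[got$mirna_id == "m2"])
})

test_that("TPM columns sum to one million", {
  counts <- tiny_expr(c(5, 40, 15, 60), c("a", "b"), c("s1", "s2"))
  tpm <- tpm_quantify(counts)
  expect_equal(tpm$s1, c(250000, 750000))
  expect_equal(unname(colSums(expr_to_matrix(tpm))), c(1e6, 1e6))

  single <- tiny_expr(7, "a", "s1")
  expect_equal(tpm_quantify(single)$s1, 1e6)

  zero <- tiny_expr(c(1, 0, 1, 0), c("a", "b"), c("s1", "s2"))
  expect_error(tpm_quantify(zero), "s2")

  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(50, 30) + 1, 10, 5,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
    got <- expr_to_matrix(tpm_quantify(matrix_to_expr(m)))
    expect_equal(unname(colSums(got)), rep(1e6, 5), tolerance = 1e-6)
  }
})

test_that("tissue presence counts per-tissue, common and unique miRNAs", {
  design <- tiny_design()
  m <- matrix(0, 3, 6, dimnames = list(c("all", "anther_only", "absent"),
                                       design$sample_id))
  m["all", ] <- 5
  m["anther_only", "anther_1"] <- 2
  pres <- tissue_presence(matrix_to_expr(m), design)
  expect_equal(pres$n_all_tissues, 1)
  pt <- pres$per_tissue
  expect_equal(pt$n_unique[pt$tissue == "anther"], 1)
  expect_equal(pt$n_present[pt$tissue == "leaf"], 1)
  # the all-zero miRNA appears in no intersection
  expect_equal(sum(pt$n_present), 6 + 1)

  bad_design <- rbind(design, tibble::tibble(sample_id = "ghost",
                                             tissue = "root"))
  expect_error(tissue_presence(matrix_to_expr(m), bad_design),
               "tissue without samples")
})

test_that("first-base composition fractions sum to one per length class", {
  got <- base_composition(c("AGG", "CGG", "GGG", "UGG"))
  expect_equal(got$fraction, rep(0.25, 4))

  u_only <- base_composition(c("UAAA", "UCCC"))
  expect_equal(u_only$fraction, 1)

  set.seed(9)
  seqs <- vapply(1:50, function(i) random_rna_str(sample(18:24, 1)),
                 character(1))
  got2 <- base_composition(seqs)
  sums <- tapply(got2$fraction, got2$length, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(base_composition(character(0)), "empty")
})
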