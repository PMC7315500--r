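test_that("GIDDM counts ignore grey and require two assigned isoforms", {
  assignment <- tibble::tibble(
    feature_id = c("a.1", "a.2", "b.1", "b.2", "b.3", "c.1", "c.2", "d.1"),
    module = c("blue", "brown", "blue", "blue", "grey", "blue", "grey", "blue")
  )
  gene_map <- tibble::tibble(
    isoform_id = assignment$feature_id,
    gene_id = sub("\\..*", "", assignment$feature_id)
  )
  sites <- tibble::tibble(isoform_id = "a.2")
  got <- find_giddm(assignment, gene_map, sites)
  pg <- got$per_gene
  expect_true(pg$giddm[pg$gene_id == "a"])
  expect_false(pg$giddm[pg$gene_id == "b"]) # {blue, blue, grey}
  expect_false("c" %in% pg$gene_id)          # only one assigned isoform
  expect_false("d" %in% pg$gene_id)
  expect_equal(got$counts$n_giddm, 1L)
  expect_equal(got$counts$n_giddm_targeted, 1L)

  expect_error(
    find_giddm(assignment, gene_map[-1, ], sites), "without gene mapping")
})

test_that("hub-targeting contingency reproduces proportions and extremes", {
  even <- targeting_contingency(n_module = 1000, n_module_targeted = 200,
                                n_hub = 100, n_hub_targeted = 20)
  expect_equal(even$pct_module, 20)
  expect_equal(even$pct_hub, 20)
  expect_gt(even$p_value, 0.5)

  deg <- targeting_contingency(100, 30, 100, 30)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))

  expect_error(targeting_contingency(100, 10, 200, 10), "exceed")
})

test_that("chi-squared on targeting tables tracks Fisher enumeration", {
  # (hub targeted, hub total, module targeted, module total); all cells >= 20
  cases <- list(c(45, 100, 75, 200), c(40, 100, 120, 400),
                c(30, 100, 85, 300), c(25, 80, 80, 280))
  for (cs in cases) {
    got <- targeting_contingency(n_module = cs[4], n_module_targeted = cs[3],
                                 n_hub = cs[2], n_hub_targeted = cs[1])
    tab <- matrix(c(cs[1], cs[2] - cs[1],
                    cs[3] - cs[1], (cs[4] - cs[2]) - (cs[3] - cs[1])),
                  2, byrow = TRUE)
    fis <- fisher.test(tab)$p.value
    expect_lt(abs(log10(got$p_value) - log10(fis)), 0.3)
    expect_equal(got$p_value < 0.01, fis < 0.01)
  }
})

test_that("targeted isoforms compare against untargeted siblings only", {
  design <- tiny_design()
  gene_map <- tibble::tibble(
    isoform_id = c("a.1", "a.2", "b.1", "b.2", "c.1"),
    gene_id = c("a", "a", "b", "b", "c")
  )
  m <- matrix(5, 5, 6, dimnames = list(gene_map$isoform_id, design$sample_id))
  sites <- tibble::tibble(isoform_id = c("a.1", "b.1", "c.1"))
  same <- targeted_vs_untargeted(matrix_to_expr(m), design, gene_map, sites,
                                 "leaf")
  expect_equal(same$median_diff, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$n_genes, 2L) # gene c has no untargeted sibling

  m2 <- m
  m2[c("a.1", "b.1"), ] <- 20
  up <- targeted_vs_untargeted(matrix_to_expr(m2), design, gene_map, sites,
                               "leaf")
  expect_gt(up$median_diff, 0)
  expect_true(up$low_power) # only two qualifying genes
})

test_that("planted expression boost is detected on synthetic data", {
  demo <- get_demo()
  gene_map <- dplyr::select(demo$ds$isoforms, "isoform_id", "gene_id")
  fpkm_tbl <- demo$res$expression$fpkm
  got <- targeted_vs_untargeted(fpkm_tbl, demo$ds$design, gene_map,
                                demo$res$targets$sites, "leaf")
  expect_gt(got$median_diff, 0)
  expect_lt(got$p_value, 0.05)
})

test_that("homolog categories follow their definitions with I > III > II", {
  gene_map <- tibble::tibble(
    isoform_id = c("a.1", "a.2", "b.1", "b.2", "c.1", "c.2", "d.1", "d.2",
                   "d.3", "e.1"),
    gene_id = c("a", "a", "b", "b", "c", "c", "d", "d", "d", "e")
  )
  hits <- tibble::tibble(
    isoform_id = c("a.1", "a.2", "b.1", "b.2", "c.1", "c.2",
                   "d.1", "d.2", "d.3", "e.1"),
    hit_gene = c("X", "X", "Y", "Y", "P", "Q",
                 "G", "G", "H", "Z"),
    hit_isoform = c("X.1", "X.1", "Y.1", "Y.2", "P.1", "Q.1",
                    "G.1", "G.2", "H.1", "Z.1")
  )
  got <- homolog_category(gene_map, hits)
  cat_of <- function(g) as.character(got$category[got$gene_id == g])
  expect_equal(cat_of("a"), "II")
  expect_equal(cat_of("b"), "III")
  expect_equal(cat_of("c"), "I")
  expect_equal(cat_of("d"), "I") # mixed evidence: any cross-gene pair wins
  expect_false("e" %in% got$gene_id) # single hit-bearing isoform excluded

  dup <- rbind(hits, hits[1, ])
  expect_error(homolog_category(gene_map, dup), "multiple best hits")

  shift <- homolog_category_shift(got, c("c", "d"))
  expect_equal(shift$frac_subset[shift$category == "I"], 1)
  expect_equal(sum(shift$frac_subset), 1)
})

test_that("planted homolog categories are recovered exactly", {
  demo <- get_demo()
  ds <- demo$ds
  gene_map <- dplyr::select(ds$isoforms, "isoform_id", "gene_id")
  for (sp in unique(ds$best_hits$species)) {
    hits <- dplyr::filter(ds$best_hits, .data$species == sp)
    got <- homolog_category(gene_map, dplyr::select(hits, -"species"))
    truth <- dplyr::filter(ds$truth$homologs, .data$species == sp)
    merged <- merge(got, truth, by = "gene_id")
    expect_equal(nrow(merged), nrow(truth))
    expect_equal(as.character(merged$category.x), merged$category.y)
  }
})
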