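block_expr <- function(sizes, profiles, design, noise = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  ids <- character(0)
  for (b in seq_along(sizes)) {
    for (i in seq_len(sizes[b])) {
      ids <- c(ids, sprintf("b%d_f%03d", b, i))
      rows[[length(rows) + 1]] <-
        profiles[[b]][match(design$tissue, unique(design$tissue))] *
        exp(rnorm(nrow(design), 0, noise))
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, design$sample_id)
  matrix_to_expr(m)
}

test_that("adjacency matches closed forms and stays in [0, 1]", {
  # cor(x, y) = -0.5 for these two indicator-like profiles
  expr <- tiny_expr(c(1, 0, 0, 0, 1, 0), c("x", "y"), c("s1", "s2", "s3"))
  a <- adjacency(expr, beta = 6)
  expect_equal(a["x", "y"], 0.5^6)
  expect_equal(diag(a), c(x = 1, y = 1))

  same <- tiny_expr(c(1, 2, 3, 2, 4, 6), c("x", "y"), c("s1", "s2", "s3"))
  expect_equal(adjacency(same, beta = 9)["x", "y"], 1)

  set.seed(2)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  a2 <- adjacency(matrix_to_expr(r), beta = 6)
  expect_true(isSymmetric(unname(a2)))
  expect_true(all(a2 >= 0 & a2 <= 1))

  zv <- tiny_expr(c(1, 1, 1, 0, 1, 2), c("flat", "ok"), c("s1", "s2", "s3"))
  expect_error(adjacency(zv), "zero-variance")
})

tom_by_hand <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

test_that("TOM equals the hand formula on all 3-node configurations", {
  grid <- seq(0, 1, by = 0.25)
  for (a12 in grid) for (a13 in grid) for (a23 in grid) {
    a <- diag(3)
    a[1, 2] <- a[2, 1] <- a12
    a[1, 3] <- a[3, 1] <- a13
    a[2, 3] <- a[3, 2] <- a23
    dimnames(a) <- list(paste0("f", 1:3), paste0("f", 1:3))
    expect_equal(unname(tom_similarity(a)), tom_by_hand(a), tolerance = 1e-12)
  }
  # spot values: complete graph, isolated pair, chain
  ones <- matrix(1, 3, 3, dimnames = list(paste0("f", 1:3), paste0("f", 1:3)))
  expect_true(all(tom_similarity(ones) == 1))
  chain <- diag(3)
  chain[1, 2] <- chain[2, 1] <- 0.5
  chain[2, 3] <- chain[3, 2] <- 0.5
  dimnames(chain) <- list(paste0("f", 1:3), paste0("f", 1:3))
  expect_equal(tom_similarity(chain)[1, 2], 0.5)
  expect_equal(tom_similarity(chain)[1, 3], (0.25 + 0) / (0.5 + 1 - 0))
  asym <- ones; asym[1, 2] <- 0.2
  expect_error(tom_similarity(asym), "symmetric")
})

test_that("eigengenes track shared profiles with positive orientation", {
  design <- tiny_design(reps = 2)
  prof <- c(10, 1, 1, 1, 1, 1)
  expr <- block_expr(8, list(prof), design, noise = 0.01, seed = 3)
  me <- module_eigengene(expr, expr_to_matrix(expr) |> rownames())
  cors <- cor(t(expr_to_matrix(expr)), me)
  expect_true(all(cors > 0.99))

  # negating every member flips nothing: orientation is re-established
  neg <- matrix_to_expr(-expr_to_matrix(expr))
  me_neg <- module_eigengene(neg, rownames(expr_to_matrix(neg)))
  cors_neg <- cor(t(expr_to_matrix(neg)), me_neg)
  expect_true(all(cors_neg > 0.99))

  # PC1 explains at least as much standardized variance as any member share
  pr <- prcomp(t(scale(t(expr_to_matrix(expr)))) |> t(), center = FALSE)
  expect_gte(pr$sdev[1]^2 / sum(pr$sdev^2), 1 / nrow(expr))
})

test_that("planted blocks are detected and tiny clusters stay grey", {
  design <- tiny_design(reps = 2)
  profiles <- list(c(30, 1, 1, 1, 1, 1), c(1, 30, 1, 1, 1, 1),
                   c(1, 1, 1, 30, 1, 1))
  expr <- block_expr(c(25, 25, 4), profiles, design, noise = 0.05, seed = 4)
  adj <- adjacency(expr, beta = 6)
  tom <- tom_similarity(adj)
  got <- detect_modules(tom, expr, min_module_size = 10)
  truth <- sub("_f.*", "", got$feature_id)
  expect_equal(adjusted_rand(got$module[truth != "b3"],
                             truth[truth != "b3"]), 1)
  expect_true(all(got$module[truth == "b3"] == "grey"))
  # colour naming: equal-size blocks named from the fixed palette
  expect_setequal(unique(got$module[truth != "b3"]), c("turquoise", "blue"))
})

test_that("modules with identical tissue profiles merge", {
  design <- tiny_design(reps = 2)
  same_prof <- c(20, 1, 1, 1, 1, 1)
  expr <- block_expr(c(15, 15), list(same_prof, same_prof), design,
                     noise = 0.05, seed = 5)
  adj <- adjacency(expr, beta = 6)
  got <- detect_modules(tom_similarity(adj), expr, min_module_size = 10)
  expect_equal(dplyr::n_distinct(got$module), 1)
})

test_that("module labels do not depend on feature order", {
  design <- tiny_design(reps = 2)
  profiles <- list(c(30, 1, 1, 1, 1, 1), c(1, 1, 30, 1, 1, 1))
  expr <- block_expr(c(20, 14), profiles, design, noise = 0.05, seed = 6)
  adj <- adjacency(expr, beta = 6)
  got1 <- detect_modules(tom_similarity(adj), expr, min_module_size = 5)
  set.seed(7)
  perm <- sample(nrow(expr))
  expr_p <- expr[perm, ]
  adj_p <- adjacency(expr_p, beta = 6)
  got2 <- detect_modules(tom_similarity(adj_p), expr_p, min_module_size = 5)
  merged <- merge(got1, got2, by = "feature_id")
  expect_equal(merged$module.x, merged$module.y)
})

test_that("hub quota is min(150, module size) and module-trait r is exact", {
  design <- tiny_design(reps = 3) # 18 samples
  profiles <- list(c(25, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 25, 1))
  expr <- block_expr(c(200, 120), profiles, design, noise = 0.05, seed = 8)
  assignment <- tibble::tibble(
    feature_id = expr$feature_id,
    module = rep(c("mA", "mB"), c(200, 120))
  )
  got <- module_trait_and_kme(assignment, expr, design, hub_n = 150)
  hubs_a <- got$hubs[got$hubs$module == "mA", ]
  hubs_b <- got$hubs[got$hubs$module == "mB", ]
  expect_equal(nrow(hubs_a), 150)
  expect_equal(nrow(hubs_b), 120)
  expect_true(all(hubs_a$feature_id %in%
                    assignment$feature_id[assignment$module == "mA"]))
  mt <- got$module_trait
  expect_gt(mt$r[mt$module == "mA" & mt$tissue == "leaf"], 0.99)
  expect_lt(mt$p[mt$module == "mA" & mt$tissue == "leaf"], 1e-6)
})

test_that("t-based module-trait p agrees with a permutation oracle", {
  set.seed(9)
  n <- 15
  design <- tibble::tibble(sample_id = paste0("s", 1:n),
                           tissue = rep(c("t1", "t2", "t3"), each = 5))
  me <- as.numeric(design$tissue == "t1") + rnorm(n, 0, 0.6)
  ind <- as.numeric(design$tissue == "t1")
  r_obs <- cor(me, ind)
  p_t <- mirisonet:::cor_pvalue(r_obs, n)
  perm_r <- replicate(4000, abs(cor(me, sample(ind))))
  p_perm <- mean(perm_r >= abs(r_obs))
  expect_lt(abs(p_t - p_perm), 0.02 + 3 * sqrt(p_t * (1 - p_t) / 4000))
})

test_that("fit_coexpression tidies, summarises and plots", {
  design <- tiny_design(reps = 2)
  profiles <- list(c(30, 1, 1, 1, 1, 1), c(1, 1, 30, 1, 1, 1))
  expr <- block_expr(c(20, 16), profiles, design, noise = 0.05, seed = 10)
  fit <- fit_coexpression(expr, design, min_module_size = 10)
  td <- tidy(fit)
  expect_true(all(c("feature_id", "module", "kme", "is_hub") %in% names(td)))
  expect_true(all(td$is_hub[td$module != "grey"])) # modules under the quota
  gl <- glance(fit)
  expect_equal(gl$n_modules, 2L)
  expect_equal(gl$n_features, 36L)
  expect_s3_class(autoplot(fit), "ggplot")
})
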