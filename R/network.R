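# Weighted co-expression network built from scratch: soft-thresholded
# correlation adjacency, topological overlap, average-linkage module
# detection with eigengene merging, module eigengenes, module-trait
# correlation, kME and hub selection.

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned: `|cor|^beta`; signed: `((1 + cor)/2)^beta`. The diagonal is 1.
#'
#' @param expr Wide expression tibble (features x samples).
#' @param beta Soft-thresholding power (>= 1).
#' @param signed Use the signed transform?
#' @return A symmetric adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(expr, beta = 6, signed = FALSE) {
  m <- expr_to_matrix(expr)
  if (nrow(m) < 2 || ncol(m) < 3) {
    abort("need at least 2 features and 3 samples.")
  }
  if (beta < 1) abort("`beta` must be >= 1.")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance feature(s), filter first: ",
                 paste(head(rownames(m)[sds == 0], 5), collapse = ", ")))
  }
  r <- cor(t(m))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, where
#' `L_ij` is the shared-neighbour sum and `k_i` the connectivity; the
#' diagonal is 1.
#'
#' @param adj Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) abort("adjacency must be symmetric.")
  a0 <- adj
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom
}

#' Module eigengene
#'
#' First principal component across samples of the per-feature standardised
#' member expression, sign-oriented so the mean member correlation is
#' positive.
#'
#' @param expr Wide expression tibble.
#' @param members Character vector of member feature ids.
#' @return A named numeric vector over samples (unit norm).
#' @export
module_eigengene <- function(expr, members) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) abort("need more than one sample for an eigengene.")
  missing <- setdiff(members, rownames(m))
  if (length(missing)) {
    abort(paste0("members absent from expression table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- m[members, , drop = FALSE]
  x <- t(scale(t(x)))
  sv <- svd(x, nu = 0, nv = 1)
  me <- sv$v[, 1]
  cors <- suppressWarnings(cor(t(x), me))
  if (mean(cors, na.rm = TRUE) < 0) me <- -me
  setNames(me, colnames(m))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a static
#' height into candidate clusters; clusters below `min_module_size` are
#' assigned to "grey"; module pairs whose eigengene dissimilarity
#' (`1 - cor`) falls below `merge_threshold` are merged iteratively
#' (recomputing eigengenes after each merge); surviving modules are named by
#' a fixed colour palette in decreasing size order.
#'
#' @param tom TOM similarity matrix (features in rows/cols, named).
#' @param expr Wide expression tibble (needed for eigengene merging).
#' @param min_module_size Minimum module size (default 600; scale down for
#'   small data sets).
#' @param merge_threshold Eigengene dissimilarity below which modules merge
#'   (default 0.5).
#' @param cut_height Static tree-cut height on 1 - TOM (default 0.99).
#' @return A tibble with `feature_id` and `module` ("grey" = unassigned).
#' @export
detect_modules <- function(tom, expr, min_module_size = 600,
                           merge_threshold = 0.5, cut_height = 0.99) {
  ids <- rownames(tom)
  if (is.null(ids)) abort("`tom` must carry feature ids as dimnames.")
  if (min_module_size > nrow(tom)) {
    warn("min_module_size exceeds the feature count; all features grey")
    return(tibble(feature_id = ids, module = "grey"))
  }
  d <- as.dist(1 - tom)
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
  names(labels) <- ids

  # iterative eigengene merging
  n_samples <- ncol(expr_to_matrix(expr))
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    mes <- vapply(mods, function(mm) {
      module_eigengene(expr, ids[labels == mm])
    }, numeric(n_samples))
    cm <- cor(mes)
    diss <- 1 - cm
    diag(diss) <- Inf
    mi <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[mi[1], mi[2]] >= merge_threshold) break
    labels[labels == mods[mi[2]]] <- mods[mi[1]]
  }

  mods <- setdiff(unique(labels), "grey")
  ord <- mods[order(-vapply(mods, function(mm) sum(labels == mm), numeric(1)),
                    mods)]
  palette <- c(MODULE_COLORS, paste0("module", seq_along(ord)))
  renamed <- setNames(palette[seq_along(ord)], ord)
  labels[labels != "grey"] <- renamed[labels[labels != "grey"]]
  tibble(feature_id = ids, module = unname(labels))
}

cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Module-trait correlation, kME and hub selection
#'
#' Traits are one-hot tissue indicators over samples; module-trait r is the
#' Pearson correlation of each module eigengene with each indicator, with a
#' t-distribution p-value (n - 2 df). kME is the correlation of each
#' feature's expression with each eigengene; hubs are the top `hub_n` members
#' of each module by own-module kME (all members when the module is smaller),
#' ties broken by feature id.
#'
#' @param assignment Tibble (`feature_id`, `module`) from [detect_modules()].
#' @param expr Wide expression tibble.
#' @param design Design tibble (`sample_id`, `tissue`).
#' @param hub_n Hub quota per module (default 150).
#' @return A list with `eigengenes` (tibble sample_id x module), a
#'   `module_trait` tibble (`module`, `tissue`, `r`, `p`), a long `kme`
#'   tibble (`feature_id`, `module`, `kme`) and a `hubs` tibble
#'   (`module`, `feature_id`, `kme`, `rank`).
#' @export
module_trait_and_kme <- function(assignment, expr, design, hub_n = 150) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 samples.")
  design <- check_design(m, design)
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0) abort("no non-grey modules.")
  mes <- vapply(mods, function(mm) {
    module_eigengene(expr, assignment$feature_id[assignment$module == mm])
  }, numeric(ncol(m)))
  n <- ncol(m)

  tissues <- unique(design$tissue)
  mt <- list_rbind(map(mods, function(mm) {
    list_rbind(map(tissues, function(tt) {
      ind <- as.numeric(design$tissue == tt)
      r <- suppressWarnings(cor(mes[, mm], ind))
      tibble(module = mm, tissue = tt, r = r, p = cor_pvalue(r, n))
    }))
  }))

  kme_mat <- suppressWarnings(cor(t(m[assignment$feature_id, , drop = FALSE]), mes))
  kme <- as_tibble(kme_mat, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "module", values_to = "kme")

  own <- assignment |>
    filter(.data$module != "grey") |>
    inner_join(kme, by = c("feature_id", "module")) |>
    group_by(.data$module) |>
    arrange(desc(.data$kme), .data$feature_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  hubs <- filter(own, .data$rank <= hub_n)

  list(
    eigengenes = as_tibble(mes) |>
      mutate(sample_id = colnames(m), .before = 1),
    module_trait = mt,
    kme = kme,
    hubs = hubs
  )
}

#' Fit a weighted isoform co-expression network
#'
#' End-to-end wrapper: adjacency, TOM, module detection with eigengene
#' merging, eigengenes, module-trait correlation, kME and hubs.
#'
#' @inheritParams adjacency
#' @inheritParams detect_modules
#' @inheritParams module_trait_and_kme
#' @param design Design tibble (`sample_id`, `tissue`).
#' @return An object of class `coexpression_fit`.
#' @export
fit_coexpression <- function(expr, design, beta = 6, signed = FALSE,
                             min_module_size = 600, merge_threshold = 0.5,
                             cut_height = 0.99, hub_n = 150) {
  adj <- adjacency(expr, beta = beta, signed = signed)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, expr, min_module_size = min_module_size,
                               merge_threshold = merge_threshold,
                               cut_height = cut_height)
  extras <- if (any(assignment$module != "grey")) {
    module_trait_and_kme(assignment, expr, design, hub_n = hub_n)
  } else {
    NULL
  }
  structure(
    list(
      assignment = assignment,
      eigengenes = extras$eigengenes,
      module_trait = extras$module_trait,
      kme = extras$kme,
      hubs = extras$hubs,
      params = list(beta = beta, signed = signed,
                    min_module_size = min_module_size,
                    merge_threshold = merge_threshold,
                    cut_height = cut_height, hub_n = hub_n)
    ),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat("Weighted co-expression network fit\n")
  cat("  features:", nrow(x$assignment), "\n")
  cat("  modules :", sum(names(sizes) != "grey"), "(grey:",
      if ("grey" %in% names(sizes)) sizes[["grey"]] else 0, ")\n")
  invisible(x)
}

#' Tidy a co-expression fit into a per-feature tibble
#'
#' @param x A `coexpression_fit`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `module`, own-module `kme` and
#'   `is_hub`.
#' @method tidy coexpression_fit
#' @export
tidy.coexpression_fit <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$kme)) {
    own <- dplyr::semi_join(x$kme, filter(out, .data$module != "grey"),
                            by = c("feature_id", "module"))
    out <- left_join(out, own, by = c("feature_id", "module"))
    hubkey <- select(x$hubs, "feature_id", "module") |> mutate(is_hub = TRUE)
    out <- left_join(out, hubkey, by = c("feature_id", "module")) |>
      mutate(is_hub = dplyr::coalesce(.data$is_hub, FALSE))
  }
  out
}

#' One-row summary of a co-expression fit
#'
#' @param x A `coexpression_fit`.
#' @param ... Unused.
#' @return A one-row tibble with feature, module and hub counts.
#' @method glance coexpression_fit
#' @export
glance.coexpression_fit <- function(x, ...) {
  a <- x$assignment
  tibble(
    n_features = nrow(a),
    n_modules = n_distinct(a$module[a$module != "grey"]),
    n_grey = sum(a$module == "grey"),
    n_hubs = if (is.null(x$hubs)) 0L else nrow(x$hubs),
    beta = x$params$beta,
    min_module_size = x$params$min_module_size
  )
}

#' Module-trait correlation heatmap
#'
#' @param object A `coexpression_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coexpression_fit
#' @export
autoplot.coexpression_fit <- function(object, ...) {
  if (is.null(object$module_trait)) abort("fit has no module-trait table.")
  ggplot2::ggplot(object$module_trait,
                  ggplot2::aes(x = .data$tissue, y = .data$module,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1e)", .data$r, .data$p)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
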