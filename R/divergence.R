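# Isoform-level divergence statistics: genes whose isoforms land in
# different co-expression modules (GIDDM), hub-targeting enrichment within a
# module, targeted-vs-untargeted isoform expression, and cross-species
# homolog categories.

#' Find genes with isoforms distributed across different modules (GIDDM)
#'
#' Grey (unassigned) isoforms are ignored; a gene is counted when at least
#' two of its isoforms are assigned to non-grey modules, and is a GIDDM when
#' those isoforms occupy at least two distinct modules. A GIDDM is "targeted"
#' when any isoform of the gene carries a retained target site.
#'
#' @param assignment Tibble (`feature_id`, `module`); feature ids are isoform
#'   ids.
#' @param gene_map Tibble with `isoform_id` and `gene_id`.
#' @param target_table Site table with an `isoform_id` column (may be empty).
#' @return A list with `per_gene` (tibble: `gene_id`, `n_assigned`,
#'   `n_modules`, `giddm`, `targeted`) and `counts` (one-row tibble:
#'   `n_genes_multi_isoform_assigned`, `n_giddm`, `n_giddm_targeted`).
#' @export
find_giddm <- function(assignment, gene_map, target_table = NULL) {
  unmapped <- setdiff(assignment$feature_id, gene_map$isoform_id)
  if (length(unmapped)) {
    abort(paste0("isoforms without gene mapping: ",
                 paste(head(unmapped, 5), collapse = ", ")))
  }
  targeted_isoforms <- if (is.null(target_table) || nrow(target_table) == 0) {
    character(0)
  } else {
    unique(target_table$isoform_id)
  }
  targeted_genes <- unique(gene_map$gene_id[gene_map$isoform_id %in% targeted_isoforms])

  per_gene <- assignment |>
    filter(.data$module != "grey") |>
    left_join(gene_map, by = c(feature_id = "isoform_id")) |>
    group_by(.data$gene_id) |>
    summarise(n_assigned = n(), n_modules = n_distinct(.data$module),
              .groups = "drop") |>
    filter(.data$n_assigned >= 2) |>
    mutate(giddm = .data$n_modules >= 2,
           targeted = .data$gene_id %in% targeted_genes)

  counts <- tibble(
    n_genes_multi_isoform_assigned = nrow(per_gene),
    n_giddm = sum(per_gene$giddm),
    n_giddm_targeted = sum(per_gene$giddm & per_gene$targeted)
  )
  list(per_gene = per_gene, counts = counts)
}

#' Chi-squared test on a module-wide vs hub targeting contingency
#'
#' Builds the 2x2 table of targeted status against hub membership within one
#' module (the module-wide count includes the hubs; non-hub counts are
#' derived by subtraction) and applies a Yates-corrected chi-squared test.
#'
#' @param n_module,n_module_targeted Module size and its targeted count
#'   (hubs included).
#' @param n_hub,n_hub_targeted Hub-set size and its targeted count.
#' @param correct Yates continuity correction (default TRUE).
#' @return A one-row tibble with counts, the two proportions (as
#'   percentages), `statistic` and `p_value`, plus a `degenerate` flag.
#' @export
targeting_contingency <- function(n_module, n_module_targeted, n_hub,
                                  n_hub_targeted, correct = TRUE) {
  if (n_hub > n_module || n_hub_targeted > n_module_targeted) {
    abort("hub counts cannot exceed module counts.")
  }
  degenerate <- n_module <= n_hub
  tab <- matrix(c(
    n_hub_targeted, n_hub - n_hub_targeted,
    n_module_targeted - n_hub_targeted,
    (n_module - n_hub) - (n_module_targeted - n_hub_targeted)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("hub", "non_hub"), c("targeted", "untargeted")))
  ht <- if (!degenerate) {
    suppressWarnings(chisq.test(tab, correct = correct))
  } else {
    NULL
  }
  tibble(
    n_module = n_module, n_module_targeted = n_module_targeted,
    n_hub = n_hub, n_hub_targeted = n_hub_targeted,
    pct_module = round(100 * n_module_targeted / n_module, 2),
    pct_hub = round(100 * n_hub_targeted / n_hub, 2),
    statistic = if (is.null(ht)) NA_real_ else unname(ht$statistic),
    p_value = if (is.null(ht)) NA_real_ else ht$p.value,
    degenerate = degenerate
  )
}

#' Hub-targeting enrichment for one module of a network fit
#'
#' @param fit A `coexpression_fit`.
#' @param target_table Site table with an `isoform_id` column.
#' @param module Module name.
#' @inheritParams targeting_contingency
#' @return See [targeting_contingency()].
#' @export
hub_target_enrichment <- function(fit, target_table, module, correct = TRUE) {
  members <- fit$assignment$feature_id[fit$assignment$module == module]
  if (length(members) == 0) abort(paste0("no such module: ", module))
  hubs <- fit$hubs$feature_id[fit$hubs$module == module]
  targeted <- unique(target_table$isoform_id)
  targeting_contingency(
    n_module = length(members),
    n_module_targeted = sum(members %in% targeted),
    n_hub = length(hubs),
    n_hub_targeted = sum(hubs %in% targeted),
    correct = correct
  )
}

#' Compare expression of targeted vs untargeted isoforms of the same genes
#'
#' For each gene with at least one targeted and one untargeted isoform, the
#' mean abundance of targeted isoforms is paired against the mean of
#' untargeted isoforms in the samples of one tissue; a Wilcoxon signed-rank
#' test across genes summarises the shift.
#'
#' @param expr Wide expression tibble (FPKM).
#' @param design Design tibble.
#' @param gene_map Tibble with `isoform_id` and `gene_id`.
#' @param target_table Site table with an `isoform_id` column.
#' @param tissue Tissue whose samples are averaged.
#' @return A one-row tibble with `tissue`, `n_genes`, `median_diff`
#'   (targeted minus untargeted), `p_value` and `low_power` (TRUE when fewer
#'   than 5 qualifying genes).
#' @export
targeted_vs_untargeted <- function(expr, design, gene_map, target_table,
                                   tissue) {
  m <- expr_to_matrix(expr)
  design <- check_design(m, design)
  cols <- design$sample_id[design$tissue == tissue]
  if (length(cols) == 0) abort(paste0("no samples for tissue: ", tissue))
  level <- rowMeans(m[, cols, drop = FALSE])
  targeted <- unique(target_table$isoform_id)

  d <- gene_map |>
    filter(.data$isoform_id %in% names(level)) |>
    mutate(value = level[.data$isoform_id],
           is_targeted = .data$isoform_id %in% targeted) |>
    group_by(.data$gene_id) |>
    summarise(
      any_t = any(.data$is_targeted), any_u = any(!.data$is_targeted),
      mean_t = mean(.data$value[.data$is_targeted]),
      mean_u = mean(.data$value[!.data$is_targeted]),
      .groups = "drop"
    ) |>
    filter(.data$any_t, .data$any_u)

  n_genes <- nrow(d)
  if (n_genes == 0) {
    return(tibble(tissue = tissue, n_genes = 0L, median_diff = NA_real_,
                  p_value = NA_real_, low_power = TRUE))
  }
  diffs <- d$mean_t - d$mean_u
  p <- if (all(diffs == 0)) 1 else {
    suppressWarnings(wilcox.test(d$mean_t, d$mean_u, paired = TRUE))$p.value
  }
  tibble(tissue = tissue, n_genes = n_genes, median_diff = median(diffs),
         p_value = p, low_power = n_genes < 5)
}

#' Classify genes into cross-species homolog categories
#'
#' For genes with at least two isoforms carrying a best hit in another
#' species: category I when the isoforms hit at least two distinct genes;
#' category III when they hit the same gene through at least two distinct
#' isoforms; category II when they all hit one identical isoform. Precedence
#' I > III > II.
#'
#' @param gene_map Tibble with `isoform_id` and `gene_id`.
#' @param best_hits Tibble with `isoform_id`, `hit_gene`, `hit_isoform`; at
#'   most one row per isoform (resolve ties upstream).
#' @return A tibble with `gene_id`, `n_hit_isoforms` and `category`
#'   (factor I/II/III).
#' @export
homolog_category <- function(gene_map, best_hits) {
  best_hits <- as_tibble(best_hits)
  if (anyDuplicated(best_hits$isoform_id)) {
    abort(paste0("isoform(s) with multiple best hits: ",
                 paste(unique(best_hits$isoform_id[duplicated(best_hits$isoform_id)]),
                       collapse = ", ")))
  }
  d <- inner_join(gene_map, best_hits, by = "isoform_id") |>
    group_by(.data$gene_id) |>
    summarise(
      n_hit_isoforms = n(),
      n_genes = n_distinct(.data$hit_gene),
      n_isoforms = n_distinct(.data$hit_isoform),
      .groups = "drop"
    ) |>
    filter(.data$n_hit_isoforms >= 2) |>
    mutate(category = dplyr::case_when(
      .data$n_genes >= 2 ~ "I",
      .data$n_isoforms >= 2 ~ "III",
      TRUE ~ "II"
    )) |>
    mutate(category = factor(.data$category, levels = c("I", "II", "III")))
  select(d, "gene_id", "n_hit_isoforms", "category")
}

#' Compare homolog-category proportions between two gene subsets
#'
#' @param categories Output of [homolog_category()].
#' @param subset_genes Character vector of gene ids (e.g. GIDDMs).
#' @return A tibble with per-category fractions in the subset and the
#'   complement-inclusive whole set, and the difference in percentage points.
#' @export
homolog_category_shift <- function(categories, subset_genes) {
  frac <- function(d) {
    d |>
      count(.data$category, .drop = FALSE) |>
      mutate(fraction = .data$n / sum(.data$n))
  }
  all_f <- frac(categories) |> rename(n_all = "n", frac_all = "fraction")
  sub_f <- frac(filter(categories, .data$gene_id %in% subset_genes)) |>
    rename(n_subset = "n", frac_subset = "fraction")
  inner_join(all_f, sub_f, by = "category") |>
    mutate(shift_pct = 100 * (.data$frac_subset - .data$frac_all))
}
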