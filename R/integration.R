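# miRNA-target expression integration: per-pair Pearson correlation over
# tissue-mean profiles, the six-level correlation binning, and the DEMTG
# (differentially-expressed-miRNA target gene) proportion test.

CORRELATION_BINS <- data.frame(
  bin = c("strong_negative", "intermediate_negative", "weak_negative",
          "weak_positive", "intermediate_positive", "strong_positive"),
  lower = c(-1, -0.75, -0.25, 0, 0.25, 0.75),
  upper = c(-0.75, -0.25, 0, 0.25, 0.75, 1)
)

#' Correlate miRNA and target expression across tissues
#'
#' Both matrices are reduced to per-tissue mean profiles over the tissues
#' shared by the two designs; the Pearson correlation is computed per
#' miRNA-target pair. Pairs where either profile has zero variance are
#' excluded (reported via a message).
#'
#' @param pairs Tibble with `mirna_id` and `feature_id` (target isoform or
#'   gene).
#' @param mirna_expr Wide expression tibble for miRNAs (TPM).
#' @param target_expr Wide expression tibble for targets (FPKM).
#' @param mirna_design,target_design Design tibbles for the two matrices.
#' @return `pairs` with an `r` column; excluded pairs are dropped.
#' @export
target_correlations <- function(pairs, mirna_expr, target_expr,
                                mirna_design, target_design = mirna_design) {
  mm <- tissue_means(expr_to_matrix(mirna_expr), mirna_design)
  tm <- tissue_means(expr_to_matrix(target_expr), target_design)
  shared <- intersect(colnames(mm), colnames(tm))
  if (length(shared) < 3) abort("fewer than 3 shared tissues between designs.")
  mm <- mm[, shared, drop = FALSE]
  tm <- tm[, shared, drop = FALSE]
  pairs <- as_tibble(pairs)
  ok <- pairs$mirna_id %in% rownames(mm) & pairs$feature_id %in% rownames(tm)
  pairs <- pairs[ok, , drop = FALSE]
  r <- map_dbl(seq_len(nrow(pairs)), function(i) {
    a <- mm[pairs$mirna_id[i], ]
    b <- tm[pairs$feature_id[i], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  })
  n_excluded <- sum(is.na(r))
  if (n_excluded > 0) {
    inform(paste0(n_excluded, " pair(s) excluded for zero-variance profiles"))
  }
  pairs$r <- r
  filter(pairs, !is.na(.data$r))
}

#' Bin a correlation coefficient into six levels
#'
#' The partition of `[-1, 1]`: strong negative `[-1, -0.75]`, intermediate
#' negative `(-0.75, -0.25]`, weak negative `(-0.25, 0)`, weak positive
#' `[0, 0.25)`, intermediate positive `[0.25, 0.75)`, strong positive
#' `[0.75, 1]`.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return A factor with the six ordered bin labels.
#' @export
bin_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("|r| > 1 is not a correlation.")
  labels <- CORRELATION_BINS$bin
  out <- character(length(r))
  out[r <= -0.75] <- "strong_negative"
  out[r > -0.75 & r <= -0.25] <- "intermediate_negative"
  out[r > -0.25 & r < 0] <- "weak_negative"
  out[r >= 0 & r < 0.25] <- "weak_positive"
  out[r >= 0.25 & r < 0.75] <- "intermediate_positive"
  out[r >= 0.75] <- "strong_positive"
  factor(out, levels = labels, ordered = TRUE)
}

#' Distribution of correlations over the six bins
#'
#' @param r Numeric vector of correlations.
#' @return A tibble with `bin` and `n` (all six bins, zero-filled); counts
#'   sum to `length(r)`.
#' @export
correlation_bin_distribution <- function(r) {
  b <- bin_correlation(r)
  tibble(bin = factor(CORRELATION_BINS$bin, levels = CORRELATION_BINS$bin,
                      ordered = TRUE)) |>
    left_join(count(tibble(bin = b), .data$bin), by = "bin") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Bar chart of the correlation-bin distribution
#'
#' @param r Numeric vector of miRNA-target correlations.
#' @return A ggplot.
#' @export
plot_correlation_bins <- function(r) {
  d <- correlation_bin_distribution(r)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "miRNA-target pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' DEMTG proportion test
#'
#' Compares the proportion of differentially expressed genes among targets of
#' differentially expressed miRNAs (DEMTGs) with the genome-background DEG
#' proportion, via a 2x2 chi-squared test (Yates-corrected) of DE status
#' against target status.
#'
#' @param de_genes Character vector of DE gene ids for the contrast.
#' @param de_mirnas Character vector of DE miRNA ids for the contrast.
#' @param target_map Tibble with `mirna_id` and `gene_id`.
#' @param all_genes Character vector: the gene universe.
#' @param correct Apply Yates continuity correction (default TRUE); set
#'   `method = "fisher"` for the exact test instead.
#' @param method "chisq" (default) or "fisher".
#' @return A one-row tibble with the 2x2 counts, `p_target` (DEG fraction in
#'   DEMTGs), `p_background`, `statistic`, `p_value` and `defined` (FALSE
#'   when there are no DE miRNAs).
#' @export
demtg_test <- function(de_genes, de_mirnas, target_map, all_genes,
                       correct = TRUE, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (length(all_genes) == 0) abort("empty gene universe.")
  targets <- unique(target_map$gene_id[target_map$mirna_id %in% de_mirnas])
  targets <- intersect(targets, all_genes)
  de_genes <- intersect(de_genes, all_genes)
  if (length(de_mirnas) == 0 || length(targets) == 0) {
    return(tibble(n_target = length(targets), n_target_de = NA_integer_,
                  n_background = length(all_genes),
                  n_background_de = length(de_genes),
                  p_target = NA_real_,
                  p_background = length(de_genes) / length(all_genes),
                  statistic = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  non_targets <- setdiff(all_genes, targets)
  tab <- matrix(c(
    sum(targets %in% de_genes), sum(!targets %in% de_genes),
    sum(non_targets %in% de_genes), sum(!non_targets %in% de_genes)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("target", "non_target"), c("de", "not_de")))
  ht <- if (method == "chisq") {
    suppressWarnings(chisq.test(tab, correct = correct))
  } else {
    fisher.test(tab)
  }
  tibble(
    n_target = length(targets),
    n_target_de = tab["target", "de"],
    n_background = length(all_genes),
    n_background_de = length(de_genes),
    p_target = tab["target", "de"] / length(targets),
    p_background = length(de_genes) / length(all_genes),
    statistic = if (method == "chisq") unname(ht$statistic) else NA_real_,
    p_value = ht$p.value,
    defined = TRUE
  )
}
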