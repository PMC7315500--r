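# Two-group differential expression shared by the miRNA catalogue and the
# isoform expression module. The count test is edgeR's exact negative
# binomial test with a common dispersion; the fold change is computed on
# per-million-normalised group means with a pseudo-count of 1, so it is
# finite and antisymmetric under group swap. A feature is called DE when
# FDR < 0.05 and |log2FC| > 1 (both strict).

#' Two-group differential expression of count features
#'
#' @param counts Wide expression tibble of raw counts.
#' @param design Design tibble (`sample_id`, `tissue`).
#' @param contrast Character vector of two tissue labels `c(group1, group2)`;
#'   `log2fc > 0` means higher in `group1` relative to `group2`.
#' @param fdr_max,lfc_min DE thresholds: called iff FDR < `fdr_max` and
#'   |log2FC| > `lfc_min` (strict inequalities).
#' @param dispersion Optional fixed NB dispersion; by default estimated from
#'   the data (common dispersion), falling back to 0.1 with a message when
#'   either group has a single sample.
#' @return A tibble with `feature_id`, `log2fc`, `p_value`, `fdr`, `de`
#'   (logical) and `direction` ("up"/"down" for DE features, NA otherwise).
#' @export
de_features <- function(counts, design, contrast, fdr_max = 0.05,
                        lfc_min = 1, dispersion = NULL) {
  m <- expr_to_matrix(counts)
  design <- check_design(m, design)
  if (length(contrast) != 2) abort("`contrast` must name exactly two groups.")
  missing <- setdiff(contrast, design$tissue)
  if (length(missing)) {
    abort(paste0("contrast group(s) absent from design: ",
                 paste(missing, collapse = ", ")))
  }
  cols1 <- design$sample_id[design$tissue == contrast[1]]
  cols2 <- design$sample_id[design$tissue == contrast[2]]
  sub <- m[, c(cols1, cols2), drop = FALSE]
  grp <- factor(rep(c("g1", "g2"), c(length(cols1), length(cols2))),
                levels = c("g2", "g1"))

  dge <- edgeR::DGEList(counts = sub, group = grp)
  dge <- edgeR::calcNormFactors(dge) # TMM guards against composition bias
  if (is.null(dispersion)) {
    if (length(cols1) >= 2 && length(cols2) >= 2) {
      dge <- edgeR::estimateCommonDisp(dge)
    } else {
      inform("singleton group: using fallback common dispersion 0.1")
      dge$common.dispersion <- 0.1
    }
  } else {
    dge$common.dispersion <- dispersion
  }
  et <- edgeR::exactTest(dge, pair = c("g2", "g1"))
  p <- et$table$PValue

  # fold change on per-million normalised group means, pseudo-count 1
  norm <- edgeR::cpm(dge, normalized.lib.sizes = TRUE)
  mu1 <- rowMeans(norm[, cols1, drop = FALSE])
  mu2 <- rowMeans(norm[, cols2, drop = FALSE])
  log2fc <- log2((mu1 + 1) / (mu2 + 1))

  fdr <- p.adjust(p, method = "BH")
  de <- fdr < fdr_max & abs(log2fc) > lfc_min
  tibble(
    feature_id = rownames(sub),
    log2fc = log2fc,
    p_value = p,
    fdr = fdr,
    de = de,
    direction = ifelse(de, ifelse(log2fc > 0, "up", "down"), NA_character_)
  )
}

#' Differential expression of miRNAs
#'
#' Identical contract to [de_features()]; provided as the catalogue-facing
#' name.
#'
#' @inheritParams de_features
#' @return See [de_features()].
#' @export
de_mirna <- function(counts, design, contrast, fdr_max = 0.05, lfc_min = 1,
                     dispersion = NULL) {
  de_features(counts, design, contrast, fdr_max = fdr_max, lfc_min = lfc_min,
              dispersion = dispersion)
}
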