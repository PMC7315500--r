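# Isoform/gene abundance: FPKM normalisation, the variability filter feeding
# the co-expression network, and qPCR relative quantification.

#' FPKM normalisation
#'
#' FPKM_ij = count_ij / (length_i / 1e3) / (libsize_j / 1e6). Library sizes
#' default to column sums of the count matrix.
#'
#' @param counts Wide expression tibble of raw counts.
#' @param feature_lengths Tibble with the feature-id column (same name as in
#'   `counts`) and a `length` column in nt, or a named numeric vector.
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes; defaults to column sums.
#' @return A wide expression tibble of FPKM values.
#' @export
fpkm <- function(counts, feature_lengths, library_sizes = NULL) {
  m <- expr_to_matrix(counts)
  if (is.data.frame(feature_lengths)) {
    len <- setNames(feature_lengths$length, feature_lengths[[1]])
  } else {
    len <- feature_lengths
  }
  len <- len[rownames(m)]
  if (any(is.na(len))) {
    abort(paste0("missing length for feature(s): ",
                 paste(rownames(m)[is.na(len)][1:min(5, sum(is.na(len)))],
                       collapse = ", ")))
  }
  if (any(len <= 0)) {
    abort(paste0("non-positive length for feature: ",
                 rownames(m)[which(len <= 0)[1]]))
  }
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  library_sizes <- library_sizes[colnames(m)]
  if (any(library_sizes <= 0)) abort("library sizes must be positive.")
  out <- sweep(m / (len / 1e3), 2, library_sizes / 1e6, "/")
  res <- matrix_to_expr(out, feature_col = names(counts)[1])
  attr(res, "unit") <- "FPKM"
  res
}

#' Variability filter for network construction
#'
#' Retains features with mean abundance above `mean_min` and coefficient of
#' variation above `cv_min` (both strict), where the mean and the C.V. (sample
#' standard deviation / mean) are computed across the per-tissue mean
#' profiles, i.e. the filter selects features variable across tissues rather
#' than across replicates.
#'
#' @param expr Wide expression tibble (FPKM).
#' @param design Design tibble (`sample_id`, `tissue`).
#' @param mean_min Minimum mean (default 0.1, strict).
#' @param cv_min Minimum C.V. (default 2, strict).
#' @param across Compute mean/C.V. across `"tissues"` (per-tissue means,
#'   default) or raw `"samples"`.
#' @return A list with `retained` (character vector of feature ids) and
#'   `report` (tibble with per-feature mean, cv, pass flags) plus counts
#'   `n_input`, `n_pass_mean`, `n_pass_cv`, `n_retained` as attributes of the
#'   report via the `summary` element.
#' @export
variability_filter <- function(expr, design, mean_min = 0.1, cv_min = 2,
                               across = c("tissues", "samples")) {
  across <- match.arg(across)
  m <- expr_to_matrix(expr)
  prof <- if (across == "tissues") tissue_means(m, design) else m
  if (ncol(prof) < 2) abort("need at least two columns to compute a C.V.")
  mu <- rowMeans(prof)
  sdev <- apply(prof, 1, sd)
  cv <- ifelse(mu > 0, sdev / mu, 0)
  report <- tibble(
    feature_id = rownames(m),
    mean = unname(mu), cv = unname(cv),
    pass_mean = mu > mean_min,
    pass_cv = cv > cv_min
  ) |>
    mutate(retained = .data$pass_mean & .data$pass_cv)
  list(
    retained = report$feature_id[report$retained],
    report = report,
    summary = tibble(
      n_input = nrow(report),
      n_pass_mean = sum(report$pass_mean),
      n_pass_cv = sum(report$pass_cv),
      n_retained = sum(report$retained)
    )
  )
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct_target - Ct_reference; ddCt = dCt_sample -
#' dCt_calibrator; relative expression = 2^-ddCt (1 for the calibrator by
#' construction).
#'
#' @param ct A data frame with columns `sample`, `ct_target`, `ct_reference`.
#' @param calibrator Name of the calibrator sample.
#' @return `ct` with `dct`, `ddct` and `rel_expr` columns added.
#' @export
ddct <- function(ct, calibrator) {
  ct <- as_tibble(ct)
  if (!all(c("sample", "ct_target", "ct_reference") %in% names(ct))) {
    abort("`ct` must have columns `sample`, `ct_target`, `ct_reference`.")
  }
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    abort("missing or non-finite Ct value (reference gene not measured?)")
  }
  if (!calibrator %in% ct$sample) {
    abort(paste0("calibrator sample not found: ", calibrator))
  }
  ct$dct <- ct$ct_target - ct$ct_reference
  cal <- ct$dct[ct$sample == calibrator][1]
  ct$ddct <- ct$dct - cal
  ct$rel_expr <- 2^(-ct$ddct)
  ct
}
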