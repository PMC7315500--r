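# Shared helpers for the wide expression-tibble convention:
# first column = feature id, remaining columns = one numeric column per sample,
# plus a design tibble mapping sample_id -> tissue.

#' Convert a wide expression tibble to a numeric matrix
#'
#' @param expr A data frame whose first column holds feature identifiers and
#'   whose remaining columns are numeric sample columns.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
expr_to_matrix <- function(expr) {
  expr <- as_tibble(expr)
  if (ncol(expr) < 2) {
    abort("`expr` needs a feature-id column plus at least one sample column.")
  }
  ids <- as.character(expr[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate feature ids in expression table: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("all sample columns must be numeric.")
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to a wide expression tibble
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param feature_col Name for the feature-id column.
#' @return A tibble.
#' @export
matrix_to_expr <- function(m, feature_col = "feature_id") {
  out <- as_tibble(m, rownames = feature_col)
  out
}

check_design <- function(expr_mat, design) {
  design <- as_tibble(design)
  if (!all(c("sample_id", "tissue") %in% names(design))) {
    abort("`design` must have columns `sample_id` and `tissue`.")
  }
  missing <- setdiff(colnames(expr_mat), design$sample_id)
  if (length(missing)) {
    abort(paste0("samples without a tissue label: ", paste(missing, collapse = ", ")))
  }
  design[match(colnames(expr_mat), design$sample_id), , drop = FALSE]
}

# feature x tissue matrix of per-tissue mean abundance
tissue_means <- function(expr_mat, design) {
  design <- check_design(expr_mat, design)
  tissues <- unique(design$tissue)
  out <- vapply(tissues, function(tt) {
    cols <- design$sample_id[design$tissue == tt]
    rowMeans(expr_mat[, cols, drop = FALSE])
  }, numeric(nrow(expr_mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr_mat))
  dimnames(out) <- list(rownames(expr_mat), tissues)
  out
}

# canonical RNA alphabet: uppercase, T -> U
normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA sequence string
#'
#' @param x Character vector of sequences over ACGU (T tolerated).
#' @return Character vector of reverse complements over ACGU.
#' @export
rna_reverse_complement <- function(x) {
  x <- normalize_rna(x)
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(RNA_COMPLEMENT[b])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

encode_rna <- function(s) {
  # A=1, C=2, G=3, U=4
  v <- utf8ToInt(s)
  code <- integer(length(v))
  code[v == 65L] <- 1L
  code[v == 67L] <- 2L
  code[v == 71L] <- 3L
  code[v == 85L] <- 4L
  if (any(code == 0L)) abort("sequence contains letters outside ACGU.")
  code
}
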