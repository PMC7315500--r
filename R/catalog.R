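# Mature-miRNA catalogue operations: small-RNA read filtering and collapsing,
# transposable-element annotation of precursors, TPM quantification,
# per-tissue presence, and first-base composition.

#' Length-filter and collapse small RNA reads
#'
#' Drops reads containing N, retains lengths 18-29 nt inclusive, and collapses
#' identical sequences, summing their counts.
#'
#' @param reads Character vector of read sequences (ACGUN alphabet; T
#'   tolerated).
#' @param min_len,max_len Inclusive length bounds (defaults 18 and 29).
#' @return A tibble with `sequence` and `count`, sorted by count descending
#'   then sequence.
#' @export
filter_and_collapse <- function(reads, min_len = 18, max_len = 29) {
  if (length(reads) == 0) return(tibble(sequence = character(), count = integer()))
  reads <- normalize_rna(reads)
  reads <- reads[!grepl("N", reads, fixed = TRUE)]
  len <- nchar(reads)
  reads <- reads[len >= min_len & len <= max_len]
  if (length(reads) == 0) return(tibble(sequence = character(), count = integer()))
  tab <- table(reads)
  tibble(sequence = names(tab), count = as.integer(tab)) |>
    arrange(desc(.data$count), .data$sequence)
}

#' Flag pre-miRNA intervals that overlap transposable elements
#'
#' An interval is TE-related when it shares at least 1 bp with a TE interval
#' on the same chromosome (half-open coordinates; strand ignored). Precursors
#' on chromosomes absent from the TE set are treated as non-overlapping.
#'
#' @param premirna_intervals Tibble of precursor intervals (`chrom`, `start`,
#'   `end`, `name`).
#' @param te_intervals Tibble of TE intervals (`chrom`, `start`, `end`).
#' @return `premirna_intervals` with a logical `te_related` column.
#' @export
annotate_te_overlap <- function(premirna_intervals, te_intervals) {
  pre <- as_tibble(premirna_intervals)
  te <- as_tibble(te_intervals)
  unknown <- setdiff(unique(pre$chrom), unique(te$chrom))
  if (length(unknown) && nrow(te) > 0) {
    inform(paste0("no TE intervals on: ", paste(unknown, collapse = ", ")))
  }
  pre$te_related <- map_lgl(seq_len(nrow(pre)), function(i) {
    same <- te[te$chrom == pre$chrom[i], , drop = FALSE]
    any(pre$start[i] < same$end & same$start < pre$end[i])
  })
  pre
}

#' Propagate TE flags from precursors to mature miRNAs
#'
#' A mature miRNA is TE-related when any precursor producing it is.
#'
#' @param mirna_premirna_map Tibble with `mirna_id` and `premirna_id`.
#' @param premirna_flags Tibble with `name` (precursor id) and `te_related`.
#' @return A tibble with `mirna_id` and `is_te_related`.
#' @export
mature_te_flags <- function(mirna_premirna_map, premirna_flags) {
  mirna_premirna_map |>
    left_join(select(premirna_flags, name = "name", te_related = "te_related"),
              by = c(premirna_id = "name")) |>
    group_by(.data$mirna_id) |>
    summarise(is_te_related = any(.data$te_related, na.rm = TRUE),
              .groups = "drop")
}

#' Convert small-RNA counts to TPM
#'
#' Small RNAs share an effective length, so TPM reduces to counts per million
#' over the per-sample total: every column of the result sums to 1e6.
#'
#' @param counts A wide expression tibble of raw counts.
#' @return A wide expression tibble of TPM values.
#' @export
tpm_quantify <- function(counts) {
  m <- expr_to_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("zero column sum in sample(s): ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  tpm <- sweep(m, 2, totals, "/") * 1e6
  out <- matrix_to_expr(tpm, feature_col = names(counts)[1])
  attr(out, "unit") <- "TPM"
  out
}

#' Per-tissue presence of miRNAs and intersection counts
#'
#' A miRNA is present in a tissue when any replicate exceeds the abundance
#' threshold. Returns the presence table plus the marginal and intersection
#' counts an UpSet plot would display: per-tissue totals, the count common to
#' all tissues, and counts unique to a single tissue.
#'
#' @param abundance Wide expression tibble (TPM).
#' @param design Design tibble (`sample_id`, `tissue`).
#' @param threshold Present iff abundance > threshold (default 0).
#' @return A list with `presence` (tibble feature x tissue logical),
#'   `per_tissue` (tibble `tissue`, `n_present`, `n_unique`) and
#'   `n_all_tissues` (scalar).
#' @export
tissue_presence <- function(abundance, design, threshold = 0) {
  m <- expr_to_matrix(abundance)
  all_tissues <- unique(design$tissue)
  design <- check_design(m, design)
  tissues <- unique(design$tissue)
  empty_tissues <- setdiff(all_tissues, tissues)
  if (length(empty_tissues)) {
    abort(paste0("tissue without samples: ", paste(empty_tissues, collapse = ", ")))
  }
  pres <- vapply(tissues, function(tt) {
    cols <- design$sample_id[design$tissue == tt]
    apply(m[, cols, drop = FALSE] > threshold, 1, any)
  }, logical(nrow(m)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = nrow(m))
  dimnames(pres) <- list(rownames(m), tissues)
  n_tissues_present <- rowSums(pres)
  per_tissue <- tibble(
    tissue = tissues,
    n_present = unname(colSums(pres)),
    n_unique = vapply(tissues, function(tt) {
      sum(pres[, tt] & n_tissues_present == 1)
    }, numeric(1), USE.NAMES = FALSE)
  )
  list(
    presence = as_tibble(pres, rownames = names(abundance)[1]),
    per_tissue = per_tissue,
    n_all_tissues = sum(n_tissues_present == length(tissues))
  )
}

#' First-nucleotide composition by length class
#'
#' @param sequences Character vector of miRNA sequences.
#' @return A tibble with `length`, `base` (A/C/G/U), `n` and `fraction`;
#'   fractions sum to 1 within each length class.
#' @export
base_composition <- function(sequences) {
  if (length(sequences) == 0) abort("empty catalogue")
  sequences <- normalize_rna(sequences)
  tibble(
    length = nchar(sequences),
    base = substr(sequences, 1, 1)
  ) |>
    count(.data$length, .data$base) |>
    group_by(.data$length) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}
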