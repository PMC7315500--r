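# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are uniformly 0-based half-open; GFF3 (1-based,
# inclusive) is converted on read, BED's native convention is kept as-is.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are uppercased and T is normalised to U so that every downstream
#' operation works on a single ACGU alphabet. Record ids are the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @param normalize Normalise to the RNA alphabet (uppercase, T->U)?
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  lines <- readLines(path)
  first <- which(!grepl("^\\s*$", lines) & !startsWith(lines, ";"))[1]
  if (!is.na(first) && !startsWith(lines[first], ">")) {
    abort(paste0("malformed FASTA at line ", first, ": sequence before header"))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- as.character(set)
  if (normalize) seqs <- normalize_rna(seqs)
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns `id` and `sequence` (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Builds the transcript-coordinate segmentation (5'UTR / CDS / 3'UTR) of each
#' mRNA from its `five_prime_UTR`, `CDS` and `three_prime_UTR` children,
#' strand-aware, converting GFF's 1-based inclusive genomic coordinates to
#' 0-based half-open transcript coordinates. The three segments always tile
#' `[0, length)`; any segment may be empty.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per transcript: `isoform_id`, `gene_id`,
#'   `length`, and `utr5_start`, `utr5_end`, `cds_start`, `cds_end`,
#'   `utr3_start`, `utr3_end` (0-based half-open).
#' @export
read_gff_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$Parent_chr <- if (!"Parent" %in% names(df)) {
    rep(NA_character_, nrow(df))
  } else {
    vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[1])
    }, character(1))
  }

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0) abort("no mRNA/transcript features in GFF3 file.")
  seg <- df[df$type %in% c("five_prime_UTR", "CDS", "three_prime_UTR"), , drop = FALSE]
  orphan <- is.na(seg$Parent_chr)
  if (any(orphan)) {
    abort(paste0(
      "GFF3 features without a Parent link: ",
      paste(utils::head(paste0(seg$type[orphan], "@", seg$seqnames[orphan], ":",
                               seg$start[orphan]), 5), collapse = ", ")
    ))
  }

  one_tx <- function(i) {
    tx_id <- mrna$ID[i]
    strand <- as.character(mrna$strand[i])
    kids <- seg[seg$Parent_chr == tx_id, , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 1) {
      o <- order(cds$start)
      if (any(cds$start[o][-1] <= cds$end[o][-nrow(cds)])) {
        abort(paste0("overlapping CDS segments in transcript ", tx_id))
      }
    }
    w <- function(type) sum(kids$width[kids$type == type])
    len5 <- w("five_prime_UTR"); lenc <- w("CDS"); len3 <- w("three_prime_UTR")
    total <- len5 + lenc + len3
    if (total == 0) {
      total <- mrna$width[i]
      lenc <- total
    }
    # in transcript coordinates the 5'UTR always precedes the CDS regardless
    # of genomic strand; only segment lengths are needed
    gene <- mrna$Parent_chr[i]
    tibble(
      isoform_id = tx_id,
      gene_id = if (is.na(gene)) tx_id else gene,
      length = total,
      utr5_start = 0L, utr5_end = len5,
      cds_start = len5, cds_end = len5 + lenc,
      utr3_start = len5 + lenc, utr3_end = total,
      strand = strand
    )
  }
  list_rbind(map(seq_len(nrow(mrna)), one_tx))
}

#' Read genomic intervals from a BED3+ file
#'
#' @param path Path to a BED file (0-based half-open, BED's native convention).
#' @return A tibble with columns `chrom`, `start`, `end`, `name` (may be NA)
#'   and `strand` ('.' when unstated). An empty file yields an empty tibble.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", which(nf < 3)[1], " has fewer than 3 fields"))
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    abort(paste0("invalid interval (start >= end or non-numeric) at BED line ", bad[1]))
  }
  name <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4) fields[[i]][4] else NA_character_
  }, character(1))
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 6) fields[[i]][6] else "."
  }, character(1))
  tibble(chrom = chrom, start = start, end = end, name = name, strand = strand)
}

#' Write genomic intervals to a BED file
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, and optionally
#'   `name` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, x$start, x$end, name, 0, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV expression matrix (features x samples)
#'
#' @param path Path to a tab-separated file whose first column is the feature
#'   id and whose remaining columns are numeric sample columns.
#' @return A wide expression tibble.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a sample design table (sample_id, tissue)
#'
#' @param path Path to a TSV with columns `sample_id` and `tissue`.
#' @return A tibble.
#' @export
read_design_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(d))) {
    abort("design table must have columns `sample_id` and `tissue`.")
  }
  d
}
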