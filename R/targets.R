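# Complementarity search: exhaustive scan of the transcript sense strand for
# windows complementary to a miRNA under the mispair penalty score. Every
# window is evaluated as the gapless antiparallel duplex plus every duplex
# containing exactly one internal single-nucleotide bulge (extra target base)
# or gap (missing target base); the minimum-score duplex represents the
# window. Scanning is vectorised across window starts, so cost is
# O(L * m * variants) with small constants.

# Enumerate alignment variants for a miRNA of length m:
#   variant 0: gapless; windows of length m
#   bulge at window position k (k = 2..m): window length m+1, the extra
#     target base is flanked by paired columns; doubling position is the
#     adjacent 5'-side miRNA base, m-k+1
#   gap at pair column j0 (j0 = 2..m-1): miRNA position m-j0+1 unpaired,
#     window length m-1
scan_variants <- function(m) {
  v <- list(list(kind = "gapless", len = m, offsets = 0:(m - 1),
                 cols = seq_len(m), extra = 0))
  for (k in 2:m) {
    offs <- ifelse(seq_len(m) < k, seq_len(m) - 1L, seq_len(m))
    v[[length(v) + 1]] <- list(
      kind = "bulge", k = k, len = m + 1L, offsets = offs,
      cols = seq_len(m),
      extra = PENALTY_INDEL * position_weight(m - k + 1L)
    )
  }
  if (m >= 3) {
    for (j0 in 2:(m - 1)) {
      offs <- ifelse(seq_len(m) < j0, seq_len(m) - 1L, seq_len(m) - 2L)
      offs <- offs[-j0]
      v[[length(v) + 1]] <- list(
        kind = "gap", j0 = j0, len = m - 1L, offsets = offs,
        cols = seq_len(m)[-j0],
        extra = PENALTY_INDEL * position_weight(m - j0 + 1L)
      )
    }
  }
  v
}

# score one variant at every feasible start; returns numeric vector indexed
# by start (NA where the window runs off the transcript)
variant_scores <- function(tt, qrev_pen_rows, wv, variant, n_starts) {
  L <- length(tt)
  S <- L - variant$len + 1L
  out <- rep(NA_real_, n_starts)
  if (S < 1) return(out)
  starts <- seq_len(S)
  idx <- outer(starts - 1L, variant$offsets, "+") + 1L
  tm <- matrix(tt[idx], S, length(variant$offsets))
  pen <- matrix(qrev_pen_rows[cbind(
    rep(variant$cols, each = S),
    as.vector(tm)
  )], S, length(variant$offsets))
  out[starts] <- as.vector(pen %*% wv[variant$cols]) + variant$extra
  out
}

#' Find candidate miRNA target sites on one transcript
#'
#' Scans the transcript sense strand exhaustively: every window is evaluated
#' as the gapless antiparallel duplex of the miRNA against the window plus
#' every duplex containing exactly one internal single-nucleotide bulge or
#' gap in the target. Per window the minimum-score duplex is kept; sites with
#' score at or below `cutoff` are reported, and overlapping sites of the same
#' miRNA are reduced to the best-scoring one (ties resolved leftmost).
#'
#' @param mirna_sequence miRNA sequence, 5'->3', ACGU (T tolerated).
#' @param target_sequence Transcript sequence, 5'->3'.
#' @param cutoff Maximum penalty score retained (default 3).
#' @return A tibble with one row per retained site: `start`, `end` (0-based
#'   half-open transcript coordinates), `score`, `variant` (gapless / bulge /
#'   gap), `n_mismatch`, `n_gu`, and `alignment` (three-line display string).
#' @export
find_candidate_sites <- function(mirna_sequence, target_sequence, cutoff = 3) {
  q <- normalize_rna(mirna_sequence)
  t_seq <- normalize_rna(target_sequence)
  m <- nchar(q)
  L <- nchar(t_seq)
  empty <- tibble(start = integer(), end = integer(), score = numeric(),
                  variant = character(), n_mismatch = integer(),
                  n_gu = integer(), alignment = character())
  if (m > L || m < 2) return(empty)

  qq <- encode_rna(q)
  tt <- encode_rna(t_seq)
  qrev <- qq[m:1]
  P <- penalty_table()
  # penalty rows for the pair columns (miRNA base fixed per column)
  qrev_pen_rows <- P[qrev, , drop = FALSE]
  wv <- position_weight(m - seq_len(m) + 1L)

  variants <- scan_variants(m)
  n_starts <- L - m + 2L # widest feasible range (gap variant)
  score_mat <- vapply(variants, function(v) {
    variant_scores(tt, qrev_pen_rows, wv, v, n_starts)
  }, numeric(n_starts))
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, nrow = n_starts)

  best_var <- apply(score_mat, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.min(r)
  })
  best_score <- score_mat[cbind(seq_len(n_starts), best_var)]
  keep <- which(!is.na(best_score) & best_score <= cutoff)
  if (length(keep) == 0) return(empty)

  sites <- list_rbind(map(keep, function(s) {
    v <- variants[[best_var[s]]]
    tibble(start = s - 1L, end = s - 1L + v$len, score = best_score[s],
           variant_idx = best_var[s])
  }))

  # reduce overlapping sites to the best-scoring one, ties leftmost
  sites <- arrange(sites, .data$score, .data$start)
  kept <- list()
  for (i in seq_len(nrow(sites))) {
    cand <- sites[i, ]
    clash <- any(map_lgl(kept, function(k) {
      cand$start < k$end && k$start < cand$end
    }))
    if (!clash) kept[[length(kept) + 1]] <- cand
  }
  sites <- arrange(list_rbind(kept), .data$start)

  detail <- map(seq_len(nrow(sites)), function(i) {
    v <- variants[[sites$variant_idx[i]]]
    render_alignment(qq, tt[(sites$start[i] + 1):sites$end[i]], v)
  })
  sites$variant <- map_chr(detail, "kind")
  sites$n_mismatch <- map_int(detail, "n_mismatch")
  sites$n_gu <- map_int(detail, "n_gu")
  sites$alignment <- map_chr(detail, "display")
  select(sites, -"variant_idx")
}

# build per-column states and a three-line display for one duplex
render_alignment <- function(qq, window, variant) {
  bases <- c("A", "C", "G", "U")
  m <- length(qq)
  qrev <- qq[m:1]
  P <- penalty_table()
  tline <- qline <- pline <- character(0)
  n_mm <- n_gu <- 0L
  push <- function(tch, pch, qch) {
    tline <<- c(tline, tch); pline <<- c(pline, pch); qline <<- c(qline, qch)
  }
  j <- 1L # pair column
  for (wpos in seq_len(variant$len)) {
    if (variant$kind == "bulge" && wpos == variant$k) {
      push(bases[window[wpos]], " ", "-")
      next
    }
    if (variant$kind == "gap" && j == variant$j0) {
      push("-", " ", bases[qrev[j]])
      j <- j + 1L
    }
    p <- P[qrev[j], window[wpos]]
    sym <- if (p == 0) "|" else if (p == PENALTY_GU) "o" else " "
    if (p == PENALTY_MISMATCH) n_mm <- n_mm + 1L
    if (p == PENALTY_GU) n_gu <- n_gu + 1L
    push(bases[window[wpos]], sym, bases[qrev[j]])
    j <- j + 1L
  }
  if (variant$kind == "gap" && variant$j0 == m) {
    push("-", " ", bases[qrev[m]])
  }
  list(
    kind = variant$kind, n_mismatch = n_mm, n_gu = n_gu,
    display = paste0(
      "5' ", paste(tline, collapse = ""), " 3' target\n",
      "   ", paste(pline, collapse = ""), "\n",
      "3' ", paste(qline, collapse = ""), " 5' miRNA"
    )
  )
}

#' Predict miRNA targets across a set of isoforms
#'
#' Runs [find_candidate_sites()] for every miRNA x isoform pair and assembles
#' the site table, per-isoform summaries (number of sites, number of distinct
#' regulating miRNAs) and a per-gene classification into fully targeted
#' (every isoform carries a retained site), partially targeted, or
#' untargeted.
#'
#' @param mirnas A data frame with columns `mirna_id` and `sequence`.
#' @param isoforms A data frame with columns `isoform_id`, `gene_id`,
#'   `sequence`, and (optionally, for region labels) the segmentation columns
#'   produced by [read_gff_transcripts()].
#' @param cutoff Maximum penalty score retained (default 3).
#' @return A list with tibbles `sites`, `isoform_summary`, `gene_summary`.
#' @export
predict_targets <- function(mirnas, isoforms, cutoff = 3) {
  mirnas <- as_tibble(mirnas)
  isoforms <- as_tibble(isoforms)
  if (anyDuplicated(isoforms$isoform_id)) {
    abort(paste0("duplicate isoform ids: ",
                 paste(unique(isoforms$isoform_id[duplicated(isoforms$isoform_id)]),
                       collapse = ", ")))
  }
  has_seg <- all(c("utr5_end", "cds_end", "utr3_end") %in% names(isoforms))

  sites <- list_rbind(map(seq_len(nrow(mirnas)), function(i) {
    per_iso <- map(seq_len(nrow(isoforms)), function(k) {
      s <- find_candidate_sites(mirnas$sequence[i], isoforms$sequence[k], cutoff)
      if (nrow(s) == 0) return(NULL)
      s$mirna_id <- mirnas$mirna_id[i]
      s$isoform_id <- isoforms$isoform_id[k]
      s$gene_id <- isoforms$gene_id[k]
      s
    })
    list_rbind(keep(per_iso, Negate(is.null)))
  }))
  if (nrow(sites) == 0) {
    sites <- tibble(start = integer(), end = integer(), score = numeric(),
                    variant = character(), n_mismatch = integer(),
                    n_gu = integer(), alignment = character(),
                    mirna_id = character(), isoform_id = character(),
                    gene_id = character())
  }
  sites <- select(sites, "mirna_id", "isoform_id", "gene_id", dplyr::everything())
  if (has_seg && nrow(sites) > 0) {
    sites <- annotate_site_region(sites, isoforms)
  }

  isoform_summary <- sites |>
    group_by(.data$isoform_id, .data$gene_id) |>
    summarise(n_sites = n(), n_mirnas = n_distinct(.data$mirna_id),
              .groups = "drop")
  isoform_summary <- isoforms |>
    select("isoform_id", "gene_id") |>
    left_join(isoform_summary, by = c("isoform_id", "gene_id")) |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           n_mirnas = dplyr::coalesce(.data$n_mirnas, 0L))

  gene_summary <- isoform_summary |>
    group_by(.data$gene_id) |>
    summarise(n_isoforms = n(),
              n_targeted = sum(.data$n_sites > 0),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_targeted == 0 ~ "untargeted",
      .data$n_targeted == .data$n_isoforms ~ "fully_targeted",
      TRUE ~ "partially_targeted"
    ))

  list(sites = sites, isoform_summary = isoform_summary,
       gene_summary = gene_summary)
}

#' Label target sites by transcript region
#'
#' Assigns each site the region (5UTR / CDS / 3UTR) with which it overlaps
#' most; ties are broken in favour of the CDS.
#'
#' @param sites A site table with columns `isoform_id`, `start`, `end`.
#' @param isoforms Isoform table carrying the segmentation columns.
#' @return `sites` with a `region` column added.
#' @export
annotate_site_region <- function(sites, isoforms) {
  seg <- isoforms |>
    select("isoform_id", "utr5_start", "utr5_end", "cds_start", "cds_end",
           "utr3_start", "utr3_end")
  x <- left_join(as_tibble(sites), seg, by = "isoform_id")
  if (any(x$start < 0 | x$end > x$utr3_end)) {
    abort("site outside transcript bounds")
  }
  ov <- function(s, e, a, b) pmax(0, pmin(e, b) - pmax(s, a))
  o5 <- ov(x$start, x$end, x$utr5_start, x$utr5_end)
  oc <- ov(x$start, x$end, x$cds_start, x$cds_end)
  o3 <- ov(x$start, x$end, x$utr3_start, x$utr3_end)
  # CDS wins ties; otherwise the larger overlap
  region <- ifelse(oc >= o5 & oc >= o3, "CDS",
                   ifelse(o5 > o3, "5UTR", "3UTR"))
  sites$region <- region
  sites
}

#' Region proportions over a site table
#'
#' @param sites A site table with a `region` column.
#' @return A tibble with `region`, `n` and `pct` (percentages sum to 100).
#' @export
site_region_proportions <- function(sites) {
  out <- sites |>
    count(.data$region) |>
    mutate(pct = 100 * .data$n / sum(.data$n))
  all_regions <- tibble(region = c("5UTR", "CDS", "3UTR"))
  all_regions |>
    left_join(out, by = "region") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           pct = dplyr::coalesce(.data$pct, 0))
}
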