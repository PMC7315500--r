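# Independent brute-force oracle for the site scanner. It enumerates every
# window start and every <=1-indel duplex with plain loops, scoring each
# column with direct penalty arithmetic (no shared code with the vectorised
# scan path beyond sequence normalisation).

oracle_pair_penalty <- function(qb, tb) {
  wc <- (qb == "A" && tb == "U") || (qb == "U" && tb == "A") ||
    (qb == "G" && tb == "C") || (qb == "C" && tb == "G")
  if (wc) return(0)
  gu <- (qb == "G" && tb == "U") || (qb == "U" && tb == "G")
  if (gu) return(0.5)
  1
}

oracle_weight <- function(pos) if (pos >= 2 && pos <= 13) 2 else 1

# score a duplex given the miRNA bases (5'->3'), the target window bases
# (5'->3') and the variant: list(kind, k (bulge window pos) or j0 (gapped
# pair column))
oracle_duplex_score <- function(qb, window, variant) {
  m <- length(qb)
  score <- 0
  j <- 1
  for (wpos in seq_along(window)) {
    if (variant$kind == "bulge" && wpos == variant$k) {
      score <- score + 1 * oracle_weight(m - variant$k + 1)
      next
    }
    if (variant$kind == "gap" && j == variant$j0) {
      score <- score + 1 * oracle_weight(m - variant$j0 + 1)
      j <- j + 1
    }
    mirna_pos <- m - j + 1
    score <- score + oracle_pair_penalty(qb[mirna_pos], window[wpos]) *
      oracle_weight(mirna_pos)
    j <- j + 1
  }
  score
}

oracle_scan <- function(mirna, target, cutoff = 3) {
  q <- chartr("Tt", "Uu", toupper(mirna))
  t_seq <- chartr("Tt", "Uu", toupper(target))
  qb <- strsplit(q, "")[[1]]
  tb <- strsplit(t_seq, "")[[1]]
  m <- length(qb)
  L <- length(tb)
  if (m > L) return(data.frame(start = integer(), end = integer(),
                               score = numeric()))
  variants <- list(list(kind = "gapless", len = m))
  for (k in 2:m) variants[[length(variants) + 1]] <-
    list(kind = "bulge", len = m + 1, k = k)
  for (j0 in 2:(m - 1)) variants[[length(variants) + 1]] <-
    list(kind = "gap", len = m - 1, j0 = j0)

  rows <- list()
  for (s in seq_len(L - m + 2)) {
    best <- Inf
    best_len <- NA
    for (v in variants) {
      if (s + v$len - 1 > L) next
      sc <- oracle_duplex_score(qb, tb[s:(s + v$len - 1)], v)
      if (sc < best) {
        best <- sc
        best_len <- v$len
      }
    }
    if (is.finite(best) && best <= cutoff) {
      rows[[length(rows) + 1]] <- data.frame(start = s - 1,
                                             end = s - 1 + best_len,
                                             score = best)
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       score = numeric()))
  out <- do.call(rbind, rows)
  # same overlap rule: best score wins, ties leftmost
  out <- out[order(out$score, out$start), , drop = FALSE]
  kept <- out[0, ]
  for (i in seq_len(nrow(out))) {
    cand <- out[i, ]
    if (nrow(kept) == 0 ||
        !any(cand$start < kept$end & kept$start < cand$end)) {
      kept <- rbind(kept, cand)
    }
  }
  kept[order(kept$start), , drop = FALSE]
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
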