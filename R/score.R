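# Position-dependent mispair penalty scoring of miRNA:target duplexes.
#
# Penalties per alignment column: Watson-Crick pair 0; G:U wobble +0.5;
# mismatch, single-nucleotide bulge (extra target base) or gap (missing
# target base) +1. Penalties are doubled when the column sits at miRNA
# positions 2-13 counted from the miRNA 5' end. A bulge column carries no
# miRNA base; for the doubling test it takes the position of the adjacent
# miRNA base on the 5' side. Duplexes with score <= 3 are retained.

PENALTY_MISMATCH <- 1
PENALTY_GU <- 0.5
PENALTY_INDEL <- 1
DOUBLING_WINDOW <- c(2L, 13L)

# 4x4 penalty lookup, rows = miRNA base, cols = target base (A,C,G,U)
penalty_table <- function() {
  P <- matrix(PENALTY_MISMATCH, 4, 4,
              dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  P["A", "U"] <- 0; P["U", "A"] <- 0; P["G", "C"] <- 0; P["C", "G"] <- 0
  P["G", "U"] <- PENALTY_GU; P["U", "G"] <- PENALTY_GU
  P
}

position_weight <- function(mirna_pos) {
  ifelse(mirna_pos >= DOUBLING_WINDOW[1] & mirna_pos <= DOUBLING_WINDOW[2], 2, 1)
}

#' Score a miRNA:target duplex alignment
#'
#' Computes the penalty score of an explicit duplex alignment. The alignment
#' is a data frame of columns with a `state` (one of `WC_pair`, `GU_pair`,
#' `mismatch`, `bulge_in_target`, `gap_in_target`) and the miRNA position
#' `mirna_pos` the column is scored at (1 = miRNA 5' end; a `bulge_in_target`
#' column has no miRNA base and takes the position of the adjacent miRNA base
#' on its 5' side).
#'
#' @param columns A data frame with columns `state` and `mirna_pos`.
#' @return The penalty score (numeric scalar).
#' @examples
#' perfect <- data.frame(state = rep("WC_pair", 21), mirna_pos = 1:21)
#' score_duplex(perfect) # 0
#' wobble16 <- perfect; wobble16$state[wobble16$mirna_pos == 16] <- "GU_pair"
#' score_duplex(wobble16) # 0.5
#' @export
score_duplex <- function(columns) {
  columns <- as_tibble(columns)
  states <- c("WC_pair", "GU_pair", "mismatch", "bulge_in_target", "gap_in_target")
  if (!all(columns$state %in% states)) {
    abort(paste0("unknown column state: ",
                 paste(setdiff(columns$state, states), collapse = ", ")))
  }
  n_indel <- sum(columns$state %in% c("bulge_in_target", "gap_in_target"))
  if (n_indel > 1) {
    abort("invalid alignment: more than one single-nucleotide bulge/gap column")
  }
  base_cols <- columns$mirna_pos[columns$state != "bulge_in_target"]
  m <- max(columns$mirna_pos)
  if (!setequal(base_cols, seq_len(m)) || anyDuplicated(base_cols)) {
    abort("non-bulge columns must cover miRNA positions 1..length exactly once")
  }
  pen <- c(WC_pair = 0, GU_pair = PENALTY_GU, mismatch = PENALTY_MISMATCH,
           bulge_in_target = PENALTY_INDEL, gap_in_target = PENALTY_INDEL)
  sum(pen[columns$state] * position_weight(columns$mirna_pos))
}
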