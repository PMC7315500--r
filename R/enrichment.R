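# Term enrichment for gene sets: central hypergeometric upper-tail tests,
# and a Wallenius noncentral hypergeometric variant that absorbs a
# per-gene sampling bias (e.g. transcript length) through an odds parameter.
# The Wallenius pmf is evaluated from its standard integral representation
# with adaptive quadrature.

#' Wallenius noncentral hypergeometric probability mass
#'
#' Probability of drawing `x` white balls in `n` biased draws without
#' replacement from an urn with `m1` white and `m2` black balls, white balls
#' weighted by `odds`.
#'
#' @param x Integer vector of white-ball counts.
#' @param m1,m2 White/black ball counts in the urn.
#' @param n Number of draws.
#' @param odds Weight ratio white:black (1 = central hypergeometric).
#' @return Numeric vector of probabilities.
#' @export
dwallenius <- function(x, m1, m2, n, odds = 1) {
  vapply(x, function(k) {
    if (k < max(0, n - m2) || k > min(n, m1)) return(0)
    d <- odds * (m1 - k) + (m2 - (n - k))
    if (d <= 0) {
      # all remaining mass: only reachable support point
      return(1)
    }
    f <- function(t) {
      (1 - t^(odds / d))^k * (1 - t^(1 / d))^(n - k)
    }
    int <- integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
    choose(m1, k) * choose(m2, n - k) * int
  }, numeric(1))
}

#' Wallenius upper-tail probability
#'
#' @inheritParams dwallenius
#' @param q Observed white-ball count; returns P(X >= q).
#' @return Upper-tail probability.
#' @export
pwallenius_upper <- function(q, m1, m2, n, odds = 1) {
  support <- seq(max(0, n - m2), min(n, m1))
  keep <- support[support >= q]
  if (length(keep) == 0) return(0)
  min(1, sum(dwallenius(keep, m1, m2, n, odds)))
}

#' Term enrichment with central or bias-aware hypergeometric tests
#'
#' Without `bias_weights`, per-term over-representation p-values come from
#' the central hypergeometric upper tail. With `bias_weights` (for example
#' transcript lengths), the Wallenius noncentral hypergeometric upper tail is
#' used, with the term's odds estimated as the mean weight inside the term
#' divided by the mean weight outside it. P-values are BH-adjusted across
#' terms.
#'
#' @param study_set Character vector of study gene ids (subset of
#'   `population`).
#' @param population Character vector: the gene universe.
#' @param term_map Tibble with `gene_id` and `term`; genes without
#'   annotation simply contribute no term counts.
#' @param bias_weights Optional named numeric vector of per-gene weights.
#' @return A tibble with `term`, `study_count`, `study_total`,
#'   `population_count`, `population_total`, `odds`, `p_value`, `fdr`,
#'   sorted by p-value.
#' @export
enrich_terms <- function(study_set, population, term_map,
                         bias_weights = NULL) {
  if (length(study_set) == 0) abort("empty study set.")
  extra <- setdiff(study_set, population)
  if (length(extra)) {
    abort(paste0("study genes outside the population: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  term_map <- filter(as_tibble(term_map), .data$gene_id %in% population)
  terms <- unique(term_map$term)
  n_total <- length(population)
  n_study <- length(study_set)

  rows <- map(terms, function(te) {
    in_term <- unique(term_map$gene_id[term_map$term == te])
    m1 <- length(in_term)
    if (m1 == 0) return(NULL)
    k <- sum(study_set %in% in_term)
    if (is.null(bias_weights)) {
      odds <- 1
      p <- phyper(k - 1, m1, n_total - m1, n_study, lower.tail = FALSE)
    } else {
      w_in <- mean(bias_weights[in_term], na.rm = TRUE)
      w_out <- mean(bias_weights[setdiff(population, in_term)], na.rm = TRUE)
      odds <- w_in / w_out
      p <- pwallenius_upper(k, m1, n_total - m1, n_study, odds)
    }
    tibble(term = te, study_count = k, study_total = n_study,
           population_count = m1, population_total = n_total,
           odds = odds, p_value = p)
  })
  out <- list_rbind(keep(rows, Negate(is.null)))
  if (nrow(out) == 0) abort("no term has population members.")
  out$fdr <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value, .data$term)
}
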