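# Seeded synthetic-data generator with planted ground truth. It emulates the
# statistical structure the pipeline assumes: a six-tissue replicated design,
# genes whose isoforms share segments but differ by inclusion of a planted
# miRNA binding site (so some miRNAs target only part of a gene's isoforms),
# block-structured tissue-specific expression with negative miRNA-target
# coupling, negative-binomially overdispersed counts, TE-overlapping
# precursor loci, and two pseudo-species homolog maps planting categories
# I/II/III.

#' Simulation configuration
#'
#' @param seed Mandatory RNG seed (integer).
#' @param n_genes Number of genes.
#' @param isoform_count_probs Probabilities of 1, 2, 3 isoforms per gene.
#' @param n_mirnas Number of mature miRNAs.
#' @param mirna_length miRNA length (nt).
#' @param frac_te_mirna Fraction of miRNAs with TE-overlapping precursors.
#' @param tissues Tissue labels.
#' @param replicates Replicates per tissue (recycled to `length(tissues)`).
#' @param n_modules Number of planted co-expression modules.
#' @param frac_background Fraction of genes given a flat (housekeeping-like)
#'   expression profile; they carry no planted module or site and are the
#'   population the C.V. filter removes.
#' @param mu_background Mean count of background isoforms in every tissue.
#' @param frac_genes_targeted Fraction of genes given a planted miRNA site.
#' @param frac_partial Among targeted multi-isoform genes, fraction whose
#'   site sits in a skippable segment (partial targeting).
#' @param frac_sites_distorted Fraction of planted sites given one random
#'   distortion (G:U, mismatch, bulge or gap).
#' @param frac_giddm Among multi-isoform genes, fraction whose isoforms are
#'   split across two modules.
#' @param repression_strength Strength in `[0, 1]` of the anti-correlation
#'   between a miRNA's profile and its targets' profile.
#' @param nb_dispersion Negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mu_high,mu_low Mean counts in a module's own tissue / elsewhere.
#' @param targeted_boost Multiplier on targeted-isoform means.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param n_cds_segments,cds_segment_len CDS segment layout; isoforms beyond
#'   the first each skip one internal CDS segment.
#' @param homolog_category_probs Probabilities of homolog categories I/II/III
#'   for multi-isoform genes, per pseudo-species.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 60,
                       isoform_count_probs = c(0.3, 0.4, 0.3),
                       n_mirnas = 20,
                       mirna_length = 21,
                       frac_te_mirna = 0.44,
                       tissues = c("leaf", "petiole", "petal", "anther",
                                   "unpollinated_carpel", "pollinated_carpel"),
                       replicates = c(5, 2, 2, 2, 2, 2),
                       n_modules = 3,
                       frac_background = 0.4,
                       mu_background = 600,
                       frac_genes_targeted = 0.5,
                       frac_partial = 0.6,
                       frac_sites_distorted = 0.2,
                       frac_giddm = 0.25,
                       repression_strength = 0.9,
                       nb_dispersion = 0.05,
                       mu_high = 2000,
                       mu_low = 5,
                       targeted_boost = 4,
                       utr5_len = 60,
                       utr3_len = 80,
                       n_cds_segments = 4,
                       cds_segment_len = 90,
                       homolog_category_probs = c(I = 0.3, II = 0.4, III = 0.3)) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  cfg <- as.list(environment())
  cfg$replicates <- rep(replicates, length.out = length(tissues))
  stopifnot(
    n_genes >= 1, n_mirnas >= 1, mirna_length >= 15,
    abs(sum(isoform_count_probs) - 1) < 1e-8,
    abs(sum(homolog_category_probs) - 1) < 1e-8,
    frac_te_mirna >= 0, frac_te_mirna <= 1,
    frac_genes_targeted >= 0, frac_genes_targeted <= 1,
    frac_sites_distorted >= 0, frac_sites_distorted <= 1,
    repression_strength >= 0, repression_strength <= 1,
    nb_dispersion > 0, mu_high > mu_low, mu_low > 0, mu_background > 0,
    frac_background >= 0, frac_background < 1,
    n_cds_segments >= 3, n_modules >= 1
  )
  if (mirna_length + 2 > cds_segment_len ||
      mirna_length + 2 > utr5_len || mirna_length + 2 > utr3_len) {
    abort("planted site longer than the shortest segment; enlarge segments.")
  }
  structure(cfg, class = "sim_config")
}

random_rna <- function(n_seq, len, first_base = NULL) {
  bases <- c("A", "C", "G", "U")
  vapply(seq_len(n_seq), function(i) {
    s <- sample(bases, len, replace = TRUE)
    if (!is.null(first_base)) s[1] <- first_base
    paste(s, collapse = "")
  }, character(1))
}

GU_PARTNER <- c(G = "U", U = "G", A = NA, C = NA)

#' Plant a miRNA binding site into a transcript sequence
#'
#' Writes the reverse complement of the miRNA into the sequence at `position`
#' (0-based), applying the requested distortions, and returns the analytic
#' penalty score of the resulting duplex under the mispair penalty rules.
#'
#' @param sequence Host RNA sequence.
#' @param mirna_sequence miRNA sequence, 5'->3'.
#' @param position 0-based start of the site in `sequence`.
#' @param distortions A list of distortions, each
#'   `list(type = "gu"|"mismatch"|"bulge"|"gap", mirna_pos = p)` with p
#'   counted from the miRNA 5' end. At most one bulge/gap.
#' @return A list with `sequence` (modified host), `site` (the planted
#'   site), `length` (site length; the miRNA length +1 for a bulge, -1 for a
#'   gap) and `expected_score`.
#' @export
plant_site <- function(sequence, mirna_sequence, position, distortions = list()) {
  q <- normalize_rna(mirna_sequence)
  m <- nchar(q)
  qb <- strsplit(q, "")[[1]]
  site <- strsplit(rna_reverse_complement(q), "")[[1]] # site[j] pairs miRNA m-j+1
  score <- 0
  n_indel <- sum(vapply(distortions, function(d) d$type %in% c("bulge", "gap"),
                        logical(1)))
  if (n_indel > 1) abort("at most one bulge or gap per site.")
  # substitutions first: an indel shifts site indices, so it is applied last
  is_indel <- vapply(distortions, function(d) d$type %in% c("bulge", "gap"),
                     logical(1))
  distortions <- c(distortions[!is_indel], distortions[is_indel])
  for (d in distortions) {
    p <- d$mirna_pos
    j <- m - p + 1 # site index pairing miRNA position p
    if (d$type == "gu") {
      if (p < 1 || p > m) abort("distortion position outside the miRNA.")
      partner <- GU_PARTNER[[qb[p]]]
      if (is.na(partner)) {
        abort(paste0("G:U not possible at miRNA position ", p,
                     " (base ", qb[p], ")"))
      }
      site[j] <- partner
      score <- score + PENALTY_GU * position_weight(p)
    } else if (d$type == "mismatch") {
      if (p < 1 || p > m) abort("distortion position outside the miRNA.")
      site[j] <- qb[p] # identical bases never pair
      score <- score + PENALTY_MISMATCH * position_weight(p)
    } else if (d$type == "bulge") {
      if (p < 1 || p > m - 1) abort("bulge position must be in 1..m-1.")
      # extra target base between the pairs of miRNA positions p and p+1;
      # doubling uses the 5'-side neighbour p
      avoid <- c(RNA_COMPLEMENT[qb[p]], RNA_COMPLEMENT[qb[p + 1]],
                 GU_PARTNER[[qb[p]]], GU_PARTNER[[qb[p + 1]]])
      cand <- setdiff(c("A", "C", "G", "U"), avoid[!is.na(avoid)])
      if (length(cand) == 0) {
        # every base pairs with a flank somehow; avoid at least WC pairing
        cand <- setdiff(c("A", "C", "G", "U"),
                        c(RNA_COMPLEMENT[qb[p]], RNA_COMPLEMENT[qb[p + 1]]))
      }
      ins <- cand[1]
      site <- append(site, ins, after = m - p)
      score <- score + PENALTY_INDEL * position_weight(p)
    } else if (d$type == "gap") {
      if (p < 2 || p > m - 1) abort("gap position must be in 2..m-1.")
      site <- site[-j]
      score <- score + PENALTY_INDEL * position_weight(p)
    } else {
      abort(paste0("unknown distortion type: ", d$type))
    }
  }
  site_str <- paste(site, collapse = "")
  L <- nchar(sequence)
  if (position < 0 || position + m > L) {
    abort("site does not fit at the requested position.")
  }
  out <- paste0(substr(sequence, 1, position), site_str,
                substr(sequence, position + m + 1, L))
  list(sequence = out, site = site_str, length = nchar(site_str),
       expected_score = score)
}

random_distortion <- function(m) {
  type <- sample(c("gu", "mismatch", "bulge", "gap"), 1)
  # keep single-distortion scores <= 2 and positions valid/internal
  p <- switch(type,
    gu = NA, # chosen later where the base allows it
    mismatch = sample(seq_len(m), 1),
    bulge = sample(seq_len(m - 1), 1),
    gap = sample(2:(m - 1), 1)
  )
  list(type = type, mirna_pos = p)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `mirnas`, `isoforms`,
#'   `premirna_intervals`, `te_intervals`, `mirna_counts`, `isoform_counts`,
#'   `design`, `feature_lengths`, `best_hits`, `truth` (list of tibbles:
#'   `targets`, `modules`, `homologs`, `te`) and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  bases <- c("A", "C", "G", "U")
  n_iso_choices <- seq_along(cfg$isoform_count_probs)

  ## ---- miRNAs, precursors, TE intervals -------------------------------
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  mirna_seq <- vapply(seq_len(cfg$n_mirnas), function(i) {
    first <- if (runif(1) < 0.5) "U" else sample(bases, 1)
    random_rna(1, cfg$mirna_length, first_base = first)
  }, character(1))
  te_related <- rep(FALSE, cfg$n_mirnas)
  te_related[sample(cfg$n_mirnas, round(cfg$frac_te_mirna * cfg$n_mirnas))] <- TRUE

  chroms <- paste0("chr", sample(1:8, cfg$n_mirnas, replace = TRUE))
  pre_start <- sample(1000:100000, cfg$n_mirnas)
  premirna <- tibble(
    chrom = chroms, start = pre_start, end = pre_start + 120L,
    name = sprintf("pre-%s", mirna_ids), strand = "+"
  )
  te_rows <- list()
  for (i in seq_len(cfg$n_mirnas)) {
    if (te_related[i]) {
      off <- sample(-80:80, 1)
      te_rows[[length(te_rows) + 1]] <- tibble(
        chrom = chroms[i], start = pre_start[i] + off,
        end = pre_start[i] + off + 150L,
        name = sprintf("TE_%03d", i), strand = "."
      )
    }
  }
  # background TEs well away from any precursor
  n_bg <- max(3, round(cfg$n_mirnas / 4))
  te_rows[[length(te_rows) + 1]] <- tibble(
    chrom = paste0("chr", sample(1:8, n_bg, replace = TRUE)),
    start = sample(200000:300000, n_bg), end = NA_integer_,
    name = sprintf("TE_bg%02d", seq_len(n_bg)), strand = "."
  ) |> mutate(end = .data$start + 400L)
  te_intervals <- list_rbind(te_rows)

  mirnas <- tibble(
    mirna_id = mirna_ids, sequence = mirna_seq,
    length = nchar(mirna_seq), is_te_related = te_related,
    premirna_id = premirna$name
  )

  ## ---- genes, isoforms, planted sites ---------------------------------
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  n_iso <- sample(n_iso_choices, cfg$n_genes, replace = TRUE,
                  prob = cfg$isoform_count_probs)
  background_gene <- rep(FALSE, cfg$n_genes)
  background_gene[sample(cfg$n_genes,
                         round(cfg$frac_background * cfg$n_genes))] <- TRUE
  module_gene_idx <- which(!background_gene)
  targeted_gene <- rep(FALSE, cfg$n_genes)
  targeted_gene[sample(module_gene_idx,
                       round(cfg$frac_genes_targeted *
                               length(module_gene_idx)))] <- TRUE

  iso_rows <- list()
  truth_targets <- list()
  nseg <- cfg$n_cds_segments
  for (g in seq_len(cfg$n_genes)) {
    utr5 <- random_rna(1, cfg$utr5_len)
    utr3 <- random_rna(1, cfg$utr3_len)
    segs <- as.list(random_rna(nseg, cfg$cds_segment_len))

    planted <- NULL
    if (targeted_gene[g]) {
      mi <- ((g - 1) %% cfg$n_mirnas) + 1
      multi <- n_iso[g] >= 2
      partial <- multi && runif(1) < cfg$frac_partial
      # partial targeting: site in the segment skipped by isoform 2
      seg_kind <- if (partial) "skip" else {
        sample(c("utr5", "cds", "utr3"), 1, prob = c(0.10, 0.75, 0.15))
      }
      distortions <- list()
      if (runif(1) < cfg$frac_sites_distorted) {
        d <- random_distortion(cfg$mirna_length)
        if (d$type == "gu") {
          qb <- strsplit(mirna_seq[mi], "")[[1]]
          ok <- which(qb %in% c("G", "U"))
          if (length(ok)) d$mirna_pos <- sample(ok, 1) else d <- NULL
        }
        if (!is.null(d)) distortions <- list(d)
      }
      host_len <- switch(seg_kind, utr5 = cfg$utr5_len, utr3 = cfg$utr3_len,
                         cfg$cds_segment_len)
      pos <- sample(0:(host_len - cfg$mirna_length - 1), 1)
      host <- switch(seg_kind,
                     utr5 = utr5, utr3 = utr3,
                     skip = segs[[2]], cds = segs[[1]])
      pl <- plant_site(host, mirna_seq[mi], pos, distortions)
      if (seg_kind == "utr5") utr5 <- pl$sequence
      else if (seg_kind == "utr3") utr3 <- pl$sequence
      else if (seg_kind == "skip") segs[[2]] <- pl$sequence
      else segs[[1]] <- pl$sequence
      planted <- list(mirna = mi, kind = seg_kind, pos = pos,
                      len = pl$length, score = pl$expected_score,
                      distorted = length(distortions) > 0)
    }

    # isoform k >= 2 skips internal CDS segment k (2, 3, ...)
    for (k in seq_len(n_iso[g])) {
      skipped <- if (k >= 2) k else 0L
      inc <- setdiff(seq_len(nseg), skipped)
      cds_seq <- paste(unlist(segs[inc]), collapse = "")
      seq_full <- paste0(utr5, cds_seq, utr3)
      l5 <- nchar(utr5); lc <- nchar(cds_seq); l3 <- nchar(utr3)
      iso_id <- sprintf("%s.%d", gene_ids[g], k)
      iso_rows[[length(iso_rows) + 1]] <- tibble(
        isoform_id = iso_id, gene_id = gene_ids[g], sequence = seq_full,
        length = l5 + lc + l3,
        utr5_start = 0L, utr5_end = l5, cds_start = l5, cds_end = l5 + lc,
        utr3_start = l5 + lc, utr3_end = l5 + lc + l3
      )
      if (!is.null(planted)) {
        has_site <- !(planted$kind == "skip" && skipped == 2L)
        if (has_site) {
          seg_offset <- switch(planted$kind,
            utr5 = 0L,
            cds = l5,
            skip = l5 + nchar(segs[[1]]),
            utr3 = l5 + lc
          )
          region <- switch(planted$kind, utr5 = "5UTR", utr3 = "3UTR", "CDS")
          truth_targets[[length(truth_targets) + 1]] <- tibble(
            mirna_id = mirna_ids[planted$mirna], isoform_id = iso_id,
            gene_id = gene_ids[g],
            start = seg_offset + planted$pos,
            end = seg_offset + planted$pos + planted$len,
            region = region, expected_score = planted$score,
            distorted = planted$distorted
          )
        }
      }
    }
  }
  isoforms <- list_rbind(iso_rows)
  truth_targets <- if (length(truth_targets)) list_rbind(truth_targets) else
    tibble(mirna_id = character(), isoform_id = character(),
           gene_id = character(), start = integer(), end = integer(),
           region = character(), expected_score = numeric(),
           distorted = logical())

  ## ---- module assignment and expression -------------------------------
  design <- tibble(
    tissue = rep(cfg$tissues, cfg$replicates)
  ) |>
    group_by(.data$tissue) |>
    mutate(sample_id = paste0(.data$tissue, "_", row_number())) |>
    ungroup() |>
    select("sample_id", "tissue")
  # keep samples in tissue order
  design <- design[order(match(design$tissue, cfg$tissues)), ]

  modules <- paste0("M", seq_len(cfg$n_modules))
  module_tissue <- cfg$tissues[((seq_len(cfg$n_modules) - 1) %% length(cfg$tissues)) + 1]
  gene_module <- integer(cfg$n_genes) # 0 = background (flat profile)
  gene_module[module_gene_idx] <-
    ((seq_along(module_gene_idx) - 1) %% cfg$n_modules) + 1

  multi <- setdiff(which(n_iso >= 2), which(background_gene))
  giddm_genes <- sample(multi, round(cfg$frac_giddm * length(multi)))

  iso_module <- integer(nrow(isoforms))
  for (i in seq_len(nrow(isoforms))) {
    g <- match(isoforms$gene_id[i], gene_ids)
    k <- as.integer(sub(".*\\.", "", isoforms$isoform_id[i]))
    mod <- gene_module[g]
    if (mod > 0 && g %in% giddm_genes && k >= 2 && cfg$n_modules >= 2) {
      mod <- (gene_module[g] %% cfg$n_modules) + 1
    }
    iso_module[i] <- mod
  }

  profile_of_module <- function(mod) {
    if (mod == 0) return(rep(cfg$mu_background, length(cfg$tissues)))
    mu <- rep(cfg$mu_low, length(cfg$tissues))
    mu[match(module_tissue[mod], cfg$tissues)] <- cfg$mu_high
    mu
  }

  targeted_iso <- isoforms$isoform_id %in% truth_targets$isoform_id
  iso_mu <- matrix(0, nrow(isoforms), length(cfg$tissues),
                   dimnames = list(isoforms$isoform_id, cfg$tissues))
  size_factor <- exp(rnorm(nrow(isoforms), 0, 0.2))
  for (i in seq_len(nrow(isoforms))) {
    mu <- profile_of_module(iso_module[i]) * size_factor[i]
    if (targeted_iso[i]) mu <- mu * cfg$targeted_boost
    iso_mu[i, ] <- mu
  }

  nb_size <- 1 / cfg$nb_dispersion
  draw_counts <- function(mu_mat) {
    out <- matrix(0L, nrow(mu_mat), nrow(design),
                  dimnames = list(rownames(mu_mat), design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- mu_mat[, design$tissue[j]]
      out[, j] <- rnbinom(nrow(mu_mat), mu = mu, size = nb_size)
    }
    out
  }
  isoform_counts <- draw_counts(iso_mu)

  # miRNA mean profiles: anti-correlated with their targets' tissue profile
  mirna_mu <- matrix(0, cfg$n_mirnas, length(cfg$tissues),
                     dimnames = list(mirna_ids, cfg$tissues))
  for (i in seq_len(cfg$n_mirnas)) {
    tg <- truth_targets$isoform_id[truth_targets$mirna_id == mirna_ids[i]]
    if (length(tg)) {
      target_prof <- colMeans(iso_mu[tg, , drop = FALSE])
      anti <- max(target_prof) + min(target_prof) - target_prof
      flat <- rep(mean(target_prof), length(target_prof))
      mu <- cfg$repression_strength * anti +
        (1 - cfg$repression_strength) * flat
    } else {
      mu <- profile_of_module(sample.int(cfg$n_modules, 1)) *
        exp(rnorm(1, 0, 0.2))
    }
    mirna_mu[i, ] <- mu
  }
  mirna_counts <- draw_counts(mirna_mu)

  ## ---- homolog categories ---------------------------------------------
  species <- c("speciesA", "speciesB")
  hit_rows <- list()
  hom_rows <- list()
  for (g in which(n_iso >= 2)) {
    iso_of_g <- isoforms$isoform_id[isoforms$gene_id == gene_ids[g]]
    for (sp in species) {
      cat_g <- sample(names(cfg$homolog_category_probs), 1,
                      prob = cfg$homolog_category_probs)
      sp_gene <- paste0(sp, "_G", g)
      hits <- switch(cat_g,
        II = tibble(isoform_id = iso_of_g, hit_gene = sp_gene,
                    hit_isoform = paste0(sp_gene, ".1")),
        III = tibble(isoform_id = iso_of_g, hit_gene = sp_gene,
                     hit_isoform = paste0(sp_gene, ".", seq_along(iso_of_g))),
        I = tibble(isoform_id = iso_of_g,
                   hit_gene = paste0(sp_gene, letters[seq_along(iso_of_g)]),
                   hit_isoform = paste0(sp_gene, letters[seq_along(iso_of_g)], ".1"))
      )
      hits$species <- sp
      hit_rows[[length(hit_rows) + 1]] <- hits
      hom_rows[[length(hom_rows) + 1]] <- tibble(
        gene_id = gene_ids[g], species = sp, category = cat_g
      )
    }
  }
  best_hits <- if (length(hit_rows)) list_rbind(hit_rows) else
    tibble(isoform_id = character(), hit_gene = character(),
           hit_isoform = character(), species = character())
  truth_homologs <- if (length(hom_rows)) list_rbind(hom_rows) else
    tibble(gene_id = character(), species = character(), category = character())

  structure(list(
    mirnas = mirnas,
    isoforms = isoforms,
    premirna_intervals = premirna,
    te_intervals = te_intervals,
    mirna_counts = matrix_to_expr(mirna_counts, "feature_id"),
    isoform_counts = matrix_to_expr(isoform_counts, "feature_id"),
    design = design,
    feature_lengths = tibble(feature_id = isoforms$isoform_id,
                             length = isoforms$length),
    best_hits = best_hits,
    truth = list(
      targets = truth_targets,
      modules = tibble(
        isoform_id = isoforms$isoform_id,
        module = ifelse(iso_module == 0, "background", modules[pmax(iso_module, 1)]),
        tissue = ifelse(iso_module == 0, NA_character_,
                        module_tissue[pmax(iso_module, 1)])),
      homologs = truth_homologs,
      te = select(mirnas, "mirna_id", "is_te_related"),
      gene_targeted = tibble(gene_id = gene_ids, targeted = targeted_gene)
    ),
    config = cfg
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic miRNA/isoform dataset (seed", x$config$seed, ")\n")
  cat("  miRNAs   :", nrow(x$mirnas), "\n")
  cat("  isoforms :", nrow(x$isoforms), "genes:",
      n_distinct(x$isoforms$gene_id), "\n")
  cat("  samples  :", nrow(x$design), "in", n_distinct(x$design$tissue),
      "tissues\n")
  cat("  planted sites:", nrow(x$truth$targets), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' FASTA for sequences, GFF3 for transcript models, BED for precursor and TE
#' intervals, TSV for counts, design, best hits and truth tables — so the
#' pipeline consumes synthetic data through the same readers as real data.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_fasta(tibble(id = ds$mirnas$mirna_id, sequence = ds$mirnas$sequence),
              fp("mirnas.fa"))
  write_fasta(tibble(id = ds$isoforms$isoform_id,
                     sequence = ds$isoforms$sequence), fp("isoforms.fa"))
  writeLines(sim_gff_lines(ds$isoforms), fp("isoforms.gff3"))
  write_bed_intervals(ds$premirna_intervals, fp("premirna.bed"))
  write_bed_intervals(ds$te_intervals, fp("te.bed"))
  readr::write_tsv(ds$mirna_counts, fp("mirna_counts.tsv"))
  readr::write_tsv(ds$isoform_counts, fp("isoform_counts.tsv"))
  readr::write_tsv(ds$design, fp("design.tsv"))
  readr::write_tsv(ds$best_hits, fp("best_hits.tsv"))
  for (nm in names(ds$truth)) {
    readr::write_tsv(ds$truth[[nm]], fp(paste0("truth_", nm, ".tsv")))
  }
  invisible(dir)
}

sim_gff_lines <- function(isoforms) {
  lines <- c("##gff-version 3")
  for (g in unique(isoforms$gene_id)) {
    iso <- isoforms[isoforms$gene_id == g, , drop = FALSE]
    lines <- c(lines, paste(g, "sim", "gene", 1, max(iso$length), ".", "+",
                            ".", paste0("ID=", g), sep = "\t"))
    for (i in seq_len(nrow(iso))) {
      id <- iso$isoform_id[i]
      seg <- function(type, s, e) {
        if (e > s) paste(g, "sim", type, s + 1, e, ".", "+", ".",
                         paste0("ID=", id, ":", type, ";Parent=", id),
                         sep = "\t") else NULL
      }
      lines <- c(
        lines,
        paste(g, "sim", "mRNA", 1, iso$length[i], ".", "+", ".",
              paste0("ID=", id, ";Parent=", g), sep = "\t"),
        seg("five_prime_UTR", iso$utr5_start[i], iso$utr5_end[i]),
        seg("CDS", iso$cds_start[i], iso$cds_end[i]),
        seg("three_prime_UTR", iso$utr3_start[i], iso$utr3_end[i])
      )
    }
  }
  lines
}
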