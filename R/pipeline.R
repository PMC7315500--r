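# Orchestration: run every stage on file inputs with one configuration
# object, write per-stage TSVs plus a JSON manifest. The demo wrapper
# generates a seeded synthetic dataset and runs the full pipeline on it.

#' Pipeline configuration
#'
#' Collects input paths and every threshold the stages use. Defaults equal
#' the thresholds the analysis is defined with: small-RNA length bounds
#' 18-29, FDR < 0.05, |log2FC| > 1, mean FPKM > 0.1, C.V. > 2, penalty-score
#' cutoff 3, soft power 6, minimum module size 600, merge threshold 0.5, hub
#' quota 150.
#'
#' @param mirna_fasta,isoform_fasta,isoform_gff,premirna_bed,te_bed,
#'   mirna_counts,isoform_counts,design,best_hits Input file paths
#'   (`best_hits` optional, NA to skip homolog categories).
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest (stages are deterministic).
#' @param score_cutoff,fdr_max,lfc_min,fpkm_min,cv_min,beta,min_module_size,
#'   merge_threshold,hub_n,presence_threshold Stage thresholds.
#' @param reference_tissue DE contrasts are every other tissue against this
#'   tissue (default: last tissue in the design).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fasta, isoform_fasta, isoform_gff,
                            premirna_bed, te_bed, mirna_counts,
                            isoform_counts, design, best_hits = NA,
                            out_dir, seed = 1,
                            score_cutoff = 3, fdr_max = 0.05, lfc_min = 1,
                            fpkm_min = 0.1, cv_min = 2, beta = 6,
                            min_module_size = 600, merge_threshold = 0.5,
                            hub_n = 150, presence_threshold = 0,
                            reference_tissue = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full miRNA-isoform pipeline
#'
#' Stages: miRNA catalogue (TPM, presence, TE annotation, DE) -> target
#' prediction -> isoform expression (FPKM, variability filter, DE) ->
#' co-expression network -> miRNA-target correlation and DEMTG tests ->
#' divergence statistics (GIDDM, hub enrichment, targeted-vs-untargeted,
#' homolog categories). Writes per-stage TSVs and `manifest.json` under
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list with the in-memory stage results and the manifest,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  inputs <- stage("read", {
    list(
      mirnas = read_fasta(config$mirna_fasta),
      isoform_seqs = read_fasta(config$isoform_fasta),
      tx = read_gff_transcripts(config$isoform_gff),
      premirna = read_bed_intervals(config$premirna_bed),
      te = read_bed_intervals(config$te_bed),
      mirna_counts = read_expression_tsv(config$mirna_counts),
      isoform_counts = read_expression_tsv(config$isoform_counts),
      design = read_design_tsv(config$design),
      best_hits = if (!is.na(config$best_hits))
        readr::read_tsv(config$best_hits, show_col_types = FALSE) else NULL
    )
  })
  design <- inputs$design
  tissues <- unique(design$tissue)
  ref <- config$reference_tissue %||% tissues[length(tissues)]
  isoforms <- inputs$tx |>
    inner_join(rename(inputs$isoform_seqs, isoform_id = "id"),
               by = "isoform_id")

  catalog <- stage("catalog", {
    tpm <- tpm_quantify(inputs$mirna_counts)
    pres <- tissue_presence(tpm, design, threshold = config$presence_threshold)
    pre_flags <- annotate_te_overlap(inputs$premirna, inputs$te)
    de <- list_rbind(map(setdiff(tissues, ref), function(tt) {
      mutate(de_mirna(inputs$mirna_counts, design, c(tt, ref),
                      fdr_max = config$fdr_max, lfc_min = config$lfc_min),
             contrast = paste0(tt, "_vs_", ref))
    }))
    list(tpm = tpm, presence = pres, te = pre_flags, de = de)
  })

  targets <- stage("targets", {
    predict_targets(
      rename(inputs$mirnas, mirna_id = "id"),
      isoforms, cutoff = config$score_cutoff
    )
  })

  expression <- stage("expression", {
    lens <- tibble(feature_id = isoforms$isoform_id, length = isoforms$length)
    fk <- fpkm(inputs$isoform_counts, lens)
    filt <- variability_filter(fk, design, mean_min = config$fpkm_min,
                               cv_min = config$cv_min)
    de <- list_rbind(map(setdiff(tissues, ref), function(tt) {
      mutate(de_features(inputs$isoform_counts, design, c(tt, ref),
                         fdr_max = config$fdr_max, lfc_min = config$lfc_min),
             contrast = paste0(tt, "_vs_", ref))
    }))
    list(fpkm = fk, filter = filt, de = de)
  })

  network <- stage("network", {
    kept <- filter(expression$fpkm,
                   .data$feature_id %in% expression$filter$retained)
    fit_coexpression(kept, design, beta = config$beta,
                     min_module_size = config$min_module_size,
                     merge_threshold = config$merge_threshold,
                     hub_n = config$hub_n)
  })

  integration <- stage("integration", {
    pairs <- distinct(targets$sites, .data$mirna_id,
                      feature_id = .data$isoform_id)
    cors <- target_correlations(pairs, catalog$tpm, expression$fpkm,
                                design, design)
    bins <- correlation_bin_distribution(cors$r)
    gene_map <- select(isoforms, "isoform_id", "gene_id")
    all_genes <- unique(gene_map$gene_id)
    target_map <- distinct(targets$sites, .data$mirna_id, .data$gene_id)
    demtg <- list_rbind(map(setdiff(tissues, ref), function(tt) {
      ctr <- paste0(tt, "_vs_", ref)
      de_g <- expression$de |>
        filter(.data$contrast == ctr, .data$de) |>
        left_join(gene_map, by = c(feature_id = "isoform_id")) |>
        pull("gene_id") |> unique()
      de_m <- catalog$de$feature_id[catalog$de$contrast == ctr & catalog$de$de]
      mutate(demtg_test(de_g, de_m, target_map, all_genes), contrast = ctr)
    }))
    list(correlations = cors, bins = bins, demtg = demtg)
  })

  divergence <- stage("divergence", {
    gene_map <- select(isoforms, "isoform_id", "gene_id")
    giddm <- find_giddm(network$assignment, gene_map, targets$sites)
    mods <- setdiff(unique(network$assignment$module), "grey")
    hub_enrich <- if (length(mods)) {
      list_rbind(map(mods, function(mm) {
        mutate(hub_target_enrichment(network, targets$sites, mm), module = mm)
      }))
    } else NULL
    tvu <- list_rbind(map(tissues, function(tt) {
      targeted_vs_untargeted(expression$fpkm, design, gene_map,
                             targets$sites, tt)
    }))
    hom <- if (!is.null(inputs$best_hits)) {
      list_rbind(map(unique(inputs$best_hits$species), function(sp) {
        mutate(homolog_category(
          gene_map, filter(inputs$best_hits, .data$species == sp) |>
            select(-"species")), species = sp)
      }))
    } else NULL
    list(giddm = giddm, hub_enrichment = hub_enrich,
         targeted_vs_untargeted = tvu, homolog_categories = hom)
  })

  stage("write", {
    readr::write_tsv(catalog$tpm, out("mirna_tpm.tsv"))
    readr::write_tsv(catalog$de, out("mirna_de.tsv"))
    readr::write_tsv(catalog$te, out("premirna_te.tsv"))
    readr::write_tsv(targets$sites, out("target_sites.tsv"))
    readr::write_tsv(targets$gene_summary, out("target_gene_summary.tsv"))
    readr::write_tsv(expression$filter$report, out("variability_filter.tsv"))
    readr::write_tsv(expression$de, out("isoform_de.tsv"))
    readr::write_tsv(tidy(network), out("modules.tsv"))
    if (!is.null(network$module_trait)) {
      readr::write_tsv(network$module_trait, out("module_trait.tsv"))
    }
    readr::write_tsv(integration$correlations, out("pair_correlations.tsv"))
    readr::write_tsv(integration$bins, out("correlation_bins.tsv"))
    readr::write_tsv(integration$demtg, out("demtg.tsv"))
    readr::write_tsv(divergence$giddm$per_gene, out("giddm.tsv"))
    if (!is.null(divergence$hub_enrichment)) {
      readr::write_tsv(divergence$hub_enrichment, out("hub_enrichment.tsv"))
    }
    readr::write_tsv(divergence$targeted_vs_untargeted,
                     out("targeted_vs_untargeted.tsv"))
    if (!is.null(divergence$homolog_categories)) {
      readr::write_tsv(divergence$homolog_categories,
                       out("homolog_categories.tsv"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirisonet")),
    seed = config$seed,
    thresholds = config[c("score_cutoff", "fdr_max", "lfc_min", "fpkm_min",
                          "cv_min", "beta", "min_module_size",
                          "merge_threshold", "hub_n", "presence_threshold")],
    reference_tissue = ref,
    rows = list(
      mirnas = nrow(inputs$mirnas),
      isoforms = nrow(isoforms),
      target_sites = nrow(targets$sites),
      retained_isoforms = length(expression$filter$retained),
      modules = n_distinct(network$assignment$module[
        network$assignment$module != "grey"]),
      de_mirna_calls = sum(catalog$de$de),
      de_isoform_calls = sum(expression$de$de),
      giddm = divergence$giddm$counts$n_giddm
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(catalog = catalog, targets = targets,
                 expression = expression, network = network,
                 integration = integration, divergence = divergence,
                 manifest = manifest))
}

#' One-command synthetic end-to-end demo
#'
#' Generates a seeded synthetic dataset, writes it to `dir/data`, and runs
#' the full pipeline on those files with test-scale network settings.
#'
#' @param seed RNG seed.
#' @param dir Working directory for data and results.
#' @param config Optional [sim_config()] overriding the default generator
#'   settings (its seed wins over `seed`).
#' @param min_module_size Test-scale module size floor (default 15).
#' @return The [run_pipeline()] result, invisibly.
#' @export
demo_pipeline <- function(seed = 1, dir = tempfile("mirisonet_demo"),
                          config = NULL, min_module_size = 15) {
  cfg <- config %||% sim_config(seed = seed)
  ds <- generate_dataset(cfg)
  data_dir <- file.path(dir, "data")
  write_sim_dataset(ds, data_dir)
  pc <- pipeline_config(
    mirna_fasta = file.path(data_dir, "mirnas.fa"),
    isoform_fasta = file.path(data_dir, "isoforms.fa"),
    isoform_gff = file.path(data_dir, "isoforms.gff3"),
    premirna_bed = file.path(data_dir, "premirna.bed"),
    te_bed = file.path(data_dir, "te.bed"),
    mirna_counts = file.path(data_dir, "mirna_counts.tsv"),
    isoform_counts = file.path(data_dir, "isoform_counts.tsv"),
    design = file.path(data_dir, "design.tsv"),
    best_hits = file.path(data_dir, "best_hits.tsv"),
    out_dir = file.path(dir, "results"),
    seed = cfg$seed,
    min_module_size = min_module_size
  )
  run_pipeline(pc)
}
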