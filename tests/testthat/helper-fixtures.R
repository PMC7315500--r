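# Shared fixtures. The full-scale synthetic run (default generator settings,
# complete pipeline) is expensive, so it is computed once per session and
# reused by the pipeline and acceptance tests.

DEMO_SEED <- 1

demo_cache <- new.env(parent = emptyenv())

get_demo <- function() {
  if (is.null(demo_cache$res)) {
    demo_cache$ds <- generate_dataset(sim_config(seed = DEMO_SEED))
    demo_cache$res <- suppressMessages(
      demo_pipeline(seed = DEMO_SEED, dir = file.path(tempdir(), "demo_run"))
    )
  }
  list(ds = demo_cache$ds, res = demo_cache$res)
}

# six-tissue single-replicate design for small hand-built matrices
tiny_design <- function(tissues = c("leaf", "petiole", "petal", "anther",
                                    "ucarpel", "pcarpel"), reps = 1) {
  d <- expand.grid(rep = seq_len(reps), tissue = tissues,
                   stringsAsFactors = FALSE)
  tibble::tibble(sample_id = paste0(d$tissue, "_", d$rep), tissue = d$tissue)
}

tiny_expr <- function(values, feature_ids, sample_ids) {
  m <- matrix(values, nrow = length(feature_ids), byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  mirisonet::matrix_to_expr(m)
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
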