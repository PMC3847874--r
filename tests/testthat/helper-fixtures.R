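# Shared fixture builders and a per-session cache for simulated studies.

toy_expression <- function(n_feat = 3, n_samp = 2, seed = 1,
                           features = sprintf("g%d", seq_len(n_feat)),
                           samples = sprintf("s%d", seq_len(n_samp))) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_feat * n_samp, mean = 7), n_feat, n_samp,
                dimnames = list(features, samples))
    expression_matrix(m, "toy")
  })
}

toy_network <- function(edges_df, B = 10) {
  edges_df$mi <- edges_df$mi %||% runif(nrow(edges_df), 0.1, 1)
  edges_df$support <- edges_df$support %||% B
  consensus_network(edges_df, B = B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cache so expensive simulated studies are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# The study conditions used for parameter-recovery checks: 5 TFs, 50 target
# genes, 200 samples per cohort, residual noise 0.2.
recovery_config <- function(seed) {
  cohort_config(n_samples = 200, n_tfs = 5, n_targets = 50, n_background = 200,
                n_signature = 20, regulon_size_range = c(5, 12),
                noise_sd = 0.2, group_shift = 1.0, seed = seed)
}

# Undirected pair keys for comparing inferred and planted edge sets.
undirected_keys <- function(a, b) unique(paste(pmin(a, b), pmax(a, b)))

# Published per-TF signature-coverage statistics (13 TFs: ranks, coverages,
# FDRs, prognostic effects), bundled as input data.
read_coverage_table <- function() {
  utils::read.delim(system.file("extdata", "tf_signature_coverage.tsv",
                                package = "upregnet", mustWork = TRUE),
                    colClasses = c(tf = "character", effect = "character"))
}
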