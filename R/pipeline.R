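#' Run the full upstream-regulator discovery pipeline
#'
#' Executes the complete analysis end to end: input loading (or synthetic
#' study generation), mutual-information network inference with bootstrap
#' consensus, regulatory-mode annotation, master regulator analysis,
#' stepwise-regression edge filtering with coverage re-ranking, prognostic
#' effect assignment across cohorts, and survival evaluation of the
#' selected TFs on the held-out cohort. All artifacts are written to
#' `out_dir` together with a manifest recording stage completion, seeds and
#' thresholds; with a fixed seed the result tables are byte-identical
#' across runs.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{synthetic}{Either `TRUE`/a list of [cohort_config()] arguments
#'       to simulate the study, or absent to read inputs from files.}
#'     \item{train_expression, test_expression, signature, tf_list,
#'       train_labels, test_survival}{Input file paths (file mode).}
#'     \item{B, alpha, epsilon, n_perm}{Network inference settings
#'       (defaults 25, 0.05, 0, 1000).}
#'     \item{fdr, k, slr_alpha}{MRA/SLR settings (defaults 0.05, 10, 0.05).}
#'     \item{universe}{Fisher universe: `"network"` (genes in the inferred
#'       network, default) or `"array"` (all genes on the expression
#'       matrix).}
#'     \item{evaluate}{Run survival evaluation of the selected TFs on the
#'       test cohort (default `TRUE`).}
#'   }
#' @return Invisibly, a list with the in-memory stage results
#'   (`network`, `mra`, `slr`, `effects`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop_upregnet("config must name 'out_dir'")
  seed <- as.integer(config$seed %||% 1L)
  B <- as.integer(config$B %||% 25L)
  alpha <- config$alpha %||% 0.05
  epsilon <- config$epsilon %||% 0
  n_perm <- as.integer(config$n_perm %||% 1000L)
  fdr_cut <- config$fdr %||% 0.05
  k <- as.integer(config$k %||% 10L)
  slr_alpha <- config$slr_alpha %||% 0.05
  evaluate <- isTRUE(config$evaluate %||% TRUE)
  synthetic <- !is.null(config$synthetic) && !isFALSE(config$synthetic)

  # Pre-flight: every required input must exist before any stage runs.
  if (!synthetic) {
    required <- c("train_expression", "test_expression", "signature", "tf_list",
                  "train_labels")
    if (evaluate) required <- c(required, "test_survival")
    for (key in required) {
      path <- config[[key]]
      if (is.null(path))
        stop_upregnet("config missing required input '", key, "'")
      if (!file.exists(path))
        stop_upregnet("input file for '", key, "' not found: ", path)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed,
                   thresholds = list(B = B, alpha = alpha, epsilon = epsilon,
                                     n_perm = n_perm, fdr = fdr_cut, k = k,
                                     slr_alpha = slr_alpha),
                   stages = list())
  results <- list()
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- paste0("failed: ", conditionMessage(e))
      flush_manifest()
      stop_upregnet("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- "completed"
    flush_manifest()
    res
  }

  inputs <- run_stage("load", function() {
    if (synthetic) {
      args <- if (is.list(config$synthetic)) config$synthetic else list()
      args$seed <- seed
      cfg <- do.call(cohort_config, args)
      study <- simulate_study(cfg)
      write_study(study, file.path(out_dir, "inputs"))
      list(train = study$cohorts[[1L]]$expr,
           test = study$cohorts[[2L]]$expr,
           sig = study$truth$signature,
           tf_ids = study$truth$tf_ids,
           train_labels = study$cohorts[[1L]]$labels,
           test_surv = study$cohorts[[2L]]$survival,
           truth = study$truth)
    } else {
      list(train = read_expression_matrix(config$train_expression, "train"),
           test = read_expression_matrix(config$test_expression, "test"),
           sig = read_signature(config$signature),
           tf_ids = readLines(config$tf_list),
           train_labels = read_group_labels(config$train_labels),
           test_surv = if (evaluate) read_survival(config$test_survival))
    }
  })

  results$network <- run_stage("infer", function() {
    net <- bootstrap_consensus(inputs$train, inputs$tf_ids, B = B,
                               alpha = alpha, epsilon = epsilon, seed = seed,
                               n_perm = n_perm)
    net <- annotate_modes(net, inputs$train)
    write_network(net, file.path(out_dir, "network.tsv"))
    net
  })

  results$mra <- run_stage("mra", function() {
    regulons <- extract_regulons(results$network)
    universe <- if (identical(config$universe %||% "network", "array"))
      feature_ids(inputs$train) else NULL
    rows <- mra_enrichment(regulons, inputs$sig, universe = universe)
    ranked <- rank_and_select(rows, fdr_cut = fdr_cut, k = k)
    write_ranked_table(ranked, file.path(out_dir, "mra_table.tsv"))
    list(regulons = regulons, table = ranked)
  })

  results$slr <- run_stage("slr", function() {
    slr <- slr_network(inputs$train, results$mra$table, results$mra$regulons,
                       inputs$sig, fdr_cut = fdr_cut, alpha = slr_alpha, k = k)
    writeLines(c("regulator\ttarget",
                 paste(slr$edges$regulator, slr$edges$target, sep = "\t")),
               file.path(out_dir, "slr_network.tsv"))
    write_ranked_table(slr$table, file.path(out_dir, "slr_table.tsv"))
    slr
  })

  results$effects <- run_stage("effect", function() {
    union_tfs <- union(selected_tfs(results$mra$table),
                       selected_tfs(results$slr$table))
    e <- results$network$edges
    sub <- e[e$regulator %in% union_tfs, c("regulator", "target")]
    eff <- cohort_consistency(sub, list(inputs$train, inputs$test), inputs$sig)
    utils::write.table(eff$effects, file.path(out_dir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eff
  })

  if (evaluate) {
    results$evaluation <- run_stage("evaluate", function() {
      markers <- selected_tfs(results$slr$table)
      pred <- classify_cohort(inputs$train, inputs$train_labels, inputs$test,
                              markers)
      write_group_labels(pred, file.path(out_dir, "predicted_labels.tsv"))
      lr <- logrank_test(inputs$test_surv, pred)
      writeLines(c("statistic\tvalue",
                   paste0("chi_square\t", fmt_num(lr$chi_square)),
                   paste0("p_value\t", fmt_num(lr$p_value))),
                 file.path(out_dir, "logrank.tsv"))
      list(markers = markers, predicted = pred, logrank = lr)
    })
  }

  results$manifest <- manifest
  invisible(results)
}

# Serialize a ranked MRA/SLR coverage table deterministically.
write_ranked_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tf\tregulon_size\toverlap\tp_value\tfdr\trank\tselected", con)
  if (nrow(tab))
    writeLines(paste(tab$tf, tab$regulon_size, tab$overlap, fmt_num(tab$p_value),
                     fmt_num(tab$fdr), ifelse(is.na(tab$rank), "NA", tab$rank),
                     ifelse(tab$selected, "1", "0"), sep = "\t"), con)
  invisible(path)
}
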