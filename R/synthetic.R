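# Synthetic two-cohort generator: a planted TF-target linear regulatory
# network, risk-classed signature genes differentially expressed by
# prognostic group, and group-dependent exponential disease-free-survival
# times. Desk-scale stand-in for a pair of microarray cohorts.

#' Configuration for the synthetic cohort generator
#'
#' @param n_samples Samples per cohort.
#' @param n_tfs Number of transcription factors.
#' @param n_targets Number of (non-TF) target genes.
#' @param n_background Number of unregulated background genes (independent
#'   noise). These make the gene universe realistically large relative to
#'   the signature - on a genome-wide array the signature is a tiny
#'   fraction of all genes, which is what gives regulon-signature overlaps
#'   their statistical leverage - and provide false-positive opportunities
#'   for the network inference.
#' @param n_signature Number of signature genes drawn from the regulated
#'   targets.
#' @param regulon_size_range Two integers: per-TF regulon size is drawn
#'   uniformly from this interval (must fit within `n_targets`).
#' @param noise_sd Residual noise SD of target expression (log2 units).
#' @param group_shift Good-vs-poor TF expression shift (log2 units); each
#'   TF receives +/- `group_shift / 2` by group.
#' @param hazard_good,hazard_poor Exponential event rates (events/month);
#'   `hazard_poor >= hazard_good`, with equality planting no prognostic
#'   difference (useful for null calibration).
#' @param censor_time Administrative censoring time (months).
#' @param tf_tf_prob Probability of a planted TF->TF edge (ordered pairs,
#'   acyclic), exercising higher-order regulatory structure.
#' @param baseline Baseline log2 expression (typical microarray midrange).
#' @param seed Integer seed; all draws derive deterministic sub-streams.
#' @return Object of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 100L, n_tfs = 8L, n_targets = 60L,
                          n_background = 240L, n_signature = 25L,
                          regulon_size_range = c(6L, 15L),
                          noise_sd = 0.3, group_shift = 1.0,
                          hazard_good = 0.01, hazard_poor = 0.04,
                          censor_time = 60, tf_tf_prob = 0.1,
                          baseline = 7.0, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_tfs = as.integer(n_tfs),
              n_targets = as.integer(n_targets),
              n_background = as.integer(n_background),
              n_signature = as.integer(n_signature),
              regulon_size_range = as.integer(regulon_size_range),
              noise_sd = noise_sd, group_shift = group_shift,
              hazard_good = hazard_good, hazard_poor = hazard_poor,
              censor_time = censor_time, tf_tf_prob = tf_tf_prob,
              baseline = baseline, seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 1L || n_tfs < 1L || n_targets < 1L || n_signature < 1L)
      stop_upregnet("all counts must be at least 1")
    if (n_background < 0L)
      stop_upregnet("n_background must be non-negative")
    if (length(regulon_size_range) != 2L ||
        regulon_size_range[1L] > regulon_size_range[2L])
      stop_upregnet("regulon_size_range must be an ordered pair")
    if (regulon_size_range[2L] > n_targets)
      stop_upregnet("infeasible regulon sizes: maximum exceeds n_targets")
    if (n_signature > n_targets)
      stop_upregnet("n_signature cannot exceed n_targets")
    if (hazard_good <= 0 || hazard_poor <= 0 || hazard_poor < hazard_good)
      stop_upregnet("hazards must be positive with hazard_poor >= hazard_good ",
                    "(equality plants no prognostic difference)")
    if (noise_sd < 0 || group_shift < 0 || censor_time < 0)
      stop_upregnet("noise_sd, group_shift and censor_time must be non-negative")
  })
  structure(cfg, class = "CohortConfig")
}

#' Generate the planted ground truth
#'
#' Draws a random acyclic TF-TF plus bipartite TF-target structure with
#' signed linear coefficients, selects signature genes among the regulated
#' targets, assigns risk classes so that low-risk genes are up-regulated in
#' the good-prognosis group (and high-risk genes down), and computes each
#' TF's planted prognostic effect from its coefficient signs and target
#' risk classes by the [assign_effect()] rule.
#'
#' @param config A [cohort_config()].
#' @return Object of class `GroundTruth`: `tf_ids`, `target_ids`, `edges`
#'   (data frame `tf`, `target`, `beta`), `shift_sign` (per-TF group-shift
#'   direction), `signature` ([gene_signature()] with `ordering_value` =
#'   planted differential-expression magnitude), `effects` (per-TF planted
#'   `"+"`/`"-"`, `NA` when the TF has no signature targets) and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withr::with_seed(derive_seed(config$seed, "truth"), {
    tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
    targets <- sprintf("G%03d", seq_len(config$n_targets))
    background <- if (config$n_background)
      sprintf("B%03d", seq_len(config$n_background)) else character(0)
    rbeta_signed <- function(k)
      stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
    edges <- list()
    for (tf in tfs) {
      size <- sample(seq(config$regulon_size_range[1L],
                         config$regulon_size_range[2L]), 1L)
      tg <- sample(targets, size)
      edges[[tf]] <- data.frame(tf = tf, target = tg, beta = rbeta_signed(size),
                                stringsAsFactors = FALSE)
    }
    if (config$n_tfs >= 2L) {
      for (i in seq_len(config$n_tfs - 1L)) for (j in seq(i + 1L, config$n_tfs)) {
        if (stats::runif(1) < config$tf_tf_prob)
          edges[[length(edges) + 1L]] <- data.frame(
            tf = tfs[i], target = tfs[j], beta = rbeta_signed(1L),
            stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, edges)
    rownames(edges) <- NULL
    shift_sign <- stats::setNames(sample(c(-1, 1), config$n_tfs, replace = TRUE),
                                  tfs)
    # Good-minus-poor expected expression difference, propagated through the
    # acyclic TF-TF layer: delta_tf = s_tf * shift + sum(beta * delta_parent).
    delta <- stats::setNames(shift_sign * config$group_shift, tfs)
    for (j in tfs) {
      inc <- edges[edges$target == j, , drop = FALSE]
      if (nrow(inc)) delta[j] <- delta[j] + sum(inc$beta * delta[inc$tf])
    }
    tdelta <- stats::setNames(numeric(length(targets)), targets)
    for (g in targets) {
      inc <- edges[edges$target == g, , drop = FALSE]
      if (nrow(inc)) tdelta[g] <- sum(inc$beta * delta[inc$tf])
    }
    eligible <- names(tdelta)[abs(tdelta) > 1e-8]
    if (length(eligible) < config$n_signature)
      stop_upregnet("not enough regulated targets for the requested signature ",
                    "size (", length(eligible), " < ", config$n_signature, ")")
    sig_genes <- sort(sample(eligible, config$n_signature))
    sig <- gene_signature(sig_genes,
                          ifelse(tdelta[sig_genes] > 0, "low", "high"),
                          abs(tdelta[sig_genes]))
    effects <- stats::setNames(rep(NA_character_, length(tfs)), tfs)
    for (tf in tfs) {
      sub <- edges[edges$tf == tf & edges$target %in% sig_genes, , drop = FALSE]
      if (!nrow(sub)) next
      effects[tf] <- assign_effect(
        sig$risk_class[match(sub$target, sig$gene)],
        ifelse(sub$beta > 0, "activation", "repression"))
    }
    structure(list(tf_ids = tfs, target_ids = targets,
                   background_ids = background, edges = edges,
                   shift_sign = shift_sign, signature = sig,
                   effects = effects, config = config),
              class = "GroundTruth")
  })
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d TFs, %d targets, %d planted edges, %d signature genes\n",
              length(x$tf_ids), length(x$target_ids), nrow(x$edges),
              nrow(x$signature)))
  invisible(x)
}

#' Simulate one cohort's expression and group labels
#'
#' TF expression is Normal(baseline, 1) plus +/- `group_shift / 2` by
#' prognostic group (a TF targeted by another TF additionally inherits
#' `beta * (parent - baseline)`); each target gene is
#' `baseline + sum(beta * (TF - baseline)) + Normal(0, noise_sd)`. Distinct
#' cohort labels draw independent noise from deterministic sub-streams of
#' the configured seed.
#'
#' @param truth A [generate_truth()] result.
#' @param config A [cohort_config()].
#' @param cohort_label Cohort tag; also keys the random sub-stream.
#' @return List with `expr` ([expression_matrix()]) and `labels` (named
#'   `good`/`poor` vector).
#' @export
simulate_expression <- function(truth, config, cohort_label = "cohort") {
  stopifnot(inherits(truth, "GroundTruth"), inherits(config, "CohortConfig"))
  withr::with_seed(derive_seed(config$seed, paste0("expr:", cohort_label)), {
    n <- config$n_samples
    samples <- sprintf("%s_S%03d", cohort_label, seq_len(n))
    groups <- sample(c("good", "poor"), n, replace = TRUE)
    if (length(unique(groups)) < 2L && n >= 2L)
      groups[1L] <- setdiff(c("good", "poor"), groups[2L])
    gsign <- ifelse(groups == "good", 1, -1)
    feats <- c(truth$tf_ids, truth$target_ids, truth$background_ids)
    vals <- matrix(NA_real_, length(feats), n,
                   dimnames = list(feats, samples))
    for (tf in truth$tf_ids) {
      row <- config$baseline +
        truth$shift_sign[tf] * gsign * config$group_shift / 2 +
        stats::rnorm(n)
      inc <- truth$edges[truth$edges$target == tf, , drop = FALSE]
      for (i in seq_len(nrow(inc)))
        row <- row + inc$beta[i] * (vals[inc$tf[i], ] - config$baseline)
      vals[tf, ] <- row
    }
    for (g in truth$target_ids) {
      inc <- truth$edges[truth$edges$target == g, , drop = FALSE]
      row <- config$baseline + stats::rnorm(n, 0, config$noise_sd)
      for (i in seq_len(nrow(inc)))
        row <- row + inc$beta[i] * (vals[inc$tf[i], ] - config$baseline)
      vals[g, ] <- row
    }
    for (b in truth$background_ids)
      vals[b, ] <- config$baseline + stats::rnorm(n)
    list(expr = expression_matrix(vals, cohort_label),
         labels = stats::setNames(groups, samples))
  })
}

#' Simulate disease-free survival for labeled samples
#'
#' Event times are exponential with the group's hazard, administratively
#' censored at `censor_time`; `event = 0` iff censored.
#'
#' @param labels Named `good`/`poor` vector.
#' @param config A [cohort_config()].
#' @param stream_key String keying the random sub-stream (use the cohort
#'   label to make cohorts independent).
#' @return A [survival_table()].
#' @export
simulate_survival <- function(labels, config, stream_key = "surv") {
  stopifnot(inherits(config, "CohortConfig"))
  if (!length(labels)) stop_upregnet("labels must be non-empty")
  validate_group_labels(labels)
  withr::with_seed(derive_seed(config$seed, paste0("surv:", stream_key)), {
    rate <- ifelse(labels == "poor", config$hazard_poor, config$hazard_good)
    raw <- stats::rexp(length(labels), rate)
    survival_table(names(labels), pmin(raw, config$censor_time),
                   as.integer(raw <= config$censor_time))
  })
}

#' Simulate a complete two-cohort study
#'
#' Generates the ground truth once and simulates expression, group labels
#' and survival for each requested cohort with independent noise.
#'
#' @param config A [cohort_config()].
#' @param cohort_labels Character vector of cohort tags.
#' @return List with `truth` and `cohorts` (per cohort: `expr`, `labels`,
#'   `survival`).
#' @export
simulate_study <- function(config, cohort_labels = c("discovery", "validation")) {
  truth <- generate_truth(config)
  cohorts <- lapply(cohort_labels, function(lbl) {
    sim <- simulate_expression(truth, config, lbl)
    list(expr = sim$expr, labels = sim$labels,
         survival = simulate_survival(sim$labels, config, stream_key = lbl))
  })
  names(cohorts) <- cohort_labels
  list(truth = truth, cohorts = cohorts)
}

#' Write a simulated study to disk
#'
#' Writes per-cohort expression, labels and survival TSVs plus the
#' signature and planted truth edge list into a directory.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signature(study$truth$signature, file.path(dir, "signature.tsv"))
  edges <- study$truth$edges
  writeLines(c("tf\ttarget\tbeta",
               paste(edges$tf, edges$target, fmt_num(edges$beta), sep = "\t")),
             file.path(dir, "truth_edges.tsv"))
  writeLines(study$truth$tf_ids, file.path(dir, "tf_list.txt"))
  for (lbl in names(study$cohorts)) {
    co <- study$cohorts[[lbl]]
    write_expression_matrix(co$expr, file.path(dir, paste0("expr_", lbl, ".tsv")))
    write_group_labels(co$labels, file.path(dir, paste0("labels_", lbl, ".tsv")))
    write_survival(co$survival, file.path(dir, paste0("survival_", lbl, ".tsv")))
  }
  invisible(dir)
}
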