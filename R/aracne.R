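# ARACNE-style network inference: pairwise MI between TFs and all genes,
# significance thresholding, DPI pruning, bootstrap consensus voting, and
# probe-to-gene collapsing.

# Number of unordered candidate pairs with at least one TF endpoint.
n_candidate_pairs <- function(n_features, n_tfs) {
  n_tfs * (n_features - 1) - choose(n_tfs, 2)
}

# Pairwise MI for all unordered pairs with >= 1 TF endpoint.
# Returns data.frame(regulator, target, mi) with one row per pair; for a
# TF-TF pair the regulator slot holds the TF listed first in `tfs`.
mi_pair_table <- function(mat, tfs, n_bins = NULL) {
  feats <- rownames(mat)
  out_r <- character(0); out_t <- character(0); out_m <- numeric(0)
  done_tfs <- character(0)
  for (tf in tfs) {
    partners <- setdiff(feats, c(tf, done_tfs))
    x <- mat[tf, ]
    mis <- vapply(partners, function(p) estimate_mi(x, mat[p, ], n_bins), 0)
    out_r <- c(out_r, rep(tf, length(partners)))
    out_t <- c(out_t, partners)
    out_m <- c(out_m, mis)
    done_tfs <- c(done_tfs, tf)
  }
  data.frame(regulator = out_r, target = out_t, mi = out_m,
             stringsAsFactors = FALSE)
}

#' Data Processing Inequality pruning
#'
#' For every fully connected triangle of edges, the weakest edge is marked
#' for removal when its MI is strictly below `min` of the other two scaled
#' by `(1 - epsilon)`; all removals are applied simultaneously after
#' scanning every triangle, so the result is order-independent. Exact ties
#' are never removed. Edges are treated as unordered pairs.
#'
#' @param edges Data frame whose first two columns are the edge endpoints
#'   and which carries an `mi` column.
#' @param epsilon DPI tolerance in `[0, 1)`; 0 is strict pruning.
#' @return The input data frame restricted to surviving edges.
#' @export
apply_dpi <- function(edges, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1)
    stop_upregnet("epsilon must lie in [0, 1)")
  if (nrow(edges) < 3L) return(edges)
  u <- as.character(edges[[1L]]); v <- as.character(edges[[2L]])
  mi <- edges$mi
  nodes <- unique(c(u, v))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) numeric(0))
  for (i in seq_along(u)) {
    adj[[u[i]]][v[i]] <- mi[i]
    adj[[v[i]]][u[i]] <- mi[i]
  }
  drop <- vapply(seq_along(u), function(i) {
    nu <- adj[[u[i]]]; nv <- adj[[v[i]]]
    common <- intersect(names(nu), names(nv))
    length(common) > 0 &&
      any(mi[i] < pmin(nu[common], nv[common]) * (1 - epsilon))
  }, NA)
  edges[!drop, , drop = FALSE]
}

#' Infer a single significance-thresholded, DPI-pruned network
#'
#' Computes MI for every TF-gene pair (TF-TF pairs once), keeps pairs with
#' MI at or above the significance threshold, and prunes indirect edges by
#' the Data Processing Inequality.
#'
#' @param expr An [expression_matrix()].
#' @param tf_ids Candidate regulator identifiers; those absent from `expr`
#'   are dropped with a warning.
#' @param threshold An [mi_threshold()] object or a plain numeric MI cutoff.
#' @param epsilon DPI tolerance (default 0).
#' @return Data frame `regulator`, `target`, `mi` (one row per unordered
#'   pair; TF-TF pairs carry the first-listed TF as regulator).
#' @export
infer_single_network <- function(expr, tf_ids, threshold, epsilon = 0) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!length(tf_ids)) stop_upregnet("empty TF list")
  cutoff <- if (inherits(threshold, "MIThreshold")) threshold$threshold_mi
            else as.numeric(threshold)
  present <- intersect(tf_ids, feature_ids(expr))
  absent <- setdiff(tf_ids, present)
  if (length(absent))
    warning("dropping ", length(absent), " TF(s) absent from expression matrix: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  if (!length(present)) stop_upregnet("no TFs present in the expression matrix")
  pairs <- mi_pair_table(expr$values, present)
  pairs <- pairs[pairs$mi >= cutoff, , drop = FALSE]
  apply_dpi(pairs, epsilon)
}

#' Bootstrap consensus network
#'
#' Resamples the cohort's samples with replacement `B` times, infers a
#' thresholded DPI-pruned network per replicate (the MI significance
#' threshold is recalibrated on each replicate's resampled data), counts
#' per-edge support, and retains edges whose support is significantly
#' larger than chance under a Binomial(B, p-hat) null with the pooled edge
#' rate p-hat, Bonferroni-corrected over candidate pairs. The consensus MI
#' of a retained edge is its mean MI over supporting replicates.
#'
#' @inheritParams infer_single_network
#' @param B Number of bootstrap networks (default 100; tests and examples
#'   use less for speed).
#' @param alpha Family-wise level used both for the per-replicate MI
#'   threshold and the consensus vote.
#' @param seed Integer seed; every replicate derives its own sub-stream.
#' @param n_perm Permutations per replicate threshold calibration.
#' @param level Network level tag, `"gene"` or `"probe"`.
#' @return A [consensus_network()].
#' @export
bootstrap_consensus <- function(expr, tf_ids, B = 100L, alpha = 0.05,
                                epsilon = 0, seed = 1L, n_perm = 1000L,
                                level = c("gene", "probe")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  level <- match.arg(level)
  if (B < 2L) stop_upregnet("B must be at least 2")
  n <- ncol(expr$values)
  if (n < 8L) stop_upregnet("too few samples for bootstrap resampling (n < 8)")
  present <- intersect(tf_ids, feature_ids(expr))
  if (!length(present)) stop_upregnet("no TFs present in the expression matrix")
  if (length(present) < length(tf_ids))
    warning("dropping ", length(tf_ids) - length(present),
            " TF(s) absent from expression matrix")
  m <- n_candidate_pairs(nrow(expr$values), length(present))

  all_edges <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- withr::with_seed(derive_seed(seed, paste0("boot", b)),
                            sample.int(n, n, replace = TRUE))
    sub <- expr$values[, idx, drop = FALSE]
    # null built from the original data with the replicate's resampling
    # applied after permutation, so the duplicate-sample tie structure
    # (which itself inflates MI) is represented in the null
    thr <- mi_threshold(n, m, alpha = alpha, n_perm = n_perm,
                        seed = derive_seed(seed, paste0("thr", b)),
                        data = expr$values, resample_idx = idx)
    pairs <- mi_pair_table(sub, present)
    pairs <- pairs[pairs$mi >= thr$threshold_mi, , drop = FALSE]
    all_edges[[b]] <- apply_dpi(pairs, epsilon)
  }
  pooled <- do.call(rbind, all_edges)
  if (!nrow(pooled)) return(consensus_network(
    data.frame(regulator = character(0), target = character(0),
               mi = numeric(0), support = integer(0)), B = B, level = level))
  key <- paste(pooled$regulator, pooled$target, sep = "\r")
  support <- tapply(pooled$mi, key, length)
  mi_mean <- tapply(pooled$mi, key, mean)
  phat <- nrow(pooled) / (B * m)
  vote_p <- stats::pbinom(support - 1, B, phat, lower.tail = FALSE)
  keep <- names(support)[vote_p < alpha / m]
  if (!length(keep)) return(consensus_network(
    data.frame(regulator = character(0), target = character(0),
               mi = numeric(0), support = integer(0)), B = B, level = level))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  reg <- vapply(parts, `[`, "", 1L)
  tgt <- vapply(parts, `[`, "", 2L)
  edges <- data.frame(regulator = reg, target = tgt,
                      mi = as.numeric(mi_mean[keep]),
                      support = as.integer(support[keep]),
                      stringsAsFactors = FALSE)
  # TF-TF interactions are direction-less: materialize both orientations.
  both <- edges$target %in% present
  if (any(both)) {
    rev <- edges[both, ]
    tmp <- rev$regulator; rev$regulator <- rev$target; rev$target <- tmp
    edges <- rbind(edges, rev)
  }
  edges <- edges[order(edges$regulator, -edges$mi, edges$target), ]
  consensus_network(edges, B = B, level = level)
}

#' Collapse a probe-level network to the gene level
#'
#' Maps each probe-probe edge to its gene pair, drops edges that become
#' gene-level self-loops (two probes of one gene), and merges duplicate
#' gene pairs keeping the maximal (default) or mean MI and the maximal
#' support.
#'
#' @param net Probe-level [consensus_network()].
#' @param map Probe-to-gene map as from [read_probe_map()] (each probe maps
#'   to exactly one gene).
#' @param mi_merge `"max"` (default, most optimistic evidence) or `"mean"`.
#' @return Gene-level `ConsensusNetwork`.
#' @export
collapse_probes <- function(net, map, mi_merge = c("max", "mean")) {
  stopifnot(inherits(net, "ConsensusNetwork"))
  mi_merge <- match.arg(mi_merge)
  if (net$level != "probe")
    stop_upregnet("collapse_probes expects a probe-level network")
  e <- net$edges
  probes <- unique(c(e$regulator, e$target))
  missing <- setdiff(probes, map$probe)
  if (length(missing))
    stop_upregnet("probe(s) absent from probe-gene map: ",
                  paste(missing, collapse = ", "))
  g <- stats::setNames(map$gene, map$probe)
  rg <- unname(g[e$regulator]); tg <- unname(g[e$target])
  keep <- rg != tg
  e <- e[keep, , drop = FALSE]; rg <- rg[keep]; tg <- tg[keep]
  if (!nrow(e)) return(consensus_network(
    data.frame(regulator = character(0), target = character(0),
               mi = numeric(0), support = integer(0)), B = net$B, level = "gene"))
  key <- paste(rg, tg, sep = "\r")
  mi <- if (mi_merge == "max") tapply(e$mi, key, max) else tapply(e$mi, key, mean)
  support <- tapply(e$support, key, max)
  parts <- strsplit(names(mi), "\r", fixed = TRUE)
  edges <- data.frame(regulator = vapply(parts, `[`, "", 1L),
                      target = vapply(parts, `[`, "", 2L),
                      mi = as.numeric(mi), support = as.integer(support),
                      stringsAsFactors = FALSE)
  consensus_network(edges, B = net$B, level = "gene")
}
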