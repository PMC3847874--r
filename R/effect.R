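# Regulatory-mode annotation (sign of Spearman correlation) and per-TF
# prognostic effect assignment from the risk classes of its signature
# targets, with a cross-cohort consistency report.

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank vectors; ties receive average
#' ranks. Constant input is an error (the correlation is undefined, which
#' must be distinguishable from 0).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_upregnet("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop_upregnet("Spearman correlation needs n >= 3")
  if (min(x) == max(x) || min(y) == max(y))
    stop_upregnet("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Annotate edges with regulatory mode and Spearman correlation
#'
#' `mode = activation` when the TF-target Spearman correlation is positive,
#' `repression` when negative; an exactly zero correlation leaves the mode
#' `undetermined` and flags the edge.
#'
#' @param net A [consensus_network()] or an edge data frame with columns
#'   `regulator`, `target`.
#' @param expr [expression_matrix()] containing every edge endpoint.
#' @return Same shape as the input with `mode`, `rho` (and `flagged`)
#'   columns filled in.
#' @export
annotate_modes <- function(net, expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  is_net <- inherits(net, "ConsensusNetwork")
  e <- if (is_net) net$edges else as.data.frame(net)
  missing <- setdiff(unique(c(e$regulator, e$target)), feature_ids(expr))
  if (length(missing))
    stop_upregnet("edge endpoint(s) absent from expression matrix: ",
                  paste(missing, collapse = ", "))
  rho <- vapply(seq_len(nrow(e)), function(i)
    spearman_rho(expr$values[e$regulator[i], ], expr$values[e$target[i], ]), 0)
  e$rho <- rho
  e$mode <- ifelse(rho > 0, "activation",
                   ifelse(rho < 0, "repression", "undetermined"))
  e$flagged <- rho == 0
  if (is_net) {
    net$edges <- e
    net
  } else e
}

#' Assign the prognostic effect of a TF
#'
#' A TF is assigned a positive (`"+"`) prognostic effect when the number of
#' favorable regulations - activated low-risk plus repressed high-risk
#' signature targets - is strictly more than half of its determined-mode
#' signature targets; otherwise the effect is negative (`"-"`). Exactly
#' half is therefore `"-"`.
#'
#' @param risk_class Character vector (`"low"`/`"high"`), one per signature
#'   target of the TF.
#' @param mode Matching vector of regulatory modes (`"activation"`,
#'   `"repression"`, `"undetermined"`); undetermined targets are excluded.
#' @return `"+"` or `"-"`.
#' @export
assign_effect <- function(risk_class, mode) {
  if (length(risk_class) != length(mode))
    stop_upregnet("'risk_class' and 'mode' must have equal length")
  det <- mode %in% c("activation", "repression")
  if (!any(det)) stop_upregnet("no targets with a determined regulatory mode")
  risk_class <- risk_class[det]; mode <- mode[det]
  favorable <- sum((mode == "activation" & risk_class == "low") |
                   (mode == "repression" & risk_class == "high"))
  if (favorable > length(mode) / 2) "+" else "-"
}

#' Per-cohort TF effect table and cross-cohort concordance
#'
#' For each cohort, recomputes the Spearman correlation of every TF with
#' its signature targets on that cohort's expression, summarizes the mean
#' correlation against the TF's low-risk and high-risk targets, assigns
#' the prognostic effect, and reports the fraction of TFs whose effect sign
#' agrees across all cohorts.
#'
#' @param net Edge list (or `ConsensusNetwork`) restricted to the TFs of
#'   interest; only edges into signature genes are used.
#' @param expr_by_cohort List of [expression_matrix()] objects (>= 2 for a
#'   concordance verdict; a single cohort yields concordance 1).
#' @param sig A [gene_signature()].
#' @return List with `effects` (data frame: `tf`, `n_targets`,
#'   `n_activated_low`, `n_repressed_high`, `effect`, `mean_rho_low`,
#'   `mean_rho_high`, `cohort_label`) and `concordance` (fraction of TFs
#'   with identical effect in every cohort).
#' @export
cohort_consistency <- function(net, expr_by_cohort, sig) {
  stopifnot(inherits(sig, "Signature"))
  e0 <- if (inherits(net, "ConsensusNetwork")) net$edges else as.data.frame(net)
  e0 <- e0[e0$target %in% sig$gene, , drop = FALSE]
  risk <- stats::setNames(sig$risk_class, sig$gene)
  rows <- list()
  for (expr in expr_by_cohort) {
    e <- annotate_modes(e0, expr)
    for (tf in unique(e$regulator)) {
      sub <- e[e$regulator == tf, , drop = FALSE]
      if (!nrow(sub)) next
      rc <- risk[sub$target]
      det <- sub$mode %in% c("activation", "repression")
      if (!any(det)) {
        message("TF '", tf, "' has no determined-mode signature targets in ",
                expr$cohort_label, "; skipped")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf,
        n_targets = sum(det),
        n_activated_low = sum(sub$mode == "activation" & rc == "low"),
        n_repressed_high = sum(sub$mode == "repression" & rc == "high"),
        effect = assign_effect(rc, sub$mode),
        mean_rho_low = if (any(rc == "low")) mean(sub$rho[rc == "low"]) else NA_real_,
        mean_rho_high = if (any(rc == "high")) mean(sub$rho[rc == "high"]) else NA_real_,
        cohort_label = expr$cohort_label,
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows)
  if (is.null(effects))
    stop_upregnet("no TF has signature targets in any cohort")
  by_tf <- split(effects$effect, effects$tf)
  n_cohort <- length(expr_by_cohort)
  complete <- by_tf[lengths(by_tf) == n_cohort]
  concordance <- if (length(complete))
    mean(vapply(complete, function(v) length(unique(v)) == 1L, NA))
  else NA_real_
  list(effects = effects, concordance = concordance)
}
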