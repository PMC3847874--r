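# Master Regulator Analysis: regulon extraction, Fisher enrichment against
# the signature, BH FDR, signature-coverage competition ranking and top-k
# selection.

#' Extract regulons from a gene-level network
#'
#' One regulon per regulator with at least one target; the targets are the
#' regulator's out-neighbors.
#'
#' @param net A [consensus_network()] (gene level).
#' @return Named list of character vectors (`TF -> targets`).
#' @export
extract_regulons <- function(net) {
  stopifnot(inherits(net, "ConsensusNetwork"))
  if (net$level != "gene")
    stop_upregnet("regulons are extracted from gene-level networks")
  e <- net$edges
  if (!nrow(e)) return(stats::setNames(list(), character(0)))
  split(e$target, e$regulator)
}

# One-sided (enrichment) Fisher exact p: probability of drawing at least
# `overlap` signature genes when sampling `regulon_size` genes without
# replacement from a universe containing `sig_size` signature genes.
# Identical to fisher.test(alternative = "greater") on the 2x2 table.
fisher_enrichment_p <- function(overlap, regulon_size, sig_size, universe_size) {
  stats::phyper(overlap - 1, sig_size, universe_size - sig_size, regulon_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, elementwise `>=` the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_upregnet("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Master regulator enrichment table
#'
#' Tests each TF regulon for overlap with the prognostic signature by a
#' one-sided Fisher exact test on the 2x2 table (overlap, regulon minus
#' signature, signature minus regulon, rest of universe) and adjusts the
#' p-values by Benjamini-Hochberg across all analyzed TFs.
#'
#' @param regulons Named list as from [extract_regulons()].
#' @param sig A [gene_signature()]. Signature genes outside the universe are
#'   dropped with a warning.
#' @param universe Character vector of genes forming the test universe;
#'   defaults to all distinct genes (regulators and targets) in the
#'   regulons.
#' @return Data frame with columns `tf`, `regulon_size`, `overlap`,
#'   `p_value`, `fdr` (one row per regulon).
#' @export
mra_enrichment <- function(regulons, sig, universe = NULL) {
  stopifnot(inherits(sig, "Signature"))
  if (is.null(universe))
    universe <- unique(c(names(regulons), unlist(regulons, use.names = FALSE)))
  if (!length(universe)) stop_upregnet("empty gene universe")
  sig_genes <- sig$gene
  outside <- setdiff(sig_genes, universe)
  if (length(outside)) {
    warning(length(outside), " signature gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "")
    sig_genes <- setdiff(sig_genes, outside)
  }
  u <- length(universe)
  s <- length(sig_genes)
  rows <- lapply(names(regulons), function(tf) {
    targets <- intersect(unique(regulons[[tf]]), universe)
    ov <- length(intersect(targets, sig_genes))
    data.frame(tf = tf, regulon_size = length(targets), overlap = ov,
               p_value = fisher_enrichment_p(ov, length(targets), s, u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Rank significant TFs by signature coverage and select the top k
#'
#' TFs passing the FDR cutoff are ranked by signature coverage (overlap)
#' descending using competition ranking: tied TFs share the minimum rank of
#' their group and the next distinct coverage resumes after the whole
#' group. A TF is selected when its rank is `<= k`; because a tie group
#' shares one rank, a group that begins at rank `<= k` is selected in full
#' even if it extends past `k`. Reporting order within a tie group is
#' ascending FDR, then descending regulon size, then TF identifier.
#'
#' @param rows Data frame as from [mra_enrichment()] (columns `tf`,
#'   `regulon_size`, `overlap`, `fdr`).
#' @param fdr_cut FDR cutoff for eligibility (default 0.05).
#' @param k Selection size (default 10).
#' @return `rows` with added `rank` (NA for TFs failing the cutoff) and
#'   logical `selected`, sorted by rank then the tie-break keys, with
#'   non-significant TFs last.
#' @export
rank_and_select <- function(rows, fdr_cut = 0.05, k = 10L) {
  if (k < 1L) stop_upregnet("k must be at least 1")
  stopifnot(all(c("tf", "overlap", "fdr") %in% names(rows)))
  rows <- as.data.frame(rows)
  sig <- rows$fdr < fdr_cut
  rows$rank <- rep(NA_integer_, nrow(rows))
  ov <- rows$overlap[sig]
  rows$rank[sig] <- vapply(ov, function(o) 1L + sum(ov > o), 0L)
  rows$selected <- !is.na(rows$rank) & rows$rank <= k
  rsz <- if ("regulon_size" %in% names(rows)) rows$regulon_size else 0
  ord <- order(!sig, rows$rank, rows$fdr, -rsz, rows$tf)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Selected TFs of a ranked MRA table
#' @param rows Output of [rank_and_select()].
#' @return Character vector of selected TF identifiers.
#' @export
selected_tfs <- function(rows) rows$tf[rows$selected]

#' Union signature coverage of a TF set
#'
#' Number of distinct signature genes covered by the regulons of the given
#' TFs.
#'
#' @param regulons Named list as from [extract_regulons()].
#' @param sig A [gene_signature()].
#' @param tfs TF identifiers.
#' @return Integer count.
#' @export
coverage_union <- function(regulons, sig, tfs) {
  covered <- unique(unlist(regulons[intersect(tfs, names(regulons))],
                           use.names = FALSE))
  length(intersect(covered, sig$gene))
}

#' Union and intersection of two marker selections
#' @param a,b Character vectors of TF identifiers.
#' @return List with elements `union` and `intersection`.
#' @export
marker_set_ops <- function(a, b) {
  list(union = union(a, b), intersection = intersect(a, b))
}
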