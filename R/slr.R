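# Stepwise linear regression filtering of TF-target edges: each signature
# gene's log2 expression is modeled from its candidate upstream TFs, AIC
# stepwise selection keeps a minimal TF set, non-significant coefficients
# are pruned, and TF coverage is re-ranked on the filtered network.

#' AIC score for a least-squares fit
#'
#' `AIC = n * ln(RSS / n) + 2 * n_params`, with the additive constants of
#' the Gaussian likelihood dropped: only AIC differences matter for
#' selection, and this convention matches [stats::extractAIC()].
#'
#' @param rss Residual sum of squares (> 0; exactly 0 returns `-Inf` with a
#'   warning).
#' @param n Number of observations (must exceed `n_params`).
#' @param n_params Number of estimated mean parameters (intercept included).
#' @return Numeric AIC value.
#' @examples
#' aic_score(10, 20, 2)  # 20 * log(0.5) + 4
#' @export
aic_score <- function(rss, n, n_params) {
  if (n <= n_params) stop_upregnet("saturated model: n must exceed n_params")
  if (rss < 0) stop_upregnet("rss must be non-negative")
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * n_params
}

# Fit y ~ X[, sel] by OLS and package as a LinearFit.
linear_fit <- function(y, X, sel, target_gene = "") {
  df <- data.frame(.y = y, X[, sel, drop = FALSE], check.names = FALSE)
  fml <- if (length(sel))
    stats::as.formula(paste(".y ~", paste0("`", sel, "`", collapse = " + ")))
  else stats::as.formula(".y ~ 1")
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  co <- stats::coef(fit)
  pv <- stats::setNames(sm[, "Pr(>|t|)"], rownames(sm))
  rss <- sum(stats::residuals(fit)^2)
  structure(list(
    target_gene = target_gene,
    selected_tfs = sel,
    coefficients = co,
    coef_p_values = pv,
    rss = rss,
    aic = if (rss > 0) aic_score(rss, length(y), length(sel) + 1L) else -Inf,
    n = length(y),
    data = list(y = y, X = X)),
    class = "LinearFit")
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf("LinearFit '%s': %d TF(s) selected of n = %d (AIC %.3f)\n",
              x$target_gene, length(x$selected_tfs), x$n, x$aic))
  invisible(x)
}

#' Bidirectional stepwise AIC selection of upstream TFs
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' add-or-drop move with the largest AIC decrease and stops when no move
#' decreases AIC (the [stats::step()] algorithm). Exact duplicate candidate
#' columns are dropped (first kept) with a warning; when the candidate count
#' crowds the sample size (`n <= p + 2`) candidates are pre-screened by
#' absolute marginal correlation down to `n - 3`.
#'
#' @param y Numeric response vector (log2 expression of a signature gene).
#' @param candidates Named numeric matrix or data frame, one column per
#'   candidate TF (log2 expression, samples in rows).
#' @param target_gene Identifier recorded in the returned fit.
#' @return Object of class `LinearFit`: `target_gene`, `selected_tfs`,
#'   `coefficients`, `coef_p_values`, `rss`, `aic`, `n`.
#' @export
stepwise_select <- function(y, candidates, target_gene = "") {
  X <- as.matrix(candidates)
  if (is.null(colnames(X)) || any(!nzchar(colnames(X))))
    stop_upregnet("candidates must be named")
  if (nrow(X) != length(y)) stop_upregnet("response/candidate length mismatch")
  if (!ncol(X)) stop_upregnet("at least one candidate is required")
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("dropping duplicate candidate column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }
  n <- length(y)
  if (n <= ncol(X) + 2L) {
    keep_n <- max(1L, n - 3L)
    sc <- abs(apply(X, 2L, function(col)
      if (stats::sd(col) == 0) 0 else stats::cor(col, y)))
    X <- X[, order(-sc)[seq_len(keep_n)], drop = FALSE]
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  nm <- colnames(X)
  upper <- stats::as.formula(paste("~", paste0("`", nm, "`", collapse = " + ")))
  base <- stats::lm(.y ~ 1, data = df)
  sel_fit <- stats::step(base, scope = list(lower = ~1, upper = upper),
                         direction = "both", trace = 0)
  sel <- setdiff(all.vars(stats::formula(sel_fit)), ".y")
  linear_fit(y, X, sel, target_gene)
}

#' Prune non-significant coefficients from a stepwise fit
#'
#' Iteratively drops the TF with the largest coefficient p-value `>= alpha`
#' and refits, until every remaining coefficient has `p < alpha` or no TFs
#' remain. The TF p-values are two-sided t-tests on the OLS standard
#' errors; refitting is required because removal changes the remaining
#' p-values.
#'
#' @param fit A `LinearFit` from [stepwise_select()].
#' @param alpha Retention threshold (default 0.05).
#' @return A `LinearFit` whose TF coefficients all have `p < alpha`.
#' @export
prune_nonsignificant <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "LinearFit"))
  cur <- fit
  repeat {
    sel <- cur$selected_tfs
    if (!length(sel)) return(cur)
    pv <- vapply(sel, function(s) {
      p <- cur$coef_p_values[s]
      if (is.na(p)) p <- cur$coef_p_values[paste0("`", s, "`")]
      unname(p)
    }, 0)
    bad <- pv[is.na(pv) | pv >= alpha]
    if (!length(bad)) return(cur)
    worst <- names(bad)[which.max(ifelse(is.na(bad), Inf, bad))]
    cur <- linear_fit(cur$data$y, cur$data$X, setdiff(sel, worst),
                      cur$target_gene)
  }
}

#' SLR edge filtering and coverage re-ranking
#'
#' For each signature gene, the candidate explanatory TFs are the
#' MRA-significant TFs linked to it in the network; stepwise AIC selection
#' followed by coefficient pruning keeps only strong linear TF-target
#' relations. The surviving (TF, gene) pairs form the filtered network, TF
#' coverage is recounted as the number of signature genes retaining the TF,
#' and the TFs are re-ranked by [rank_and_select()].
#'
#' @param expr Gene-level [expression_matrix()].
#' @param mra_rows Data frame from [mra_enrichment()].
#' @param regulons Named list from [extract_regulons()].
#' @param sig A [gene_signature()].
#' @param fdr_cut MRA significance cutoff defining candidate TFs.
#' @param alpha Coefficient retention threshold for pruning.
#' @param k Selection size for the re-ranking.
#' @return List with `edges` (data frame `regulator`, `target`), `fits`
#'   (per-gene `LinearFit`s), `table` (re-ranked coverage table) and
#'   `skipped` (signature genes with no upstream candidate TFs).
#' @export
slr_network <- function(expr, mra_rows, regulons, sig, fdr_cut = 0.05,
                        alpha = 0.05, k = 10L) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(sig, "Signature"))
  sig_tf <- mra_rows$tf[mra_rows$fdr < fdr_cut]
  fits <- list()
  skipped <- character(0)
  kept <- list()
  for (g in sig$gene) {
    cands <- sig_tf[vapply(sig_tf, function(tf)
      g %in% regulons[[tf]], NA)]
    cands <- setdiff(cands, g)
    cands <- intersect(cands, feature_ids(expr))
    if (!length(cands) || !g %in% feature_ids(expr)) {
      skipped <- c(skipped, g)
      message("signature gene '", g, "' has no usable upstream TFs; skipped")
      next
    }
    X <- t(expr$values[cands, , drop = FALSE])
    fit <- stepwise_select(expr$values[g, ], X, target_gene = g)
    fit <- prune_nonsignificant(fit, alpha)
    fits[[g]] <- fit
    if (length(fit$selected_tfs))
      kept[[g]] <- data.frame(regulator = fit$selected_tfs, target = g,
                              stringsAsFactors = FALSE)
  }
  edges <- if (length(kept)) do.call(rbind, kept) else
    data.frame(regulator = character(0), target = character(0))
  rownames(edges) <- NULL
  cov <- table(factor(edges$regulator, levels = sig_tf))
  tab <- mra_rows[mra_rows$fdr < fdr_cut, , drop = FALSE]
  tab$overlap <- as.integer(cov[tab$tf])
  tab <- rank_and_select(tab, fdr_cut = fdr_cut, k = k)
  list(edges = edges, fits = fits, table = tab, skipped = skipped)
}
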