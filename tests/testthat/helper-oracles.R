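# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, brute force, direct formulas) and share
# no code with the package internals.

# Hypergeometric upper-tail enrichment p by direct choose() summation.
oracle_fisher_p <- function(overlap, regulon, sig, universe) {
  hi <- min(regulon, sig)
  if (overlap > hi) return(0)
  i <- seq(overlap, hi)
  sum(exp(lchoose(sig, i) + lchoose(universe - sig, regulon - i) -
          lchoose(universe, regulon)))
}

# Brute-force DPI: enumerate every node triple, test the removal rule on
# each edge of every complete triangle, apply all removals simultaneously.
oracle_dpi <- function(edges, epsilon = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  k <- key(edges[[1]], edges[[2]])
  mi <- setNames(edges$mi, k)
  nodes <- unique(c(edges[[1]], edges[[2]]))
  doomed <- character(0)
  if (length(nodes) >= 3) {
    trip <- utils::combn(nodes, 3)
    for (c_i in seq_len(ncol(trip))) {
      a <- trip[1, c_i]; b <- trip[2, c_i]; d <- trip[3, c_i]
      ks <- c(key(a, b), key(a, d), key(b, d))
      if (!all(ks %in% k)) next
      m <- mi[ks]
      for (e in 1:3)
        if (m[e] < min(m[-e]) * (1 - epsilon)) doomed <- c(doomed, ks[e])
    }
  }
  edges[!k %in% doomed, , drop = FALSE]
}

# Direct Benjamini-Hochberg step-up formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Log-rank chi-square by an explicit loop over distinct event times,
# accumulating hypergeometric observed-minus-expected and variance.
oracle_logrank_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Exhaustive best-subset AIC search (n * log(rss/n) + 2 * (k + 1)).
oracle_best_subset_aic <- function(y, X) {
  p <- ncol(X)
  n <- length(y)
  best <- n * log(sum(lm.fit(cbind(1, X[, 0]), y)$residuals^2) / n) + 2
  for (sz in seq_len(p)) {
    cmb <- utils::combn(p, sz)
    for (c_i in seq_len(ncol(cmb))) {
      idx <- cmb[, c_i]
      rss <- sum(stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)$residuals^2)
      aic <- n * log(rss / n) + 2 * (sz + 1)
      if (aic < best) best <- aic
    }
  }
  best
}
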