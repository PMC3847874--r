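#' Construct a consensus regulatory network
#'
#' TF->target edge list with mutual-information weight and bootstrap support,
#' optionally annotated with a regulatory mode (`activation`/`repression`,
#' from the sign of the TF-target Spearman correlation) and the correlation
#' itself. A TF-TF interaction, whose direction mutual information cannot
#' resolve, is stored as two directed rows so each TF appears in the other's
#' regulon.
#'
#' @param edges Data frame with columns `regulator`, `target`, `mi`,
#'   `support` and optionally `mode`, `rho`.
#' @param B Number of bootstrap networks the consensus was voted from.
#' @param level `"gene"` or `"probe"`.
#' @return Object of class `ConsensusNetwork`: list with elements `edges`,
#'   `B`, `level`.
#' @export
consensus_network <- function(edges, B, level = c("gene", "probe")) {
  level <- match.arg(level)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("regulator", "target", "mi", "support")
  if (!all(required %in% names(edges)))
    stop_upregnet("edges need columns: ", paste(required, collapse = ", "))
  if (!"mode" %in% names(edges)) edges$mode <- rep(NA_character_, nrow(edges))
  if (!"rho" %in% names(edges)) edges$rho <- rep(NA_real_, nrow(edges))
  edges <- edges[, c("regulator", "target", "mi", "support", "mode", "rho")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target))
    stop_upregnet("self-edges are not allowed")
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop_upregnet("duplicate (regulator, target) pair(s)")
  if (any(edges$mi < 0)) stop_upregnet("mi must be non-negative")
  if (any(edges$support < 0 | edges$support > B))
    stop_upregnet("support must lie in [0, B]")
  bad <- setdiff(unique(edges$mode[!is.na(edges$mode)]),
                 c("activation", "repression", "undetermined"))
  if (length(bad))
    stop_upregnet("unknown regulatory mode token(s): ", paste(bad, collapse = ", "))
  rownames(edges) <- NULL
  structure(list(edges = edges, B = as.integer(B), level = level),
            class = "ConsensusNetwork")
}

#' @export
print.ConsensusNetwork <- function(x, ...) {
  cat(sprintf("ConsensusNetwork (%s level): %d edges, %d regulators, B = %d\n",
              x$level, nrow(x$edges), length(unique(x$edges$regulator)), x$B))
  invisible(x)
}

#' Read / write a consensus network edge list
#'
#' TSV with header `regulator<TAB>target<TAB>mi<TAB>support<TAB>mode<TAB>rho`
#' (`mode` and `rho` may be `NA`). On write, edges are sorted by regulator
#' and descending mutual information.
#'
#' @param path File path.
#' @param B,level Passed to [consensus_network()] on read (the edge list file
#'   itself does not carry them).
#' @return [read_network()] returns a `ConsensusNetwork`.
#' @export
read_network <- function(path, B = 100L, level = "gene") {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("regulator", "target", "mi", "support") %in% names(df)))
    stop_upregnet("network file needs header: regulator, target, mi, support[, mode, rho]")
  edges <- data.frame(
    regulator = df$regulator, target = df$target,
    mi = as.numeric(df$mi), support = as.integer(df$support),
    mode = if ("mode" %in% names(df)) ifelse(df$mode == "NA", NA, df$mode) else NA_character_,
    rho = if ("rho" %in% names(df)) suppressWarnings(as.numeric(df$rho)) else NA_real_,
    stringsAsFactors = FALSE)
  consensus_network(edges, B = B, level = level)
}

#' @rdname read_network
#' @param net A `ConsensusNetwork`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ConsensusNetwork"))
  e <- net$edges[order(net$edges$regulator, -net$edges$mi, net$edges$target), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("regulator\ttarget\tmi\tsupport\tmode\trho", con)
  if (nrow(e))
    writeLines(paste(e$regulator, e$target, fmt_num(e$mi), e$support,
                     ifelse(is.na(e$mode), "NA", e$mode), fmt_num(e$rho),
                     sep = "\t"), con)
  invisible(path)
}
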