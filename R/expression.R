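#' Construct an expression matrix
#'
#' Container for log2 expression values, features (probes or genes) in rows
#' and samples in columns, tagged with a cohort label. Feature and sample
#' identifiers must be unique and every value finite; missing values are not
#' supported.
#'
#' @param values Numeric matrix of log2 expression, with rownames (feature
#'   identifiers) and colnames (sample identifiers).
#' @param cohort_label Free-text cohort tag.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `cohort_label`.
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(c("TP53", "MYC", "KRAS"), c("s1", "s2")))
#' expression_matrix(m, "toy")
#' @export
expression_matrix <- function(values, cohort_label = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_upregnet("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_upregnet("expression matrix needs feature rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop_upregnet("duplicate feature identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop_upregnet("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop_upregnet("expression values must all be finite (missing values are not supported)")
  structure(list(values = values, cohort_label = as.character(cohort_label)[1]),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d features x %d samples\n",
              x$cohort_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row whose first cell is ignored and whose remaining cells
#' are sample identifiers; each subsequent row is a feature identifier
#' followed by numeric log2 values. Ragged rows, duplicate identifiers and
#' non-numeric or missing cells are hard errors.
#'
#' @param path File path.
#' @param cohort_label Cohort tag to attach; defaults to the file name.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   cohort_label = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_upregnet("expression file needs a header and at least one feature row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  samples <- fields[[1L]][-1L]
  width <- length(fields[[1L]])
  rows <- fields[-1L]
  bad <- which(lengths(rows) != width)
  if (length(bad))
    stop_upregnet("ragged row(s) at line(s) ", paste(bad + 1L, collapse = ", "),
                  " (expected ", width, " fields)")
  ids <- vapply(rows, `[`, "", 1L)
  vals <- matrix(NA_real_, length(rows), length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    v <- suppressWarnings(as.numeric(cells))
    bad_j <- which(is.na(v))
    if (length(bad_j))
      stop_upregnet("non-numeric or missing value for feature '", ids[i],
                    "' (row ", i, "), sample '", samples[bad_j[1L]],
                    "' (column ", bad_j[1L], "): '", cells[bad_j[1L]], "'")
    vals[i, ] <- v
  }
  expression_matrix(vals, cohort_label)
}

#' Write an expression matrix to a tab-separated file
#'
#' Values are serialized in scientific notation with 12 significant digits so
#' that write-then-read round trips are stable well beyond test tolerance.
#'
#' @param expr An `ExpressionMatrix`.
#' @param path Output file path.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(expr$values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr$values)), function(i) {
    paste(c(rownames(expr$values)[i], fmt_num(expr$values[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Log2 expression ratio between prognostic groups
#'
#' Mean log2 expression of a gene in the poor-prognosis group minus the mean
#' in the good-prognosis group. Because the values are already log2, the
#' difference of group means is the log2 fold change.
#'
#' @param expr An `ExpressionMatrix`.
#' @param labels Group labels as returned by [read_group_labels()]: a named
#'   character vector (`sample -> "good"/"poor"`).
#' @param gene Feature identifier.
#' @return Numeric scalar, poor-minus-good mean log2 expression.
#' @export
log2_group_ratio <- function(expr, labels, gene) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  validate_group_labels(labels, expr)
  if (!gene %in% rownames(expr$values))
    stop_upregnet("gene '", gene, "' not present in the expression matrix")
  poor <- names(labels)[labels == "poor"]
  good <- names(labels)[labels == "good"]
  if (!length(poor) || !length(good))
    stop_upregnet("both prognostic groups must be non-empty")
  mean(expr$values[gene, poor]) - mean(expr$values[gene, good])
}
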