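#' Construct a prognostic gene signature
#'
#' An ordered list of marker genes partitioned into `low`- and `high`-risk
#' classes (genes up- and down-regulated, respectively, in the patient group
#' of better survival), optionally carrying an ordering value (magnitude of
#' differential expression) used by the signature-size sweep.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param risk_class Character vector, each `"low"` or `"high"`.
#' @param ordering_value Optional numeric vector for ranked prefix selection.
#' @return A data frame of class `Signature` with columns `gene`,
#'   `risk_class`, `ordering_value`.
#' @export
gene_signature <- function(gene, risk_class, ordering_value = NA_real_) {
  gene <- as.character(gene)
  risk_class <- as.character(risk_class)
  if (!length(gene)) stop_upregnet("no signature entries")
  if (length(risk_class) != length(gene))
    stop_upregnet("'gene' and 'risk_class' lengths differ")
  bad <- setdiff(unique(risk_class), c("low", "high"))
  if (length(bad))
    stop_upregnet("risk_class must be 'low' or 'high'; got: ",
                  paste(bad, collapse = ", "))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    stop_upregnet("duplicate signature gene(s): ", paste(dup, collapse = ", "))
  out <- data.frame(gene = gene, risk_class = risk_class,
                    ordering_value = as.numeric(rep_len(ordering_value, length(gene))),
                    stringsAsFactors = FALSE)
  class(out) <- c("Signature", "data.frame")
  out
}

#' @export
print.Signature <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("Signature: %d genes (%d low-risk, %d high-risk)\n",
              nrow(x), cc[["low"]], cc[["high"]]))
  invisible(x)
}

#' Count signature genes per risk class
#' @param sig A `Signature`.
#' @return Named integer vector with elements `low` and `high`.
#' @export
class_counts <- function(sig) {
  c(low = sum(sig$risk_class == "low"), high = sum(sig$risk_class == "high"))
}

#' Read / write a signature file
#'
#' Headerless TSV: `gene<TAB>risk_class[<TAB>ordering_value]`.
#'
#' @param path File path.
#' @return [read_signature()] returns a `Signature`.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_upregnet("no signature entries in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop_upregnet("signature rows need at least gene and risk_class")
  ov <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, 0)
  gene_signature(vapply(fields, `[`, "", 1L),
                 vapply(fields, `[`, "", 2L), ov)
}

#' @rdname read_signature
#' @param sig A `Signature`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "Signature"))
  lines <- paste(sig$gene, sig$risk_class, fmt_num(sig$ordering_value), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a probe-to-gene map
#'
#' Headerless TSV `probe<TAB>gene`. Each probe maps to exactly one gene; a
#' gene may own several probes.
#'
#' @param path File path.
#' @return Data frame with columns `probe`, `gene`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("probe", "gene"),
                          colClasses = "character")
  dup <- unique(df$probe[duplicated(df$probe)])
  if (length(dup))
    stop_upregnet("probe(s) mapped more than once: ", paste(dup, collapse = ", "))
  df
}

#' @rdname read_probe_map
#' @param map Data frame with columns `probe`, `gene`.
#' @export
write_probe_map <- function(map, path) {
  writeLines(paste(map$probe, map$gene, sep = "\t"), path)
  invisible(path)
}

#' Read / write prognostic group labels
#'
#' Headerless TSV `sample<TAB>group` with group in `{good, poor}`.
#'
#' @param path File path.
#' @return Named character vector mapping sample id to `"good"`/`"poor"`.
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("sample", "group"),
                          colClasses = "character")
  bad <- setdiff(unique(df$group), c("good", "poor"))
  if (length(bad))
    stop_upregnet("group labels must be 'good' or 'poor'; got: ",
                  paste(bad, collapse = ", "))
  dup <- unique(df$sample[duplicated(df$sample)])
  if (length(dup))
    stop_upregnet("duplicate sample(s) in labels: ", paste(dup, collapse = ", "))
  stats::setNames(df$group, df$sample)
}

#' @rdname read_group_labels
#' @param labels Named character vector (`sample -> good/poor`).
#' @export
write_group_labels <- function(labels, path) {
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}

validate_group_labels <- function(labels, expr = NULL) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop_upregnet("group labels must be a named vector (sample -> good/poor)")
  bad <- setdiff(unique(labels), c("good", "poor"))
  if (length(bad))
    stop_upregnet("group labels must be 'good' or 'poor'; got: ",
                  paste(bad, collapse = ", "))
  if (!is.null(expr)) {
    missing <- setdiff(names(labels), sample_ids(expr))
    if (length(missing))
      stop_upregnet("labeled sample(s) absent from expression matrix: ",
                    paste(missing, collapse = ", "))
  }
  invisible(labels)
}

#' Construct / read / write a disease-free-survival table
#'
#' One record per sample: follow-up time in months and an event indicator
#' (1 = relapse/event, 0 = censored). Headerless TSV
#' `sample<TAB>time_months<TAB>event`.
#'
#' @param sample Character vector of unique sample identifiers.
#' @param time Non-negative numeric follow-up times (months).
#' @param event Integer 0/1 event indicators.
#' @return Data frame of class `SurvivalTable`.
#' @export
survival_table <- function(sample, time, event) {
  sample <- as.character(sample)
  time <- as.numeric(time)
  event <- suppressWarnings(as.numeric(event))
  dup <- unique(sample[duplicated(sample)])
  if (length(dup))
    stop_upregnet("duplicate sample(s) in survival table: ", paste(dup, collapse = ", "))
  if (any(is.na(time)) || any(time < 0))
    stop_upregnet("survival times must be non-negative numbers")
  if (any(is.na(event)) || !all(event %in% c(0, 1)))
    stop_upregnet("event indicator must be 0 (censored) or 1 (event)")
  out <- data.frame(sample = sample, time = time, event = as.integer(event),
                    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

#' @rdname survival_table
#' @param path File path.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("sample", "time", "event"),
                          colClasses = c("character", "character", "character"))
  survival_table(df$sample, suppressWarnings(as.numeric(df$time)), df$event)
}

#' @rdname survival_table
#' @param surv A `SurvivalTable`.
#' @export
write_survival <- function(surv, path) {
  writeLines(paste(surv$sample, fmt_num(surv$time), surv$event, sep = "\t"), path)
  invisible(path)
}
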