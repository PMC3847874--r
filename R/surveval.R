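# Evaluation of marker sets (signature genes or TFs) as prognostic
# classifiers: SVM class prediction on an independent cohort, Kaplan-Meier
# estimation, log-rank comparison, and a marker-count sweep.

#' Predict prognostic groups on an independent cohort
#'
#' Trains a linear-kernel support-vector classifier (C = 1) on the marker
#' rows of the training cohort, standardizing each marker with training
#' statistics, and predicts good/poor labels for the test cohort.
#'
#' @param train,test [expression_matrix()] objects.
#' @param train_labels Named character vector (`sample -> good/poor`)
#'   covering the training samples.
#' @param markers Marker feature identifiers; markers missing from either
#'   matrix are dropped with a warning.
#' @return Named character vector of predicted labels for the test samples.
#' @export
classify_cohort <- function(train, train_labels, test, markers) {
  stopifnot(inherits(train, "ExpressionMatrix"), inherits(test, "ExpressionMatrix"))
  validate_group_labels(train_labels, train)
  usable <- intersect(intersect(markers, feature_ids(train)), feature_ids(test))
  dropped <- setdiff(markers, usable)
  if (length(dropped))
    warning("dropping marker(s) absent from a cohort: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  if (!length(usable)) stop_upregnet("no markers shared by both cohorts")
  samples <- intersect(sample_ids(train), names(train_labels))
  y <- factor(train_labels[samples], levels = c("good", "poor"))
  if (length(unique(y)) < 2L)
    stop_upregnet("training labels must contain both classes")
  xtr <- t(train$values[usable, samples, drop = FALSE])
  model <- e1071::svm(x = xtr, y = y, kernel = "linear", cost = 1, scale = TRUE)
  xte <- t(test$values[usable, , drop = FALSE])
  pred <- stats::predict(model, xte)
  stats::setNames(as.character(pred), sample_ids(test))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of disease-free survival for each prognostic
#' group, via [survival::survfit()]. Survival starts at 1, is
#' non-increasing, and drops only at event times; events precede
#' censorings at tied times.
#'
#' @param surv A [survival_table()].
#' @param groups Named character vector (`sample -> group`); every named
#'   sample must appear in `surv`.
#' @return Named list (one element per group) of data frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(surv, groups) {
  unknown <- setdiff(names(groups), surv$sample)
  if (length(unknown))
    stop_upregnet("sample(s) missing from survival table: ",
                  paste(unknown, collapse = ", "))
  idx <- match(names(groups), surv$sample)
  time <- surv$time[idx]; event <- surv$event[idx]
  grp <- factor(unname(groups))
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  if (is.null(sf$strata)) {
    out <- list(data.frame(time = sf$time, n_risk = sf$n.risk,
                           n_event = sf$n.event, surv = sf$surv))
    names(out) <- levels(grp)[1L]
    return(out)
  }
  lens <- sf$strata
  starts <- cumsum(c(1L, utils::head(lens, -1L)))
  out <- lapply(seq_along(lens), function(g) {
    i <- seq(starts[g], length.out = lens[g])
    data.frame(time = sf$time[i], n_risk = sf$n.risk[i],
               n_event = sf$n.event[i], surv = sf$surv[i])
  })
  names(out) <- sub("^grp=", "", names(lens))
  out
}

#' Two-group log-rank test
#'
#' Standard unstratified log-rank chi-square with 1 degree of freedom
#' (via [survival::survdiff()]); the p-value is the chi-square upper tail.
#'
#' @inheritParams km_estimate
#' @return Object of class `LogRankResult`: `chi_square`, `p_value`,
#'   `n_events` (per group), `observed`, `expected` (per-group O and E).
#' @export
logrank_test <- function(surv, groups) {
  unknown <- setdiff(names(groups), surv$sample)
  if (length(unknown))
    stop_upregnet("sample(s) missing from survival table: ",
                  paste(unknown, collapse = ", "))
  if (length(unique(groups)) != 2L)
    stop_upregnet("log-rank test needs exactly two non-empty groups")
  idx <- match(names(groups), surv$sample)
  time <- surv$time[idx]; event <- surv$event[idx]
  if (sum(event) == 0L) stop_upregnet("no events")
  grp <- factor(unname(groups))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd$chisq)
  structure(list(
    chi_square = chi,
    p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
    n_events = stats::setNames(as.vector(sd$obs), sub("^grp=", "", names(sd$n))),
    observed = stats::setNames(as.vector(sd$obs), sub("^grp=", "", names(sd$n))),
    expected = stats::setNames(as.vector(sd$exp), sub("^grp=", "", names(sd$n)))),
    class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  %s: O = %g, E = %.3f\n", names(x$observed), x$observed,
              x$expected), sep = "")
  invisible(x)
}

#' Prognostic performance across marker-list prefix sizes
#'
#' For each ranked marker list and each prefix size, trains a classifier on
#' the training cohort, predicts the test cohort, and records the log-rank
#' p-value between the predicted groups on the test cohort's survival.
#'
#' @param orderings Named list of ranked marker identifier vectors.
#' @param sizes Integer vector of prefix sizes; sizes exceeding a list's
#'   length are truncated with a warning.
#' @inheritParams classify_cohort
#' @param surv_test [survival_table()] for the test cohort.
#' @return Numeric matrix of log-rank p-values, orderings in rows and
#'   sizes in columns.
#' @export
size_sweep <- function(orderings, sizes, train, train_labels, test, surv_test) {
  stopifnot(is.list(orderings), length(sizes) >= 1L)
  out <- matrix(NA_real_, length(orderings), length(sizes),
                dimnames = list(names(orderings), as.character(sizes)))
  for (o in seq_along(orderings)) {
    ord <- orderings[[o]]
    for (s in seq_along(sizes)) {
      sz <- sizes[s]
      if (sz > length(ord)) {
        warning("size ", sz, " exceeds marker list length ", length(ord),
                "; truncated")
        sz <- length(ord)
      }
      pred <- classify_cohort(train, train_labels, test, utils::head(ord, sz))
      # A degenerate single-class prediction has no log-rank p-value.
      out[o, s] <- tryCatch(logrank_test(surv_test, pred)$p_value,
                            error = function(e) NA_real_)
    }
  }
  out
}
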