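# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a base seed and a string key, so
# that independent stages (cohorts, bootstrap replicates, survival draws) use
# non-overlapping but reproducible random streams.
derive_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(key)) h <- (h * 69069 + k) %% 2147483647
  as.integer(h)
}

# Serialize a numeric for TSV output: scientific notation, 12 significant
# digits, round-trip stable at test tolerance.
fmt_num <- function(x) {
  out <- sprintf("%.11e", x)
  out[is.na(x)] <- "NA"
  out
}

# Unordered pair key for edge bookkeeping.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

stop_upregnet <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
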