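## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize free-text metadata into searchable terms
#'
#' Case-folds and splits on any run of non-alphanumeric characters, dropping
#' empty fragments. The same normalization is applied when the inverted index
#' is built and when a query is parsed, so matching is exact on normalized
#' terms (no stemming, no fuzzy matching). Normalization is involutive:
#' applying it to its own output is the identity.
#'
#' @param x character vector of raw text values.
#' @return character vector of normalized terms (may be longer or shorter
#'   than `x`; empty input yields `character(0)`).
#' @examples
#' normalize_terms("Brain - Cortex")  # "brain" "cortex"
#' @export
normalize_terms <- function(x) {
  x <- tolower(as.character(x))
  out <- unlist(strsplit(x, "[^a-z0-9]+"), use.names = FALSE)
  out[nzchar(out)]
}

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Parse packed per-sample coverage lists: a leading comma, then
## comma-separated sample_id:count pairs with strictly increasing ids,
## e.g. ",1:5,7:2". Returns a long data.table(junction_id, sample_id, coverage).
parse_packed_coverages <- function(packed, junction_ids, lines = NULL) {
  lines <- lines %||% seq_along(packed)
  ok_lead <- startsWith(packed, ",") & nchar(packed) > 1L
  if (!all(ok_lead)) {
    i <- which(!ok_lead)[1L]
    stop(sprintf(
      "malformed packed sample list at line %d (column 'samples'): %s",
      lines[i], sQuote(packed[i])), call. = FALSE)
  }
  body <- substr(packed, 2L, nchar(packed))
  pairs <- strsplit(body, ",", fixed = TRUE)
  nper <- lengths(pairs)
  flat <- unlist(pairs, use.names = FALSE)
  owner <- rep.int(seq_along(packed), nper)
  good <- grepl("^[0-9]+:[0-9]+$", flat)
  if (!all(good)) {
    i <- which(!good)[1L]
    stop(sprintf(
      "malformed sample:coverage pair %s at line %d (column 'samples')",
      sQuote(flat[i]), lines[owner[i]]), call. = FALSE)
  }
  sp <- tstrsplit(flat, ":", fixed = TRUE)
  sid <- as.integer(sp[[1L]])
  cnt <- as.integer(sp[[2L]])
  if (any(cnt < 1L)) {
    i <- which(cnt < 1L)[1L]
    stop(sprintf(
      "coverage value %d < 1 at line %d (column 'samples'); absent samples must be omitted",
      cnt[i], lines[owner[i]]), call. = FALSE)
  }
  ## ids strictly increasing within each row
  incr <- c(TRUE, diff(sid) > 0L)
  incr[c(1L, cumsum(nper)[-length(nper)] + 1L)] <- TRUE
  if (!all(incr)) {
    i <- which(!incr)[1L]
    stop(sprintf(
      "sample ids not strictly increasing at line %d (column 'samples')",
      lines[owner[i]]), call. = FALSE)
  }
  data.table(junction_id = rep.int(junction_ids, nper),
             sample_id = sid, coverage = cnt)
}

## Serialize a coverage table back to packed lists, one string per junction id
## (in the order of `junction_ids`). Ids with no coverage get NA.
format_packed_coverages <- function(cov, junction_ids) {
  cov <- cov[order(junction_id, sample_id)]
  packed <- cov[, .(samples = paste0(",", paste(sample_id, coverage, sep = ":",
                                                collapse = ","))),
                by = junction_id]
  packed$samples[match(junction_ids, packed$junction_id)]
}

## Coverage summaries per junction over a (long) coverage table. Junctions in
## `junction_ids` absent from `cov` get zero summaries.
summarize_coverages <- function(cov, junction_ids) {
  ## plain .N/sum/median keep data.table's optimized grouped C routines;
  ## sums are promoted to double afterwards (an integer-overflowing sum
  ## would error out of the C routine rather than wrap)
  sm <- cov[, .(samples_count = .N,
                coverage_sum = sum(coverage),
                coverage_median = median(coverage)),
            by = junction_id]
  sm[, coverage_sum := as.numeric(coverage_sum)]
  sm[, coverage_median := as.numeric(coverage_median)]
  sm[, coverage_avg := coverage_sum / samples_count]
  idx <- match(junction_ids, sm$junction_id)
  out <- data.table(
    junction_id     = junction_ids,
    samples_count   = sm$samples_count[idx],
    coverage_sum    = sm$coverage_sum[idx],
    coverage_avg    = sm$coverage_avg[idx],
    coverage_median = sm$coverage_median[idx])
  for (col in c("samples_count", "coverage_sum", "coverage_avg", "coverage_median")) {
    v <- out[[col]]
    v[is.na(v)] <- 0
    set(out, j = col, value = v)
  }
  out$samples_count <- as.integer(out$samples_count)
  out
}
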