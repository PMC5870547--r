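## High-level queries built from basic queries: Shared Sample Count (SSC),
## Junction Inclusion Ratio (JIR), Percent Spliced In (PSI) and Tissue
## Specificity (TS, tie-corrected Kruskal-Wallis across tissue groups).

## Per-sample coverage sums over the junctions of a group result.
group_sample_sums <- function(res) {
  if (!nrow(res$coverages))
    return(data.table(sample_id = integer(0), total = numeric(0)))
  res$coverages[, .(total = sum(as.numeric(coverage))), by = sample_id]
}

#' Shared Sample Count (SSC)
#'
#' Measures the overall prevalence of a compound splicing pattern: for each
#' query group g, S_g is the set of samples with coverage >= 1 in at least
#' one junction returned by g; the shared count is the size of the
#' intersection of all S_g. For a cassette-exon screen the two groups are
#' the flank queries anchored on the exon's splice sites
#' (`end_equals exonStart-1` and `start_equals exonEnd+1`).
#'
#' @param groups list of query groups / [query_spec()]s / query strings
#'   (>= 1). A group returning no junctions contributes an empty sample set
#'   (shared count 0), not an error.
#' @param ix a [build_indices()] object.
#' @return object of class `jx_ssc`: `sample_sets` (per group),
#'   `shared_samples`, `shared_count`.
#' @export
shared_sample_count <- function(groups, ix) {
  if (!is.list(groups) || inherits(groups, c("jx_group", "jx_query")))
    groups <- list(groups)
  if (!length(groups)) stop("need at least one query group", call. = FALSE)
  sets <- lapply(groups, function(g) {
    res <- run_group(as_group(g), ix)
    sort(unique(res$coverages$sample_id))
  })
  names(sets) <- names(groups) %||% paste0("group", seq_along(sets))
  if (is.null(names(groups))) names(sets) <- paste0("group", seq_along(sets))
  shared <- Reduce(intersect, sets)
  structure(list(sample_sets = sets, shared_samples = shared,
                 shared_count = length(shared)), class = "jx_ssc")
}

#' @export
print.jx_ssc <- function(x, ...) {
  cat(sprintf("<jx_ssc> %d group(s); set sizes: %s; shared_count = %d\n",
              length(x$sample_sets),
              paste(lengths(x$sample_sets), collapse = ", "),
              x$shared_count))
  invisible(x)
}

#' Junction Inclusion Ratio (JIR)
#'
#' Ranks samples by the relative prevalence of one splicing pattern over
#' another. For each sample s, with a = total coverage over group A's
#' junctions and b = total over group B's, the score is
#' `(b - a) / (a + b + 1)`. The +1 regularizer keeps the score finite,
#' bounds it in `[-1, 1)`, and shrinks low-coverage samples toward 0.
#' Samples with `a + b == 0` are omitted. Output is sorted by descending
#' score, ties broken by ascending sample_id; swapping the groups negates
#' every score.
#'
#' @param groupA,groupB query groups / specs / strings; A holds the
#'   junctions whose absence should rank a sample highly (e.g. the excised
#'   junctions of a variant isoform), B the reference junctions.
#' @param ix a [build_indices()] object.
#' @return data.table(sample_id, a, b, score, rank), ranked 1..n.
#' @export
junction_inclusion_ratio <- function(groupA, groupB, ix) {
  ra <- group_sample_sums(run_group(as_group(groupA), ix))
  rb <- group_sample_sums(run_group(as_group(groupB), ix))
  setnames(ra, "total", "a"); setnames(rb, "total", "b")
  m <- merge(ra, rb, by = "sample_id", all = TRUE)
  for (col in c("a", "b")) {
    v <- m[[col]]; v[is.na(v)] <- 0; set(m, j = col, value = v)
  }
  m <- m[a + b > 0]
  m[, score := (b - a) / (a + b + 1)]
  setorder(m, -score, sample_id)
  m[, rank := seq_len(.N)]
  m[]
}

#' Percent Spliced In (PSI)
#'
#' The cassette-exon special case of JIR. For one cassette event described
#' by two inclusion-flank queries and one exclusion query, each sample's
#' inclusion evidence is the mean of its two flank coverages,
#' `i = (c_L + c_R) / 2`, the exclusion evidence is `e`, and
#' `PSI = i / (i + e)`. Samples with `i + e == 0` or total evidence
#' `c_L + c_R + e < min_total` are omitted (a conventional depth floor for
#' interpretable PSI).
#'
#' @param inclusion_left,inclusion_right,exclusion queries / groups /
#'   strings targeting the three junctions of one cassette event.
#' @param ix a [build_indices()] object.
#' @param min_total minimum total read evidence per sample (default 20).
#' @return data.table(sample_id, count_left, count_right, count_excl, psi,
#'   rank), sorted by descending PSI, ties by ascending sample_id.
#' @export
percent_spliced_in <- function(inclusion_left, inclusion_right, exclusion,
                               ix, min_total = 20L) {
  grab <- function(g, nm) {
    s <- group_sample_sums(run_group(as_group(g), ix))
    setnames(s, "total", nm)
    s
  }
  m <- Reduce(function(x, y) merge(x, y, by = "sample_id", all = TRUE),
              list(grab(inclusion_left, "count_left"),
                   grab(inclusion_right, "count_right"),
                   grab(exclusion, "count_excl")))
  for (col in c("count_left", "count_right", "count_excl")) {
    v <- m[[col]]; v[is.na(v)] <- 0; set(m, j = col, value = v)
  }
  m[, i_cov := (count_left + count_right) / 2]
  m[, e_cov := count_excl]
  m <- m[i_cov + e_cov > 0 & count_left + count_right + count_excl >= min_total]
  m[, psi := i_cov / (i_cov + e_cov)]
  m[, c("i_cov", "e_cov") := NULL]
  setorder(m, -psi, sample_id)
  m[, rank := seq_len(.N)]
  m[]
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' Midranks are assigned over the pooled values; the statistic is
#' `H = 12 / (N (N + 1)) * sum n_i (rbar_i - (N + 1) / 2)^2`, divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)` over tie-group sizes t.
#' When all values are tied the corrected statistic is defined as 0 with
#' p = 1. The p-value is the upper tail of the chi-square distribution with
#' k - 1 degrees of freedom; for small samples a permutation p-value
#' (label permutation, `(1 + #{H* >= H}) / (B + 1)`) is available, since
#' the chi-square approximation is inaccurate at small N.
#'
#' @param groups list of >= 2 numeric vectors, all nonempty, total N >= 3.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm number of label permutations for `p_method = "permutation"`.
#' @return list of class `jx_kw` with `H` (tie-corrected), `df`, `p`,
#'   `method`, group sizes `n`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000L) {
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("all groups must be nonempty", call. = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  if (N < 3L) stop("need at least 3 observations in total", call. = FALSE)
  k <- length(groups)
  v <- unlist(groups, use.names = FALSE)
  g <- rep.int(seq_len(k), n)
  r <- rank(v)
  stat_from_ranks <- function(rr) {
    sums <- vapply(split(rr, g), sum, numeric(1L))
    12 / (N * (N + 1)) * sum(sums^2 / n) - 3 * (N + 1)
  }
  t_sizes <- tabulate(match(r, unique(r)))
  corr <- 1 - sum(t_sizes^3 - t_sizes) / (N^3 - N)
  if (corr <= 0) {
    H <- 0; p <- 1
  } else {
    H <- stat_from_ranks(r) / corr
    if (H < 0 && H > -1e-12) H <- 0
    p <- switch(p_method,
      chisq = pchisq(H, df = k - 1L, lower.tail = FALSE),
      permutation = {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          Hb <- stat_from_ranks(sample(r)) / corr
          if (Hb >= H - 1e-12) hits <- hits + 1L
        }
        (1 + hits) / (n_perm + 1)
      })
  }
  structure(list(H = H, df = k - 1L, p = p, method = p_method, n = n),
            class = "jx_kw")
}

#' @export
print.jx_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (tie-corrected): H = %.4f, df = %d, p = %.4g (%s)\n",
              x$H, x$df, x$p, x$method))
  invisible(x)
}

#' Tissue Specificity (TS)
#'
#' Tests whether evidence for a splicing pattern is restricted to certain
#' tissues. Every sample with a nonempty tissue label gets a value: 1/0
#' presence of coverage in any junction returned by the group
#' (`value_mode = "presence"`, robust to depth differences) or the total
#' coverage (`value_mode = "coverage"`). Values are grouped by tissue and
#' compared with the tie-corrected Kruskal-Wallis test; a small p indicates
#' tissue-restricted splicing.
#'
#' @param group a query group / spec / string selecting the junctions of
#'   the pattern.
#' @param ix a [build_indices()] object.
#' @param tissue_field metadata field holding the tissue label
#'   (default `"tissue"`). Samples with an empty label are excluded; fewer
#'   than two nonempty tissue groups is an error.
#' @param value_mode `"presence"` (default) or `"coverage"`.
#' @param p_method,n_perm forwarded to [kruskal_wallis()].
#' @return object of class `jx_ts`: `table` (per-tissue n and mean value),
#'   `values` (named list of per-tissue vectors), `H`, `df`, `p`,
#'   `value_mode`.
#' @export
tissue_specificity <- function(group, ix, tissue_field = "tissue",
                               value_mode = c("presence", "coverage"),
                               p_method = c("chisq", "permutation"),
                               n_perm = 10000L) {
  value_mode <- match.arg(value_mode)
  samples <- ix$comp$samples
  if (!tissue_field %in% names(samples))
    stop(sprintf("metadata has no field '%s'", tissue_field), call. = FALSE)
  res <- run_group(as_group(group), ix)
  sums <- group_sample_sums(res)
  tis <- samples[[tissue_field]]
  keep <- !is.na(tis) & nzchar(tis)
  sdt <- data.table(sample_id = samples$sample_id[keep], tissue = tis[keep])
  v <- sums$total[match(sdt$sample_id, sums$sample_id)]
  v[is.na(v)] <- 0
  if (value_mode == "presence") v <- as.numeric(v > 0)
  groups <- split(v, sdt$tissue)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    stop("tissue specificity requires at least two nonempty tissue groups",
         call. = FALSE)
  kw <- kruskal_wallis(groups, p_method = match.arg(p_method), n_perm = n_perm)
  tab <- data.table(tissue = names(groups), n = lengths(groups),
                    mean_value = vapply(groups, mean, numeric(1L)))
  structure(list(table = tab, values = groups, H = kw$H, df = kw$df,
                 p = kw$p, value_mode = value_mode), class = "jx_ts")
}

#' @export
print.jx_ts <- function(x, ...) {
  cat(sprintf("<jx_ts> value_mode = %s\n", x$value_mode))
  print(x$table)
  cat(sprintf("H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  invisible(x)
}
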