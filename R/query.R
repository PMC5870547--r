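## Basic-query engine: parse query strings, plan index usage, execute
## R/F/M constraint combinations, combine query groups by union/intersection.

#' Construct a query specification
#'
#' A basic query combines up to three constraint kinds: a genomic region
#' (R), filters on junction summary columns (F), and a metadata term query
#' over samples (M). At least one must be present. An explicit sample-id
#' restriction may be supplied programmatically; like a metadata
#' constraint, it causes summaries to be recomputed over the admitted
#' samples before F filters are evaluated.
#'
#' @param region `NULL`, a string `"chrom:start-end[:mode]"`, or a list with
#'   elements chrom, start, end, mode.
#' @param filters list of filters, each either a string like
#'   `"samples_count>=5"` or a list with elements column, op, value
#'   (and optionally value2 for `op = "range"`).
#' @param metadata `NULL` or a term query string (see [query_terms()]).
#' @param samples `NULL` or an integer vector of admitted sample ids.
#' @return object of class `jx_query`.
#' @export
query_spec <- function(region = NULL, filters = list(), metadata = NULL,
                       samples = NULL) {
  if (is.character(region)) region <- parse_region(region)
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    region$mode <- match.arg(region$mode %||% "overlap", REGION_MODES)
    region$start <- as.integer(region$start)
    region$end <- as.integer(region$end)
    if (region$start > region$end)
      stop("region start must be <= end", call. = FALSE)
  }
  if (is.character(filters)) filters <- as.list(filters)
  filters <- lapply(filters, function(f) {
    if (is.character(f) && length(f) == 1L) f <- parse_filter(f)
    stopifnot(all(c("column", "op", "value") %in% names(f)))
    if (!f$column %in% FILTER_COLUMNS)
      stop(sprintf("unknown filter column '%s'; supported: %s", f$column,
                   paste(FILTER_COLUMNS, collapse = ", ")), call. = FALSE)
    f
  })
  if (!is.null(metadata)) {
    metadata <- trimws(metadata)
    if (!nzchar(metadata)) stop("metadata constraint is empty", call. = FALSE)
  }
  if (!is.null(samples)) samples <- sort(unique(as.integer(samples)))
  if (is.null(region) && !length(filters) && is.null(metadata))
    stop("a query needs at least one of region/filters/metadata", call. = FALSE)
  structure(list(region = region, filters = filters, metadata = metadata,
                 sample_restriction = samples), class = "jx_query")
}

parse_region <- function(text, offset = 0L) {
  m <- regmatches(text, regexec(
    "^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)(:([a-z_]+))?$", text))[[1L]]
  if (!length(m))
    stop(sprintf("syntax error in region at offset %d: expected chrom:start-end[:mode], got %s",
                 offset, sQuote(text)), call. = FALSE)
  mode <- if (nzchar(m[6L])) m[6L] else "overlap"
  if (!mode %in% REGION_MODES)
    stop(sprintf("unknown region mode '%s' at offset %d; modes: %s", mode,
                 offset, paste(REGION_MODES, collapse = ", ")), call. = FALSE)
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]),
       mode = mode)
}

parse_filter <- function(text, offset = 0L) {
  m <- regmatches(text, regexec(
    "^([A-Za-z_]+)[[:space:]]*(>=|<=|=|>|<)[[:space:]]*(.*)$", text))[[1L]]
  if (!length(m))
    stop(sprintf("syntax error in constraint at offset %d: %s", offset,
                 sQuote(text)), call. = FALSE)
  column <- m[2L]; op <- m[3L]; valtxt <- trimws(m[4L])
  if (!column %in% FILTER_COLUMNS)
    stop(sprintf("unknown column '%s' at offset %d; supported: %s", column,
                 offset + 0L, paste(FILTER_COLUMNS, collapse = ", ")),
         call. = FALSE)
  if (!nzchar(valtxt))
    stop(sprintf("missing value after '%s%s' at offset %d", column, op,
                 offset + nchar(column) + nchar(op)), call. = FALSE)
  value <- if (column %in% CATEGORICAL_COLUMNS) valtxt else {
    v <- suppressWarnings(as.numeric(valtxt))
    if (is.na(v))
      stop(sprintf("non-numeric value %s for column '%s' at offset %d",
                   sQuote(valtxt), column, offset), call. = FALSE)
    v
  }
  list(column = column, op = op, value = value)
}

#' Parse a query string
#'
#' Grammar: `&`-joined constraint components, each one of
#' `region=<chrom>:<start>-<end>[:<mode>]`, `metadata=<atoms>`, or
#' `<column><op><value>` with `op` one of `>=`, `<=`, `=`, `>`, `<`.
#' Syntax errors report the character offset of the offending component.
#'
#' @param text query string, e.g.
#'   `"region=chr1:100-200 & samples_count>=5 & metadata=tissue:brain"`.
#' @return a [query_spec()] object.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pieces <- strsplit(text, "&", fixed = TRUE)[[1L]]
  offsets <- cumsum(c(0L, nchar(pieces[-length(pieces)]) + 1L))
  region <- NULL; metadata <- NULL; filters <- list()
  for (i in seq_along(pieces)) {
    raw <- pieces[i]
    comp <- trimws(raw)
    off <- offsets[i] + (nchar(raw) - nchar(sub("^[[:space:]]+", "", raw)))
    if (!nzchar(comp))
      stop(sprintf("empty constraint at offset %d", off), call. = FALSE)
    if (startsWith(comp, "region=")) {
      if (!is.null(region))
        stop(sprintf("duplicate region constraint at offset %d", off),
             call. = FALSE)
      region <- parse_region(sub("^region=", "", comp), off + 7L)
    } else if (startsWith(comp, "metadata=")) {
      if (!is.null(metadata))
        stop(sprintf("duplicate metadata constraint at offset %d", off),
             call. = FALSE)
      metadata <- sub("^metadata=", "", comp)
      if (!nzchar(trimws(metadata)))
        stop(sprintf("empty metadata constraint at offset %d", off + 9L),
             call. = FALSE)
    } else {
      filters[[length(filters) + 1L]] <- parse_filter(comp, off)
    }
  }
  query_spec(region = region, filters = filters, metadata = metadata)
}

## A filter may drive the plan from the stored-value numeric index when the
## query carries no sample restriction (stored == effective values), or --
## under a restriction -- when the predicate is monotone-safe: restriction
## can only reduce samples_count and coverage_sum, so a lower bound on those
## columns screens a superset of the final result. length/strand/annotated
## are unaffected by restriction.
filter_is_safe_driver <- function(f, restricted) {
  if (!restricted) return(TRUE)
  if (f$column %in% c("length", "strand", "annotated")) return(TRUE)
  f$column %in% c("samples_count", "coverage_sum") && f$op %in% c(">=", ">")
}

#' Plan a query
#'
#' Chooses the most selective available index as the driver: the interval
#' index when a region is present; otherwise the usable numeric filter with
#' the smallest estimated bucket mass; otherwise the metadata constraint.
#' With no applicable index the plan falls back to a full scan (the engine
#' is total without indices). The plan records its choice for
#' explainability; executing it is always equivalent to the naive scan.
#'
#' @param q a [query_spec()] (or query string).
#' @param ix a [build_indices()] object.
#' @return object of class `jx_plan`.
#' @export
plan_query <- function(q, ix) {
  if (is.character(q)) q <- parse_query(q)
  stopifnot(inherits(q, "jx_query"), inherits(ix, "jx_indices"))
  restricted <- !is.null(q$metadata) || !is.null(q$sample_restriction)
  n <- nrow(ix$comp$junctions)
  steps <- character(0)
  driver <- NULL
  if (!is.null(q$region)) {
    driver <- list(type = "region")
    steps <- c(steps, sprintf("driver: interval index %s:%d-%d mode=%s",
                              q$region$chrom, q$region$start, q$region$end,
                              q$region$mode))
  } else if (length(q$filters)) {
    usable <- vapply(q$filters, filter_is_safe_driver, logical(1L),
                     restricted = restricted)
    if (any(usable)) {
      mass <- rep(Inf, length(q$filters))
      for (k in which(usable)) {
        f <- q$filters[[k]]
        mass[k] <- numeric_index_mass(ix$numeric[[f$column]], f$op, f$value,
                                      f$value2 %||% NULL)
      }
      k <- which.min(mass)
      driver <- list(type = "numeric", filter = k)
      f <- q$filters[[k]]
      steps <- c(steps, sprintf(
        "driver: numeric index on %s (%s %s, est. %d/%d junctions)",
        f$column, f$op, format(f$value), as.integer(mass[k]), n))
    }
  }
  if (is.null(driver)) {
    if (!is.null(q$metadata)) {
      driver <- list(type = "metadata")
      steps <- c(steps, sprintf("driver: inverted index, metadata '%s' (scan restricted junctions)",
                                q$metadata))
    } else {
      driver <- list(type = "scan")
      steps <- c(steps, "driver: full scan (no applicable index)")
      warning("no applicable index; falling back to full scan", call. = FALSE)
    }
  }
  if (restricted)
    steps <- c(steps, "restrict samples (metadata/explicit) and recompute summaries; drop junctions with no admitted sample")
  if (length(q$filters))
    steps <- c(steps, sprintf("refine: %d filter(s) on %s summaries",
                              length(q$filters),
                              if (restricted) "post-restriction" else "stored"))
  if (!is.null(q$region))
    steps <- c(steps, "refine: region predicate")
  steps <- c(steps, "order results by (chrom, start, end, strand, junction_id)")
  structure(list(query = q, ix = ix, driver = driver, steps = steps),
            class = "jx_plan")
}

#' @export
print.jx_plan <- function(x, ...) {
  cat("<jx_plan>\n")
  for (s in x$steps) cat(" -", s, "\n")
  invisible(x)
}

apply_region_predicate <- function(region, chrom, start, end) {
  same <- chrom == region$chrom
  switch(region$mode,
    overlap = same & start <= region$end & end >= region$start,
    within = same & start >= region$start & end <= region$end,
    exact = same & start == region$start & end == region$end,
    start_equals = same & start == region$start,
    end_equals = same & end == region$end)
}

apply_filter <- function(f, values) {
  if (f$column %in% CATEGORICAL_COLUMNS) {
    value <- if (f$column == "annotated") as.integer(f$value) else f$value
    if (f$op != "=")
      stop(sprintf("column '%s' is categorical; only '=' is supported",
                   f$column), call. = FALSE)
    return(values == value)
  }
  switch(f$op,
    ">=" = values >= f$value, "<=" = values <= f$value,
    "=" = values == f$value, ">" = values > f$value, "<" = values < f$value,
    "range" = values >= f$value & values <= f$value2,
    stop(sprintf("unsupported op '%s'", f$op), call. = FALSE))
}

empty_result <- function(ix, q, admitted) {
  structure(list(junctions = ix$comp$junctions[0L],
                 coverages = ix$comp$coverages[0L],
                 admitted_samples = admitted, query = q),
            class = "jx_result")
}

#' Execute a query plan
#'
#' Semantics: (1) candidate junctions come from the driver index; (2) when a
#' metadata constraint (or explicit sample restriction) is present, the
#' admitted sample set is computed, every candidate's coverages are
#' restricted to it, summaries are recomputed over the restriction, and
#' candidates left with no admitted sample are dropped; (3) F filters are
#' evaluated on the summaries current at that point (recomputed if
#' restricted, stored otherwise); (4) the region predicate is re-applied;
#' results are ordered by (chrom, start, end, strand, junction_id).
#'
#' @param p a [plan_query()] plan.
#' @return object of class `jx_result`: `junctions` (summaries over the
#'   admitted samples), `coverages` (restricted long table),
#'   `admitted_samples` (`NULL` when unrestricted), `query`.
#' @export
execute_plan <- function(p) {
  stopifnot(inherits(p, "jx_plan"))
  q <- p$query; ix <- p$ix
  jdt <- ix$comp$junctions; cov <- ix$comp$coverages

  admitted <- NULL
  if (!is.null(q$metadata)) admitted <- query_terms(ix$terms, q$metadata)
  if (!is.null(q$sample_restriction)) {
    admitted <- if (is.null(q$metadata)) q$sample_restriction
                else intersect(admitted, q$sample_restriction)
  }
  restricted <- !is.null(admitted)
  if (restricted && !length(admitted)) return(empty_result(ix, q, admitted))

  cand_ids <- switch(p$driver$type,
    region = {
      r <- q$region
      query_region(ix$interval, r$chrom, r$start, r$end, r$mode)
    },
    numeric = {
      f <- q$filters[[p$driver$filter]]
      query_numeric(ix$numeric[[f$column]], f$op, f$value, f$value2 %||% NULL)
    },
    jdt$junction_id)
  if (!length(cand_ids)) return(empty_result(ix, q, admitted))
  rows <- ix$id2row[cand_ids + 1L]

  cov_sub <- NULL
  if (restricted) {
    cov_sub <- cov[.(cand_ids)]
    mask <- logical(ix$max_sample_id + 1L)
    mask[admitted + 1L] <- TRUE
    cov_sub <- cov_sub[mask[sample_id + 1L]]
    sm <- summarize_coverages(cov_sub, cand_ids)
    keep <- sm$samples_count > 0L
    cand_ids <- cand_ids[keep]; rows <- rows[keep]; sm <- sm[keep]
    if (!length(cand_ids)) return(empty_result(ix, q, admitted))
    get_col <- function(column) {
      if (column %in% SUMMARY_COLUMNS) sm[[column]]
      else filter_column_values(jdt, column)[rows]
    }
  } else {
    get_col <- function(column) filter_column_values(jdt, column)[rows]
  }

  keep <- rep(TRUE, length(cand_ids))
  for (f in q$filters) keep <- keep & apply_filter(f, get_col(f$column))
  if (!is.null(q$region))
    keep <- keep & apply_region_predicate(q$region, jdt$chrom[rows],
                                          jdt$start[rows], jdt$end[rows])
  cand_ids <- cand_ids[keep]; rows <- rows[keep]
  if (!length(cand_ids)) return(empty_result(ix, q, admitted))

  out <- jdt[rows]
  if (restricted) {
    sm <- sm[keep]
    for (col in SUMMARY_COLUMNS) set(out, j = col, value = sm[[col]])
    out_cov <- cov_sub[junction_id %in% cand_ids]
  } else {
    out_cov <- cov[.(cand_ids)]
  }
  setorder(out, chrom, start, end, strand, junction_id)
  setkey(out_cov, junction_id, sample_id)
  structure(list(junctions = out, coverages = out_cov,
                 admitted_samples = admitted, query = q),
            class = "jx_result")
}

#' @export
print.jx_result <- function(x, ...) {
  cat(sprintf("<jx_result> %d junctions%s\n", nrow(x$junctions),
              if (is.null(x$admitted_samples)) ""
              else sprintf(" over %d admitted samples",
                           length(x$admitted_samples))))
  invisible(x)
}

#' Parse, plan and execute a query in one call
#'
#' @param ix a [build_indices()] object.
#' @param q a query string or [query_spec()].
#' @return a `jx_result` (see [execute_plan()]).
#' @export
run_query <- function(ix, q) execute_plan(plan_query(q, ix))

#' Construct a query group
#'
#' A named list of basic queries combined by set operation: `union` keeps
#' junctions returned by at least one member, `intersection` keeps junctions
#' returned by every member. Junction identity across members is positional
#' -- (chrom, start, end, strand) -- not junction_id.
#'
#' @param queries list of [query_spec()] objects or query strings.
#' @param set_op `"union"` or `"intersection"`.
#' @return object of class `jx_group`.
#' @export
query_group <- function(queries, set_op = c("union", "intersection")) {
  set_op <- match.arg(set_op)
  if (inherits(queries, "jx_query")) queries <- list(queries)
  queries <- lapply(queries, function(q) {
    if (is.character(q)) parse_query(q) else q
  })
  if (!length(queries)) stop("query group must be nonempty", call. = FALSE)
  stopifnot(all(vapply(queries, inherits, logical(1L), "jx_query")))
  structure(list(queries = queries, set_op = set_op), class = "jx_group")
}

as_group <- function(x) {
  if (inherits(x, "jx_group")) return(x)
  if (inherits(x, "jx_query") || is.character(x)) return(query_group(x))
  stop("expected a query, query string, or query group", call. = FALSE)
}

#' Execute a query group
#'
#' Members execute independently; their result sets are combined by the
#' group's set operation, keyed by (chrom, start, end, strand). When a
#' junction is returned by several members, its summaries (and restricted
#' coverages) are taken from the member with the widest admitted sample set
#' (an unrestricted member counts as widest).
#'
#' @param g a [query_group()] (a single query is promoted to a group of one).
#' @param ix a [build_indices()] object.
#' @return a `jx_result`; `admitted_samples` is the union of member admitted
#'   sets, or `NULL` if any contributing member was unrestricted.
#' @export
run_group <- function(g, ix) {
  g <- as_group(g)
  results <- lapply(g$queries, function(q) run_query(ix, q))
  if (length(results) == 1L) return(results[[1L]])
  sizes <- vapply(results, function(r) {
    if (is.null(r$admitted_samples)) Inf else length(r$admitted_samples)
  }, numeric(1L))
  parts <- rbindlist(lapply(seq_along(results), function(m) {
    j <- copy(results[[m]]$junctions)
    set(j, j = "member", value = m)
    set(j, j = "adm_size", value = sizes[m])
    j
  }))
  if (!nrow(parts)) return(empty_result(ix, g$queries[[1L]], NULL))
  set(parts, j = "pos_key",
      value = paste(parts$chrom, parts$start, parts$end, parts$strand,
                    sep = "\r"))
  if (g$set_op == "intersection") {
    n_members <- parts[, .(n = uniqueN(member)), by = pos_key]
    keep_keys <- n_members$pos_key[n_members$n == length(results)]
    parts <- parts[pos_key %in% keep_keys]
    if (!nrow(parts)) return(empty_result(ix, g$queries[[1L]], NULL))
  }
  setorder(parts, pos_key, -adm_size, member)
  chosen <- unique(parts, by = "pos_key")
  contrib <- sort(unique(chosen$member))
  adm <- NULL
  if (all(is.finite(sizes[contrib]))) {
    adm <- sort(unique(unlist(lapply(contrib,
      function(m) results[[m]]$admitted_samples))))
  }
  cov_parts <- rbindlist(lapply(contrib, function(m) {
    ids <- chosen$junction_id[chosen$member == m]
    results[[m]]$coverages[.(ids), nomatch = NULL]
  }))
  out <- chosen[, !c("member", "adm_size", "pos_key")]
  setorder(out, chrom, start, end, strand, junction_id)
  setkey(cov_parts, junction_id, sample_id)
  structure(list(junctions = out, coverages = cov_parts,
                 admitted_samples = adm, query = g),
            class = "jx_result")
}
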