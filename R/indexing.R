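## Index families combined by the planner: interval index over junction
## coordinates (the R-tree role, backed by IRanges), ordered numeric indices
## over summary columns (the B-tree role), and a term-document inverted
## index over sample metadata.

## Columns a numeric index / F filter may address. strand and annotated are
## categorical (equality only); annotated is the 0/1 flag "any source".
FILTER_COLUMNS <- c("samples_count", "coverage_sum", "coverage_avg",
                    "coverage_median", "length", "strand", "annotated")
CATEGORICAL_COLUMNS <- c("strand", "annotated")

REGION_MODES <- c("overlap", "within", "exact", "start_equals", "end_equals")

as_jx_table <- function(x) {
  if (inherits(x, "jx_table")) return(x)
  if (inherits(x, "jx_compilation"))
    return(structure(list(junctions = x$junctions, coverages = x$coverages),
                     class = "jx_table"))
  stop("expected a jx_table or jx_compilation", call. = FALSE)
}

#' Build the interval index
#'
#' Per-chromosome searchable interval structure over junction intron
#' coordinates (1-based, closed), mapping intervals to junction ids.
#' Duplicate intervals (e.g. the same intron on both strands) are all
#' retrievable; strand is not part of the interval key.
#'
#' @param x a [jx_table] or [compilation].
#' @return object of class `jx_interval_index`.
#' @export
build_interval_index <- function(x) {
  j <- as_jx_table(x)$junctions
  per <- lapply(split(seq_len(nrow(j)), j$chrom), function(rows) {
    list(ranges = IRanges(start = j$start[rows], end = j$end[rows]),
         starts = j$start[rows], ends = j$end[rows],
         ids = j$junction_id[rows])
  })
  structure(list(chroms = per), class = "jx_interval_index")
}

#' Query the interval index
#'
#' Closed-interval semantics: `[a,b]` overlaps `[c,d]` iff `a <= d && c <= b`.
#' Modes: `overlap` (any intersection), `within` (junction interval contained
#' in the query interval), `exact` (both ends equal), `start_equals` /
#' `end_equals` (the named junction coordinate equals the query start / end).
#' An unknown chromosome yields an empty result, not an error.
#'
#' @param ix a `jx_interval_index`.
#' @param chrom chromosome name.
#' @param start,end 1-based closed query interval (`start <= end`).
#' @param mode one of `r paste0('"', REGION_MODES, '"', collapse = ", ")`.
#' @return sorted integer vector of junction ids.
#' @export
query_region <- function(ix, chrom, start, end,
                         mode = c("overlap", "within", "exact",
                                  "start_equals", "end_equals")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ix, "jx_interval_index"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("region query requires start <= end", call. = FALSE)
  ch <- ix$chroms[[chrom]]
  if (is.null(ch)) return(integer(0))
  hits <- switch(mode,
    overlap = ch$ids[ch$starts <= end & ch$ends >= start],
    within = {
      ov <- findOverlaps(ch$ranges, IRanges(start, end), type = "within")
      ch$ids[queryHits(ov)]
    },
    exact = ch$ids[ch$starts == start & ch$ends == end],
    start_equals = ch$ids[ch$starts == start],
    end_equals = ch$ids[ch$ends == end])
  sort(hits)
}

#' Build a numeric index over one summary column
#'
#' Ordered mapping from stored column value to junction ids. Predicates are
#' answered on the original (pre-restriction) values; when a metadata
#' restriction is active the planner re-applies filters to post-restriction
#' summaries (see [execute_plan()]).
#'
#' @param x a [jx_table] or [compilation].
#' @param column one of `r paste0('"', FILTER_COLUMNS, '"', collapse = ", ")`.
#' @return object of class `jx_numeric_index`.
#' @export
build_numeric_index <- function(x, column) {
  j <- as_jx_table(x)$junctions
  if (!column %in% FILTER_COLUMNS)
    stop(sprintf("unsupported column '%s'; supported: %s", column,
                 paste(FILTER_COLUMNS, collapse = ", ")), call. = FALSE)
  v <- filter_column_values(j, column)
  ord <- order(v, j$junction_id)
  structure(list(column = column, values = v[ord], ids = j$junction_id[ord],
                 categorical = column %in% CATEGORICAL_COLUMNS),
            class = "jx_numeric_index")
}

## Stored values of a filter column for a junction table.
filter_column_values <- function(j, column) {
  switch(column,
    strand = j$strand,
    annotated = as.integer(j$annotated != "0"),
    j[[column]])
}

#' Query a numeric index
#'
#' @param ix a `jx_numeric_index`.
#' @param op one of `">="`, `"<="`, `"="`, `">"`, `"<"`, `"range"`
#'   (categorical columns support `"="` only).
#' @param value predicate value (lower bound for `"range"`).
#' @param value2 upper bound for `"range"`.
#' @return sorted integer vector of junction ids.
#' @export
query_numeric <- function(ix, op, value, value2 = NULL) {
  stopifnot(inherits(ix, "jx_numeric_index"))
  n <- length(ix$values)
  if (ix$categorical) {
    if (op != "=")
      stop(sprintf("column '%s' is categorical; only '=' is supported",
                   ix$column), call. = FALSE)
    if (ix$column == "annotated") value <- as.integer(value)
    return(sort(ix$ids[ix$values == value]))
  }
  value <- as.numeric(value)
  lo_hi <- function(x) {
    c(findInterval(x, ix$values, left.open = TRUE),  # count of values <  x
      findInterval(x, ix$values))                    # count of values <= x
  }
  b <- lo_hi(value)
  idx <- switch(op,
    ">=" = if (b[1L] < n) (b[1L] + 1L):n else integer(0),
    ">"  = if (b[2L] < n) (b[2L] + 1L):n else integer(0),
    "<=" = seq_len(b[2L]),
    "<"  = seq_len(b[1L]),
    "="  = if (b[2L] > b[1L]) (b[1L] + 1L):b[2L] else integer(0),
    "range" = {
      if (is.null(value2)) stop("range query needs two values", call. = FALSE)
      b2 <- lo_hi(as.numeric(value2))
      if (b2[2L] > b[1L]) (b[1L] + 1L):b2[2L] else integer(0)
    },
    stop(sprintf("unsupported op '%s'", op), call. = FALSE))
  sort(ix$ids[idx])
}

## Number of junctions satisfying a filter, from the sorted index (no
## materialization). Used for planner selectivity estimates.
numeric_index_mass <- function(ix, op, value, value2 = NULL) {
  n <- length(ix$values)
  if (ix$categorical) return(sum(ix$values == value))
  value <- as.numeric(value)
  lt <- findInterval(value, ix$values, left.open = TRUE)
  le <- findInterval(value, ix$values)
  switch(op,
    ">=" = n - lt, ">" = n - le, "<=" = le, "<" = lt, "=" = le - lt,
    "range" = max(0L, findInterval(as.numeric(value2), ix$values) - lt),
    n)
}

#' Build the metadata term index
#'
#' Term-document inverted index: every metadata field value is normalized
#' with [normalize_terms()] and each (field, term) pair maps to the posting
#' set of sample ids.
#'
#' @param samples sample-metadata data.table.
#' @param fields character vector of fields to index (default: all fields
#'   except `sample_id`).
#' @return object of class `jx_term_index`.
#' @export
build_term_index <- function(samples, fields = NULL) {
  samples <- as.data.table(samples)
  all_fields <- setdiff(names(samples), "sample_id")
  fields <- fields %||% all_fields
  missing <- setdiff(fields, all_fields)
  if (length(missing))
    stop(sprintf("fields absent from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  posting_list <- lapply(fields, function(f) {
    toks <- lapply(samples[[f]], normalize_terms)
    data.table(field = f,
               token = unlist(toks, use.names = FALSE),
               sample_id = rep.int(samples$sample_id, lengths(toks)))
  })
  postings <- unique(rbindlist(posting_list))
  setkey(postings, field, token)
  structure(list(postings = postings, fields = fields,
                 sample_ids = sort(samples$sample_id)),
            class = "jx_term_index")
}

#' Query the metadata term index
#'
#' A query is a whitespace-separated conjunction of atoms. A
#' `field:text` atom matches samples whose named field contains every
#' normalized term of `text`; a bare atom matches the term in any indexed
#' field. The result is the intersection of all atoms' posting sets. An
#' empty query is an error: "all samples" must be requested explicitly.
#'
#' @param ix a `jx_term_index`.
#' @param query query string, e.g. `"tissue:brain study:gtex"`.
#' @return sorted integer vector of sample ids.
#' @export
query_terms <- function(ix, query) {
  stopifnot(inherits(ix, "jx_term_index"))
  query <- trimws(query)
  if (!nzchar(query))
    stop("empty metadata query; matching all samples must be explicit",
         call. = FALSE)
  atoms <- strsplit(query, "[[:space:]]+")[[1L]]
  atoms <- atoms[nzchar(atoms)]
  if (!length(atoms)) stop("empty metadata query", call. = FALSE)
  postings <- ix$postings
  lookup <- function(f, tok) postings[.(f, tok), sample_id, nomatch = NULL]
  sets <- lapply(atoms, function(atom) {
    colon <- regexpr(":", atom, fixed = TRUE)
    if (colon > 0L) {
      f <- substr(atom, 1L, colon - 1L)
      if (!f %in% ix$fields)
        stop(sprintf("unknown metadata field '%s'; indexed fields: %s", f,
                     paste(ix$fields, collapse = ", ")), call. = FALSE)
      toks <- normalize_terms(substr(atom, colon + 1L, nchar(atom)))
      if (!length(toks))
        stop(sprintf("metadata atom '%s' has no searchable term", atom),
             call. = FALSE)
      Reduce(intersect, lapply(toks, function(tk) lookup(f, tk)))
    } else {
      toks <- normalize_terms(atom)
      if (!length(toks))
        stop(sprintf("metadata atom '%s' has no searchable term", atom),
             call. = FALSE)
      Reduce(intersect, lapply(toks, function(tk) {
        sort(unique(unlist(lapply(ix$fields, lookup, tok = tk))))
      }))
    }
  })
  sort(Reduce(intersect, sets))
}

#' Build all indices for a compilation
#'
#' Convenience wrapper producing the three index families plus fast lookup
#' structures used by [execute_plan()].
#'
#' @param comp a [compilation].
#' @param fields metadata fields to index (default all).
#' @return object of class `jx_indices`.
#' @export
build_indices <- function(comp, fields = NULL) {
  stopifnot(inherits(comp, "jx_compilation"))
  numeric <- lapply(FILTER_COLUMNS, function(col) build_numeric_index(comp, col))
  names(numeric) <- FILTER_COLUMNS
  j <- comp$junctions
  id2row <- integer(0)
  if (nrow(j)) {
    id2row <- integer(max(j$junction_id) + 1L)
    id2row[j$junction_id + 1L] <- seq_len(nrow(j))
  }
  max_sid <- if (nrow(comp$samples)) max(comp$samples$sample_id) else 0L
  structure(list(
    comp = comp,
    interval = build_interval_index(comp),
    numeric = numeric,
    terms = build_term_index(comp$samples, fields),
    id2row = id2row,
    max_sample_id = max_sid), class = "jx_indices")
}

INDEX_MAGIC <- "SJQIDX1"

#' Persist / restore built indices
#'
#' The persistence format is private but versioned with a magic string; a
#' file written by a different version is rejected.
#'
#' @param ix a `jx_indices` object.
#' @param path file path.
#' @return `load_indices` returns the restored `jx_indices`.
#' @export
save_indices <- function(ix, path) {
  stopifnot(inherits(ix, "jx_indices"))
  saveRDS(list(magic = INDEX_MAGIC, indices = ix), path, version = 2L)
  invisible(path)
}

#' @rdname save_indices
#' @export
load_indices <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$magic, INDEX_MAGIC))
    stop(sprintf("not a recognized index file (magic %s)",
                 sQuote(obj$magic %||% "<none>")), call. = FALSE)
  obj$indices
}
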