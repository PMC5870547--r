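## Compilation data model: junction tables, sample metadata, summary
## recomputation over sample subsets.

## The on-disk junction-table dialect: tab-separated, UTF-8, optional
## '#'-prefixed header, 17 columns in this fixed order.
JX_COLUMNS <- c(
  "junction_id", "chrom", "start", "end", "length", "strand", "annotated",
  "left_motif", "right_motif", "left_annotated", "right_annotated",
  "samples", "samples_count", "coverage_sum", "coverage_avg",
  "coverage_median", "compilation_id")

## In-memory junction columns (packed list and compilation_id are
## serialization-only; coverages live in a separate long table).
JX_MEM_COLUMNS <- setdiff(JX_COLUMNS, c("samples", "compilation_id"))

## Summary columns recomputable over a sample subset.
SUMMARY_COLUMNS <- c("samples_count", "coverage_sum", "coverage_avg",
                     "coverage_median")

## Tolerance for verifying stored coverage_avg/coverage_median in strict
## mode: half a unit of the fixed 2-decimal serialization, plus rounding slack.
STRICT_FLOAT_TOL <- 0.005 + 1e-9

#' Construct a junction set
#'
#' Bundles a junction table (one row per junction, coordinates 1-based and
#' fully closed on the intron) with its long-format coverage table
#' (`junction_id`, `sample_id`, `coverage`; absence means zero coverage, so
#' all stored coverage values are >= 1). Junctions are kept sorted by
#' (chrom, start, end, strand, junction_id) and summaries are recomputed
#' from the coverages.
#'
#' @param junctions data.table/data.frame with at least junction_id, chrom,
#'   start, end, strand; annotation and motif columns are filled with
#'   defaults when absent.
#' @param coverages data.table/data.frame with junction_id, sample_id,
#'   coverage (all integer, coverage >= 1).
#' @return an object of class `jx_table`.
#' @export
jx_table <- function(junctions, coverages) {
  j <- as.data.table(junctions)
  cov <- as.data.table(coverages)
  defaults <- list(length = NA_integer_, annotated = "0", left_motif = "GT",
                   right_motif = "AG", left_annotated = "0",
                   right_annotated = "0")
  for (col in names(defaults)) {
    if (!col %in% names(j)) set(j, j = col, value = defaults[[col]])
  }
  j$junction_id <- as.integer(j$junction_id)
  j$start <- as.integer(j$start)
  j$end <- as.integer(j$end)
  if (anyNA(j$junction_id) || any(j$junction_id < 0L))
    stop("junction_id must be a non-negative integer", call. = FALSE)
  if (anyDuplicated(j$junction_id))
    stop("duplicate junction_id values", call. = FALSE)
  if (any(j$start > j$end))
    stop("junction start must be <= end (1-based closed intron interval)",
         call. = FALSE)
  if (!all(j$strand %in% c("+", "-", "?")))
    stop("strand must be one of '+', '-', '?'", call. = FALSE)
  dup <- duplicated(j, by = c("chrom", "start", "end", "strand")) |
    duplicated(j, by = c("chrom", "start", "end", "strand"), fromLast = TRUE)
  if (any(dup)) {
    ids <- j$junction_id[dup]
    stop(sprintf("duplicate junction coordinates (chrom,start,end,strand); junction_ids: %s",
                 paste(sort(ids), collapse = ", ")), call. = FALSE)
  }
  j$length <- j$end - j$start + 1L
  cov$junction_id <- as.integer(cov$junction_id)
  cov$sample_id <- as.integer(cov$sample_id)
  cov$coverage <- as.integer(cov$coverage)
  if (nrow(cov)) {
    if (any(cov$coverage < 1L))
      stop("coverage values must be >= 1 (absence encodes zero)", call. = FALSE)
    if (!all(cov$junction_id %in% j$junction_id))
      stop("coverage rows reference unknown junction_ids", call. = FALSE)
  }
  setorder(j, chrom, start, end, strand, junction_id)
  sm <- summarize_coverages(cov, j$junction_id)
  for (col in SUMMARY_COLUMNS) set(j, j = col, value = sm[[col]])
  setcolorder(j, JX_MEM_COLUMNS)
  setkey(cov, junction_id, sample_id)
  structure(list(junctions = j, coverages = cov), class = "jx_table")
}

#' @export
print.jx_table <- function(x, ...) {
  cat(sprintf("<jx_table> %d junctions, %d coverage entries, %d distinct samples\n",
              nrow(x$junctions), nrow(x$coverages),
              length(unique(x$coverages$sample_id))))
  invisible(x)
}

#' Load a junction table
#'
#' Reads the tab-separated 17-column junction dialect (see package overview).
#' Coverages are parsed from the packed sample list; summary columns are
#' verified against the parsed coverages in strict mode (exactly for counts
#' and sums, to serialization precision for averages and medians) and
#' recomputed silently in lax mode. Rows are sorted genomically.
#'
#' @param path file path.
#' @param strict logical; fail on summary/length mismatches (default) instead
#'   of recomputing silently.
#' @return a [jx_table].
#' @export
load_junction_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) > 0L && startsWith(first, "#")
  raw <- fread(path, sep = "\t", header = FALSE, skip = if (has_header) 1L else 0L,
               colClasses = "character", quote = "")
  if (ncol(raw) != length(JX_COLUMNS))
    stop(sprintf("expected %d tab-separated columns, found %d",
                 length(JX_COLUMNS), ncol(raw)), call. = FALSE)
  setnames(raw, JX_COLUMNS)
  lines <- seq_len(nrow(raw)) + as.integer(has_header)

  to_int <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- is.na(v) & nzchar(raw[[col]]) & !is.na(raw[[col]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("malformed integer %s at line %d (column '%s')",
                   sQuote(raw[[col]][i]), lines[i], col), call. = FALSE)
    }
    v
  }
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & nzchar(raw[[col]]) & !is.na(raw[[col]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("malformed number %s at line %d (column '%s')",
                   sQuote(raw[[col]][i]), lines[i], col), call. = FALSE)
    }
    v
  }

  jid <- to_int("junction_id")
  st <- to_int("start"); en <- to_int("end")
  if (anyNA(jid) || anyNA(st) || anyNA(en)) {
    i <- which(is.na(jid) | is.na(st) | is.na(en))[1L]
    stop(sprintf("missing junction_id/start/end at line %d", lines[i]), call. = FALSE)
  }
  if (any(st > en)) {
    i <- which(st > en)[1L]
    stop(sprintf("start > end at line %d (columns 'start','end')", lines[i]),
         call. = FALSE)
  }
  if (!all(raw$strand %in% c("+", "-", "?"))) {
    i <- which(!raw$strand %in% c("+", "-", "?"))[1L]
    stop(sprintf("invalid strand %s at line %d (column 'strand')",
                 sQuote(raw$strand[i]), lines[i]), call. = FALSE)
  }
  if (anyDuplicated(jid))
    stop("duplicate junction_id values", call. = FALSE)
  pos <- paste(raw$chrom, st, en, raw$strand, sep = "\r")
  if (anyDuplicated(pos)) {
    d <- pos[duplicated(pos)][1L]
    ids <- jid[pos == d]
    stop(sprintf("duplicate junction coordinates at junction_ids %s",
                 paste(ids, collapse = " and ")), call. = FALSE)
  }

  cov <- parse_packed_coverages(raw$samples, jid, lines)
  sm <- summarize_coverages(cov, jid)

  if (strict) {
    check_exact <- function(col, stated, expected) {
      has <- nzchar(raw[[col]]) & !is.na(raw[[col]])
      bad <- has & (is.na(stated) | stated != expected)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop(sprintf(
          "strict load: stated %s (%s) disagrees with coverages (%s) at line %d, junction_id %d",
          col, format(stated[i]), format(expected[i]), lines[i], jid[i]),
          call. = FALSE)
      }
    }
    check_tol <- function(col, stated, expected) {
      has <- nzchar(raw[[col]]) & !is.na(raw[[col]])
      bad <- has & (is.na(stated) | abs(stated - expected) > STRICT_FLOAT_TOL)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop(sprintf(
          "strict load: stated %s (%s) disagrees with coverages (%s) at line %d, junction_id %d",
          col, format(stated[i]), format(expected[i]), lines[i], jid[i]),
          call. = FALSE)
      }
    }
    check_exact("samples_count", to_int("samples_count"), sm$samples_count)
    check_exact("coverage_sum", to_num("coverage_sum"), sm$coverage_sum)
    check_tol("coverage_avg", to_num("coverage_avg"), sm$coverage_avg)
    check_tol("coverage_median", to_num("coverage_median"), sm$coverage_median)
    len <- to_int("length")
    has <- nzchar(raw$length) & !is.na(raw$length)
    bad <- has & (is.na(len) | len != en - st + 1L)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("strict load: stated length disagrees with end-start+1 at line %d",
                   lines[i]), call. = FALSE)
    }
  }

  j <- data.table(junction_id = jid, chrom = raw$chrom, start = st, end = en,
                  strand = raw$strand, annotated = raw$annotated,
                  left_motif = raw$left_motif, right_motif = raw$right_motif,
                  left_annotated = raw$left_annotated,
                  right_annotated = raw$right_annotated)
  jx_table(j, cov)
}

#' Write a junction table
#'
#' Serializes a [jx_table] to the canonical on-disk dialect: genomically
#' sorted rows, normalized packed coverage lists, averages and medians with
#' exactly two decimals. `load_junction_table()` followed by
#' `write_junction_table()` is byte-stable.
#'
#' @param x a [jx_table] (or the junction part of a [compilation]).
#' @param path output file path.
#' @param compilation_id text stamped in the last column (default "synthetic").
#' @export
write_junction_table <- function(x, path, compilation_id = "synthetic") {
  stopifnot(inherits(x, "jx_table"))
  j <- x$junctions
  packed <- format_packed_coverages(x$coverages, j$junction_id)
  packed[is.na(packed)] <- ","
  lines <- paste(
    j$junction_id, j$chrom, j$start, j$end, j$length, j$strand, j$annotated,
    j$left_motif, j$right_motif, j$left_annotated, j$right_annotated,
    packed, j$samples_count,
    format(j$coverage_sum, trim = TRUE, scientific = FALSE, drop0trailing = TRUE),
    sprintf("%.2f", j$coverage_avg), sprintf("%.2f", j$coverage_median),
    compilation_id, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#", paste(JX_COLUMNS, collapse = "\t")), lines),
             con, sep = "\n")
  invisible(path)
}

#' Load a sample-metadata table
#'
#' Tab-separated with a header row; the sample-id column (first by
#' convention) must hold unique non-negative integers. All other fields are
#' kept as text; missing values become empty strings.
#'
#' @param path file path.
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @return data.table with integer `sample_id` first, all other columns
#'   character.
#' @export
load_sample_metadata <- function(path, id_column = "sample_id") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               quote = "")
  if (!id_column %in% names(raw))
    stop(sprintf("sample metadata lacks the declared id column '%s'", id_column),
         call. = FALSE)
  idtxt <- raw[[id_column]]
  bad <- !grepl("^[0-9]+$", idtxt)
  if (any(bad))
    stop(sprintf("non-numeric sample id %s in column '%s'",
                 sQuote(idtxt[which(bad)[1L]]), id_column), call. = FALSE)
  ids <- as.integer(idtxt)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  out <- copy(raw)
  set(out, j = id_column, value = NULL)
  for (col in names(out)) {
    v <- out[[col]]
    v[is.na(v)] <- ""
    set(out, j = col, value = v)
  }
  out <- cbind(data.table(sample_id = ids), out)
  setkey(out, sample_id)
  out[]
}

#' Write a sample-metadata table
#' @param samples data.table as returned by [load_sample_metadata()].
#' @param path output file path.
#' @export
write_sample_metadata <- function(samples, path) {
  s <- as.data.table(samples)[order(sample_id)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(s), collapse = "\t"),
               do.call(paste, c(s, sep = "\t"))), con, sep = "\n")
  invisible(path)
}

#' Assemble a compilation
#'
#' @param name compilation name (stamped into query output).
#' @param junctions a [jx_table].
#' @param samples sample-metadata data.table ([load_sample_metadata()]).
#' @return object of class `jx_compilation` with elements `name`,
#'   `junctions`, `coverages`, `samples`.
#' @export
compilation <- function(name, junctions, samples) {
  stopifnot(inherits(junctions, "jx_table"))
  samples <- as.data.table(samples)
  if (!"sample_id" %in% names(samples))
    stop("samples table must have a sample_id column", call. = FALSE)
  covered <- unique(junctions$coverages$sample_id)
  missing <- setdiff(covered, samples$sample_id)
  if (length(missing))
    stop(sprintf("coverages reference sample_ids absent from metadata: %s",
                 paste(head(sort(missing), 5L), collapse = ", ")), call. = FALSE)
  structure(list(name = name, junctions = junctions$junctions,
                 coverages = junctions$coverages, samples = samples),
            class = "jx_compilation")
}

#' @export
print.jx_compilation <- function(x, ...) {
  cat(sprintf("<jx_compilation> '%s': %d junctions, %d samples, %d metadata fields\n",
              x$name, nrow(x$junctions), nrow(x$samples), ncol(x$samples) - 1L))
  invisible(x)
}

#' Recompute junction summaries over a sample subset
#'
#' Restricts every junction's coverages to the admitted sample set and
#' recomputes samples_count, coverage_sum, coverage_avg and coverage_median
#' over the restriction (zeros when the intersection is empty). The input is
#' not modified; the operation is idempotent, and restricted counts and sums
#' never exceed the originals.
#'
#' @param x a [jx_table].
#' @param admitted integer vector of admitted sample ids.
#' @return a new [jx_table] restricted to `admitted`.
#' @export
recompute_summaries <- function(x, admitted) {
  stopifnot(inherits(x, "jx_table"))
  admitted <- as.integer(admitted)
  cov <- x$coverages[sample_id %in% admitted]
  j <- copy(x$junctions)
  sm <- summarize_coverages(cov, j$junction_id)
  for (col in SUMMARY_COLUMNS) set(j, j = col, value = sm[[col]])
  structure(list(junctions = j, coverages = cov), class = "jx_table")
}
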