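## Annotation sets: derive annotated-intron sets from gene annotations (GTF)
## and stamp each junction's annotation status (full / left / right / none,
## with source names).

#' Load an annotation source from a GTF file
#'
#' Derives the annotated-intron set: for each transcript, exons are sorted
#' by coordinate and each consecutive pair contributes the intron
#' `(exon_k.end + 1, exon_{k+1}.start - 1)` (1-based, closed). Introns are
#' deduplicated across transcripts. Splice-site sets record every annotated
#' left (lower) and right (upper) intron boundary per chromosome.
#' Transcripts with overlapping exons are skipped with a warning;
#' single-exon transcripts contribute nothing.
#'
#' @param path GTF file (1-based, closed coordinates) with exon features
#'   carrying transcript ids.
#' @param source_name label recorded for this annotation source.
#' @return object of class `jx_annotation`: `source`, `junctions`
#'   (chrom/start/end triples), `left_sites`, `right_sites`.
#' @export
load_annotation <- function(path, source_name) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (!length(gr))
    stop(sprintf("no exon features in %s", path), call. = FALSE)
  txid <- gr$transcript_id
  if (is.null(txid) || all(is.na(txid)))
    stop("GTF exon features carry no transcript_id", call. = FALSE)
  grd <- as.data.frame(gr)
  ex <- data.table(chrom = as.character(grd$seqnames),
                   start = as.integer(grd$start),
                   end = as.integer(grd$end),
                   tx = as.character(txid))
  ex <- ex[!is.na(tx)]
  setorder(ex, tx, start, end)
  ex[, prev_end := shift(end, type = "lag"), by = tx]
  bad_tx <- unique(ex$tx[!is.na(ex$prev_end) & ex$start <= ex$prev_end])
  if (length(bad_tx)) {
    warning(sprintf("skipping %d transcript(s) with overlapping exons: %s",
                    length(bad_tx),
                    paste(head(bad_tx, 5L), collapse = ", ")), call. = FALSE)
    ex <- ex[!tx %in% bad_tx]
  }
  introns <- ex[, {
    if (.N < 2L) {
      list(chrom = character(0), istart = integer(0), iend = integer(0))
    } else {
      list(chrom = chrom[-.N], istart = end[-.N] + 1L, iend = start[-1L] - 1L)
    }
  }, by = tx][, tx := NULL]
  introns <- unique(introns[istart <= iend])
  setnames(introns, c("istart", "iend"), c("start", "end"))
  setorder(introns, chrom, start, end)
  structure(list(source = source_name,
                 junctions = introns,
                 left_sites = unique(introns[, .(chrom, pos = start)]),
                 right_sites = unique(introns[, .(chrom, pos = end)])),
            class = "jx_annotation")
}

#' @export
print.jx_annotation <- function(x, ...) {
  cat(sprintf("<jx_annotation> '%s': %d introns, %d left / %d right splice sites\n",
              x$source, nrow(x$junctions), nrow(x$left_sites),
              nrow(x$right_sites)))
  invisible(x)
}

#' Stamp junction annotation status
#'
#' For every junction and every annotation source: `annotated` collects the
#' sources containing the exact (chrom, start, end) intron;
#' `left_annotated` / `right_annotated` collect the sources whose left
#' (resp. right) splice-site set contains the junction's start (resp. end)
#' coordinate. Sides are named in genomic coordinate order (left = lower
#' coordinate), not donor/acceptor order, so strand `?` is unambiguous.
#' Multiple sources are unioned, never prioritized; sets serialize as
#' comma-joined source names, `"0"` when empty. A full match implies both
#' side matches, so `annotated` is always a subset of
#' `left_annotated` intersect `right_annotated`; annotating twice with the
#' same sets is idempotent.
#'
#' @param x a [jx_table] or [compilation].
#' @param sets a `jx_annotation` or list of them.
#' @return a new object of the same class with the three annotation columns
#'   replaced.
#' @export
annotate_junctions <- function(x, sets) {
  if (inherits(sets, "jx_annotation")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1L), "jx_annotation")))
  is_comp <- inherits(x, "jx_compilation")
  j <- copy(as_jx_table(x)$junctions)
  full <- vector("list", length(sets))
  left <- vector("list", length(sets))
  right <- vector("list", length(sets))
  key_full <- paste(j$chrom, j$start, j$end, sep = "\r")
  key_left <- paste(j$chrom, j$start, sep = "\r")
  key_right <- paste(j$chrom, j$end, sep = "\r")
  for (s in seq_along(sets)) {
    a <- sets[[s]]
    full[[s]] <- key_full %in% paste(a$junctions$chrom, a$junctions$start,
                                     a$junctions$end, sep = "\r")
    left[[s]] <- key_left %in% paste(a$left_sites$chrom, a$left_sites$pos,
                                     sep = "\r")
    right[[s]] <- key_right %in% paste(a$right_sites$chrom, a$right_sites$pos,
                                       sep = "\r")
  }
  join_sources <- function(hits) {
    nm <- vapply(sets, `[[`, character(1L), "source")
    out <- vapply(seq_len(nrow(j)), function(i) {
      src <- nm[vapply(hits, `[`, logical(1L), i)]
      if (length(src)) paste(src, collapse = ",") else "0"
    }, character(1L))
    out
  }
  set(j, j = "annotated", value = join_sources(full))
  set(j, j = "left_annotated", value = join_sources(left))
  set(j, j = "right_annotated", value = join_sources(right))
  if (is_comp) {
    out <- x
    out$junctions <- j
    out
  } else {
    structure(list(junctions = j, coverages = x$coverages), class = "jx_table")
  }
}
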