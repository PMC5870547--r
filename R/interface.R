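## Command-line interface: build, basic queries, and the four high-level
## queries, with bit-exact TSV output. The installed entry point is
## inst/cli/sjq.R, a thin Rscript over sjq_main(); tests call sjq_main()
## in-process. Output conventions (fixed for golden-file testing): floating
## summaries with 2 decimal places, scores and p-values with 6 significant
## digits, no timestamps in any data stream.

fmt_score <- function(x) formatC(x, digits = 6L, format = "g", width = 1L)

#' Write a query result as TSV
#'
#' One row per junction: a `datasource` column naming the compilation, then
#' the 17 junction-table columns (packed coverage list rebuilt from the
#' result's possibly restricted coverages; averages and medians with 2
#' decimals). Header row first. An empty result yields a header-only file.
#'
#' @param res a `jx_result`.
#' @param datasource compilation name for the first and last columns.
#' @param path output path.
#' @export
write_result_tsv <- function(res, datasource, path) {
  stopifnot(inherits(res, "jx_result"))
  j <- res$junctions
  header <- paste0("#", paste(c("datasource", JX_COLUMNS), collapse = "\t"))
  if (!nrow(j)) {
    writeLines(header, path, sep = "\n")
    return(invisible(path))
  }
  packed <- format_packed_coverages(res$coverages, j$junction_id)
  packed[is.na(packed)] <- ","
  lines <- paste(
    datasource, j$junction_id, j$chrom, j$start, j$end, j$length, j$strand,
    j$annotated, j$left_motif, j$right_motif, j$left_annotated,
    j$right_annotated, packed, j$samples_count,
    format(j$coverage_sum, trim = TRUE, scientific = FALSE,
           drop0trailing = TRUE),
    sprintf("%.2f", j$coverage_avg), sprintf("%.2f", j$coverage_median),
    datasource, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

## --- argument parsing -------------------------------------------------------

parse_cli_flags <- function(argv) {
  flags <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (key %in% c("explain", "strict", "lax")) {  # boolean flags
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(argv))
          stop(sprintf("flag --%s needs a value", key), call. = FALSE)
        flags[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

need_flag <- function(args, key) {
  v <- args$flags[[key]]
  if (is.null(v)) stop(sprintf("missing required flag --%s", key), call. = FALSE)
  v
}

## Load a compilation directory (junctions.tsv + samples.tsv), preferring a
## persisted index file when present and current.
load_compilation_dir <- function(dir, strict = TRUE, name = NULL) {
  jpath <- file.path(dir, "junctions.tsv")
  spath <- file.path(dir, "samples.tsv")
  if (!file.exists(jpath))
    stop(sprintf("missing junction table: %s", jpath), call. = FALSE)
  if (!file.exists(spath))
    stop(sprintf("missing sample metadata: %s", spath), call. = FALSE)
  jx <- load_junction_table(jpath, strict = strict)
  samples <- load_sample_metadata(spath)
  compilation(name %||% basename(normalizePath(dir)), jx, samples)
}

get_indices <- function(dir, strict = TRUE, name = NULL) {
  ipath <- file.path(dir, "indices.rds")
  if (file.exists(ipath)) return(load_indices(ipath))
  build_indices(load_compilation_dir(dir, strict = strict, name = name))
}

## Groups file: one query per line, tab-separated "group<TAB>query string".
## Lines starting with '#' are comments. Queries sharing a group tag form
## one union query group.
read_groups_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such groups file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("groups file is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop(sprintf("groups file line %d lacks a tab-separated group tag and query",
                 which(bad)[1L]), call. = FALSE)
  tags <- vapply(parts, `[`, character(1L), 1L)
  queries <- vapply(parts, function(p) paste(p[-1L], collapse = "\t"),
                    character(1L))
  out <- lapply(split(queries, factor(tags, levels = unique(tags))),
                function(qs) query_group(as.list(qs), "union"))
  out
}

## --- subcommands ------------------------------------------------------------

cmd_generate <- function(args) {
  out_dir <- need_flag(args, "out")
  cfg_args <- list()
  if (!is.null(args$flags$config)) {
    cfg_args <- read_generator_config_file(args$flags$config)
  }
  if (!is.null(args$flags$seed)) cfg_args$seed <- as.integer(args$flags$seed)
  cfg <- do.call(generator_config, cfg_args)
  gen <- generate_compilation(cfg, dir = out_dir)
  message(sprintf("generated %d junctions, %d samples, %d planted event(s) -> %s",
                  nrow(gen$compilation$junctions),
                  nrow(gen$compilation$samples), nrow(gen$truth), out_dir))
  0L
}

## Flat key=value config file; repeated event lines:
##   cassette_event=chrom,up_end,exon_start,exon_end,down_start,inclusion,prevalence
##   tissue_event=chrom,start,end,tissue,prevalence
##   jir_pattern=chromA,startA,endA,chromB,startB,endB,n_outliers,effect
read_generator_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file: %s", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)=(.*)$", lines))
  bad <- lengths(kv) == 0L
  if (any(bad))
    stop(sprintf("malformed config line: %s", sQuote(lines[which(bad)[1L]])),
         call. = FALSE)
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  cfg <- list(cassette_events = list(), tissue_events = list(),
              jir_patterns = list())
  num_keys <- c("seed", "n_samples", "n_background_junctions",
                "annotated_fraction", "coverage_mu", "coverage_size",
                "chrom_length")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% num_keys) cfg[[k]] <- as.numeric(v)
    else if (k == "name") cfg$name <- v
    else if (k %in% c("tissues", "chroms")) {
      cfg[[k]] <- strsplit(v, ",", fixed = TRUE)[[1L]]
    } else if (k == "presence_range") {
      cfg$presence_range <- as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]])
    } else if (k == "cassette_event") {
      p <- strsplit(v, ",", fixed = TRUE)[[1L]]
      cfg$cassette_events <- c(cfg$cassette_events, list(cassette_event(
        p[1L], as.integer(p[2L]), as.integer(p[3L]), as.integer(p[4L]),
        as.integer(p[5L]), as.numeric(p[6L]), as.numeric(p[7L]))))
    } else if (k == "tissue_event") {
      p <- strsplit(v, ",", fixed = TRUE)[[1L]]
      cfg$tissue_events <- c(cfg$tissue_events, list(tissue_specific_event(
        p[1L], as.integer(p[2L]), as.integer(p[3L]), p[4L],
        as.numeric(p[5L]))))
    } else if (k == "jir_pattern") {
      p <- strsplit(v, ",", fixed = TRUE)[[1L]]
      cfg$jir_patterns <- c(cfg$jir_patterns, list(jir_pattern(
        list(chrom = p[1L], start = as.integer(p[2L]), end = as.integer(p[3L])),
        list(chrom = p[4L], start = as.integer(p[5L]), end = as.integer(p[6L])),
        as.integer(p[7L]), as.numeric(p[8L]))))
    } else {
      stop(sprintf("unknown config key '%s'", k), call. = FALSE)
    }
  }
  cfg
}

cmd_build <- function(args) {
  dir <- need_flag(args, "compilation")
  comp <- load_compilation_dir(dir, strict = is.null(args$flags$lax),
                               name = args$flags$name)
  ix <- build_indices(comp)
  save_indices(ix, file.path(dir, "indices.rds"))
  message(sprintf("%d junctions, %d samples", nrow(comp$junctions),
                  nrow(comp$samples)))
  0L
}

cmd_query <- function(args) {
  dir <- need_flag(args, "compilation")
  qtext <- need_flag(args, "query")
  out <- need_flag(args, "out")
  ix <- get_indices(dir, name = args$flags$name)
  p <- plan_query(parse_query(qtext), ix)
  if (isTRUE(args$flags$explain)) {
    for (s in p$steps) message(" - ", s)
  }
  res <- execute_plan(p)
  write_result_tsv(res, ix$comp$name, out)
  message(sprintf("%d junction(s) -> %s", nrow(res$junctions), out))
  0L
}

cmd_ssc <- function(args) {
  ix <- get_indices(need_flag(args, "compilation"), name = args$flags$name)
  groups <- read_groups_file(need_flag(args, "groups"))
  out <- need_flag(args, "out")
  ssc <- shared_sample_count(groups, ix)
  lines <- c("#group\tn_samples\tsample_ids",
             vapply(names(ssc$sample_sets), function(nm) {
               paste(nm, length(ssc$sample_sets[[nm]]),
                     paste(ssc$sample_sets[[nm]], collapse = ","), sep = "\t")
             }, character(1L)),
             sprintf("#shared_count=%d", ssc$shared_count))
  writeLines(lines, out, sep = "\n")
  message(sprintf("shared_count = %d", ssc$shared_count))
  0L
}

cmd_jir <- function(args) {
  ix <- get_indices(need_flag(args, "compilation"), name = args$flags$name)
  groups <- read_groups_file(need_flag(args, "groups"))
  out <- need_flag(args, "out")
  if (!all(c("A", "B") %in% names(groups)))
    stop("jir needs groups tagged 'A' and 'B' in the groups file",
         call. = FALSE)
  scores <- junction_inclusion_ratio(groups$A, groups$B, ix)
  lines <- c("#sample_id\ta\tb\tscore\trank",
             if (nrow(scores)) paste(scores$sample_id,
               format(scores$a, trim = TRUE, scientific = FALSE,
                      drop0trailing = TRUE),
               format(scores$b, trim = TRUE, scientific = FALSE,
                      drop0trailing = TRUE),
               fmt_score(scores$score), scores$rank, sep = "\t"))
  writeLines(lines, out, sep = "\n")
  message(sprintf("%d sample(s) scored", nrow(scores)))
  0L
}

cmd_psi <- function(args) {
  ix <- get_indices(need_flag(args, "compilation"), name = args$flags$name)
  groups <- read_groups_file(need_flag(args, "groups"))
  out <- need_flag(args, "out")
  want <- c("left", "right", "exclusion")
  if (!all(want %in% names(groups)))
    stop("psi needs groups tagged 'left', 'right' and 'exclusion'",
         call. = FALSE)
  min_total <- as.integer(args$flags[["min-total"]] %||% 20L)
  scores <- percent_spliced_in(groups$left, groups$right, groups$exclusion,
                               ix, min_total = min_total)
  lines <- c("#sample_id\tcount_left\tcount_right\tcount_excl\tpsi\trank",
             if (nrow(scores)) paste(scores$sample_id,
               format(scores$count_left, trim = TRUE, drop0trailing = TRUE),
               format(scores$count_right, trim = TRUE, drop0trailing = TRUE),
               format(scores$count_excl, trim = TRUE, drop0trailing = TRUE),
               fmt_score(scores$psi), scores$rank, sep = "\t"))
  writeLines(lines, out, sep = "\n")
  message(sprintf("%d sample(s) scored", nrow(scores)))
  0L
}

cmd_ts <- function(args) {
  ix <- get_indices(need_flag(args, "compilation"), name = args$flags$name)
  groups <- read_groups_file(need_flag(args, "groups"))
  out <- need_flag(args, "out")
  group <- if (length(groups) == 1L) groups[[1L]] else
    query_group(unlist(lapply(groups, `[[`, "queries"), recursive = FALSE),
                "union")
  ts <- tissue_specificity(group, ix,
                           tissue_field = args$flags[["tissue-field"]] %||% "tissue",
                           value_mode = args$flags[["value-mode"]] %||% "presence")
  lines <- c("#tissue\tn\tmean_value",
             paste(ts$table$tissue, ts$table$n,
                   sprintf("%.2f", ts$table$mean_value), sep = "\t"),
             sprintf("#H=%s\tdf=%d\tp=%s", fmt_score(ts$H), ts$df,
                     fmt_score(ts$p)))
  writeLines(lines, out, sep = "\n")
  message(sprintf("H = %s, df = %d, p = %s", fmt_score(ts$H), ts$df,
                  fmt_score(ts$p)))
  0L
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic compilation), `build` (load a
#' compilation directory strictly and persist its indices), `query` (one
#' basic query, TSV out, `--explain` prints the plan), and the high-level
#' queries `ssc`, `jir`, `psi`, `ts` (group definitions read from a
#' declarative groups file, one query per line with a group tag column).
#' Returns the process exit status (0 on success); errors print to stderr
#' and return 1.
#'
#' @param argv character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly usable with `quit(status = )`.
#' @export
sjq_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sjq <subcommand> [flags]",
    "subcommands: generate build query ssc jir psi ts",
    "common flags: --compilation DIR --out PATH --groups FILE --query STR",
    "              --seed INT --config FILE --explain --lax", sep = "\n")
  if (!length(argv)) { message(usage); return(1L) }
  sub <- argv[1L]
  args <- parse_cli_flags(argv[-1L])
  handler <- switch(sub,
    generate = cmd_generate, build = cmd_build, query = cmd_query,
    ssc = cmd_ssc, jir = cmd_jir, psi = cmd_psi, ts = cmd_ts,
    NULL)
  if (is.null(handler)) {
    message(sprintf("unknown subcommand '%s'\n%s", sub, usage))
    return(1L)
  }
  tryCatch(handler(args), error = function(e) {
    message("sjq: ", conditionMessage(e))
    1L
  })
}
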