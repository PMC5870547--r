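## Seeded generator of synthetic compilations (junction table + sample
## metadata + truth table) with planted structure, so every query type and
## every high-level statistic is testable offline. Background junction
## presence per sample is Bernoulli with a per-junction prevalence;
## coverage conditional on presence is 1 + negative binomial (overdispersed,
## matching RNA-seq count behavior). Planted events:
##   - cassette exons: three junctions (two inclusion flanks, one exclusion
##     spanning the exon) with per-sample counts consistent with the
##     event's inclusion rate;
##   - tissue-specific junctions: covered only in samples of the active
##     tissue, at a stated prevalence;
##   - JIR outlier patterns: a pair of constitutively covered junctions
##     where a few outlier samples switch isoform -- their group A
##     (excised) junction loses all coverage and their group B junction is
##     inflated by the effect size, emulating a dramatic variant-isoform
##     signature.

#' Describe a planted cassette-exon event
#'
#' Coordinates are exon boundaries: the upstream exon ends at `up_end`, the
#' cassette exon spans `[exon_start, exon_end]`, the downstream exon starts
#' at `down_start`. The event emits the two inclusion-flank introns
#' `(up_end+1, exon_start-1)` and `(exon_end+1, down_start-1)` and the
#' exclusion intron `(up_end+1, down_start-1)`. Expressing samples (chosen
#' with probability `prevalence`) draw a read depth `1 + NB(depth_mu,
#' depth_size)` split binomially between inclusion and exclusion with the
#' (optionally per-tissue) `inclusion` rate.
#'
#' @param chrom,up_end,exon_start,exon_end,down_start event coordinates
#'   (1-based; `up_end + 2 <= exon_start`, `exon_end + 2 <= down_start`).
#' @param inclusion scalar inclusion rate in `[0,1]`, or a named vector of
#'   per-tissue rates.
#' @param prevalence fraction of samples expressing the event.
#' @param depth_mu,depth_size negative-binomial read depth parameters.
#' @return list of class `jx_event_cassette`.
#' @export
cassette_event <- function(chrom, up_end, exon_start, exon_end, down_start,
                           inclusion = 0.5, prevalence = 0.8,
                           depth_mu = 19, depth_size = 4) {
  stopifnot(up_end + 2L <= exon_start, exon_end + 2L <= down_start,
            exon_start <= exon_end,
            all(inclusion >= 0), all(inclusion <= 1),
            prevalence >= 0, prevalence <= 1)
  structure(list(chrom = chrom, up_end = as.integer(up_end),
                 exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end),
                 down_start = as.integer(down_start),
                 inclusion = inclusion, prevalence = prevalence,
                 depth_mu = depth_mu, depth_size = depth_size),
            class = "jx_event_cassette")
}

#' Describe a planted tissue-specific junction
#'
#' @param chrom,start,end intron coordinates (1-based, closed).
#' @param tissue the active tissue; only its samples can be covered.
#' @param prevalence fraction of active-tissue samples covered.
#' @param depth_mu,depth_size negative-binomial coverage parameters.
#' @return list of class `jx_event_tissue`.
#' @export
tissue_specific_event <- function(chrom, start, end, tissue,
                                  prevalence = 0.6,
                                  depth_mu = 7, depth_size = 2) {
  stopifnot(start <= end, prevalence >= 0, prevalence <= 1)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), tissue = tissue,
                 prevalence = prevalence, depth_mu = depth_mu,
                 depth_size = depth_size),
            class = "jx_event_tissue")
}

#' Describe a planted JIR outlier pattern
#'
#' Junctions A and B are covered in every sample with coverage
#' `1 + NB(base_mu, base_size)`. `n_outliers` samples switch isoform:
#' their junction A coverage is removed entirely and their junction B
#' coverage is multiplied by `effect`.
#'
#' @param junctionA,junctionB each `list(chrom=, start=, end=)`.
#' @param n_outliers number of outlier samples.
#' @param effect multiplicative inflation of group B coverage in outliers.
#' @param base_mu,base_size negative-binomial baseline coverage parameters.
#' @return list of class `jx_event_jir`.
#' @export
jir_pattern <- function(junctionA, junctionB, n_outliers = 3L, effect = 10,
                        base_mu = 19, base_size = 4) {
  stopifnot(n_outliers >= 1L, effect > 1)
  structure(list(junctionA = junctionA, junctionB = junctionB,
                 n_outliers = as.integer(n_outliers), effect = effect,
                 base_mu = base_mu, base_size = base_size),
            class = "jx_event_jir")
}

#' Generator configuration
#'
#' Defaults describe a mid-sized multi-tissue cohort: 200 samples over four
#' tissues, 1000 background junctions with per-junction sample prevalence
#' uniform on `presence_range`, and overdispersed coverage
#' `1 + NB(coverage_mu, coverage_size)` conditional on presence.
#'
#' @param seed RNG seed; generation is deterministic (byte-identical) for a
#'   fixed seed.
#' @param n_samples number of samples.
#' @param tissues tissue labels; `tissue_weights` are sampling weights
#'   (default uniform).
#' @param n_background_junctions background (unplanted) junction count.
#' @param annotated_fraction fraction of background junctions stamped as
#'   fully annotated by the synthetic source.
#' @param coverage_mu,coverage_size negative-binomial coverage parameters
#'   (coverage = 1 + NB, so the mean is `coverage_mu + 1`).
#' @param presence_range range of the per-junction Bernoulli presence
#'   probability.
#' @param cassette_events,tissue_events,jir_patterns lists of planted
#'   events ([cassette_event()], [tissue_specific_event()],
#'   [jir_pattern()]).
#' @param chroms,chrom_length background coordinate space.
#' @param tissue_weights sampling weights for `tissues`.
#' @param name compilation name.
#' @return validated list of class `jx_genconfig`.
#' @export
generator_config <- function(seed = 1L, n_samples = 200L,
                             tissues = c("brain", "liver", "heart", "kidney"),
                             tissue_weights = NULL,
                             n_background_junctions = 1000L,
                             annotated_fraction = 0.5,
                             coverage_mu = 7, coverage_size = 2,
                             presence_range = c(0.1, 0.8),
                             cassette_events = list(),
                             tissue_events = list(),
                             jir_patterns = list(),
                             chroms = c("chr1", "chr2"),
                             chrom_length = 1e7,
                             name = "synth") {
  stopifnot(n_samples >= 1L, length(tissues) >= 1L,
            n_background_junctions >= 0L,
            annotated_fraction >= 0, annotated_fraction <= 1,
            coverage_mu > 0, coverage_size > 0,
            length(presence_range) == 2L,
            all(presence_range >= 0), all(presence_range <= 1))
  if (inherits(cassette_events, "jx_event_cassette"))
    cassette_events <- list(cassette_events)
  if (inherits(tissue_events, "jx_event_tissue"))
    tissue_events <- list(tissue_events)
  if (inherits(jir_patterns, "jx_event_jir"))
    jir_patterns <- list(jir_patterns)
  for (ev in tissue_events)
    if (!ev$tissue %in% tissues)
      stop(sprintf("tissue-specific event names unknown tissue '%s'",
                   ev$tissue), call. = FALSE)
  cfg <- structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    tissues = tissues,
    tissue_weights = tissue_weights %||% rep(1, length(tissues)),
    n_background_junctions = as.integer(n_background_junctions),
    annotated_fraction = annotated_fraction,
    coverage_mu = coverage_mu, coverage_size = coverage_size,
    presence_range = presence_range,
    cassette_events = cassette_events, tissue_events = tissue_events,
    jir_patterns = jir_patterns,
    chroms = chroms, chrom_length = chrom_length, name = name),
    class = "jx_genconfig")
  key <- planted_coord_keys(cfg)
  if (anyDuplicated(key))
    stop("planted event junction coordinates collide with each other",
         call. = FALSE)
  cfg
}

## Coordinate keys (chrom:start:end) of all planted junctions.
planted_coord_keys <- function(cfg) {
  keys <- character(0)
  for (ev in cfg$cassette_events) {
    keys <- c(keys,
      paste(ev$chrom, ev$up_end + 1L, ev$exon_start - 1L, sep = ":"),
      paste(ev$chrom, ev$exon_end + 1L, ev$down_start - 1L, sep = ":"),
      paste(ev$chrom, ev$up_end + 1L, ev$down_start - 1L, sep = ":"))
  }
  for (ev in cfg$tissue_events)
    keys <- c(keys, paste(ev$chrom, ev$start, ev$end, sep = ":"))
  for (ev in cfg$jir_patterns) {
    keys <- c(keys,
      paste(ev$junctionA$chrom, ev$junctionA$start, ev$junctionA$end, sep = ":"),
      paste(ev$junctionB$chrom, ev$junctionB$start, ev$junctionB$end, sep = ":"))
  }
  keys
}

#' Generate a synthetic compilation
#'
#' Deterministic for a fixed seed (two runs produce byte-identical files).
#' The truth table records every planted event with its coordinates and the
#' affected sample ids, so tests and acceptance workflows can bind
#' expectations to the plan. Background junctions whose coordinates collide
#' with a planted event (or each other) are redrawn, with a message.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory; when given, writes
#'   `junctions.tsv`, `samples.tsv` and `truth.tsv` there.
#' @return list with `compilation` (a [compilation]), `truth` (data.table),
#'   `config`, and `paths` (when `dir` was given).
#' @export
generate_compilation <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "jx_genconfig"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    samples <- data.table(
      sample_id = seq_len(n),
      tissue = sample(cfg$tissues, n, replace = TRUE,
                      prob = cfg$tissue_weights),
      study = sample(c("studyA", "studyB", "studyC"), n, replace = TRUE))
    samples[, description := paste("RNA-seq of", tissue, "tissue sample",
                                   sample_id, "from", study)]

    planted <- planted_junctions(cfg, samples)
    background <- background_junctions(cfg, planted$keys)

    jdt <- rbindlist(list(background$junctions, planted$junctions),
                     use.names = TRUE)
    cov <- rbindlist(list(background$coverages, planted$coverages),
                     use.names = TRUE)
    ## a compilation holds only evidenced junctions: drop any junction that
    ## no sample ended up covering (e.g. the exclusion junction of a
    ## cassette event at inclusion rate 1.0)
    jdt <- jdt[tmp_id %in% unique(cov$junction_id)]
    ## positional ids in genomic order
    setorder(jdt, chrom, start, end, strand)
    old_id <- jdt$tmp_id
    jdt[, junction_id := seq_len(.N)]
    cov[, junction_id := jdt$junction_id[match(junction_id, old_id)]]
    jdt[, tmp_id := NULL]

    jx <- jx_table(jdt, cov)
    comp <- compilation(cfg$name, jx, samples)
    truth <- planted$truth
    truth[, event_id := paste0(event_type, "_", seq_len(.N)), by = event_type]
    setcolorder(truth, c("event_id", "event_type", "chrom", "start", "end",
                         "tissue", "params", "samples"))

    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(junctions = file.path(dir, "junctions.tsv"),
                    samples = file.path(dir, "samples.tsv"),
                    truth = file.path(dir, "truth.tsv"))
      write_junction_table(jx, paths$junctions, compilation_id = cfg$name)
      write_sample_metadata(samples, paths$samples)
      con <- file(paths$truth, open = "wb")
      writeLines(c(paste(names(truth), collapse = "\t"),
                   if (nrow(truth)) do.call(paste, c(truth, sep = "\t"))),
                 con, sep = "\n")
      close(con)
    }
    list(compilation = comp, truth = truth, config = cfg, paths = paths)
  })
}

## Background junctions: random coordinates (redrawn on collision), random
## strand, Bernoulli presence, 1 + NB coverage. Uses temporary ids.
background_junctions <- function(cfg, forbidden_keys) {
  nj <- cfg$n_background_junctions
  if (nj == 0L) {
    return(list(
      junctions = data.table(tmp_id = integer(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0), annotated = character(0),
                             left_annotated = character(0),
                             right_annotated = character(0)),
      coverages = data.table(junction_id = integer(0), sample_id = integer(0),
                             coverage = integer(0))))
  }
  draw <- function(m) {
    data.table(chrom = sample(cfg$chroms, m, replace = TRUE),
               start = sample.int(as.integer(cfg$chrom_length - 60000L), m,
                                  replace = TRUE) + 10000L,
               len = sample(50:20000, m, replace = TRUE),
               strand = sample(c("+", "-"), m, replace = TRUE))
  }
  jd <- draw(nj)
  jd[, end := start + len - 1L]
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  repeat {
    k <- key(jd)
    bad <- duplicated(k) | k %in% forbidden_keys
    if (!any(bad)) break
    message(sprintf("regenerating %d background junction(s) colliding with planted or existing coordinates",
                    sum(bad)))
    rd <- draw(sum(bad))
    rd[, end := start + len - 1L]
    jd[bad, c("chrom", "start", "end", "len", "strand") :=
         rd[, .(chrom, start, end, len, strand)]]
  }
  jd[, len := NULL]
  jd[, tmp_id := seq_len(.N)]
  ## annotation stamp: a fraction fully annotated by the synthetic sources
  ## (a core source plus a permissive one that also covers extra events),
  ## some left-only / right-only partial matches among the rest
  u <- runif(nj)
  ann <- character(nj); lann <- character(nj); rann <- character(nj)
  full <- u < cfg$annotated_fraction
  permissive <- full & runif(nj) < 0.5
  ann[] <- "0"; lann[] <- "0"; rann[] <- "0"
  ann[full] <- ifelse(permissive[full], "refgenes,permgenes", "refgenes")
  lann[full] <- ann[full]; rann[full] <- ann[full]
  partial <- !full & u < cfg$annotated_fraction + 0.1
  lann[partial] <- "permgenes"
  partial2 <- !full & !partial & u < cfg$annotated_fraction + 0.2
  rann[partial2] <- "permgenes"
  jd[, `:=`(annotated = ann, left_annotated = lann, right_annotated = rann)]

  pj <- runif(nj, cfg$presence_range[1L], cfg$presence_range[2L])
  pres <- matrix(runif(nj * cfg$n_samples) < pj, nrow = nj)  # recycles by row
  idx <- which(pres, arr.ind = TRUE)
  cover <- 1L + rnbinom(nrow(idx), size = cfg$coverage_size,
                        mu = cfg$coverage_mu)
  cov <- data.table(junction_id = idx[, 1L], sample_id = idx[, 2L],
                    coverage = as.integer(cover))
  setorder(cov, junction_id, sample_id)
  list(junctions = jd[, .(tmp_id, chrom, start, end, strand, annotated,
                          left_annotated, right_annotated)],
       coverages = cov)
}

## Planted junctions, coverages and the truth table. Temporary ids continue
## after the background block.
planted_junctions <- function(cfg, samples) {
  n <- cfg$n_samples
  next_id <- cfg$n_background_junctions
  jrows <- list(); crows <- list(); trows <- list()
  add_junction <- function(chrom, start, end) {
    next_id <<- next_id + 1L
    jrows[[length(jrows) + 1L]] <<- data.table(
      tmp_id = next_id, chrom = chrom, start = as.integer(start),
      end = as.integer(end), strand = "+", annotated = "0",
      left_annotated = "0", right_annotated = "0")
    next_id
  }
  add_cov <- function(id, sample_ids, coverage) {
    keep <- coverage >= 1L
    if (!any(keep)) return(invisible())
    crows[[length(crows) + 1L]] <<- data.table(
      junction_id = id, sample_id = sample_ids[keep],
      coverage = as.integer(coverage[keep]))
  }

  for (ev in cfg$cassette_events) {
    idL <- add_junction(ev$chrom, ev$up_end + 1L, ev$exon_start - 1L)
    idR <- add_junction(ev$chrom, ev$exon_end + 1L, ev$down_start - 1L)
    idE <- add_junction(ev$chrom, ev$up_end + 1L, ev$down_start - 1L)
    expr <- which(runif(n) < ev$prevalence)
    depth <- 1L + rnbinom(length(expr), size = ev$depth_size, mu = ev$depth_mu)
    rate <- if (length(ev$inclusion) > 1L) {
      unname(ev$inclusion[samples$tissue[expr]])
    } else rep(ev$inclusion, length(expr))
    incl <- rbinom(length(expr), depth, rate)
    excl <- depth - incl
    add_cov(idL, expr, incl)
    add_cov(idR, expr, incl)
    add_cov(idE, expr, excl)
    trows[[length(trows) + 1L]] <- data.table(
      event_type = "cassette", chrom = ev$chrom, start = ev$exon_start,
      end = ev$exon_end, tissue = "",
      params = sprintf("up_end=%d;down_start=%d;inclusion=%s;prevalence=%g;n_inclusion_samples=%d",
                       ev$up_end, ev$down_start,
                       paste(format(ev$inclusion), collapse = "|"),
                       ev$prevalence, sum(incl > 0L)),
      samples = paste(expr[incl > 0L], collapse = ","))
  }

  for (ev in cfg$tissue_events) {
    id <- add_junction(ev$chrom, ev$start, ev$end)
    active <- samples$sample_id[samples$tissue == ev$tissue]
    covered <- active[runif(length(active)) < ev$prevalence]
    add_cov(id, covered,
            1L + rnbinom(length(covered), size = ev$depth_size,
                         mu = ev$depth_mu))
    trows[[length(trows) + 1L]] <- data.table(
      event_type = "tissue_specific", chrom = ev$chrom, start = ev$start,
      end = ev$end, tissue = ev$tissue,
      params = sprintf("prevalence=%g;n_covered=%d", ev$prevalence,
                       length(covered)),
      samples = paste(covered, collapse = ","))
  }

  for (ev in cfg$jir_patterns) {
    idA <- add_junction(ev$junctionA$chrom, ev$junctionA$start,
                        ev$junctionA$end)
    idB <- add_junction(ev$junctionB$chrom, ev$junctionB$start,
                        ev$junctionB$end)
    base_a <- 1L + rnbinom(n, size = ev$base_size, mu = ev$base_mu)
    base_b <- 1L + rnbinom(n, size = ev$base_size, mu = ev$base_mu)
    outliers <- sort(sample.int(n, ev$n_outliers))
    base_a[outliers] <- 0L                       # excised junction vanishes
    base_b[outliers] <- as.integer(round(base_b[outliers] * ev$effect))
    add_cov(idA, seq_len(n), base_a)
    add_cov(idB, seq_len(n), base_b)
    trows[[length(trows) + 1L]] <- data.table(
      event_type = "jir_pattern", chrom = ev$junctionA$chrom,
      start = ev$junctionA$start, end = ev$junctionA$end, tissue = "",
      params = sprintf("junctionB=%s:%d-%d;effect=%g;n_outliers=%d",
                       ev$junctionB$chrom, ev$junctionB$start,
                       ev$junctionB$end, ev$effect, ev$n_outliers),
      samples = paste(outliers, collapse = ","))
  }

  empty_truth <- data.table(event_type = character(0), chrom = character(0),
                            start = integer(0), end = integer(0),
                            tissue = character(0), params = character(0),
                            samples = character(0))
  list(
    junctions = if (length(jrows)) rbindlist(jrows) else
      data.table(tmp_id = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 annotated = character(0), left_annotated = character(0),
                 right_annotated = character(0)),
    coverages = if (length(crows)) rbindlist(crows) else
      data.table(junction_id = integer(0), sample_id = integer(0),
                 coverage = integer(0)),
    truth = if (length(trows)) rbindlist(trows) else empty_truth,
    keys = planted_coord_keys(cfg))
}

#' Derive qualitative expectations from a truth table
#'
#' Binds the generator's planted events to checkable queries: a planted
#' tissue-specific junction yields a TS query expected to reject at
#' p < 0.01; a JIR pattern yields the two group queries with its outliers
#' expected in the top ranks; a cassette exon yields the two
#' splice-site-anchored SSC flank queries with the shared count expected to
#' reach the planted inclusion-sample count.
#'
#' @param truth truth data.table from [generate_compilation()].
#' @return data.table(event_id, query_type, query, expectation); empty
#'   truth yields an empty table.
#' @export
expected_truth_queries <- function(truth) {
  truth <- as.data.table(truth)
  out <- list()
  param_value <- function(params, key) {
    sub(sprintf(".*%s=([^;]*).*", key), "\\1", params)
  }
  for (i in seq_len(nrow(truth))) {
    row <- truth[i]
    if (row$event_type == "tissue_specific") {
      out[[length(out) + 1L]] <- data.table(
        event_id = row$event_id, query_type = "ts",
        query = sprintf("region=%s:%d-%d:exact", row$chrom, row$start, row$end),
        expectation = "kw_p<0.01")
    } else if (row$event_type == "jir_pattern") {
      qB <- param_value(row$params, "junctionB")
      n_out <- length(strsplit(row$samples, ",", fixed = TRUE)[[1L]])
      out[[length(out) + 1L]] <- data.table(
        event_id = row$event_id, query_type = "jir",
        query = sprintf("A: region=%s:%d-%d:exact | B: region=%s:exact",
                        row$chrom, row$start, row$end, qB),
        expectation = sprintf("outliers_in_top_%d", n_out))
    } else if (row$event_type == "cassette") {
      n_incl <- as.integer(param_value(row$params, "n_inclusion_samples"))
      left_site <- row$start - 1L
      right_site <- row$end + 1L
      out[[length(out) + 1L]] <- data.table(
        event_id = row$event_id, query_type = "ssc",
        query = sprintf("region=%s:%d-%d:end_equals | region=%s:%d-%d:start_equals",
                        row$chrom, left_site, left_site,
                        row$chrom, right_site, right_site),
        expectation = sprintf("shared_count>=%d", n_incl))
    }
  }
  if (!length(out)) {
    return(data.table(event_id = character(0), query_type = character(0),
                      query = character(0), expectation = character(0)))
  }
  rbindlist(out)
}
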