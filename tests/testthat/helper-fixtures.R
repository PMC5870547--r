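## Shared fixtures: a tiny hand-built compilation, an independent
## linear-scan oracle for the query engine, a permutation oracle for the
## Kruskal-Wallis test, and a randomized query generator. The oracles are
## deliberately written in plain base R, independent of the package's index
## and planner code paths.

suppressMessages(library(data.table))

## --- tiny hand-built compilation -------------------------------------------
## 5 samples: 1-3 brain (studies sraA/sraA/sraB), 4-5 liver (sraB/sraC).
## 6 junctions on chr1/chr2 covering the contrast cases used across tests:
##   j1 chr1:100-200 + covered in brain (1,2) and liver (4)
##   j2 chr1:100-200 - same interval, opposite strand (duplicate-interval case)
##   j3 chr1:150-400 + liver-only (4,5)
##   j4 chr1:500-800 + brain-only (1,2,3), annotated
##   j5 chr2:100-200 + all samples
##   j6 chr2:900-950 + single sample (3)
tiny_compilation <- function() {
  j <- data.table(
    junction_id = 1:6,
    chrom  = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start  = c(100L, 100L, 150L, 500L, 100L, 900L),
    end    = c(200L, 200L, 400L, 800L, 200L, 950L),
    strand = c("+", "-", "+", "+", "+", "+"),
    annotated = c("0", "0", "0", "refgenes", "refgenes,permgenes", "0"),
    left_annotated = c("0", "0", "0", "refgenes", "refgenes,permgenes", "0"),
    right_annotated = c("0", "0", "0", "refgenes", "refgenes,permgenes", "0"))
  cov <- data.table(
    junction_id = c(1L, 1L, 1L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 5L, 6L),
    sample_id   = c(1L, 2L, 4L, 1L, 4L, 5L, 1L, 2L, 3L, 1L, 2L, 3L, 4L, 5L, 3L),
    coverage    = c(5L, 2L, 7L, 3L, 10L, 4L, 6L, 8L, 2L, 1L, 1L, 2L, 3L, 5L, 9L))
  samples <- data.table(
    sample_id = 1:5,
    tissue = c("Brain", "Brain", "Brain", "Liver", "Liver"),
    study = c("sraA", "sraA", "sraB", "sraB", "sraC"),
    description = c("adult brain cortex", "fetal Brain tissue",
                    "brain cerebellum", "adult liver", "liver biopsy"))
  compilation("tiny", jx_table(j, cov), samples)
}

## --- independent linear-scan oracle ----------------------------------------

## Precomputed plain-R structures for the oracle (built once per compilation).
oracle_prepare <- function(comp) {
  j <- as.data.frame(comp$junctions)
  cov <- as.data.frame(comp$coverages)
  samples <- as.data.frame(comp$samples)
  tok <- function(x) {
    t <- unlist(strsplit(tolower(x), "[^a-z0-9]+"))
    t[nzchar(t)]
  }
  fields <- setdiff(names(samples), "sample_id")
  tokens <- lapply(fields, function(f) lapply(samples[[f]], tok))
  names(tokens) <- fields
  list(j = j, cov = cov, samples = samples, fields = fields, tokens = tokens,
       jfac = factor(cov$junction_id, levels = j$junction_id))
}

oracle_admitted <- function(pre, metaquery) {
  atoms <- strsplit(trimws(metaquery), "[[:space:]]+")[[1]]
  atoms <- atoms[nzchar(atoms)]
  tokq <- function(x) {
    t <- unlist(strsplit(tolower(x), "[^a-z0-9]+"))
    t[nzchar(t)]
  }
  ids <- pre$samples$sample_id
  match_tok <- function(f, tk) {
    ids[vapply(pre$tokens[[f]], function(ts) tk %in% ts, logical(1))]
  }
  sets <- lapply(atoms, function(atom) {
    if (grepl(":", atom, fixed = TRUE)) {
      f <- sub(":.*$", "", atom)
      toks <- tokq(sub("^[^:]*:", "", atom))
      Reduce(intersect, lapply(toks, function(tk) match_tok(f, tk)))
    } else {
      toks <- tokq(atom)
      Reduce(intersect, lapply(toks, function(tk) {
        sort(unique(unlist(lapply(pre$fields, match_tok, tk = tk))))
      }))
    }
  })
  sort(Reduce(intersect, sets))
}

## Literal application of the documented query semantics: full scan, sample
## restriction, summary recomputation, filters, region predicate. Returns
## the sorted junction_id set.
oracle_scan <- function(pre, q) {
  j <- pre$j
  admitted <- NULL
  if (!is.null(q$metadata)) admitted <- oracle_admitted(pre, q$metadata)
  if (!is.null(q$sample_restriction)) {
    admitted <- if (is.null(q$metadata)) sort(unique(q$sample_restriction))
                else intersect(admitted, q$sample_restriction)
  }
  restricted <- !is.null(admitted)

  if (restricted) {
    inset <- pre$cov$sample_id %in% admitted
    cnt <- tapply(inset, pre$jfac, sum)
    cnt[is.na(cnt)] <- 0
    counts <- as.numeric(cnt)
    get_summary <- function(col) {
      x <- pre$cov$coverage[inset]
      f <- pre$jfac[inset]
      switch(col,
        samples_count = counts,
        coverage_sum = {
          s <- tapply(as.numeric(x), f, sum); s[is.na(s)] <- 0; as.numeric(s)
        },
        coverage_avg = {
          s <- tapply(as.numeric(x), f, sum); s[is.na(s)] <- 0
          ifelse(counts > 0, as.numeric(s) / counts, 0)
        },
        coverage_median = {
          m <- tapply(as.numeric(x), f, stats::median); m[is.na(m)] <- 0
          as.numeric(m)
        })
    }
    keep <- counts > 0
  } else {
    get_summary <- function(col) j[[col]]
    keep <- rep(TRUE, nrow(j))
  }

  for (f in q$filters) {
    v <- switch(f$column,
      strand = j$strand,
      annotated = as.integer(j$annotated != "0"),
      length = j$length,
      get_summary(f$column))
    keep <- keep & switch(f$op,
      ">=" = v >= f$value, "<=" = v <= f$value, "=" = v == f$value,
      ">" = v > f$value, "<" = v < f$value,
      "range" = v >= f$value & v <= f$value2)
  }
  if (!is.null(q$region)) {
    r <- q$region
    same <- j$chrom == r$chrom
    keep <- keep & switch(r$mode,
      overlap = same & j$start <= r$end & j$end >= r$start,
      within = same & j$start >= r$start & j$end <= r$end,
      exact = same & j$start == r$start & j$end == r$end,
      start_equals = same & j$start == r$start,
      end_equals = same & j$end == r$end)
  }
  sort(j$junction_id[keep])
}

## --- randomized query generation --------------------------------------------

## Draws a random query spec against a compilation; exercises all region
## modes, all filter columns/ops and metadata atoms (including misses).
random_query <- function(comp) {
  j <- comp$junctions
  has_region <- runif(1) < 0.6
  region <- NULL
  if (has_region) {
    mode <- sample(c("overlap", "within", "exact", "start_equals",
                     "end_equals"), 1)
    if (runif(1) < 0.5 && nrow(j)) {
      ## anchor on a real junction so point-equality modes get hits
      row <- j[sample.int(nrow(j), 1)]
      chrom <- row$chrom
      if (mode %in% c("exact", "start_equals", "end_equals")) {
        start <- row$start; end <- row$end
      } else {
        w <- sample(c(10L, 1000L, 100000L), 1)
        start <- max(1L, row$start - w); end <- row$end + w
      }
    } else {
      chrom <- sample(c(unique(j$chrom), "chrZZ"), 1)
      a <- sample.int(9000000L, 2) + 10000L
      start <- min(a); end <- max(a)
    }
    region <- list(chrom = chrom, start = start, end = end, mode = mode)
  }
  nfilt <- sample(0:2, 1, prob = c(0.3, 0.45, 0.25))
  filters <- list()
  numeric_cols <- c("samples_count", "coverage_sum", "coverage_avg",
                    "coverage_median", "length")
  for (k in seq_len(nfilt)) {
    column <- sample(c(numeric_cols, "strand", "annotated"), 1)
    if (column == "strand") {
      filters[[k]] <- list(column = column, op = "=",
                           value = sample(c("+", "-", "?"), 1))
    } else if (column == "annotated") {
      filters[[k]] <- list(column = column, op = "=", value = sample(0:1, 1))
    } else {
      vals <- j[[column]]
      value <- if (length(vals) && runif(1) < 0.7) {
        sample(vals, 1)
      } else round(runif(1, 0, max(c(vals, 10))), 2)
      filters[[k]] <- list(column = column,
                           op = sample(c(">=", "<=", "=", ">", "<"), 1),
                           value = as.numeric(value))
    }
  }
  metadata <- NULL
  if (runif(1) < 0.4 || (is.null(region) && !length(filters))) {
    tissues <- unique(comp$samples$tissue)
    metadata <- sample(c(
      paste0("tissue:", sample(tissues, 1)),
      paste0("study:", sample(unique(comp$samples$study), 1)),
      sample(tolower(tissues), 1),
      paste("tissue:", sample(tissues, 1), " ",
            sample(unique(comp$samples$study), 1), sep = ""),
      "tissue:plasma"), 1)  # last one has no matches
  }
  query_spec(region = region, filters = filters, metadata = metadata)
}

## --- Kruskal-Wallis permutation oracle --------------------------------------

## Monte-Carlo estimate of P(H* >= H_obs) under label permutation, using the
## rank-sum identity; returns the estimate and its standard error.
kw_permutation_oracle <- function(groups, n_draws = 1e5) {
  v <- unlist(groups)
  n <- lengths(groups)
  g <- rep.int(seq_along(groups), n)
  N <- length(v)
  r <- rank(v)
  tt <- table(r)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  hstat <- function(rr) {
    sums <- vapply(split(rr, g), sum, numeric(1))
    (12 / (N * (N + 1)) * sum(sums^2 / n) - 3 * (N + 1)) / corr
  }
  H_obs <- hstat(r)
  M <- matrix(r[vapply(seq_len(n_draws), function(i) sample.int(N),
                       integer(N))], nrow = N)
  S <- 0
  idx <- split(seq_len(N), g)
  for (grp in seq_along(idx)) {
    rows <- idx[[grp]]
    Rg <- if (length(rows) == 1L) M[rows, ] else colSums(M[rows, , drop = FALSE])
    S <- S + Rg^2 / n[grp]
  }
  H_star <- (12 / (N * (N + 1)) * S - 3 * (N + 1)) / corr
  p_hat <- (1 + sum(H_star >= H_obs - 1e-12)) / (n_draws + 1)
  list(H = H_obs, p = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_draws))
}

## A query matching every junction of a compilation (total F predicate).
sample_queries_covering_all <- function(comp) {
  query_spec(filters = list(list(column = "samples_count", op = ">=",
                                 value = 1)))
}

## Default synthetic compilation used by several suites.
default_test_compilation <- function(seed = 20240915, n_samples = 200L,
                                     n_background = 1000L, ...) {
  cfg <- generator_config(seed = seed, n_samples = n_samples,
                          n_background_junctions = n_background, ...)
  generate_compilation(cfg)
}
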