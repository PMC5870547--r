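test_that("shared sample count is the intersection of group evidence", {
  comp <- tiny_compilation()
  ix <- build_indices(comp)

  ## j4 covers {1,2,3}; j1+j3 cover {1,2,4,5}: shared = {1,2}
  ssc <- shared_sample_count(list("region=chr1:500-800:exact",
                                  query_group(list("region=chr1:100-200:exact & strand=+",
                                                   "region=chr1:150-400:exact"))),
                             ix)
  expect_equal(ssc$sample_sets[[1]], c(1L, 2L, 3L))
  expect_equal(ssc$sample_sets[[2]], c(1L, 2L, 4L, 5L))
  expect_equal(ssc$shared_samples, c(1L, 2L))
  expect_equal(ssc$shared_count, 2L)

  ## single group degenerates to its own size
  one <- shared_sample_count(list("region=chr1:500-800:exact"), ix)
  expect_equal(one$shared_count, 3L)

  ## an empty group yields zero, not an error
  zed <- shared_sample_count(list("region=chr1:500-800:exact",
                                  "region=chr9:1-10"), ix)
  expect_equal(zed$shared_count, 0L)

  ## monotone: adding a group never increases the count
  more <- shared_sample_count(list("region=chr1:500-800:exact",
                                   "region=chr1:100-200:exact & strand=+",
                                   "region=chr2:100-200:exact"), ix)
  expect_lte(more$shared_count, one$shared_count)
})

test_that("SSC equals brute-force set intersection on random group families", {
  gen <- default_test_compilation(seed = 61, n_samples = 60L,
                                  n_background = 250L)
  comp <- gen$compilation
  ix <- build_indices(comp)
  pre <- oracle_prepare(comp)
  set.seed(31)
  for (rep in 1:30) {
    groups <- replicate(sample(1:3, 1), random_query(comp), simplify = FALSE)
    got <- shared_sample_count(groups, ix)
    sets <- lapply(groups, function(q) {
      ids <- oracle_scan(pre, q)
      adm <- if (!is.null(q$metadata)) oracle_admitted(pre, q$metadata)
      covered <- pre$cov$sample_id[pre$cov$junction_id %in% ids]
      if (!is.null(adm)) covered <- covered[covered %in% adm]
      sort(unique(covered))
    })
    expect_equal(got$shared_count, length(Reduce(intersect, sets)))
  }
})

test_that("JIR scores, bounds, ordering and antisymmetry hold", {
  ## hand fixture: one sample with a=2 (junction A) and b=5 (junction B)
  j <- data.table::data.table(junction_id = 1:2, chrom = "chr1",
                              start = c(100L, 500L), end = c(200L, 700L),
                              strand = "+")
  cov <- data.table::data.table(junction_id = c(1L, 2L), sample_id = 1L,
                                coverage = c(2L, 5L))
  samples <- data.table::data.table(sample_id = 1L, tissue = "brain")
  ix <- build_indices(compilation("toy", jx_table(j, cov), samples))
  scores <- junction_inclusion_ratio("region=chr1:100-200:exact",
                                     "region=chr1:500-700:exact", ix)
  expect_equal(scores$score, 0.375)
  expect_equal(scores$a, 2)
  expect_equal(scores$b, 5)

  ## a == b for every sample: all scores 0, ranked by ascending sample_id
  gen <- default_test_compilation(seed = 71, n_samples = 30L,
                                  n_background = 100L)
  ix2 <- build_indices(gen$compilation)
  qa <- sample_queries_covering_all(gen$compilation)
  sym <- junction_inclusion_ratio(qa, qa, ix2)
  expect_true(all(sym$score == 0))
  expect_identical(sym$sample_id, sort(sym$sample_id))
  expect_identical(sym$rank, seq_len(nrow(sym)))

  ## antisymmetry and bounds on random fixtures
  set.seed(37)
  comp <- gen$compilation
  pre_queries <- replicate(20, random_query(comp), simplify = FALSE)
  for (rep in 1:10) {
    ga <- pre_queries[[sample.int(20, 1)]]
    gb <- pre_queries[[sample.int(20, 1)]]
    ab <- junction_inclusion_ratio(ga, gb, ix2)
    ba <- junction_inclusion_ratio(gb, ga, ix2)
    m <- merge(ab, ba, by = "sample_id")
    expect_equal(m$score.x, -m$score.y)
    expect_true(all(ab$score >= -1 & ab$score < 1))
  }
})

test_that("JIR ranks planted isoform-switch outliers first", {
  cfg <- generator_config(seed = 81, n_samples = 200L,
                          n_background_junctions = 50L,
                          jir_patterns = jir_pattern(
                            list(chrom = "chr2", start = 5000000L, end = 5000800L),
                            list(chrom = "chr2", start = 5100000L, end = 5100900L),
                            n_outliers = 3L, effect = 10))
  gen <- generate_compilation(cfg)
  ix <- build_indices(gen$compilation)
  outliers <- as.integer(strsplit(gen$truth$samples[
    gen$truth$event_type == "jir_pattern"], ",")[[1]])
  scores <- junction_inclusion_ratio("region=chr2:5000000-5000800:exact",
                                     "region=chr2:5100000-5100900:exact", ix)
  expect_setequal(scores$sample_id[scores$rank <= 3], outliers)
})

test_that("PSI implements the cassette special case with a depth floor", {
  ## one sample: c_L = 8, c_R = 4, e = 3 -> i = 6, psi = 6/9
  j <- data.table::data.table(junction_id = 1:3, chrom = "chr1",
                              start = c(100L, 300L, 100L),
                              end = c(199L, 399L, 399L), strand = "+")
  cov <- data.table::data.table(junction_id = 1:3, sample_id = 1L,
                                coverage = c(8L, 4L, 3L))
  samples <- data.table::data.table(sample_id = 1L, tissue = "brain")
  ix <- build_indices(compilation("toy", jx_table(j, cov), samples))
  qL <- "region=chr1:100-199:exact"
  qR <- "region=chr1:300-399:exact"
  qE <- "region=chr1:100-399:exact"

  psi <- percent_spliced_in(qL, qR, qE, ix, min_total = 10L)
  expect_equal(psi$psi, 6 / 9)
  expect_equal(psi[, c(count_left, count_right, count_excl)], c(8, 4, 3))

  ## below the floor the sample is omitted (8 + 4 + 3 < 20)
  expect_equal(nrow(percent_spliced_in(qL, qR, qE, ix, min_total = 20L)), 0L)

  ## boundaries: e = 0 -> 1.0; i = 0 -> 0.0
  cov2 <- data.table::data.table(junction_id = c(1L, 2L, 3L),
                                 sample_id = c(1L, 1L, 2L),
                                 coverage = c(30L, 10L, 25L))
  ix2 <- build_indices(compilation("toy2", jx_table(j, cov2),
                                   data.table::data.table(sample_id = 1:2,
                                                          tissue = "brain")))
  psi2 <- percent_spliced_in(qL, qR, qE, ix2, min_total = 20L)
  expect_equal(psi2$psi[psi2$sample_id == 1L], 1.0)
  expect_equal(psi2$psi[psi2$sample_id == 2L], 0.0)

  ## PSI in [0,1] and PSI + PSO = 1 on a planted cassette compilation
  cfg <- generator_config(seed = 91, n_samples = 100L,
                          n_background_junctions = 30L,
                          cassette_events = cassette_event(
                            "chr1", 2000000L, 2000501L, 2000700L, 2001201L,
                            inclusion = 0.5, prevalence = 0.9))
  gen <- generate_compilation(cfg)
  ix3 <- build_indices(gen$compilation)
  qL3 <- "region=chr1:2000001-2000500:exact"
  qR3 <- "region=chr1:2000701-2001200:exact"
  qE3 <- "region=chr1:2000001-2001200:exact"
  psi3 <- percent_spliced_in(qL3, qR3, qE3, ix3, min_total = 1L)
  expect_true(all(psi3$psi >= 0 & psi3$psi <= 1))
  pso <- with(psi3, (count_excl) /
                ((count_left + count_right) / 2 + count_excl))
  expect_equal(psi3$psi + pso, rep(1, nrow(psi3)))
})

test_that("kruskal_wallis reproduces the worked example and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1L)
  expect_equal(kw$p, pchisq(kw$H, 1, lower.tail = FALSE))

  ## cross-check against the independent base-R implementation
  ref <- stats::kruskal.test(c(1, 2, 3, 4, 5, 6), factor(rep(1:2, each = 3)))
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, unname(ref$p.value))

  ## all-tied input: corrected statistic defined as 0, p = 1
  tied <- kruskal_wallis(list(c(2, 2, 2), c(2, 2)))
  expect_equal(tied$H, 0)
  expect_equal(tied$p, 1)

  ## identical groups, no ties
  same <- kruskal_wallis(list(c(1, 3, 5), c(2, 4, 6)))
  expect_lt(same$H, 1)

  expect_error(kruskal_wallis(list(c(1, 2))), "at least two groups")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "nonempty")

  ## ties are corrected identically to the reference implementation
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    groups <- replicate(k, sample(1:5, sample(3:8, 1), replace = TRUE),
                        simplify = FALSE)
    if (length(unique(unlist(groups))) == 1L) next
    kw2 <- kruskal_wallis(groups)
    ref2 <- stats::kruskal.test(unlist(groups),
                                factor(rep.int(seq_len(k), lengths(groups))))
    expect_equal(kw2$H, unname(ref2$statistic))
    expect_equal(kw2$p, unname(ref2$p.value))
  }
})

test_that("kruskal_wallis is invariant under monotone transforms", {
  set.seed(5)
  groups <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, function(x) exp(x)))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) x^3))$H, h0)
})

test_that("small-N permutation p agrees with an independent oracle", {
  set.seed(13)
  for (rep in 1:5) {
    N <- sample(6:8, 1)
    k <- sample(2:3, 1)
    groups <- split(rnorm(N), sort(rep_len(seq_len(k), N)))
    pk <- kruskal_wallis(groups, p_method = "permutation", n_perm = 20000L)
    orc <- kw_permutation_oracle(groups, n_draws = 20000L)
    se <- sqrt(orc$p * (1 - orc$p) * (1 / 20000 + 1 / 20000))
    expect_lt(abs(pk$p - orc$p), max(4 * se, 0.01))
  }
})

test_that("tissue specificity detects planted signal and handles nulls", {
  ## identical values across tissues: H = 0, p = 1
  gen <- default_test_compilation(seed = 101, n_samples = 80L,
                                  n_background = 40L)
  ix <- build_indices(gen$compilation)
  all_q <- sample_queries_covering_all(gen$compilation)
  ts_flat <- tissue_specificity(all_q, ix, value_mode = "presence")
  expect_equal(ts_flat$H, 0)
  expect_equal(ts_flat$p, 1)

  ## planted brain-specific junction in a 4-tissue compilation
  cfg <- generator_config(seed = 102, n_samples = 200L,
                          n_background_junctions = 40L,
                          tissue_events = tissue_specific_event(
                            "chr1", 7000000L, 7000600L, "brain", 0.6))
  gen2 <- generate_compilation(cfg)
  ix2 <- build_indices(gen2$compilation)
  ts <- tissue_specificity("region=chr1:7000000-7000600:exact", ix2)
  expect_lt(ts$p, 0.01)
  ## coverage mode agrees on the planted signal
  ts_cov <- tissue_specificity("region=chr1:7000000-7000600:exact", ix2,
                               value_mode = "coverage")
  expect_lt(ts_cov$p, 0.01)

  ## fewer than two nonempty tissue groups is an error
  mono <- gen2$compilation
  mono$samples$tissue <- "brain"
  ix3 <- build_indices(mono)
  expect_error(tissue_specificity("region=chr1:7000000-7000600:exact", ix3),
               "at least two nonempty tissue groups")
  ## unknown tissue field
  expect_error(tissue_specificity("region=chr1:7000000-7000600:exact", ix2,
                                  tissue_field = "organ"), "no field")
})
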