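test_that("query strings parse into R/F/M constraint specs", {
  q <- parse_query("region=chr1:100-200 & samples_count>=5")
  expect_s3_class(q, "jx_query")
  expect_equal(q$region, list(chrom = "chr1", start = 100L, end = 200L,
                              mode = "overlap"))
  expect_length(q$filters, 1)
  expect_equal(q$filters[[1]][c("column", "op", "value")],
               list(column = "samples_count", op = ">=", value = 5))
  expect_null(q$metadata)

  q2 <- parse_query("region=chr1:100-200 & coverage_avg>=2.0 & metadata=tissue:brain")
  expect_equal(q2$metadata, "tissue:brain")
  expect_equal(q2$filters[[1]]$column, "coverage_avg")

  q3 <- parse_query("region=chr2:5-10:start_equals")
  expect_equal(q3$region$mode, "start_equals")

  ## syntax errors carry character offsets; unknown columns list the options
  expect_error(parse_query("samples_count>="), "missing value.*offset 15")
  expect_error(parse_query("region=chr1:100-200 & fudge>=3"),
               "unknown column 'fudge'.*samples_count")
  expect_error(parse_query("region=chr1:banana"), "offset 7")
  expect_error(parse_query("region=chr1:100-200:sideways"), "unknown region mode")
  expect_error(parse_query("metadata="), "empty metadata")
  expect_error(query_spec(), "at least one")
})

test_that("the planner picks drivers by selectivity and explains itself", {
  gen <- default_test_compilation(seed = 21, n_samples = 50L,
                                  n_background = 200L)
  ix <- build_indices(gen$compilation)

  p <- plan_query("region=chr1:100000-100100 & samples_count>=5", ix)
  expect_equal(p$driver$type, "region")
  expect_match(paste(p$steps, collapse = "\n"), "interval index")

  p2 <- plan_query("samples_count>=40", ix)
  expect_equal(p2$driver$type, "numeric")
  expect_match(p2$steps[1], "numeric index on samples_count")

  ## among several filters the smallest estimated bucket mass drives
  p3 <- plan_query("samples_count>=1 & length>=19999000", ix)
  expect_equal(p3$query$filters[[p3$driver$filter]]$column, "length")

  p4 <- plan_query("metadata=tissue:brain", ix)
  expect_equal(p4$driver$type, "metadata")

  ## under a metadata restriction a <= filter must not drive the plan
  p5 <- plan_query("coverage_sum<=3 & metadata=tissue:brain", ix)
  expect_false(p5$driver$type == "numeric" &&
                 p5$query$filters[[p5$driver$filter]]$op == "<=")
})

test_that("metadata restriction recomputes summaries before F filters", {
  comp <- tiny_compilation()
  ix <- build_indices(comp)

  ## liver-only junction j3 is excluded under a brain restriction
  with_m <- run_query(ix, "region=chr1:1-1000 & samples_count>=1 & metadata=tissue:brain")
  expect_false(3L %in% with_m$junctions$junction_id)
  ## same query without metadata keeps it
  without_m <- run_query(ix, "region=chr1:1-1000 & samples_count>=1")
  expect_true(3L %in% without_m$junctions$junction_id)

  ## summaries in the result are over admitted samples only: j1 has
  ## coverages {1:5, 2:2, 4:7}; brain admits {1,2,3}
  j1 <- with_m$junctions[with_m$junctions$junction_id == 1L]
  expect_equal(j1$samples_count, 2L)
  expect_equal(j1$coverage_sum, 7)
  expect_equal(j1$coverage_avg, 3.5)
  expect_equal(with_m$admitted_samples, c(1L, 2L, 3L))

  ## no matching sample: empty result, not an error
  none <- run_query(ix, "region=chr1:1-1000 & metadata=tissue:plasma")
  expect_equal(nrow(none$junctions), 0L)

  ## a <= filter that only holds post-restriction: j1 stored sum 14, brain
  ## restricted sum 7
  le <- run_query(ix, "coverage_sum<=7 & metadata=tissue:brain")
  expect_true(1L %in% le$junctions$junction_id)
})

test_that("explicit sample restrictions behave like metadata admission", {
  comp <- tiny_compilation()
  ix <- build_indices(comp)
  r <- run_query(ix, query_spec(region = "chr1:1-1000", samples = c(4L, 5L)))
  expect_equal(sort(r$junctions$junction_id), c(1L, 3L))
  expect_equal(r$junctions$coverage_sum[r$junctions$junction_id == 1L], 7)
})

test_that("filters commute and tightening a bound never adds junctions", {
  gen <- default_test_compilation(seed = 31, n_samples = 60L,
                                  n_background = 300L)
  ix <- build_indices(gen$compilation)
  set.seed(8)
  for (rep in 1:20) {
    q <- random_query(gen$compilation)
    if (length(q$filters) < 2) next
    qp <- q
    qp$filters <- rev(qp$filters)
    expect_identical(execute_plan(plan_query(q, ix))$junctions,
                     execute_plan(plan_query(qp, ix))$junctions)
  }
  base <- query_spec(filters = list(list(column = "samples_count",
                                         op = ">=", value = 5)))
  ids0 <- execute_plan(plan_query(base, ix))$junctions$junction_id
  for (bound in c(10, 20, 40)) {
    tight <- query_spec(filters = list(list(column = "samples_count",
                                            op = ">=", value = bound)))
    ids <- execute_plan(plan_query(tight, ix))$junctions$junction_id
    expect_true(all(ids %in% ids0))
    ids0 <- ids
  }
})

test_that("planned execution equals the naive scan on random specs", {
  gen <- default_test_compilation(seed = 41, n_samples = 80L,
                                  n_background = 400L)
  comp <- gen$compilation
  ix <- build_indices(comp)
  pre <- oracle_prepare(comp)
  set.seed(17)
  for (rep in 1:300) {
    q <- random_query(comp)
    got <- execute_plan(plan_query(q, ix))$junctions$junction_id
    expect_identical(sort(got), oracle_scan(pre, q))
  }
})

test_that("result sets stream as the junction dialect in genomic order", {
  comp <- tiny_compilation()
  ix <- build_indices(comp)
  res <- run_query(ix, "region=chr1:1-1000")
  j <- res$junctions
  expect_false(is.unsorted(order(j$chrom, j$start, j$end, j$strand)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_tsv(res, "tiny", path)
  lines <- readLines(path)
  expect_match(lines[1], "^#datasource\tjunction_id")
  expect_equal(length(lines), nrow(j) + 1L)
  expect_match(lines[2], "^tiny\t")
})

test_that("query groups combine members by union and intersection", {
  comp <- tiny_compilation()
  ix <- build_indices(comp)

  ## group of one is the single query
  single <- run_group(query_group("region=chr1:1-1000"), ix)
  expect_identical(single$junctions,
                   run_query(ix, "region=chr1:1-1000")$junctions)

  ## two disjoint regions intersect to nothing
  disjoint <- run_group(query_group(list("region=chr1:100-200:exact",
                                         "region=chr2:100-200:exact"),
                                    "intersection"), ix)
  expect_equal(nrow(disjoint$junctions), 0L)

  ## union keeps the widest admitted set's summaries: j1 under brain (7) vs
  ## unrestricted (14) -- union must report 14
  u <- run_group(query_group(list(
    "region=chr1:100-200:exact & metadata=tissue:brain",
    "region=chr1:100-200:exact"), "union"), ix)
  expect_equal(u$junctions$coverage_sum[u$junctions$junction_id == 1L], 14)
  expect_null(u$admitted_samples)

  ## randomized groups match set algebra over member oracles
  gen <- default_test_compilation(seed = 51, n_samples = 50L,
                                  n_background = 200L)
  comp2 <- gen$compilation
  ix2 <- build_indices(comp2)
  pre2 <- oracle_prepare(comp2)
  set.seed(23)
  for (rep in 1:40) {
    qs <- replicate(sample(2:3, 1), random_query(comp2), simplify = FALSE)
    op <- sample(c("union", "intersection"), 1)
    got <- sort(run_group(query_group(qs, op), ix2)$junctions$junction_id)
    member_ids <- lapply(qs, function(q) oracle_scan(pre2, q))
    want <- sort(Reduce(switch(op, union = union, intersection = intersect),
                        member_ids))
    expect_identical(got, as.integer(want))
  }
})
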