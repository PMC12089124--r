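test_that("iteration histogram counts are exact and percentages recompute", {
  co <- toy_cohort(list(c(1L, 2L), c(2L, 3L), c(1L, 2L), c(4L, 5L)),
                   iterations = c(2L, 2L, 3L, 7L))
  h <- iteration_histogram(co)
  expect_identical(h$iterations, c(2L, 3L, 7L))
  expect_identical(h$count, c(2L, 1L, 1L))
  expect_equal(h$percent, c(50, 25, 25))
  expect_identical(sum(h$count), 4L)
  expect_equal(sum(h$percent), 100)
})

test_that("self-similarity is degenerate at k and mismatched ids error", {
  co <- toy_cohort(list(c(1L, 2L), c(2L, 3L), c(5L, 6L)))
  s <- pairwise_similarity(co, co)
  expect_identical(s$shared, 0:2)
  expect_identical(s$count, c(0L, 0L, 3L))
  expect_equal(s$percent[3], 100)
  other <- toy_cohort(list(c(1L, 2L), c(2L, 3L)))
  expect_error(pairwise_similarity(co, other), "pattern ids")
})

test_that("similarity counts common active nodes per matched pattern", {
  a <- toy_cohort(list(c(1L, 2L), c(2L, 3L), c(5L, 6L)))
  b <- toy_cohort(list(c(1L, 2L), c(3L, 4L), c(1L, 4L)))
  s <- pairwise_similarity(a, b)
  expect_identical(attr(s, "shared"), c(2L, 1L, 0L))
  expect_identical(s$count, c(1L, 1L, 1L))
})

test_that("multiplicity profile reports both run-level and distinct-level shares", {
  # two runs share one output set among three runs total
  co <- toy_cohort(list(c(1L, 2L), c(1L, 2L), c(3L, 4L)))
  mp <- multiplicity_profile(co)
  expect_identical(mp$multiplicity, c(1L, 2L))
  expect_identical(mp$n_runs, c(1L, 2L))
  expect_identical(mp$n_patterns, c(1L, 1L))
  expect_equal(mp$run_percent, c(100 / 3, 200 / 3))
  expect_equal(mp$pattern_percent, c(50, 50))
  expect_equal(sum(mp$run_percent), 100)
  expect_equal(sum(mp$pattern_percent), 100)
  # all-distinct cohort is 100% unique under both accountings
  co2 <- toy_cohort(list(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  mp2 <- multiplicity_profile(co2)
  expect_identical(mp2$multiplicity, 1L)
  expect_equal(mp2$run_percent, 100)
  expect_equal(mp2$pattern_percent, 100)
})

test_that("activation probabilities count node membership and sum to k", {
  co <- toy_cohort(list(c(1L, 2L), c(2L, 3L), c(2L, 6L), c(1L, 6L)))
  ap <- activation_probabilities(co)
  expect_identical(ap$node, 1:6)
  expect_equal(ap$probability, c(2, 3, 1, 0, 0, 2) / 4)
  expect_equal(sum(ap$probability), 2, tolerance = 1e-12)
})

test_that("cohort overlap counts common distinct output sets", {
  a <- toy_cohort(list(c(1L, 2L), c(1L, 2L), c(3L, 4L)))
  b <- toy_cohort(list(c(3L, 4L), c(5L, 6L), c(2L, 6L)))
  ov <- cohort_overlap(a, b)
  expect_identical(ov$n_common, 1L)
  expect_identical(ov$n_distinct_a, 2L)
  expect_identical(ov$n_distinct_b, 3L)
  expect_equal(ov$fraction_a, 1 / 2)
  expect_equal(ov$fraction_b, 1 / 3)
  # identity and disjointness oracles
  expect_equal(cohort_overlap(a, a)$fraction_a, 1)
  d <- toy_cohort(list(c(1L, 6L), c(4L, 5L)))
  expect_identical(cohort_overlap(a, d)$n_common, 0L)
})

test_that("cohort summaries bundle every statistic and serialize to disk", {
  sw <- small_world()
  young <- run_cohort(sw$net, sw$valid, "young", sw$calib$threshold, seed = 3L)
  old <- run_cohort(sw$net, sw$valid, "old", sw$calib$threshold, seed = 3L)
  s <- summarize_cohort(young, other = old)
  expect_s3_class(s, "cohort_summary")
  expect_identical(sum(s$iteration_histogram$count), length(young$pattern_ids))
  expect_equal(sum(s$activation_probabilities$probability), 3,
               tolerance = 1e-9)
  dir <- withr::local_tempdir()
  write_summary(s, dir)
  expect_true(file.exists(file.path(dir, "summary_young.json")))
  expect_true(file.exists(file.path(dir, "iterations_young.csv")))
  expect_true(file.exists(file.path(dir, "similarity_young_old.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary_young.json"),
                            simplifyVector = TRUE)
  expect_equal(js$overlap$n_common, cohort_overlap(young, old)$n_common)
})
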