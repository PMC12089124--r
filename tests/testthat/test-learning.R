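test_that("roulette selection follows the fitness-proportionate law", {
  # singleton pool and degenerate cases
  expect_identical(roulette_select(c(0.2, 0.3, 0.5), pool = 2L), 2L)
  expect_error(roulette_select(c(0, 0)), "zero")
  expect_error(roulette_select(c(0.1), pool = integer(0)), "non-empty")
  expect_error(roulette_select(c(-0.1, 0.2)), "non-negative")
  # chi-square against the exact multinomial at 1e5 seeded draws
  set.seed(123)
  draws <- vapply(seq_len(1e5), function(i) roulette_select(c(0.2, 0.3, 0.5)),
                  integer(1))
  counts <- tabulate(draws, 3L)
  chi <- suppressWarnings(stats::chisq.test(counts, p = c(0.2, 0.3, 0.5)))
  expect_gt(chi$p.value, 1e-4)
  # pooled selection respects the restricted mass
  set.seed(5)
  d2 <- vapply(seq_len(2e4), function(i) {
    roulette_select(c(0.5, 0.25, 0.25), pool = c(2L, 3L))
  }, integer(1))
  expect_true(all(d2 %in% c(2L, 3L)))
  expect_equal(mean(d2 == 2L), 0.5, tolerance = 0.02)
})

test_that("young step scales the chosen output's signal by exactly alpha", {
  fx <- fixture_network()
  p <- c(1L, 5L)
  before <- compute_signals(fx$network, p)
  net2 <- young_step(fx$network, p, 2L, 1.5)
  after <- compute_signals(net2, p)
  expect_equal(after[2], 1.5 * before[2], tolerance = 1e-12)
  expect_equal(after[-2], before[-2])
  # inactive rows into the chosen output are untouched
  expect_identical(net2$weights[c(2L, 3L, 4L, 6L), 2L],
                   fx$network$weights[c(2L, 3L, 4L, 6L), 2L])
  # composition: two steps scale by alpha^2
  net3 <- young_step(net2, p, 2L, 1.5)
  expect_equal(compute_signals(net3, p)[2], 1.5^2 * before[2],
               tolerance = 1e-12)
})

test_that("MIS merge moves weight within a row and conserves totals", {
  fx <- fixture_network()
  net <- fx$network
  p <- c(1L, 5L)
  before_sig <- compute_signals(net, p)
  net2 <- mis_step(net, 1L, 3L, 4L) # w[1,3] 0.15 absorbs w[1,4] 0.10
  expect_equal(net2$weights[1L, 3L], 0.25)
  expect_identical(net2$weights[1L, 4L], 0)
  expect_equal(rowSums(net2$weights), rowSums(net$weights), tolerance = 1e-9)
  after_sig <- compute_signals(net2, p)
  expect_equal(sum(after_sig), sum(before_sig), tolerance = 1e-9)
  expect_equal(after_sig[3L] - before_sig[3L], 0.10, tolerance = 1e-12)
  expect_equal(before_sig[4L] - after_sig[4L], 0.10, tolerance = 1e-12)
  expect_error(mis_step(net2, 1L, 3L, 4L), "zero")
})

test_that("first-edge selection uses weight magnitudes over active inputs", {
  fx <- fixture_network()
  # single nonzero active incoming edge -> that input with probability 1
  w <- fx$network$weights
  w[5L, 2L] <- 0
  net <- plastisim:::new_synaptic_network(6L, w)
  for (s in 1:5) {
    set.seed(s)
    expect_identical(select_first_edge(net, c(1L, 5L), 2L), 1L)
  }
  # frequencies follow the weight ratio 0.25 : 0.10
  set.seed(42)
  d <- vapply(seq_len(2e4), function(i) {
    select_first_edge(fx$network, c(1L, 5L), 2L)
  }, integer(1))
  expect_equal(mean(d == 1L), 0.25 / 0.35, tolerance = 0.02)
  w[1L, 2L] <- 0
  net0 <- plastisim:::new_synaptic_network(6L, w)
  expect_error(select_first_edge(net0, c(1L, 5L), 2L), "zero")
})

test_that("second-edge selection picks the nearest eligible donor", {
  fx <- fixture_network()
  net <- fx$network # row 1: 0.30 0.25 0.15 0.10 0.12 0.08
  # both neighbours of j = 3 exist: coin break (seed 1 -> first runif < 0.5)
  set.seed(1)
  expect_identical(select_second_edge(net, 1L, 3L), 2L)
  # left neighbour consumed -> right taken without a draw
  expect_identical(select_second_edge(net, 1L, 3L, consumed = 2L), 4L)
  # both distance-1 and one distance-2 side blocked -> remaining side
  expect_identical(
    select_second_edge(net, 1L, 3L, consumed = c(2L, 4L), protected = 1L),
    5L
  )
  # exhausted candidates -> NA
  expect_identical(
    select_second_edge(net, 1L, 3L, consumed = c(1L, 2L, 4L, 5L, 6L)),
    NA_integer_
  )
  # zero-weight outputs are skipped
  w <- net$weights
  w[1L, 2L] <- 0
  net2 <- plastisim:::new_synaptic_network(6L, w)
  expect_identical(select_second_edge(net2, 1L, 3L), 4L)
})

test_that("young learning on the fixture matches the hand-stepped trace", {
  fx <- fixture_network()
  set.seed(7)
  res <- run_young(fx$network, c(1L, 5L), fx$threshold, 1.5,
                   trace = TRUE, keep_network = TRUE)
  expect_identical(res$iterations, 3L)
  expect_identical(res$final_active, c(1L, 3L))
  expect_true(res$completed)
  expect_identical(res$trace$output, c(6L, 3L, 1L))
  expect_equal(res$trace$signal_after, c(0.345, 0.525, 0.675),
               tolerance = 1e-12)
  # only active rows were scaled; inactive rows untouched
  expect_identical(res$network$weights[c(2L, 3L, 4L, 6L), ],
                   fx$network$weights[c(2L, 3L, 4L, 6L), ])
  expect_error(run_young(fx$network, c(1L, 2L), fx$threshold),
               "not valid") # pattern (1,2) already fires output 2
})

test_that("old learning on the fixture matches the hand-stepped trace", {
  fx <- fixture_network()
  set.seed(11)
  res <- run_old(fx$network, c(1L, 5L), fx$threshold,
                 trace = TRUE, keep_network = TRUE)
  expect_identical(res$iterations, 2L)
  expect_identical(res$final_active, c(1L, 2L))
  expect_identical(res$trace$output, c(2L, 1L))
  expect_identical(res$trace$input, c(1L, 1L))
  expect_identical(res$trace$donor, c(3L, 4L))
  expect_equal(res$trace$signal_after, c(0.50, 0.55), tolerance = 1e-12)
  expect_equal(res$network$weights[1L, ], c(0.40, 0.40, 0, 0, 0.12, 0.08),
               tolerance = 1e-12)
  expect_identical(res$network$weights[5L, ], fx$network$weights[5L, ])
})

test_that("old learning conserves total signal and row sums for whole runs", {
  set.seed(31)
  net <- initialize_weights(30)
  pm <- enumerate_patterns(30, 6)
  cal <- calibrate_threshold(net, pm, 0.25)
  vp <- valid_patterns(cal, pm)
  for (q in c(1L, 500L, 2000L)) {
    p <- vp[q, ]
    before <- compute_signals(net, p)
    set.seed(q)
    res <- run_old(net, p, cal$threshold, keep_network = TRUE)
    after <- compute_signals(res$network, p)
    expect_equal(sum(after), sum(before), tolerance = 1e-9)
    expect_equal(rowSums(res$network$weights), rep(1, 30), tolerance = 1e-9)
    expect_true(all(res$network$weights >= 0))
    expect_gte(res$iterations, 6L)
    expect_identical(length(res$final_active), 6L)
  }
})

test_that("young learning iterates at least k times and activates exactly k outputs", {
  sw <- small_world()
  for (q in c(1L, 5L, 9L)) {
    set.seed(q)
    res <- run_young(sw$net, sw$valid[q, ], sw$calib$threshold, 1.5)
    expect_gte(res$iterations, 3L)
    expect_identical(length(res$final_active), 3L)
    expect_true(res$completed)
  }
})

test_that("an old run starting above threshold completes in zero iterations", {
  fx <- fixture_network()
  # pattern (1,2) has outputs 1 and 2 at 0.35 and 0.60 -> with T = 0.30 both fire
  res <- run_old(fx$network, c(1L, 2L), 0.30)
  expect_identical(res$iterations, 0L)
  expect_true(res$completed)
  expect_true(all(c(1L, 2L) %in% res$final_active))
})
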