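# Independent brute-force oracles, deliberately written with different code
# paths (explicit loops and sums) than the implementation they check.

# Signals of one pattern by explicit summation over active inputs.
oracle_signals <- function(weights, active) {
  n <- ncol(weights)
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in active) s <- s + weights[i, j]
    out[j] <- s
  }
  out
}

# Valid patterns by exhaustive strict-below filter.
oracle_valid_ids <- function(weights, patterns, threshold) {
  keep <- logical(nrow(patterns))
  for (q in seq_len(nrow(patterns))) {
    keep[q] <- max(oracle_signals(weights, patterns[q, ])) < threshold
  }
  which(keep)
}

# Build a cohort_result by hand from explicit fields (for analysis tests).
toy_cohort <- function(final_active, iterations = rep(1L, length(final_active)),
                       rule = "young", n = 6L, k = 2L) {
  plastisim:::new_cohort_result(
    rule, seq_along(final_active), iterations, final_active,
    config = list(n = n, k = k, mu = NA_real_, sigma = NA_real_,
                  alpha = NA_real_, threshold = NA_real_, seed = 1L,
                  preload_id = NA_integer_)
  )
}

# Small calibrated world shared by experiment-level tests: n = 10, k = 3.
small_world <- function(seed = 202L) {
  set.seed(seed)
  net <- initialize_weights(10L, 1, 0.2)
  patterns <- enumerate_patterns(10L, 3L)
  calib <- calibrate_threshold(net, patterns, 0.25)
  list(net = net, patterns = patterns, calib = calib,
       valid = valid_patterns(calib, patterns))
}
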