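# Cohort experiments: run one learning rule over every valid pattern, each on
# a fresh copy of the calibrated network with its own derived RNG stream, so
# cohorts are reproducible and per-pattern results are order-independent.

# Independent seed streams. Each (master seed, stream, id) triple maps to one
# 32-bit seed; ids within a stream are distinct, so per-pattern streams never
# collide inside a cohort.
stream_offset <- c(young = 1L, old = 2L, old_prior = 3L,
                   preload = 4L, choice = 5L)

derive_seed <- function(seed, stream, id = 0L) {
  off <- stream_offset[[stream]]
  base <- as.numeric(seed) %% 2147483647
  as.integer((base * 11 + off * 1e7 + as.numeric(id)) %% 2147483647)
}

new_cohort_result <- function(rule, pattern_ids, iterations, final_active,
                              config) {
  structure(
    list(rule = rule, pattern_ids = as.integer(pattern_ids),
         iterations = as.integer(iterations), final_active = final_active,
         completed = rep(TRUE, length(pattern_ids)), config = config),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> rule = %s, %d runs (threshold %.4f, seed %s)\n",
              x$rule, length(x$pattern_ids), x$config$threshold,
              format(x$config$seed)))
  it <- x$iterations
  cat(sprintf("  iterations: min %d / mean %.2f / max %d; %.2f%% at the minimum\n",
              min(it), mean(it), max(it), 100 * mean(it == min(it))))
  invisible(x)
}

#' Run a learning rule over a cohort of valid patterns
#'
#' Learns every pattern independently on a fresh copy of `net`, seeding the
#' RNG per pattern from `(seed, rule, pattern id)` so that results do not
#' depend on execution order and identical calls are bit-identical.
#'
#' @param net The calibrated `synaptic_network` (clean slate for each run).
#' @param patterns Valid-pattern matrix, e.g. from [valid_patterns()]; its
#'   `pattern_ids` attribute (row index if absent) keys the RNG streams.
#' @param rule `"young"` or `"old"`.
#' @param threshold Firing threshold from [calibrate_threshold()].
#' @param alpha Young learning rate (ignored by the old rule).
#' @param seed Master seed for the cohort.
#' @param verbose Print progress every 25,000 runs.
#' @return A `cohort_result`: `rule`, `pattern_ids`, `iterations` (integer
#'   per run), `final_active` (list of integer vectors per run), `completed`,
#'   and `config` (parameter record).
#' @export
run_cohort <- function(net, patterns, rule = c("young", "old"), threshold,
                       alpha = 1.5, seed = 1L, verbose = FALSE) {
  rule <- match.arg(rule)
  ids <- pattern_ids_of(patterns)
  m <- nrow(patterns)
  iterations <- integer(m)
  final_active <- vector("list", m)
  for (q in seq_len(m)) {
    set.seed(derive_seed(seed, rule, ids[q]))
    res <- if (rule == "young") {
      run_young(net, patterns[q, ], threshold, alpha = alpha)
    } else {
      run_old(net, patterns[q, ], threshold)
    }
    if (!res$completed) stop("incomplete run for pattern id ", ids[q])
    iterations[q] <- res$iterations
    final_active[[q]] <- res$final_active
    if (verbose && q %% 25000L == 0L) {
      message(sprintf("  [%s] %d / %d patterns", rule, q, m))
    }
  }
  config <- list(n = net$n, k = ncol(patterns), mu = net$mu, sigma = net$sigma,
                 alpha = if (rule == "young") alpha else NA_real_,
                 threshold = threshold, seed = seed, preload_id = NA_integer_)
  new_cohort_result(rule, ids, iterations, final_active, config)
}

#' Preload a network by young learning of one pattern
#'
#' Runs young learning to completion for `active` on a copy of `net` and
#' returns the resulting weights. Rows of the trained inputs then sum to more
#' than one (the young rule only multiplies weights up); untouched rows still
#' sum to one. The result models previously accumulated knowledge.
#'
#' @inheritParams run_young
#' @param seed Seed for the preloading run.
#' @return The preloaded `synaptic_network`.
#' @export
preload_young <- function(net, active, threshold, alpha = 1.5, seed = 1L) {
  set.seed(derive_seed(seed, "preload"))
  res <- run_young(net, active, threshold, alpha = alpha, keep_network = TRUE)
  res$network
}

#' Old learning with prior knowledge
#'
#' Picks one valid pattern uniformly at random (seeded), preloads the network
#' by young learning of that pattern, then runs the old rule over *all* valid
#' patterns from the shared preloaded state (fresh copy per run). Runs whose
#' start already has at least `k` activated outputs record zero iterations.
#'
#' @inheritParams run_cohort
#' @return A `cohort_result` with rule `"old_prior"`; `config$preload_id`
#'   records the preloaded pattern's id.
#' @export
run_prior_knowledge <- function(net, patterns, threshold, alpha = 1.5,
                                seed = 1L, verbose = FALSE) {
  ids <- pattern_ids_of(patterns)
  m <- nrow(patterns)
  set.seed(derive_seed(seed, "choice"))
  pick <- sample.int(m, 1L)
  preloaded <- preload_young(net, patterns[pick, ], threshold,
                             alpha = alpha, seed = seed)
  iterations <- integer(m)
  final_active <- vector("list", m)
  for (q in seq_len(m)) {
    set.seed(derive_seed(seed, "old_prior", ids[q]))
    res <- run_old(preloaded, patterns[q, ], threshold)
    iterations[q] <- res$iterations
    final_active[[q]] <- res$final_active
    if (verbose && q %% 25000L == 0L) {
      message(sprintf("  [old_prior] %d / %d patterns", q, m))
    }
  }
  config <- list(n = net$n, k = ncol(patterns), mu = net$mu, sigma = net$sigma,
                 alpha = alpha, threshold = threshold, seed = seed,
                 preload_id = ids[pick])
  new_cohort_result("old_prior", ids, iterations, final_active, config)
}
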