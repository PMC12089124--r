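# One-call reproduction of the full simulation study: initialize, calibrate,
# run the three cohorts, and compute the headline statistics.

#' Run the full simulation study
#'
#' Initializes a network, calibrates the threshold over the complete k-of-n
#' pattern space, and runs the young, old and old-with-prior-knowledge
#' cohorts over every valid pattern. Everything is driven by `seed`.
#'
#' With the default configuration this enumerates all 593,775 6-of-30
#' patterns and learns each of the ~148,000 valid ones three times; expect
#' roughly a minute of compute.
#'
#' @param seed Master seed.
#' @param config Configuration list (see [default_config()]); `seed`
#'   overrides its seed entry.
#' @param verbose Progress messages.
#' @return A list with `config`, `network`, `patterns`, `calibration`,
#'   `valid` (valid-pattern matrix) and the `cohort_result`s `young`, `old`,
#'   `prior`.
#' @export
run_study <- function(seed = 1L, config = default_config(), verbose = FALSE) {
  cfg <- validate_config(config)
  cfg$seed <- as.integer(seed)
  set.seed(derive_seed(cfg$seed, "preload", 999983L)) # init stream
  net <- initialize_weights(cfg$n, cfg$mu, cfg$sigma)
  patterns <- enumerate_patterns(cfg$n, cfg$k)
  calib <- calibrate_threshold(net, patterns, cfg$target_fraction)
  if (verbose) {
    message(sprintf("threshold %.4f; %d valid patterns (%.2f%%)",
                    calib$threshold, length(calib$valid_ids),
                    100 * calib$achieved_fraction))
  }
  vp <- valid_patterns(calib, patterns)
  young <- old <- prior <- NULL
  if ("young" %in% cfg$rules) {
    young <- run_cohort(net, vp, "young", calib$threshold, alpha = cfg$alpha,
                        seed = cfg$seed, verbose = verbose)
  }
  if ("old" %in% cfg$rules) {
    old <- run_cohort(net, vp, "old", calib$threshold,
                      seed = cfg$seed, verbose = verbose)
  }
  if ("old_prior" %in% cfg$rules) {
    prior <- run_prior_knowledge(net, vp, calib$threshold, alpha = cfg$alpha,
                                 seed = cfg$seed, verbose = verbose)
  }
  list(config = cfg, network = net, patterns = patterns, calibration = calib,
       valid = vp, young = young, old = old, prior = prior)
}

#' Headline statistics of a full study
#'
#' Computes the quantities the simulation is designed to measure: learning
#' speed of each rule, young-old output-pattern similarity, memory
#' specificity, per-node activation probabilities, distinct-pattern overlap,
#' and the prior-knowledge speed-up. Percentages are on the 0-100 scale.
#'
#' @param study Result of [run_study()] (young, old and prior cohorts all
#'   required).
#' @return A named list of scalar statistics.
#' @export
study_statistics <- function(study) {
  k <- study$config$k
  young <- study$young; old <- study$old; prior <- study$prior
  stopifnot(!is.null(young), !is.null(old), !is.null(prior))

  sim <- pairwise_similarity(young, old)
  shared <- attr(sim, "shared")

  uy <- multiplicity_profile(young)
  uo <- multiplicity_profile(old)
  unique_young <- uy$run_percent[uy$multiplicity == 1L]
  unique_old <- uo$run_percent[uo$multiplicity == 1L]

  py <- activation_probabilities(young)$probability
  po <- activation_probabilities(old)$probability
  ov <- cohort_overlap(young, old)

  list(
    threshold = study$calibration$threshold,
    valid_fraction_pct = 100 * study$calibration$achieved_fraction,
    n_valid = length(study$calibration$valid_ids),
    young_min_iterations = min(young$iterations),
    young_max_iterations = max(young$iterations),
    young_at_min_pct = 100 * mean(young$iterations == k),
    old_min_iterations = min(old$iterations),
    old_max_iterations = max(old$iterations),
    old_at_min_pct = 100 * mean(old$iterations == k),
    old_mean_iterations = mean(old$iterations),
    similarity_le2_pct = 100 * mean(shared <= 2L),
    similarity_at5_count = sum(shared == k - 1L),
    similarity_identical_count = sum(shared == k),
    unique_young_pct = unique_young,
    unique_old_pct = unique_old,
    unique_mean_pct = (unique_young + unique_old) / 2,
    activation_min_pct = 100 * min(py, po),
    activation_max_pct = 100 * max(py, po),
    activation_maxdiff_pp = 100 * max(abs(py - po)),
    overlap_common = ov$n_common,
    overlap_pct = 100 * (ov$fraction_a + ov$fraction_b) / 2,
    prior_at0_pct = 100 * mean(prior$iterations == 0L),
    prior_lt_min_pct = 100 * mean(prior$iterations < k),
    prior_mean_iterations = mean(prior$iterations)
  )
}
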