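# Cohort-level statistics: learning-speed histograms, young-vs-old output
# similarity, memory specificity (multiplicity of repeated output patterns),
# per-node activation probability, and overlap of distinct output patterns.
# All histograms are exact integer counts; percentages are recomputed from
# the counts.

output_keys <- function(cohort) {
  vapply(cohort$final_active, paste, character(1L), collapse = ";")
}

#' Histogram of iterations to completion
#'
#' @param cohort A `cohort_result`.
#' @return Data frame with `iterations`, `count` and `percent` (of cohort
#'   size), one row per observed iteration count.
#' @export
iteration_histogram <- function(cohort) {
  tb <- table(cohort$iterations)
  data.frame(iterations = as.integer(names(tb)),
             count = as.integer(tb),
             percent = 100 * as.integer(tb) / length(cohort$iterations),
             row.names = NULL)
}

#' Similarity of final output patterns between two cohorts
#'
#' For each pattern id present in both cohorts (they must cover the same ids
#' in the same order), counts the output nodes the two final active sets
#' share, and tabulates the counts over 0..k.
#'
#' @param a,b `cohort_result`s over the same valid-pattern ids.
#' @return Data frame with `shared` (0..k), `count` and `percent`; the per-id
#'   shared counts are attached as attribute `shared`.
#' @export
pairwise_similarity <- function(a, b) {
  if (!identical(a$pattern_ids, b$pattern_ids)) {
    stop("cohorts do not cover the same pattern ids", call. = FALSE)
  }
  k <- a$config$k
  shared <- mapply(function(x, y) length(intersect(x, y)),
                   a$final_active, b$final_active)
  tb <- tabulate(shared + 1L, nbins = k + 1L)
  out <- data.frame(shared = 0:k, count = tb,
                    percent = 100 * tb / length(shared))
  attr(out, "shared") <- as.integer(shared)
  out
}

#' Memory specificity: multiplicity profile of output patterns
#'
#' Groups a cohort's runs by identical final active-output set and reports,
#' for each multiplicity m, how many runs sit in an m-copy class and how many
#' distinct patterns have exactly m copies — with the share of each under
#' both accountings (the run-level and the distinct-pattern-level
#' denominator).
#'
#' @param cohort A `cohort_result`.
#' @return Data frame with `multiplicity`, `n_patterns` (distinct sets with
#'   that many copies), `n_runs`, `run_percent` and `pattern_percent`.
#' @export
multiplicity_profile <- function(cohort) {
  keys <- output_keys(cohort)
  copies <- table(keys)
  prof <- table(as.integer(copies))
  mult <- as.integer(names(prof))
  n_patterns <- as.integer(prof)
  n_runs <- mult * n_patterns
  data.frame(multiplicity = mult, n_patterns = n_patterns, n_runs = n_runs,
             run_percent = 100 * n_runs / length(keys),
             pattern_percent = 100 * n_patterns / length(copies),
             row.names = NULL)
}

#' Per-node activation probability
#'
#' Fraction of a cohort's runs whose final active-output set contains each
#' output node. For a clean-slate cohort every run activates exactly k nodes,
#' so the probabilities sum to k.
#'
#' @param cohort A `cohort_result`.
#' @return Data frame with `node` (1..n) and `probability` (fraction in
#'   0..1).
#' @export
activation_probabilities <- function(cohort) {
  n <- cohort$config$n
  counts <- tabulate(unlist(cohort$final_active), nbins = n)
  data.frame(node = seq_len(n),
             probability = counts / length(cohort$pattern_ids))
}

#' Overlap of distinct output patterns between two cohorts
#'
#' @param a,b `cohort_result`s.
#' @return A `cohort_overlap`: list with `n_common`, `n_distinct_a`,
#'   `n_distinct_b`, and `fraction_a`, `fraction_b` (the common count divided
#'   by each cohort's own distinct-pattern count).
#' @export
cohort_overlap <- function(a, b) {
  ka <- unique(output_keys(a))
  kb <- unique(output_keys(b))
  common <- length(intersect(ka, kb))
  structure(
    list(n_common = common,
         n_distinct_a = length(ka), n_distinct_b = length(kb),
         fraction_a = common / length(ka), fraction_b = common / length(kb),
         rules = c(a$rule, b$rule)),
    class = "cohort_overlap"
  )
}

#' @export
print.cohort_overlap <- function(x, ...) {
  cat(sprintf("<cohort_overlap> %s vs %s: %d common distinct output patterns\n",
              x$rules[1], x$rules[2], x$n_common))
  cat(sprintf("  %.2f%% of %d (%s) and %.2f%% of %d (%s)\n",
              100 * x$fraction_a, x$n_distinct_a, x$rules[1],
              100 * x$fraction_b, x$n_distinct_b, x$rules[2]))
  invisible(x)
}

#' Summarize a cohort (optionally against a companion cohort)
#'
#' Bundles the iteration histogram, multiplicity profile and activation
#' probabilities, plus — when `other` is given — the pairwise similarity
#' histogram and distinct-pattern overlap.
#'
#' @param cohort A `cohort_result`.
#' @param other Optional second `cohort_result` over the same pattern ids.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(cohort, other = NULL) {
  out <- list(
    rule = cohort$rule,
    n_runs = length(cohort$pattern_ids),
    config = cohort$config,
    iteration_histogram = iteration_histogram(cohort),
    multiplicity_profile = multiplicity_profile(cohort),
    activation_probabilities = activation_probabilities(cohort)
  )
  if (!is.null(other)) {
    out$similarity_histogram <- pairwise_similarity(cohort, other)
    out$overlap <- cohort_overlap(cohort, other)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> rule = %s, %d runs\n", x$rule, x$n_runs))
  it <- x$iteration_histogram
  cat(sprintf("  %.2f%% of runs at %d iterations (max %d)\n",
              it$percent[1], it$iterations[1], max(it$iterations)))
  mp <- x$multiplicity_profile
  cat(sprintf("  unique output patterns: %.2f%% of runs\n",
              mp$run_percent[mp$multiplicity == 1]))
  ap <- x$activation_probabilities$probability
  cat(sprintf("  activation probability range: [%.2f%%, %.2f%%]\n",
              100 * min(ap), 100 * max(ap)))
  if (!is.null(x$overlap)) print(x$overlap)
  invisible(x)
}
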