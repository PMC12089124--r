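# Plain-text serialization: weights as CSV (with a JSON sidecar of the init
# parameters), calibration and run manifests as JSON, cohort results and
# per-statistic tables as CSV.

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a weight matrix
#'
#' The matrix goes to `path` as a headerless n x n CSV at full double
#' precision; the init parameters (`n`, `mu`, `sigma`, `seed`) go to a JSON
#' sidecar `<path>.json`.
#'
#' @param net A `synaptic_network`.
#' @param path CSV file path.
#' @param seed Seed recorded in the sidecar (informative only).
#' @return `path`, invisibly.
#' @export
write_weights <- function(net, path, seed = NA_integer_) {
  ch <- matrix(fmt_full(net$weights), net$n, net$n)
  utils::write.table(ch, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(n = net$n, mu = net$mu, sigma = net$sigma, seed = seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_weights
#' @return For `read_weights`, the reconstructed `synaptic_network`.
#' @export
read_weights <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(w) <- NULL
  if (nrow(w) != ncol(w)) stop("weight matrix must be square", call. = FALSE)
  if (any(w < 0)) stop("weight matrix has negative entries", call. = FALSE)
  side <- paste0(path, ".json")
  mu <- NA_real_; sigma <- NA_real_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    mu <- meta$mu; sigma <- meta$sigma
  }
  new_synaptic_network(nrow(w), w, mu = mu, sigma = sigma)
}

#' Write calibration artifacts
#'
#' Emits `calibration.json` (threshold, target and achieved fractions, valid
#' count), `valid_ids.csv` (one id per line) and, optionally,
#' `max_signals.csv` (pattern_id, max_signal).
#'
#' @param calib A `calibration`.
#' @param dir Output directory (created if needed).
#' @param max_signals Also write the full per-pattern maximum-signal table.
#' @param seed Seed recorded in the JSON (informative only).
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(calib, dir, max_signals = FALSE,
                              seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(threshold = calib$threshold,
         target_fraction = calib$target_fraction,
         achieved_fraction = calib$achieved_fraction,
         n_valid = length(calib$valid_ids),
         n_patterns = calib$n_patterns, n = calib$n, k = calib$k,
         seed = seed),
    file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(data.frame(pattern_id = calib$valid_ids),
                   file.path(dir, "valid_ids.csv"), row.names = FALSE)
  if (max_signals) {
    utils::write.csv(
      data.frame(pattern_id = seq_len(calib$n_patterns),
                 max_signal = calib$max_signals),
      file.path(dir, "max_signals.csv"), row.names = FALSE
    )
  }
  invisible(dir)
}

#' Write a cohort's per-run results as CSV
#'
#' One row per learned pattern: `pattern_id`, the active inputs
#' (semicolon-joined), the rule, the iteration count, the final active
#' outputs (semicolon-joined) and `preloaded_start` (1 when the run was
#' complete before any update).
#'
#' @param cohort A `cohort_result`.
#' @param patterns The valid-pattern matrix the cohort was run on.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, patterns, path) {
  stopifnot(nrow(patterns) == length(cohort$pattern_ids))
  df <- data.frame(
    pattern_id = cohort$pattern_ids,
    active_inputs = apply(patterns, 1L, paste, collapse = ";"),
    rule = cohort$rule,
    iterations = cohort$iterations,
    final_active = output_keys(cohort),
    preloaded_start = as.integer(cohort$iterations == 0L)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param config Config list stored into the reconstructed cohort.
#' @return For `read_cohort`, the reconstructed `cohort_result`.
#' @export
read_cohort <- function(path, config = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fin <- lapply(strsplit(as.character(df$final_active), ";", fixed = TRUE),
                as.integer)
  cfg <- utils::modifyList(
    list(n = max(unlist(fin)), k = min(lengths(fin)), threshold = NA_real_,
         seed = NA_integer_, preload_id = NA_integer_),
    config
  )
  new_cohort_result(df$rule[1L], df$pattern_id, df$iterations, fin, cfg)
}

#' Write a cohort summary as JSON plus per-statistic CSVs
#'
#' Emits `summary_<rule>.json` and `iterations_<rule>.csv`,
#' `multiplicity_<rule>.csv`, `activation_<rule>.csv`; when the summary holds
#' a comparison, also `similarity_<rules>.csv` and `overlap_<rules>.csv`.
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rule <- summary$rule
  js <- list(
    rule = rule, n_runs = summary$n_runs, config = summary$config,
    iteration_histogram = summary$iteration_histogram,
    multiplicity_profile = summary$multiplicity_profile,
    activation_probabilities = summary$activation_probabilities
  )
  utils::write.csv(summary$iteration_histogram,
                   file.path(dir, sprintf("iterations_%s.csv", rule)),
                   row.names = FALSE)
  utils::write.csv(summary$multiplicity_profile,
                   file.path(dir, sprintf("multiplicity_%s.csv", rule)),
                   row.names = FALSE)
  utils::write.csv(summary$activation_probabilities,
                   file.path(dir, sprintf("activation_%s.csv", rule)),
                   row.names = FALSE)
  if (!is.null(summary$overlap)) {
    tag <- paste(summary$overlap$rules, collapse = "_")
    sim <- summary$similarity_histogram
    attr(sim, "shared") <- NULL
    utils::write.csv(sim, file.path(dir, sprintf("similarity_%s.csv", tag)),
                     row.names = FALSE)
    ov <- summary$overlap
    utils::write.csv(
      data.frame(rule_a = ov$rules[1], rule_b = ov$rules[2],
                 n_common = ov$n_common,
                 n_distinct_a = ov$n_distinct_a,
                 n_distinct_b = ov$n_distinct_b,
                 fraction_a = ov$fraction_a, fraction_b = ov$fraction_b),
      file.path(dir, sprintf("overlap_%s.csv", tag)), row.names = FALSE
    )
    js$similarity_histogram <- sim
    js$overlap <- ov[c("n_common", "n_distinct_a", "n_distinct_b",
                       "fraction_a", "fraction_b")]
  }
  jsonlite::write_json(js, file.path(dir, sprintf("summary_%s.json", rule)),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the full configuration, the calibrated threshold and a run id so
#' that any output directory is self-describing.
#'
#' @param config A validated config list (see [load_config()]).
#' @param threshold Calibrated threshold (or `NA` before calibration).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(config, threshold, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = config, threshold = threshold,
         run_id = sprintf("plastisim-%s-seed%d",
                          format(Sys.time(), "%Y%m%dT%H%M%S"), config$seed),
         package_version = as.character(utils::packageVersion("plastisim"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
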