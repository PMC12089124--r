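# Run configuration: a flat JSON file supplying the model parameters, with
# defaults matching the reference study conditions.

#' Default run configuration
#'
#' The defaults are the reference study conditions: 30 input and 30 output
#' nodes, 6-of-30 input patterns, weights from Normal(1, 0.2) row-rescaled,
#' young learning rate 1.5, threshold calibrated so ~25% of patterns are
#' valid.
#'
#' @return A named list with `n`, `k`, `mu`, `sigma`, `alpha`,
#'   `target_fraction`, `seed`, `rules`, `output_dir`.
#' @export
default_config <- function() {
  list(n = 30L, k = 6L, mu = 1, sigma = 0.2, alpha = 1.5,
       target_fraction = 0.25, seed = 1L,
       rules = c("young", "old", "old_prior"),
       output_dir = "plastisim-out")
}

validate_config <- function(cfg) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(default_config(), cfg)
  cfg$n <- as.integer(cfg$n); cfg$k <- as.integer(cfg$k)
  cfg$seed <- as.integer(cfg$seed)
  for (key in c("mu", "sigma", "alpha", "target_fraction")) {
    if (is.numeric(cfg[[key]])) cfg[[key]] <- as.numeric(cfg[[key]])
  }
  cfg$rules <- as.character(cfg$rules)
  if (is.na(cfg$n) || cfg$n < 2L) stop("config: `n` must be >= 2", call. = FALSE)
  if (is.na(cfg$k) || cfg$k < 1L || cfg$k >= cfg$n) {
    stop("config: `k` must satisfy 1 <= k < n", call. = FALSE)
  }
  if (!is.numeric(cfg$mu) || cfg$mu <= 0) stop("config: `mu` must be > 0", call. = FALSE)
  if (!is.numeric(cfg$sigma) || cfg$sigma < 0) stop("config: `sigma` must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 1) stop("config: `alpha` must be > 1", call. = FALSE)
  if (!is.numeric(cfg$target_fraction) || cfg$target_fraction <= 0 ||
      cfg$target_fraction >= 1) {
    stop("config: `target_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("config: `seed` must be an integer", call. = FALSE)
  bad <- setdiff(cfg$rules, c("young", "old", "old_prior"))
  if (length(bad) > 0L) {
    stop("config: unknown rule(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Load (or save) a run configuration
#'
#' Reads a flat JSON object, fills unset keys with [default_config()] values,
#' rejects unknown keys and validates the parameter ranges (`k < n`,
#' `alpha > 1`, `0 < target_fraction < 1`).
#'
#' @param path JSON file path.
#' @return A validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  validate_config(as.list(cfg))
}

#' @rdname load_config
#' @param config A config list to write.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
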