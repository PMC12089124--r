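# Input-pattern space: all k-of-N binary activation patterns, and the
# empirical calibration of the firing threshold that defines the
# "before learning" state (no output active for a valid pattern).

#' Enumerate all k-of-n input patterns
#'
#' Generates every combination of `k` active input nodes out of `n`, in
#' lexicographic order. The pattern id is its row index in this order.
#'
#' @param n Number of input nodes.
#' @param k Number of active inputs per pattern (0 < k <= n).
#' @return An integer matrix with `choose(n, k)` rows and `k` columns, each
#'   row a strictly increasing set of active input indices (1-based), with
#'   attribute `pattern_ids` giving the id of each row.
#' @examples
#' enumerate_patterns(6, 2) # 15 patterns
#' @export
enumerate_patterns <- function(n, k) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n) ||
      !is.numeric(k) || length(k) != 1L || k < 1 || k != trunc(k)) {
    stop("`n` and `k` must be single positive integers", call. = FALSE)
  }
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  n <- as.integer(n); k <- as.integer(k)
  pm <- t(utils::combn(n, k))
  storage.mode(pm) <- "integer"
  attr(pm, "pattern_ids") <- seq_len(nrow(pm))
  pm
}

pattern_ids_of <- function(patterns) {
  ids <- attr(patterns, "pattern_ids")
  if (is.null(ids)) ids <- seq_len(nrow(patterns))
  ids
}

# Maximum output signal per pattern, computed exactly for the whole pattern
# space. Chunked so the transient M x n signal matrix stays modest.
pattern_max_signals <- function(net, patterns, chunk = 100000L) {
  m <- nrow(patterns)
  k <- ncol(patterns)
  w <- net$weights
  out <- numeric(m)
  start <- 1L
  while (start <= m) {
    end <- min(start + chunk - 1L, m)
    idx <- start:end
    s <- w[patterns[idx, 1L], , drop = FALSE]
    if (k > 1L) {
      for (c in 2:k) s <- s + w[patterns[idx, c], , drop = FALSE]
    }
    mx <- s[, 1L]
    if (net$n > 1L) for (j in 2:net$n) mx <- pmax(mx, s[, j])
    out[idx] <- mx
    start <- end + 1L
  }
  out
}

#' Calibrate the firing threshold over a pattern space
#'
#' Computes the maximum output signal of every pattern and places the
#' threshold at the empirical quantile of those maxima: with `M` patterns the
#' threshold is the value at rank `ceiling(target_fraction * M)` (1-based,
#' ascending). A pattern is *valid* when its maximum signal is strictly below
#' the threshold, so the valid count is the largest achievable not exceeding
#' `target_fraction * M`. Valid patterns are the model's "before learning"
#' state: no output node fires.
#'
#' @param net A `synaptic_network`.
#' @param patterns Pattern matrix from [enumerate_patterns()].
#' @param target_fraction Desired fraction of valid patterns, in (0, 1).
#' @return A `calibration` object: list with `threshold`, `target_fraction`,
#'   `max_signals` (per pattern id), `valid_ids`, `achieved_fraction`,
#'   `n_patterns`, `n`, `k`.
#' @export
calibrate_threshold <- function(net, patterns, target_fraction = 0.25) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction >= 1) {
    stop("`target_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- nrow(patterns)
  if (m == 0L) stop("`patterns` must be non-empty", call. = FALSE)
  mx <- pattern_max_signals(net, patterns)
  r <- as.integer(ceiling(target_fraction * m))
  threshold <- sort(mx, partial = r)[r]
  valid_ids <- which(mx < threshold)
  achieved <- length(valid_ids) / m
  if (length(valid_ids) == 0L) {
    warning("degenerate calibration: no pattern has maximum signal strictly ",
            "below the threshold (all maxima may be equal)", call. = FALSE)
  }
  structure(
    list(threshold = threshold, target_fraction = target_fraction,
         max_signals = mx, valid_ids = valid_ids,
         achieved_fraction = achieved, n_patterns = m,
         n = net$n, k = ncol(patterns)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> threshold T = %.4f (target %.0f%% of %d patterns)\n",
              x$threshold, 100 * x$target_fraction, x$n_patterns))
  cat(sprintf("  valid patterns: %d (%.2f%%), max signal strictly below T\n",
              length(x$valid_ids), 100 * x$achieved_fraction))
  invisible(x)
}

#' Extract the valid patterns of a calibration
#'
#' Valid patterns are those whose maximum output signal is strictly below the
#' calibrated threshold, in enumeration order.
#'
#' @param calib A `calibration` from [calibrate_threshold()].
#' @param patterns The same pattern matrix the calibration was computed on.
#' @return The subset of rows of `patterns` that are valid, with attribute
#'   `pattern_ids` giving their original pattern ids.
#' @export
valid_patterns <- function(calib, patterns) {
  if (nrow(patterns) != calib$n_patterns || ncol(patterns) != calib$k) {
    stop("pattern space does not match the calibration (size mismatch)",
         call. = FALSE)
  }
  out <- patterns[calib$valid_ids, , drop = FALSE]
  attr(out, "pattern_ids") <- calib$valid_ids
  out
}
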