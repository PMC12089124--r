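# Bipartite synaptic network: N binary input nodes fully connected to N
# real-valued output nodes by non-negative weighted edges. The weight matrix
# is the single source of truth; output signals are always recomputed from it.

#' Initialize a synaptic network
#'
#' Draws an `n` x `n` weight matrix with entries from Normal(`mu`, `sigma`)
#' and rescales every row (the outgoing weights of one input node) to sum to
#' one, matching a baseline state in which all input nodes are active and each
#' contributes unit total signal. Non-positive draws are rejected and
#' resampled, since weights model excitatory synaptic strengths and the row
#' rescaling presumes positive mass.
#'
#' Randomness comes from the R session RNG; call [set.seed()] beforehand for
#' reproducible networks.
#'
#' @param n Number of input nodes (= number of output nodes). Integer >= 2.
#' @param mu Mean of the normal draw. Must be positive.
#' @param sigma Standard deviation of the normal draw (>= 0).
#' @return A `synaptic_network`: a list with elements `n`, `weights` (an
#'   `n` x `n` matrix, entry `[i, j]` the weight from input `i` to output
#'   `j`), `mu` and `sigma`.
#' @examples
#' set.seed(1)
#' net <- initialize_weights(30)
#' range(rowSums(net$weights)) # every row sums to 1
#' @export
initialize_weights <- function(n, mu = 1, sigma = 0.2) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != trunc(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  n <- as.integer(n)
  w <- matrix(stats::rnorm(n * n, mu, sigma), n, n)
  bad <- which(w <= 0)
  rounds <- 0L
  while (length(bad) > 0L) {
    w[bad] <- stats::rnorm(length(bad), mu, sigma)
    bad <- bad[w[bad] <= 0]
    rounds <- rounds + 1L
    if (rounds > 1000L) {
      stop("rejection sampling of positive weights did not converge; ",
           "check `mu` and `sigma`", call. = FALSE)
    }
  }
  w <- w / rowSums(w)
  new_synaptic_network(n, w, mu = mu, sigma = sigma)
}

new_synaptic_network <- function(n, weights, mu = NA_real_, sigma = NA_real_) {
  structure(
    list(n = as.integer(n), weights = weights, mu = mu, sigma = sigma),
    class = "synaptic_network"
  )
}

#' @export
print.synaptic_network <- function(x, ...) {
  cat(sprintf("<synaptic_network> %d inputs x %d outputs\n", x$n, x$n))
  cat(sprintf("  init: Normal(mu = %s, sigma = %s), rows rescaled to sum 1\n",
              format(x$mu), format(x$sigma)))
  cat(sprintf("  weight range: [%.6f, %.6f]; row sums in [%.9f, %.9f]\n",
              min(x$weights), max(x$weights),
              min(rowSums(x$weights)), max(rowSums(x$weights))))
  invisible(x)
}

check_pattern <- function(net, active) {
  if (length(active) == 0L) return(integer(0))
  active <- as.integer(active)
  if (anyNA(active) || any(active < 1L) || any(active > net$n)) {
    stop("invalid pattern: active input indices must lie in [1, n]",
         call. = FALSE)
  }
  if (anyDuplicated(active)) {
    stop("invalid pattern: active input indices must be distinct",
         call. = FALSE)
  }
  active
}

#' Propagate an input pattern through the network
#'
#' Each output node accumulates the weights of its incoming edges from the
#' active input nodes only; edges from inactive inputs carry no signal.
#'
#' @param net A `synaptic_network`.
#' @param active Integer vector of active input node indices (1-based,
#'   distinct). May be empty, in which case all signals are zero.
#' @return Numeric vector of `n` output signals.
#' @examples
#' net <- fixture_network()$network
#' compute_signals(net, c(1L, 4L))
#' @export
compute_signals <- function(net, active) {
  active <- check_pattern(net, active)
  if (length(active) == 0L) return(numeric(net$n))
  .colSums(net$weights[active, , drop = FALSE], length(active), net$n)
}

#' Output nodes at or above the firing threshold
#'
#' An output node counts as activated when its signal reaches the threshold
#' (`signal >= threshold`, inclusive). Note the asymmetry with input-pattern
#' validity, which requires the maximum signal to be strictly below the
#' threshold.
#'
#' @param signals Numeric vector of output signals.
#' @param threshold Firing threshold, a positive number.
#' @return Integer vector of activated output indices (possibly empty).
#' @export
active_outputs <- function(signals, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  which(signals >= threshold)
}
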