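#' Small hand-readable fixture network
#'
#' A pinned 6 x 6 weight matrix (rows sum to one by construction) with
#' 2-of-6 input patterns and a firing threshold of 0.48, small enough that
#' the whole pattern space (15 patterns), the valid set and individual
#' learning runs can be verified by hand or by brute force. Used throughout
#' the test suite as the exact oracle case.
#'
#' @return A list with `network` (a `synaptic_network`), `threshold` and `k`.
#' @examples
#' fx <- fixture_network()
#' compute_signals(fx$network, c(1L, 5L))
#' @export
fixture_network <- function() {
  w <- rbind(
    c(0.30, 0.25, 0.15, 0.10, 0.12, 0.08),
    c(0.05, 0.35, 0.20, 0.15, 0.10, 0.15),
    c(0.20, 0.10, 0.30, 0.15, 0.10, 0.15),
    c(0.10, 0.15, 0.10, 0.35, 0.20, 0.10),
    c(0.15, 0.10, 0.20, 0.10, 0.30, 0.15),
    c(0.10, 0.20, 0.15, 0.10, 0.15, 0.30)
  )
  list(network = new_synaptic_network(6L, w), threshold = 0.48, k = 2L)
}
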