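# Learning rules. Young learning multiplies the active incoming weights of a
# roulette-selected output node by alpha (LTP-style strengthening). Old
# learning rewires: a roulette-selected edge into the chosen output absorbs,
# one merge per iteration, the weight of the nearest same-input edge
# (MIS-style rewiring), conserving each input row's total weight.
#
# RNG contract (all draws come from the R session RNG, one uniform each):
#   young, per iteration: 1 draw (output roulette).
#   old, per outer episode: 1 draw (output roulette) + 1 draw (first-edge
#   roulette), then per merge at most 1 draw (left/right coin, consumed only
#   when two candidate outputs are exactly equidistant).
# This ordering is fixed so that seeded runs are reproducible and traceable.

# One roulette draw over a non-negative value vector; returns a position.
roulette_pick <- function(values) {
  cs <- cumsum(values)
  tot <- cs[length(cs)]
  u <- stats::runif(1L) * tot
  sum(cs < u) + 1L
}

#' Fitness-proportionate (roulette-wheel) selection
#'
#' Selects one index from `pool` with probability proportional to
#' `values[j]` for `j` in `pool`.
#'
#' @param values Non-negative numeric vector of fitness values (for learning,
#'   the output signals or the incoming weight magnitudes).
#' @param pool Candidate indices into `values`. Defaults to all of them.
#' @return A single selected index (an element of `pool`).
#' @examples
#' set.seed(1)
#' roulette_select(c(0.2, 0.3, 0.5))
#' @export
roulette_select <- function(values, pool = seq_along(values)) {
  if (length(pool) == 0L) stop("`pool` must be non-empty", call. = FALSE)
  v <- values[pool]
  if (anyNA(v) || any(v < 0)) {
    stop("`values` must be non-negative and non-missing over `pool`",
         call. = FALSE)
  }
  if (sum(v) <= 0) {
    stop("roulette selection failed: total fitness over the pool is zero",
         call. = FALSE)
  }
  pool[roulette_pick(v)]
}

#' One young (LTP-style) weight update
#'
#' Multiplies by `alpha` the weights of all *active* incoming edges of output
#' node `j`, so the signal of `j` scales by exactly `alpha` while all other
#' signals are unchanged. Edges from inactive inputs are untouched.
#'
#' @param net A `synaptic_network`.
#' @param active Active input indices of the pattern being learned.
#' @param j Output node to strengthen.
#' @param alpha Learning rate, > 1.
#' @return The updated `synaptic_network`.
#' @export
young_step <- function(net, active, j, alpha = 1.5) {
  active <- check_pattern(net, active)
  stopifnot(length(j) == 1L, j >= 1L, j <= net$n, alpha > 1)
  net$weights[active, j] <- net$weights[active, j] * alpha
  net
}

#' One old (MIS-style) rewiring merge
#'
#' Moves the whole weight of edge (`i`, `k`) onto edge (`i`, `j`): the second
#' synapse of input `i` is rewired onto output `j`, which gains exactly the
#' signal output `k` loses. Row `i`'s total outgoing weight is conserved.
#'
#' @param net A `synaptic_network`.
#' @param i Input node the two edges share.
#' @param j Receiving output node.
#' @param k Donor output node (`w[i, k]` must be positive).
#' @return The updated `synaptic_network`.
#' @export
mis_step <- function(net, i, j, k) {
  stopifnot(length(i) == 1L, length(j) == 1L, length(k) == 1L,
            i >= 1L, i <= net$n, j >= 1L, j <= net$n, k >= 1L, k <= net$n,
            j != k)
  if (net$weights[i, k] <= 0) {
    stop("mis_step: donor edge weight w[i, k] is zero; it must not be selected",
         call. = FALSE)
  }
  net$weights[i, j] <- net$weights[i, j] + net$weights[i, k]
  net$weights[i, k] <- 0
  net
}

#' Select the first edge of an old-learning merge
#'
#' Roulette selection among the active incoming edges of output `j`, with
#' fitness equal to the weight magnitudes (not the signals).
#'
#' @inheritParams young_step
#' @param j Output node chosen for the update.
#' @return The selected input node index.
#' @export
select_first_edge <- function(net, active, j) {
  active <- check_pattern(net, active)
  if (length(active) == 0L) stop("pattern has no active inputs", call. = FALSE)
  w <- net$weights[active, j]
  if (sum(w) <= 0) {
    stop("first-edge selection failed: all active incoming weights of `j` are zero",
         call. = FALSE)
  }
  active[roulette_pick(w)]
}

# Nearest-candidate scan used by select_second_edge and run_old. `row` is the
# outgoing weight vector of input i; returns 0L when no candidate remains.
# Draws one uniform only when both directions hold an equidistant candidate.
nearest_donor <- function(row, j, blocked, n) {
  for (d in seq_len(n - 1L)) {
    l <- j - d
    r <- j + d
    ok_l <- l >= 1L && !blocked[l] && row[l] > 0
    ok_r <- r <= n && !blocked[r] && row[r] > 0
    if (ok_l && ok_r) {
      return(if (stats::runif(1L) < 0.5) l else r)
    }
    if (ok_l) return(l)
    if (ok_r) return(r)
  }
  0L
}

#' Select the second (donor) edge of an old-learning merge
#'
#' Among the outgoing edges of input `i`, candidates are outputs `k != j`
#' with positive weight that are neither already consumed in this episode nor
#' protected (currently activated outputs keep their incoming edges).
#' Anatomical proximity is modeled as nearest output index: the candidate
#' minimizing `|k - j|` wins; a fair coin breaks an exact left/right distance
#' tie; if only one side has candidates that side is taken. Output indices
#' are a line, not a ring.
#'
#' @param net A `synaptic_network`.
#' @param i Input node the first edge originates from.
#' @param j Output node receiving the merge.
#' @param consumed Output indices already merged in this episode.
#' @param protected Output indices whose incoming edges may not be taken
#'   (typically the currently activated outputs).
#' @return The donor output index, or `NA_integer_` when no candidate remains.
#' @export
select_second_edge <- function(net, i, j, consumed = integer(0),
                               protected = integer(0)) {
  stopifnot(length(i) == 1L, i >= 1L, i <= net$n,
            length(j) == 1L, j >= 1L, j <= net$n)
  blocked <- logical(net$n)
  blocked[c(j, as.integer(consumed), as.integer(protected))] <- TRUE
  k <- nearest_donor(net$weights[i, ], as.integer(j), blocked, net$n)
  if (k == 0L) NA_integer_ else k
}

new_learning_result <- function(rule, iterations, final_active, completed,
                                trace = NULL, network = NULL) {
  structure(
    list(rule = rule, iterations = iterations,
         final_active = as.integer(final_active), completed = completed,
         trace = trace, network = network),
    class = "learning_result"
  )
}

#' @export
print.learning_result <- function(x, ...) {
  cat(sprintf("<learning_result> rule = %s, iterations = %d, completed = %s\n",
              x$rule, x$iterations, x$completed))
  cat("  final active outputs:", paste(x$final_active, collapse = " "), "\n")
  invisible(x)
}

#' Learn one pattern with the young (LTP) rule
#'
#' Repeatedly roulette-selects an output node among those not yet activated
#' (fitness = current signals) and multiplies its active incoming weights by
#' `alpha`, until `length(active)` output nodes have reached the threshold.
#' Each weight update is one iteration. The starting pattern must be valid
#' (no output activated before learning).
#'
#' @param net A `synaptic_network`; the run works on a copy.
#' @param active Active input indices of the pattern.
#' @param threshold Firing threshold `T`.
#' @param alpha Learning rate, > 1.
#' @param trace If `TRUE`, record one event per iteration.
#' @param keep_network If `TRUE`, return the updated network in the result.
#' @return A `learning_result` with `iterations`, `final_active` (exactly
#'   `length(active)` outputs), `completed`, and optionally `trace` (a data
#'   frame with columns `iter`, `output`, `signal_after`) and `network`.
#' @export
run_young <- function(net, active, threshold, alpha = 1.5, trace = FALSE,
                      keep_network = FALSE) {
  active <- check_pattern(net, active)
  k <- length(active)
  if (k == 0L) stop("pattern has no active inputs", call. = FALSE)
  stopifnot(threshold > 0, alpha > 1)
  n <- net$n
  sub <- net$weights[active, , drop = FALSE]
  sig <- .colSums(sub, k, n)
  if (any(sig >= threshold)) {
    stop("pattern is not valid: an output node is already at threshold ",
         "before learning", call. = FALSE)
  }
  is_active <- logical(n)
  n_active <- 0L
  iter <- 0L
  ev_j <- integer(0); ev_sig <- numeric(0)
  while (n_active < k) {
    pool <- which(!is_active)
    sp <- sig[pool]
    if (sum(sp) <= 0) {
      stop("degenerate state: no selectable output has positive signal",
           call. = FALSE)
    }
    j <- pool[roulette_pick(sp)]
    sub[, j] <- sub[, j] * alpha
    sig[j] <- sig[j] * alpha
    iter <- iter + 1L
    if (sig[j] >= threshold) {
      is_active[j] <- TRUE
      n_active <- n_active + 1L
    }
    if (trace) { ev_j <- c(ev_j, j); ev_sig <- c(ev_sig, sig[j]) }
  }
  tr <- if (trace) {
    data.frame(iter = seq_len(iter), rule = "young", output = ev_j,
               input = NA_integer_, donor = NA_integer_, signal_after = ev_sig)
  }
  nw <- NULL
  if (keep_network) {
    nw <- net
    nw$weights[active, ] <- sub
  }
  new_learning_result("young", iter, which(is_active), TRUE, tr, nw)
}

#' Learn one pattern with the old (MIS rewiring) rule
#'
#' Outer loop: roulette-select a not-yet-activated output `j` (fitness =
#' current signals), then roulette-select a first edge (`i`, `j`) among `j`'s
#' active incoming edges (fitness = weight magnitude). Inner loop: repeatedly
#' rewire the nearest eligible same-input donor edge onto (`i`, `j`) — one
#' merge per iteration — until `j` fires or no donor remains. Donor
#' candidates exclude already-activated (protected) outputs and outputs
#' already consumed in the episode. The run completes when `length(active)`
#' outputs are at or above threshold; a start that already satisfies this
#' (e.g. preloaded weights) completes in zero iterations. Total output signal
#' and every input row sum are conserved throughout.
#'
#' @inheritParams run_young
#' @return A `learning_result`; `final_active` has at least `length(active)`
#'   outputs (exactly that many for a clean-slate start).
#' @export
run_old <- function(net, active, threshold, trace = FALSE,
                    keep_network = FALSE) {
  active <- check_pattern(net, active)
  k <- length(active)
  if (k == 0L) stop("pattern has no active inputs", call. = FALSE)
  stopifnot(threshold > 0)
  n <- net$n
  sub <- net$weights[active, , drop = FALSE]
  sig <- .colSums(sub, k, n)
  is_active <- sig >= threshold
  n_active <- sum(is_active)
  iter <- 0L
  episodes <- 0L
  ev_j <- integer(0); ev_i <- integer(0); ev_k <- integer(0); ev_sig <- numeric(0)
  while (n_active < k) {
    episodes <- episodes + 1L
    if (episodes > 100000L) {
      stop("old learning failed to progress (episode cap reached); ",
           "final signals: ", paste(signif(sig, 6), collapse = " "),
           call. = FALSE)
    }
    pool <- which(!is_active)
    sp <- sig[pool]
    if (sum(sp) <= 0) {
      stop("degenerate state: no selectable output has positive signal",
           call. = FALSE)
    }
    j <- pool[roulette_pick(sp)]
    i_pos <- roulette_pick(sub[, j]) # row position within the active inputs
    blocked <- is_active
    blocked[j] <- TRUE
    row <- sub[i_pos, ]
    merged <- FALSE
    while (sig[j] < threshold) {
      kd <- nearest_donor(row, j, blocked, n)
      if (kd == 0L) break
      w2 <- row[kd]
      row[j] <- row[j] + w2
      row[kd] <- 0
      sig[j] <- sig[j] + w2
      sig[kd] <- sig[kd] - w2
      blocked[kd] <- TRUE
      iter <- iter + 1L
      merged <- TRUE
      if (trace) {
        ev_j <- c(ev_j, j); ev_i <- c(ev_i, active[i_pos])
        ev_k <- c(ev_k, kd); ev_sig <- c(ev_sig, sig[j])
      }
    }
    sub[i_pos, ] <- row
    if (sig[j] >= threshold) {
      is_active[j] <- TRUE
      n_active <- n_active + 1L
    } else if (!merged) {
      # The selected episode could not move any weight. Hard-error only if no
      # selectable output has a (first edge, remaining donor) combination
      # left; otherwise another roulette draw can still progress.
      feasible <- FALSE
      for (j2 in pool) {
        if (sig[j2] <= 0) next
        open <- !is_active
        open[j2] <- FALSE
        for (p in seq_len(k)) {
          if (sub[p, j2] > 0 && any(sub[p, open] > 0)) { feasible <- TRUE; break }
        }
        if (feasible) break
      }
      if (!feasible) {
        stop("old learning reached an unreachable state: no donor edge can ",
             "be rewired toward any selectable output; signals: ",
             paste(signif(sig, 6), collapse = " "), call. = FALSE)
      }
    }
  }
  tr <- if (trace) {
    data.frame(iter = seq_len(iter), rule = "old", output = ev_j,
               input = ev_i, donor = ev_k, signal_after = ev_sig)
  }
  nw <- NULL
  if (keep_network) {
    nw <- net
    nw$weights[active, ] <- sub
  }
  new_learning_result("old", iter, which(is_active), TRUE, tr, nw)
}
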