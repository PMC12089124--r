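---
title: "plastisim: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastisim: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plastisim` is a simulation study in a box: a minimal bipartite network
model of synaptic learning, two biologically motivated weight-update rules
(one for young brains, one for ageing brains), and the cohort machinery to
measure how the two differ in speed and in the structure of the memories
they form. This vignette records the model, every tunable that matters, and
the design decisions taken where more than one reading was defensible.

## The model and its assumptions

The network is a complete bipartite graph: `n` binary input nodes, `n`
real-valued output nodes, and an `n x n` matrix of non-negative weights
`w[i, j]` from input `i` to output `j`. There are no hidden layers, no
recurrence, no inhibition, no temporal dynamics: a stimulus is a static
*k-of-n* set of active inputs, and the signal of output `j` is the plain sum
of its incoming weights from active inputs. Output `j` *fires* when its
signal reaches a global threshold `T` (inclusive, `>= T`).

Weights are initialized `Normal(mu, sigma)` and each input's outgoing row is
rescaled to sum to one, so that with all inputs active every input
contributes unit signal. Two consequences used throughout the package: for a
fresh network the total output signal of any k-pattern is exactly `k`, and
the mean signal per output is `k / n`. Non-positive draws are rejected and
resampled rather than clamped: the weights model excitatory synaptic
strengths and the row rescaling presumes positive mass. At the default
`mu = 1, sigma = 0.2` a non-positive draw has probability ~3e-7, so
resampling is a formality; it matters only for deliberately extreme
parameter choices.

*Learning* a pattern means driving `k` output nodes over `T`. The output to
update is drawn by roulette-wheel selection with probability proportional to
current signal, restricted to outputs that have not yet fired. The
restriction is a deliberate reading: completion is defined as `k` *distinct*
outputs firing, and a rule that could re-select an already-fired output
would burn iterations without progress, which is inconsistent with the young
rule's observed concentration at the minimum iteration count.

**Young rule (LTP-style).** The chosen output's *active* incoming weights
are multiplied by `alpha > 1`, so its signal scales by exactly `alpha` and
nothing else changes. Scaling only the active edges (rather than the whole
column) is again a reading: inactive edges carry no signal for the current
pattern either way, but the restriction matters for what a trained network
looks like to *other* patterns, and column-wide scaling would make
preloaded networks trivially solve almost every pattern, destroying the
prior-knowledge experiment.

**Old rule (MIS-style rewiring).** One episode: pick an output `j` (roulette
over signals), then a first edge `(i, j)` among `j`'s active incoming edges
(roulette over weight magnitudes). Then, one merge per iteration, the
nearest eligible edge of the *same* input `i` is rewired onto `(i, j)`:
`w[i, j] <- w[i, j] + w[i, k]; w[i, k] <- 0`. Merging continues until `j`
fires or no eligible donor remains, in which case a new episode starts with
a fresh roulette draw. Three conventions pin this down:

* *Proximity.* "Anatomical proximity" has no natural geometry in a weight
  matrix; we use distance in output index, `|k - j|`, to the first edge's
  target, with a fair coin breaking exact left/right ties and the nonempty
  side taken when only one side has candidates. Output indices are a line,
  not a ring — index 1 and index `n` are maximally distant. This is the
  minimal structure consistent with a second synapse forming "next to" the
  first.
* *Protection.* Donor candidates exclude outputs that have already fired:
  stealing their incoming weight could silently drop a consolidated memory
  back under threshold, breaking the meaning of completion. The cost is that
  late episodes have fewer donors available.
* *Accounting.* An iteration is one merge (the young analogue: one
  multiplicative update). Episodes that end without any merge consume no
  iterations; a stall with no possible progress anywhere raises a hard error
  (analytically unreachable from a fresh network, where each active row
  carries total weight 1 > T).

The old rule conserves the total output signal and every input row sum for
the entire run (to 1e-9 in the tests); the young rule grows signal
geometrically. Both therefore terminate.

## Threshold calibration

The threshold defines the "before learning" state: a pattern is *valid* when
its maximum output signal is *strictly below* `T` (validity is strict `<`,
firing is inclusive `>=`; a tie at `T` means the pattern is not valid). `T`
is set by a deterministic empirical quantile over the exhaustive pattern
space: sort the per-pattern maxima ascending and take the value at rank
`ceiling(target_fraction * M)`, which makes the strictly-below count the
largest achievable not exceeding the target. With the default target of 25%
over the 593,775 6-of-30 patterns this yields an achieved validity a hair
under 25% for continuous maxima, and gracefully degrades (to an empty valid
set, with a warning) for degenerate dispersion such as `sigma = 0`. The full
enumeration is computed exactly, in 100k-pattern chunks — at `n = 30, k = 6`
that is ~17.8M sums and a few seconds — rather than sampled; a manual
trial-and-error threshold search would add an arbitrary degree of freedom
with no benefit.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 30 | nodes per layer (dimensionless) |
| `k` | 6 | active inputs per pattern; also the completion count — ~20% sparsity, in the range reported for hippocampal CA1 engagement |
| `mu`, `sigma` | 1, 0.2 | weight init, before row rescaling (signal units) |
| `alpha` | 1.5 | young multiplicative learning rate per update |
| `target_fraction` | 0.25 | intended valid share of the pattern space |
| `seed` | 1 | master seed; every other stream derives from it |

The interaction that dominates the *speed* statistics is between `T` and the
signal dispersion. After row rescaling the weight standard deviation is
approximately `sigma / (mu * n)`, so a k-pattern's output signals have mean
`k / n` and standard deviation roughly `sigma * sqrt(k) / (mu * n)` — about
0.016 at the defaults — and the quantile `T` sits in the upper tail of that
distribution. Whether a young update clears the threshold in one step
depends on `T / alpha` relative to that narrow signal distribution, and
whether an old merge (typical donor weight `~1/n`) clears it depends on the
`T - O_j` gap; both are therefore exquisitely sensitive to `sigma`. The
*structural* statistics (similarity, uniqueness, activation uniformity,
overlap) are driven by the roulette randomness instead and are robust to
`sigma`. This is the model's main known limitation as a quantitative tool:
the iteration histograms should be read as regime indicators, not as
calibrated predictions, unless `sigma` itself has been pinned against the
dispersion of the system being modeled.

## Cohort experiments and reproducibility

A cohort learns every valid pattern independently on a fresh copy of the
calibrated network — there is no interference between patterns, no shared
consolidation, and no capacity question (deliberately out of scope). Each
run's RNG stream is seeded from `(master seed, rule, pattern id)`, so
cohorts are bit-reproducible, independent of execution order, and
parallelizable in principle without changing results. The draw order within
a run is fixed and documented (young: one uniform per iteration; old: two
uniforms per episode plus one per exact-distance tie), which is what makes
the fixture traces in the test suite exactly reproducible.

The prior-knowledge experiment preloads the network by young-learning one
valid pattern chosen uniformly at random under the master seed (its id is
recorded in the cohort config), then runs the old rule over all valid
patterns from that shared preloaded state. Runs that start with `k` or more
outputs already firing record zero iterations. The preloaded pattern's
identity noticeably moves the zero-iteration and under-`k` shares (patterns
overlapping the preloaded inputs are the beneficiaries), so these shares
should be reported per seed rather than as constants of the model.

## Numerical choices

* All conservation checks use 1e-9 absolute tolerance; exactness claims
  (signal scaling by `alpha`, merge deltas) are asserted at 1e-12.
* Signals are always recomputed from the current weights when a run starts;
  within a run they are updated incrementally by the exact per-update deltas
  (multiplication by `alpha`; add/subtract the moved weight), never
  approximated.
* Roulette selection inverts the cumulative sum at a single uniform draw;
  zero-fitness candidates have probability zero, and a zero total mass is an
  error, not a silent fallback.
* Indices are 1-based everywhere (API and files), the native R convention.
* Thresholds are reported at 4 decimals in printed summaries but used at
  full precision internally; CSV weight serialization keeps 17 significant
  digits so round-trips are lossless at double precision.

## What the generator does and does not emulate

The synthetic network generator *is* the study system: the model has no
external data. It emulates sparse stimulus coding (k-of-n), heterogeneous
but balanced synaptic strengths (row-normalized normal weights), and a
before-learning state defined by threshold calibration. It does not emulate
neuron counts or connectivity at biological scale, inhibition, synaptic
decay or LTD, stochastic transmission, or any anatomy beyond the index-line
proximity convention. Passing tests therefore demonstrate internal
consistency of the mechanisms and statistics under the stated conditions —
young learning faster than old, largely disjoint but equally specific
memory traces, prior knowledge accelerating old learning — not quantitative
agreement with any particular biological measurement.

## Worked check at the defaults

The quickest full check is the study driver used by the acceptance script
(about a minute of compute):

```{r, eval = FALSE}
library(plastisim)
study <- run_study(seed = 1)
study_statistics(study)[c("young_at_min_pct", "old_at_min_pct",
                          "similarity_le2_pct", "unique_young_pct",
                          "overlap_pct", "prior_mean_iterations")]
```

The test suite additionally verifies the hand-steppable 6-node fixture
(exact traces for both rules under recorded uniforms), the brute-force
valid-set oracle, the roulette chi-square law, all conservation properties,
and byte-identical reproducibility of the file-based CLI pipeline.
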