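# plastisim

`plastisim` simulates how learning speed and memory formation differ between
young and ageing brains, using a deliberately small, fully analyzable model:
a bipartite artificial neural network in which learning a stimulus means
driving a set of output neurons over a firing threshold by repeated synaptic
weight updates. It is aimed at computational neuroscientists who want a
controlled test bed for comparing synaptic plasticity mechanisms, and at
anyone who wants to reproduce or perturb the model's published-style cohort
statistics (learning-speed histograms, output-pattern similarity, memory
specificity, activation uniformity, prior-knowledge speed-up).

## The model

The network is a complete bipartite graph with `N` binary input nodes and
`N` real-valued output nodes. Weights are drawn `w_ij ~ Normal(mu, sigma)`
(non-positive draws resampled) and each input's outgoing row is rescaled to
sum to 1. A stimulus is a *k-of-N* input pattern; the signal of output `j`
is

```
O_j = sum over active inputs i of w_ij
```

and output `j` fires when `O_j >= T`. The threshold `T` is calibrated over
the exhaustive `choose(N, k)` pattern space as the empirical quantile of
per-pattern maximum signals, so that a target fraction (default 25%) of
patterns are *valid* — i.e. fire no output before learning. Learning a valid
pattern means driving `k` outputs over `T`, one update per iteration, with
the output to update drawn by roulette-wheel (fitness-proportionate)
selection over the current signals of the not-yet-active outputs,
`P(j) = O_j / sum O`:

* **young rule (LTP-style)** — all active incoming weights of the chosen
  output are multiplied by a learning rate `alpha > 1` (default 1.5), so its
  signal scales by exactly `alpha`;
* **old rule (MIS-style rewiring)** — a first edge `(i, j)` into the chosen
  output is drawn by roulette over weight magnitudes; then, one merge per
  iteration, the nearest eligible edge of the *same input* `i` (by output
  index, fair coin on distance ties) is rewired onto it:
  `w_ij <- w_ij + w_ik; w_ik <- 0`. Total signal and every row sum are
  conserved; already-active outputs are protected from losing edges.

A third experiment starts old learning from weights *preloaded* by young
learning of one valid pattern, modeling learning on top of prior knowledge.
Defaults are `N = 30`, `k = 6`, `mu = 1`, `sigma = 0.2`, `alpha = 1.5`,
target validity 25%.

## Worked example

```r
library(plastisim)
study <- run_study(seed = 1)   # ~1 minute: 593,775 patterns, 3 cohorts
print(study$calibration)
print(study$young)
print(study$old)
stats <- study_statistics(study)
```

prints

```
<calibration> threshold T = 0.2278 (target 25% of 593775 patterns)
  valid patterns: 148443 (25.00%), max signal strictly below T
<cohort_result> rule = young, 148443 runs (threshold 0.2278, seed 1)
  iterations: min 6 / mean 6.00 / max 7; 99.71% at the minimum
<cohort_result> rule = old, 148443 runs (threshold 0.2278, seed 1)
  iterations: min 6 / mean 8.72 / max 17; 4.39% at the minimum
```

Both rules need at least `k = 6` iterations (one output can newly fire per
update). Young learning is much faster: almost every run finishes at the
minimum because one multiplicative boost usually lifts the selected output
over the threshold, whereas old learning must accumulate several small
rewired weights per output. The remaining headline statistics from the same
`stats` object:

```
similarity <= 2 shared nodes: 92.59%
unique outputs: young 77.60%, old 77.50%
activation probabilities in [18.99%, 21.05%], max young-old gap 0.38 pp
distinct-output overlap: 22.23%
prior knowledge: 2.99% at 0 iterations, 53.79% under 6, mean 5.26 vs 8.72
```

Read: the two rules store the *same* stimulus in mostly different output
patterns (>92% of matched runs share at most 2 of 6 active outputs, and only
~22% of distinct output patterns occur under both rules), yet both are
similarly specific (~78% of runs produce a cohort-unique output pattern) and
spread activity near-uniformly across output nodes. Preloading the network
with one young-learned pattern makes old learning substantially faster on
average (mean 5.26 vs 8.72 iterations), with ~3% of patterns already learned
at the start. The dispersion of the weight distribution strongly shapes the
speed statistics — see the methods vignette (`vignettes/plastisim-methods.Rmd`)
for how the iteration histograms move with `sigma`.

A shell front end covering the same pipeline (with CSV/JSON artifacts) is
installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "plastisim", package = "plastisim"))')" \
  report --seed 1 --out runs/demo
```

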