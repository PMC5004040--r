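---
title: "Methods: response-surface modelling and gene-set GA optimization of Phellinus fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface modelling and gene-set GA optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phellopt)
```

## The problem

*Phellinus* is a medicinal fungus whose flavonoids are produced at useful
scale only by submerged (liquid) fermentation, and the flavonoid yield
depends strongly on the culture conditions. phellopt models that dependence
and searches for the condition that maximizes predicted yield. Seven factors
span the condition space: inoculum size (volume fraction), medium pH,
initial liquid volume (mL), temperature (°C), seed-culture age (days),
fermentation time (days) and shaker rotation speed (r/min).

The package works in two stages:

1. **Response-surface regression.** A second-order polynomial
   \(Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
   \sum_{i<j} \beta_{ij} x_i x_j\)
   is fitted to experiment records by ordinary least squares, with terms
   chosen by partial-F stepwise selection.
2. **Evolutionary maximization.** The fitted surface is maximized over the
   feasible factor box by a *gene-set* genetic algorithm: a binary
   chromosome is partitioned into one contiguous segment per factor, and
   mutation resamples whole segments instead of flipping single bits.

A frozen, published 14-term yield equation (`printed_yield_model()`) is
bundled as a fixed reference objective, and a closed-form box-constrained
maximizer (`analytic_box_maximum()`) serves as an exact oracle for
validating the stochastic optimizer.

## The data and the filtering rules

The bundled dataset (`phellinus45()`) holds one-factor-at-a-time sweeps:
pH 1–14, initial volume 40–140 mL, inoculum 2–16 %, temperature 25–40 °C
and fermentation time 1–12 days, 44 records in total. (The originating
study describes the campaign as 45 experiments while its tables print 44
rows; the fixture reproduces the printed tables row-for-row.)

Records used for regression are restricted to the closed box in which the
process is biologically sensible (`factor_bounds()`): inoculum 5–12 %,
pH 5–7, volume 60–100 mL, temperature 25–30 °C, seed age 4–9 d, time
6–12 d, rotation 140–200 r/min. Two readings of the inoculum filter exist
in the source material — "0.5–1.2 %" as literally printed, and 5–12 % —
and the package defaults to the corrected 5–12 % reading because the data
contain no inoculum below 2 % and the reported optimum (12 %) is reachable
only under it; the literal reading stays available as
`factor_bounds("literal")`. Intervals are closed on both ends because
boundary settings (100 mL, 140 r/min) appear in the retained data. The
default box keeps 16 of the 44 printed records. Deduplication
(`dedup_records()`) removes only rows identical in *all* factors and the
yield; rows with equal conditions but different yields are biological
replicates and are kept. Inoculum is stored as a fraction throughout
(0.05–0.12) because the frozen published equation reproduces its reported
optimum only with a fractional first factor; user-facing output renders it
as a percentage. Fermentation time is treated in days everywhere: one
printed table header says hours, but the accompanying text and every
numeric value are consistent with days, so this is a labelling choice with
no numeric effect.

## The regression stage

`candidate_terms()` enumerates the full second-order pool: 7 squares and
all 21 pairwise interactions, plus (by default) the 7 linear main effects —
the published final model contains linear terms, so the default candidate
pool must offer them; `include_linear = FALSE` restores the squares-and-
interactions-only pool. The interaction set is generated combinatorially,
so every unordered pair appears exactly once.

`rsm_fit()` solves the least-squares problem by QR decomposition. Designs
with fewer records than columns, or rank-deficient designs, are rejected
with the collinear columns named — with heavily confounded
one-factor-at-a-time data this happens routinely and silently aliased
coefficients would be misleading.

`rsm_stepwise()` implements classic probability-of-F stepwise selection:
the best excluded candidate enters while its partial-F p-value (F with
(1, df_residual) degrees of freedom) is at most `p_enter`, then included
terms with removal p-value at least `p_remove` are dropped, worst first.
Ties in p-value are broken by candidate order. The defaults, entry 0.5 and
removal 0.10, follow the published analysis settings. Because the entry
threshold exceeds the removal threshold, a term whose p-value lies between
them can enter and be dropped forever; termination is guaranteed by three
guards: a just-removed term may not re-enter until another term changes
state, any state change that would revisit an earlier model state halts
the search (committing a pending removal first, so the oscillating term
ends excluded), and a hard cap of `2 * n_candidates^2` state changes
backs both up. Entry steps that would exhaust the residual degrees of
freedom are skipped.

`rsm_anova()` reports the usual decomposition — regression and residual
sums of squares about the mean, df (number of non-intercept terms, and
n − terms − 1), F, R, R² and residual standard error.

**What a refit can and cannot show.** The published analysis reports an
ANOVA with 24 total degrees of freedom (n = 25), but the stated filters
keep only 16 of the printed records, so the exact published row set is not
recoverable and the package does not attempt to reproduce the published
F or R² numerically. Correctness of the regression engine is instead
established against independent oracles: a normal-equations solve on small
toys (agreement to 1e−8), exact recovery of known coefficients from
noise-free synthetic data, the textbook F formula computed long-hand, and
a coverage study described below.

## The frozen yield equation and its exact maximizer

`printed_yield_model()` stores the published final equation verbatim —
14 terms plus intercept, coefficients to three decimals, never refit. At
the published optimal condition (12 % inoculum, pH 5.8, 100 mL, 28 °C,
age 9 d, time 9 d, 150 r/min) it predicts 2144.104, about 0.3 % below the
published prediction of 2150.128; that gap is the irreducible effect of
coefficient rounding and is accepted rather than "un-rounded" away.

Because the equation couples only volume and rotation speed (the single
x3·x7 interaction), its exact maximum over a box decomposes into six
one-dimensional quadratics (vertex or boundary) and one two-dimensional
block (interior stationary point, four edges, corners), all solvable in
closed form. `analytic_box_maximum()` implements this block decomposition
for any fitted surface whose interaction graph couples at most two factors
per connected component; larger blocks raise an error rather than silently
approximating. Over the default box the analytic maximum is 2150.128 at
(12 %, pH 5.87, 100 mL, 28.10 °C, 9 d, 9.04 d, 150.9 r/min).

## The gene-set genetic algorithm

Each factor occupies one contiguous run of bits (default 10), decoded
linearly onto its interval, so all-zero decodes to the lower bound and
all-one to the upper. Ten bits quantize each range into 1023 steps — at
most 0.002 pH units — far finer than the one-decimal precision at which
optima are reported. The fixed seven-segment layout is used; the variant
in which gene-sets start at half the chromosome length is noted in the
source material but is not the implemented reading, since the segments are
explicitly tied to the seven parameters.

Defaults follow the published run: population 50, crossover rate 0.8,
mutation rate 0.01, roulette-wheel selection, at most 500 generations.
Design choices that the source left open:

* **Mutation is per segment, not per bit.** The gene-set operator is
  defined as segment replacement, so the 0.01 rate is interpreted as the
  probability that each of the 7 segments of an individual is replaced by
  a fresh uniform segment.
* **Crossover cuts at bit level.** The cross operator is described
  classically, with the gene-set notion reserved for mutation; a
  segment-boundary variant is available via
  `ga_config(segment_crossover = TRUE)`.
* **One elite individual.** Elitism is not stated, but without it a
  roulette GA loses its best solution and the best-fitness trace would not
  converge monotonically; `elite_count = 0` disables it.
* **Selection weights** are the shifted fitnesses `f − min(f) + ε` with
  `ε = 1e-9 × range(f)`, which handles negative fitnesses and degenerates
  to uniform sampling when the population has converged.
* **Stopping** is whichever comes first of the generation cap, an optional
  fitness limit, or 50 generations without a best-fitness improvement
  greater than 1e-9. The published run happened to stop after 156
  iterations; that count is seed-dependent and is not treated as a target.

A run is fully reproducible from its seed; identical seeds give
bit-identical traces. Non-finite objective values abort the run with the
decoded condition named.

## The synthetic-data generator

`simulate_surface()` draws conditions uniformly inside the factor box (or
as one-factor-at-a-time sweeps mimicking the real design) and adds
Gaussian noise with configurable standard deviation to the true surface
value. Gaussian noise is the simplest model that makes parameter-recovery
studies well-posed; the generator deliberately does *not* emulate
heteroscedastic measurement error, batch effects, or the discreteness of
the real sweeps' factor levels. Passing recovery tests on this generator
therefore shows that the estimation machinery is correct, not that the
biological error structure is Gaussian.

The default noise sd of 25 yield units is roughly 1–2 % of the yields near
the optimum of the frozen surface, a realistic precision for replicated
fermentation assays. The recovery study refits the 14 true terms on
n = 100 uniform records at that noise level, 200 replicates: for every
coefficient, the estimate lies within 3 estimated standard errors of truth
in at least 95 % of replicates. (The coverage criterion is per
coefficient; a joint all-15-coefficients-at-once version of the same check
would sit exactly at its own threshold by construction — expected pass
rate \((1 - P(|t_{85}| > 3))^{15} \approx 0.949\) — and would therefore be
uninformative.)

## Problem sizes and numerical choices

The validation suite uses deliberately modest problem sizes — 20 GA runs
of ≤ 500 generations for the seeded optimization experiment, 200
replicates of n = 100 for recovery, 10⁴–10⁵ draws for distributional
checks of the operators — chosen so the full pipeline re-runs from scratch
in well under a minute while keeping Monte-Carlo error far from every
decision boundary. The GA-vs-oracle comparison accepts the decoded arg-max
within the per-factor reporting tolerances (0.5 percentage points of
inoculum, 0.15 pH, 2 mL, 0.5 °C, 0.5 d, 0.5 d, 2 r/min): along
near-flat directions of the surface (the rotation-speed curvature is only
0.234 yield units per (r/min)²) a finite-budget stochastic search cannot
resolve a single 0.06 r/min quantization step, and demanding it would test
the arithmetic of the encoder, not the optimizer. The analytic maximizer
itself is checked against a dense 200-steps-per-axis grid to within one
grid step and 0.1 yield units.

## Known limitations

* The stepwise refit of the bundled data is honest but weak: 16 heavily
  confounded one-factor-at-a-time records cannot support a 35-term
  candidate pool, and the selected model is small with modest R². The
  frozen published equation is the reproducible objective;
  `run_pipeline(use_printed_model = TRUE)` is the reference mode.
* The closed-form maximizer handles interaction blocks of at most two
  factors; richer fitted surfaces fall back to the GA alone.
* Yield units are not stated in the source data and are treated as
  arbitrary; no uncertainty is propagated through predictions or optima.
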