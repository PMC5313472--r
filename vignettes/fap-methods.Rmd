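---
title: "Future average production: models, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Future average production: models, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fapr)
```

This vignette is the package's own account of the science: the models,
the estimation choices, what the synthetic-herd generator does and does
not emulate, and the limitations a user should keep in mind. Everything
quantitative stated here is computed by the test suite or the acceptance
script; nothing is quoted from elsewhere.

## The quantity being predicted

FAP is the expected production value of milk per day of remaining life,
for one cow at one moment. "Per day of remaining life" includes dry
periods and integrates over whether the cow reaches further lactations
at all, so a high-yielding cow that is unlikely to calve again can rank
below a mediocre cow in early lactation. Production value (PVM) is
energy-corrected milk adjusted for the cow's marginal effect on the
bulk-tank somatic-cell price correction, so a high-cell cow is charged
the revenue her cells cost the whole tank.

## Component models and their assumptions

**Lactation curve.** Per herd and parity group {1, 2, 3+}, ECM follows
a Wood curve `a·DIM^b·exp(-c·DIM)` with a pregnancy decline term. Two
algebraic groupings of that term are supported; the default multiplies
the pregnancy slope by DIM (`exp(-(c + I_P d (DIM - DIM_P)) DIM)`), the
alternative adds it (`exp(-c DIM - I_P d (DIM - DIM_P))`). The flattened
typography of the source formula admits both readings; the framework is
insensitive to the choice (any lactation-curve family would do), so both
are selectable via `milk_parse` and the default is the literal reading.
Each cow enters only through one multiplicative level per lactation,
`alpha_m`, relative to the herd-average cow. Assumptions: cow effects
are proportional (no cow-specific shape), parity groups share shapes,
and the herd's feeding/management is stable over the training window.

**Cell-count curve.** Total test-day cells (tSCC = SCC x milk) follow
`exp(exp(alpha_c a + b DIM) + d exp(-exp(c) DIM) - e)` with `e` Euler's
number. The constant `e` is absorbable into `a`, and the typeset source
formula does not determine the grouping uniquely; an alternative
`"power"` grouping (`exp(-exp(c) DIM^d)` for the early component) is
selectable via `scc_parse`, and the chosen parse travels in the
serialized model file. Because `alpha_c` sits inside a double
exponential, the cow level is on a compressed scale: a few hundredths
above 1 is already a markedly cell-heavy cow. tSCC is fitted on the log
scale, which stabilises the variance and matches the multiplicative
noise of cell counts.

**Survival.** The probability of reaching a further lactation, as a
function of days open, is a generalised logistic
`S(t) = A - A/[1+(2^nu - 1) e^{-B(t-M)}]^{1/nu}` — `(2^nu - 1)` scaled
so `M` is always the half-asymptote point. It is fitted only on cows at
or above herd-average milk level: below-average cows are culled at the
manager's discretion, so their observed survival confounds biology with
selection, while above-average cows show survival that is stable in
yield. Fitting is weighted least squares on binned surviving fractions
(30-day bins, bin counts as weights, one reweighting step with inverse
binomial variances at fitted values). The logistic sub-family (`nu = 1`)
is fitted first and the asymmetric family accepted only when an F-test
supports it: with realistic days-open distributions the shoulders of
the curve are sparsely observed and `B` and `nu` trade off along a
ridge (for large `nu` the family degenerates to an exponential in
`B/nu`), so the parsimonious fit is the stabler estimate.

**Level carry-over.** Deviations of a cow's level from 1 regress toward
the herd mean across lactations with coefficient `xi`, estimated as the
slope of a no-intercept regression on cows observed in consecutive
lactations (herd-specific when at least 10 pairs exist, otherwise pooled
across herds). Jumps over several lactations multiply the per-step
coefficients; steps beyond parity 3 reuse the 3+ estimate. Because the
regressors are themselves estimated levels, the slope is attenuated
toward zero by estimation noise; no disattenuation is applied, matching
the plain regression the method is defined with (see Limitations).

**Smoothing.** Every record is converted to an instantaneous level
against its herd curve and smoothed exponentially; `lambda` in [0, 1]
balances responsiveness against noise and is chosen on a 0.01 grid to
minimise the squared distance between the smoothed value and the mean of
the cow's strictly later observations. The grid is deterministic and
global across herds (a per-herd `lambda` is possible but the objective
is nearly flat at herd sample sizes). Heifers start at level 1, or at a
dam-derived prior `1 + 0.3 (dam level - 1)` when the dam is in the data.

**Pricing.** The stepwise bulk-SCC price scheme is interpolated through
the band-midpoint anchors, linearly between and beyond them, so that
every marginal change in bulk SCC has a price consequence. Only the two
published anchors ship as defaults (+2% below 200, -4% in 400-500,
x1000 cells/mL); any national scheme can be supplied as a table of
bands. One consequence worth knowing: under a globally linear
interpolation the per-cow price charge is herd-size invariant to first
order (the charge is slope x Delta x total ECM, and Delta shrinks as
1/herd size while total ECM grows proportionally); the dilution of the
raw stepwise scheme survives interpolation only through curvature.

**Combination.** The predicted last day in milk is `DIM_P + 282 - 56`
for pregnant cows and `max(DIM + 226, 287)` for open cows (gestation
282 d, dry period 56 d, mean time to conception 61 d; all configurable
via `repro_constants()`). Future lactations run over days 3..287 (the
summation starts at day 3 to avoid the DIM^b singularity at calving)
and are averaged over the standard parity time `T_S = 282 + 61 = 343`
days. A symbol table in the source lists 321 for this constant while the
defining ratio prints 343; the package follows the defining ratio and
treats 321 as an erratum, with `t_s` configurable for either convention.
Survival for a pregnant cow is evaluated at her conception day (days
open stopped accruing there). The final-lactation distribution `gamma`
is normalised to sum to 1 over lactations j+1..8 given survival past j
(its normalisation is not otherwise pinned down). In the fitted model it
is built by life-table chaining of per-parity continuation
probabilities estimated from all resolved lactations, rather than from
the empirical final parity of completed cow careers: a 3-year training
window never contains a completed 4-lactation career, so the naive
empirical distribution is censored toward short futures, while
continuation rates are estimable at every parity. The lactation horizon
8 is configurable, and FAP is insensitive to raising it because `gamma`
folds the tail mass into the horizon.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_points` | 6 | recordings | minimum to fit a cow level; thinner lactations default to 1 (or the dam prior) |
| `min_lactations` | 20 | lactations | minimum per herd/parity group for a curve fit |
| `min_pairs` | 10 | cow pairs | below this, `xi` pools across herds |
| `min_cows_survival` | 25 | cows | below this, survival pools parities within herd |
| `completion_margin` | 120 | days | a cow absent this long before data end counts as culled, not truncated |
| gestation / dry / conception | 282 / 56 / 61 | days | Holstein reproduction calendar |
| `t_s` | 343 | days | standard time per future parity (282 + 61) |
| `n_max` | 8 | parities | lactation horizon |
| price bands | +2% < 200; -4% in 400-500 | % and x1000 cells/mL | published anchors; user-configurable |

## The synthetic-herd generator

`simulate_herds()` emulates the structure the estimation assumes, so
every stage is testable against known truth: herd curves calibrated so
mean ECM by parity sits mid-range of commercial records (25.7 / 29.1 /
30.3 kg for parities 1 / 2 / 3+), milk levels N(1, 0.4) truncated at
0.05, tSCC levels log-normal with unit median and 40% spread, level
carry-over 0.3, within-lactation level drift (random walk, 0.02 per
test) so the smoother has signal to track, observation noise 2.5 kg ECM
and 0.5 on log tSCC, and a herd test calendar of 6 or 11 visits/year.
Days open average exactly 61 days — prompt conceivers (85%) plus a
repeat-breeder tail (15%, mean 140 d) that covers the descending limb of
the survival curve; survival to the next lactation is Bernoulli at the
true sigmoid evaluated at realized days open, with truth
A = (0.92, 0.88, 0.82), B = 0.035, nu = 1, M = (180, 160, 140) per
parity group. Culling is driven only by the survival curve (a
yield-blind manager), so the generator matches the model's assumptions.

Two deliberate departures from the fitted model's own scale: the tSCC
cow level is drawn multiplicatively (log-normal) rather than inside the
double exponential, because an additive-in-exponent level with a 0.4
spread would produce astronomically heavy tails — recovery of `alpha_c`
is therefore assessed as correlation on the implied log-multiplicative
scale; and recorded pregnancy appears 35 days after conception (the
recognition lag of real recording), which the training pipeline undoes
by backdating within each lactation, as a retrospective database extract
would.

What the generator does **not** emulate: disease episodes, seasonality
of calving and yield, yield-dependent culling bias (available behind a
switch for robustness experiments, off by default), heterogeneous
herd-level feeding trends, and recording errors. Passing recovery tests
on this generator therefore demonstrates the estimation machinery is
correct under the model's own assumptions — not that the model captures
every force in real herd data.

## Numerical choices

Nonlinear fits use Levenberg-Marquardt (`minpack.lm`) with heuristic
Wood-curve starts and a small deterministic grid of perturbed starts;
the best converged attempt by residual sum of squares wins. The
pregnancy slope is dropped (fixed at 0) when a group has no pregnant
records, which otherwise leaves a zero gradient. Cow milk levels have a
closed-form weighted-ratio solution; cow tSCC levels are a 1-D
minimisation on [-10, 10] with tolerance 1e-9. The tSCC curve clamps
its log-scale value at 500 (with a warning) to guard overflow for
extreme levels. Smoothing skips missing levels, carrying the previous
value forward. Day sums use integer DIM with inclusive bounds; a cow
already past her predicted dry-off gets a zero current-lactation
contribution and a warning. Model files round-trip through JSON at full
double precision.

## Evaluation design and its limits

The validation harness follows the original design: for every
test-period cow-day, FAP and three naive predictors (latest PVM, mean
of last three, lifetime mean) are compared against the realized future
mean PVM weighted by (281 + 61 - 56)/(281 + 61) for dry-off (the
literal printed constant, kept as-is), aggregated per herd, with
rank-sum tests across herds. On model-matched synthetic herds the
ordering reproduces: FAP closest, latest PVM second, mean-of-three and
lifetime mean behind.

Two honest caveats, both visible in the test suite:

* **Survival asymptote.** At single-herd cohort sizes (~100 completed
  lactations per parity group, halved by the above-average-yield cut),
  `A` is identified only by the curvature of the plateau approach and
  its estimates pile up at the `A <= 1` bound: across 50 replicate
  herds the mean fitted `A` exceeds truth by about +0.08 while `B`,
  `nu` and `M` recover within Monte-Carlo error. This is a property of
  the data design, not the optimizer — simulations with wide days-open
  coverage recover all four parameters. The fitted survival *curve* is
  accurate where data live, which is what FAP consumes.
* **Benchmark truncation.** With a 1-year test window the realized
  future mean covers only a fragment of remaining life: a parity-1
  cow's observed future misses her higher-parity lactations (so FAP
  reads high against it) while an older survivor's observed future is
  one full high-yield lactation with no death paths (so FAP reads low).
  Herd means inherit a seed-dependent centre of a few tenths of kg/day.
  The per-day arithmetic of FAP itself is verified independently against
  Monte-Carlo life-course simulation to Monte-Carlo precision.

Problem sizes used throughout the test suite — 100-cow herds over 4
years for recovery (50 replicates), 20 such herds for the accuracy
experiment — were chosen as the smallest sizes at which every fitting
stage has the data its preconditions require (20 lactations per curve,
25 cows per survival fit) while the whole suite stays comfortably
reproducible on a laptop.
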