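---
title: "Timing copy-number gains and whole-genome duplication: models and methods"
author: "gainTiming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing copy-number gains and whole-genome duplication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainTiming)
```

# The problem

Clonal copy-number gains — present in every tumor cell — can be placed on a
*mutation-time* axis running from 0 (conception) to 1 (the end of the
tumor's clonal evolution, its most recent common ancestor). The axis is the
normalised count of accumulated clonal SNVs: order-preserving, but not
linear in calendar time. The principle is simple: when an allele copy is
duplicated, every SNV already on it is duplicated too. An SNV present on
`m` copies ("multiplicity m") must predate the gains that raised its copy
to `m`. Read counts carry this signal: an SNV of multiplicity `m` in a
segment of total tumor copy number `n_t`, in a sample of purity `rho`, has
expected variant-allele fraction

$$\mathrm{VAF} = \frac{m\,\rho}{\rho\, n_t + 2(1-\rho)}.$$

For a segment with major/minor allele copies (2,1) this gives the classic
single-gain timing estimator. For *complex* states — three or more copies
of one parental allele — the segment's history is no longer unique: many
sequences of independent gains, a whole-genome duplication (WGD), and
losses can produce the same final state. This package enumerates those
histories ("routes"), scores them against the SNV read counts, and returns
a joint posterior over routes, gain times, and a sample-shared WGD time.

# Routes as tagged binary trees

Each parental allele's surviving history is a rooted tree: the root edge
starts at time 0 with one copy, internal nodes are duplications, and leaves
at time 1 are the surviving final copies. Nodes are tagged:

* `g` — independent gain (non-WGD samples), time free in (0, 1);
* `p` / `q` — independent gain before / after the WGD, time free in
  (0, t~w~) / (t~w~, 1);
* `w` — the WGD duplicated this lineage and both daughters survive;
* `x` — the lineage crossed the WGD but the duplicated daughter left no
  surviving descendants: one implied loss;
* `0` — the whole allele was lost (one loss).

In a WGD sample, every root-to-leaf path crosses the WGD exactly once (at
a `w` or an `x`). Losses are placed minimally — only where the final state
forces them — because loss times are unidentifiable from SNV
multiplicities and enter only through the event count. Trees are unordered
(children sorted canonically), and when both alleles have the same final
copy number the allele pair is unordered too; two histories that induce
the same multiplicity-spectrum function for all timings are thereby one
canonical route. Route counts grow quickly with the state: 6 for 2+2 with
WGD, 15 for 3+2, 75 for 4+3, 666 for 5+5. Segments whose state admits more
than `maxRoutes` (default 500) canonical routes are reported but not
timed; segments with fewer than `minSnvs` (default 20) SNVs likewise.

The expected multiplicity spectrum of a route at concrete timings is
proportional to branch length: an edge spanning mutation-time `[a, b]`
with `lambda` surviving descendant copies contributes `b - a` to the
weight of multiplicity `lambda`, and weights are normalised over all
surviving branches. The test suite validates the enumeration exactly
against a brute-force generator of per-copy event sequences (all states
with major copy number up to four) and the spectra against Monte-Carlo
simulation of mutations on explicit copy genealogies (all routes with
major copy number up to five).

# Likelihood, evidence, and the joint posterior

SNV alt counts are binomial draws at the multiplicity-specific expected
VAF; the segment likelihood is the product over SNVs of the
spectrum-weighted binomial mixture. For each route the *model evidence*
integrates this likelihood over the route's timing region with a uniform
prior — gain times i.i.d. uniform on their phase range, conditioned on the
tree order, i.e. uniform on the constrained region. The evidence is
estimated by Monte Carlo with common random numbers: per route we draw
`nDraws` (default 120) order-consistent uniforms once and reuse them for
every value of the WGD time, which makes the evidence curves smooth in
t~w~ and the whole computation reproducible from one seed.

Because the region prior is normalised, the evidence penalises extra
*free* gain parameters through the usual Occam factor but does not care
how narrow the phase range is; this is the direct reading of a uniform
prior over routes and timings. (The alternative — a prior uniform on the
unit box truncated to the region — implicitly down-weights routes with
small constraint regions, i.e. a non-uniform route prior, and is not used.)

For WGD samples the simultaneity of the WGD across the genome is the key
constraint. The WGD time is discretised on a grid of `twGridCells`
(default 40) cell midpoints; each segment contributes a route-mixture
evidence curve over the grid, and the posterior factorises by the chain
rule: t~w~ is drawn from its gridded marginal (the product of the
segments' mixture curves, uniform prior), with uniform jitter inside the
cell, and then each segment's route and gain times are drawn conditionally
by importance-resampling the stored integration draws. This samples the
same joint posterior a Metropolis-within-Gibbs scheme would target, with
no burn-in or convergence diagnostics, and every draw is exact given the
grid resolution (0.025, well inside the posterior width at the coverage
this package targets). 250 joint draws are stored by default. Non-WGD
samples factorise over segments and skip the grid.

## The event-count penalty

Evidence alone penalises extra gain *parameters* but is indifferent to
implied *losses*. To obtain conservative route calls, each route's
evidence can be multiplied by `exp(-n * l)` where `n` is its total event
count (gains + losses + WGD) and `l` defaults to 2.7; `l = 0` disables
the penalty. `tunePenalty()` re-fits `l` by bisection on a cohort
simulated with exclusively parsimonious histories so that the average
posterior mass on non-parsimonious routes is ~5%. The stored evidence
curves make re-applying any penalty free — no inference re-run.

The penalty deliberately trades calibration for conservatism: on
histories that truly are non-parsimonious it shifts mass to simpler
routes and, because pre-WGD gains then get absorbed into the WGD
bifurcation, biases the WGD time early. The test suite separates the two
regimes. Recovery accuracy (timing RMSE, credible-interval coverage,
WGD-time precision) is assessed on cohorts simulated through
most-parsimonious histories — the realistic regime, since a WGD tumor's
mode-two genome is WGD-derived — scored with the default penalty, whose
prior then matches the truth. Posterior *calibration* in the
prior-matched sense (routes drawn uniformly from each state's route set,
penalty off) is also exercised; in that regime gain-timing coverage
holds, but the WGD time is only loosely determined because uniformly
drawn histories often contain no WGD-informative segment.

## WGD calling

`callWgd()` computes the bp-weighted modal major copy number. Mode 1 is
non-WGD; mode ≥ 3 is flagged `ambiguous_multi` (possible multiple WGDs —
out of scope for timing). For mode 2, every major-copy-number-two segment
with enough SNVs is timed independently under one synchronised gain, and
the sample is called WGD when time points exist that stab the 90%
credible intervals of segments covering at least 60% of the mode-2 base
pairs; the maximal-overlap time point is reported. Ties in the bp mode
resolve toward the larger copy number (conservative: flags review rather
than silently timing). The 60%/90% thresholds and the ≥ 5
reads-per-clonal-copy sample filter are exposed in `timingConfig()`.

# The simulator

`simulateSample()` generates ground-truth tumors: per segment a state, a
generating route (uniform over the state's canonical routes, or only the
most parsimonious on request), timings uniform on the route's region, and
SNVs as a Poisson process along surviving branches (`snvRate` per bp per
copy per unit mutation time; default 1e-6 with 20–60 Mb segments gives
~50–150 SNVs per segment). Read counts follow Poisson depth around the
purity-adjusted coverage (`reads per clonal copy` in 5–15 by default,
purity uniform on 0.4–0.9 — the operating range of bulk tumor whole
genomes worth timing) and binomial alt counts at the expected VAF. True
multiplicities and mutation times are annotated on every SNV.

The simulator emulates read-count noise, purity dilution and coverage; it
does *not* emulate segmentation error, subclonal copy number, kataegis,
sequencing error, or mappability artifacts. Passing recovery tests
therefore demonstrates correctness of the inference given correct clonal
copy-number input, not robustness to upstream errors in real data.

# Cohort analyses

All cohort statistics consume the stored joint draws:

* `gainRateRelativeToWgd()` — bp-weighted posterior density of
  (gain time − WGD time) in 0.1-wide bins (one bin centred on zero,
  span the 1st–99th offset percentiles), divided by the same construction
  with gain times replaced by uniforms; both sides are per-sample
  equalised so heterogeneous genome sizes cannot tilt the ratio, and a
  uniform-gain cohort gives a flat curve at 1.
* `postWgdGainPrevalence()` — a tumor counts as having post-WGD gains
  when ≥ 50% of any segment's draws contain one; non-WGD controls
  receive a same-cancer-type WGD tumor's timing posterior; cancer types
  need ≥ 10 tumors per group.
* `wgdGainProximity()` — mean over 25 WGD-time draws of the bp-weighted
  median |gain − t~w~|, against a within-cancer-type permutation of the
  WGD-time posteriors.
* `classifyPunctuated()` — dispersion = bp-weighted SD of per-segment
  posterior-median gain times; the null resamples each segment's timing
  from the cancer-type pool (1,000 permutations); punctuated below the
  5th percentile; tumors with gains on fewer than three chromosomes are
  uninformative. The dispersion statistic and segment-level resampling
  unit are package choices (several reasonable variants exist) and are
  isolated in one function for easy substitution.
* `classifyPrePostEvents()`, `armEventRates()`, `panGenomeLandscape()` —
  pre/post-WGD gain counts averaged over draws; losses read off the minor
  copy number (0 = pre-WGD loss, 1 = post-WGD loss); arm calls use the
  50%-of-bp rules; the post-WGD loss frequency is corrected for mutual
  exclusivity by dividing by one minus the pre-WGD loss frequency
  (clipped at 0.95), and pan-genome tracks are normalised so the genome
  integral is 1e9.

# Numerical choices and degenerate inputs

* Exact `.5` allele copy numbers round half-to-even (deterministic,
  unbiased); rounding that inverts major/minor re-orders them.
* Segments with major copy number 0 or 1 are never timed (nothing
  observable); minor copy number 0 contributes no branches.
* Zero-depth SNVs are excluded with a warning; SNVs are sorted by
  position at assembly so results are invariant to input order, and all
  randomness derives from one integer seed per call.
* Timing draws on constrained regions use vectorised rejection from
  i.i.d. uniforms — exact, and the acceptance indicator is independent of
  t~w~, enabling the common-random-number evidence curves.
* Mixture likelihoods are floored at 1e-300 before logs; evidence
  aggregation uses log-sum-exp throughout.
* Interval stabbing for the WGD caller evaluates candidate points at
  interval endpoints only (the coverage function is piecewise constant).

# Problem sizes

The package's validation suite uses cohorts of 16–50 simulated tumors
with 8–15 segments each and ~20–150 SNVs per segment, route sets up to
120 routes per segment, a 40-cell WGD grid, 120 Monte-Carlo draws per
route and cell, and 250 stored posterior draws. These sizes put every
headline check (route-oracle equality, spectrum MC agreement, timing and
WGD recovery, penalty calibration, null calibrations) within a desk-scale
run while leaving the estimators' Monte-Carlo error well below the
tolerances being asserted.

# Limitations

* Losses are not timed; they enter only as event counts and through the
  minor-copy-number loss classes.
* Multiple WGDs are out of scope (`ambiguous_multi`).
* Mutation time is not calendar time; no clock-like conversion is
  attempted.
* Route identifiability is intrinsically limited: distinct routes can fit
  the same read counts (notably pre-WGD gains just before t~w~ versus the
  WGD itself), which is exactly why the posterior spreads mass across
  routes and why the event-count penalty exists. On cohorts simulated
  with exclusively parsimonious histories the package assigns the
  majority of posterior mass to non-parsimonious routes when the penalty
  is off — concentrated on the complex states this package exists to
  time — and ~5% with the default penalty.

# Session info

```{r}
sessionInfo()
```
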