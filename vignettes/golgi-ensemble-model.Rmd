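---
title: "The Golgi cell ensemble conversion: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Golgi cell ensemble conversion: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GolgiEnsemble)
```

## The biological computation being modelled

Granule cell axons rise into the molecular layer and split into parallel
fibres, which contact Golgi cells in passing. Golgi cells in turn inhibit
granule cells via GABA spillover inside glomeruli, closing a negative
feedback loop around the granular layer. The hypothesis this package
simulates is that the loop's forward arm is a *statistical* computation:
the fraction of parallel fibres that are active (the activity density *j*,
in percent) is converted into a proportional, narrowly-distributed level of
glomerular inhibition, by nothing more than repeated random sampling and
averaging implemented in the anatomy.

Three physiological readings drive the model:

* **Gap junctions between Golgi apical dendrites equalise charge.** A
  dendrite plus the dendrites it shares charge with form a gap-junction
  group; charge sharing makes the group's depolarisation approach the
  *mean* of its members' synaptic input. Statistically: a sample mean of a
  random sample of the ensemble's dendritic input counts.
* **Somatic integration averages a cell's dendrites,** and firing rate is
  linear in somatic depolarisation, so on a normalised scale somatic charge
  and rate are the same number.
* **Intraglomerular GABA spillover averages afferent rates.** Each
  glomerulus receives a random subset of the ensemble's Golgi cells; its
  GABA concentration tracks the mean of their rates.

Every stage is an unbiased average, so the expected output equals the
expected input while the spread contracts — central-limit behaviour. The
scientific payoff is the dependence of the two output qualities on *j*:
**precision** (the SD of the 700 per-glomerulus values of one field) and
**accuracy** (the SD of the field mean across repeated fields/runs). Both
degrade as *j* grows, which predicts that a sparse code is the
self-stabilising operating point of the feedback loop.

## The input model

With `fibresPerTerritory` = 175,000 parallel fibres crossing a
single-dendrite territory and a density *j*, the active count is
*n* = round(*j*/100 × 175,000): 700 at 0.4%, 1,050 at 0.6%, 1,400 at 0.8%.
Each active fibre contacts a given cell with probability
`contactProbability` = 0.00342 (about 1,200 contacts from ~350,000 fibres
through a whole-cell territory, i.e. 1 in ~292), and a single apical
dendrite with a third of that (3 dendrites per cell). The active-input
count *k* is then binomial, and `pmfActiveInputs()` evaluates its mass
function.

Two numerical decisions:

* **Log-space evaluation.** The binomial coefficient is computed via
  `lgamma`; the direct factorial form overflows for *n* in the hundreds.
  The implementation agrees with an independent cumulative-product
  evaluation to ~1e-11 relative error over the sweep grid (the residual is
  `lgamma` rounding at *n* of a few thousand).
* **Rounding of n.** The standard density grid gives integer counts; for
  arbitrary *j* the count rounds to the nearest integer, because a binomial
  needs an integer number of trials.

A display convention, not a model feature: tabulated distributions
(`probabilityTable()`, `truncatedPmf()`) omit entries with probability
≤ 0.001. Sampling always uses the full mass function.

A deliberate tension is preserved rather than "corrected": the per-cell
contact probability derives from the whole-cell territory (~350,000
fibres), while the trial count uses the single-dendrite territory
(175,000). The model is implemented exactly as stated, with both constants
exposed in `ConnectivityParams`; `activeContactFraction()` provides the
whole-cell-territory figure (0.00343% of the population at 1% activity)
from its own printed inputs (1,200 of 2 × 175,000).

## The conversion chain and its open choices

A run (`runConversion()`) chains four stages under one seeded generator.
Where the biology underdetermines the algorithm, the package makes an
explicit choice and exposes the alternative:

* **Who is "surrounding"?** The matrix geometry of the dendrite population
  is not defined anatomically, so by default each dendrite samples its 6
  partners uniformly from all 89 others — the hypothesis-neutral reading.
  `EnsembleConfig(neighbourhoodWindow = W)` restricts partners to index
  distance ≤ W for sensitivity analysis.
* **Self-inclusion.** "Surrounding" is read literally: the focal dendrite
  is excluded from its own sample. `includeSelf = TRUE` gives the
  alternative where the group includes its defining member.
* **One synchronous pass.** All 90 group means are taken from the same
  snapshot; there is no iteration towards an ensemble-wide equilibrium.
  Physiological charge sharing is web-like (chains of links), which would
  only strengthen equalisation; the single pass is the conservative
  simplification.
* **Somatic partition.** The triples are a uniformly random disjoint
  partition of all 90 group means, fixed per run from the seed, not
  constrained to an anatomical field. The partition is recorded in the
  result (`somaticPartition()`) so the averaging can be independently
  re-derived.
* **Glomerular convergence.** The convergence of Golgi cells on one
  glomerulus is unknown; the model draws a sample size uniformly from
  8–12 *per glomerulus* (about a third of the 30 cells in range), samples
  that many distinct somata, and averages. Sampling is without replacement
  within a glomerulus (a cell innervates a given glomerulus at most once)
  and independent across glomeruli, which is what makes the glomerular
  population behave like sampling with replacement in the aggregate.
* **Units.** The whole chain runs on the normalised scale of "active
  inputs per dendrite"; somatic charge, firing rate and glomerular
  inhibition are the same numbers. No stage rescales.

## Seeding and reproducibility

One run consumes one seeded generator in a fixed documented order:
the dendritic binomial draw; the 90 gap-junction samples in index order;
the somatic permutation; the glomerular sample sizes, then the 700
per-glomerulus samples in order. Experiments expand a master seed into
per-replicate child seeds (`childSeeds()`, drawn once under the master
seed, all below 2^31) and record them in their detail tables, so any single
replicate can be reproduced in isolation. `runConversion()` restores the
caller's RNG state. Serialization writes doubles at 17 significant digits,
so a written table re-read from disk is bit-identical.

## The experiments and their problem sizes

The package's experiment drivers reproduce four analyses. The replicate
counts below are the package defaults used by its own test suite and
acceptance script; they were sized so that each monotonicity statement is
resolved with a comfortable margin over Monte-Carlo noise.

* **Precision sweep** (`precisionSweep()`): within-field SD of the 700
  glomerular values across *j* = 0.4–2% in steps of 0.2, 100 replicate
  conversions per grid point. The adjacent-point SD gaps are ~7% while the
  mean-of-100 SD estimate has ~1.5% relative error, so the rank ordering
  is stable.
* **Accuracy sweep** (`accuracySweep()`): SD of 100 field means per grid
  point. A single 100-field sweep estimates that SD with ~7% relative
  error — the same size as the adjacent-point gaps — so the package runs
  30 replicate sweeps per point and averages the within-sweep SDs (~1.3%
  error). The grand means are also regressed on *j*
  (`sweepLinearity()`); unbiased averaging makes the relationship linear
  with slope 1,750 × 0.00342/3 per percent, and R² ≈ 1.
* **Group-size sweep** (`groupSizeSweep()`): the swept sizes default to
  {2, 4, 6, 8, 10, 12}, bracketing the assumed physiological value 6; the
  anatomical grid is not otherwise constrained. The stage-2 contraction
  ratio (pooled group-mean SD over pooled input SD) follows 1/√size within
  a few percent — the deviation is the finite-population correction for
  sampling 6–12 of 89 without replacement, at most ~7% at size 12 —
  and the glomerular SD shows the rapidly diminishing return above size 6.
* **Repeated runs** (`repeatedRuns()`): the conversion repeated at fixed
  *j*, re-sampling every stage each run ("the same input distribution" is
  read as re-drawing from it, not freezing one realisation). Tracked per
  run: mean dendritic input, mean group mean, mean somatic value, field
  mean. The paired contrast of across-run output SD at *j* = 2% vs 0.4%
  uses 100 paired master seeds with 50 runs per arm; the true SD ratio is
  ~√5, so 50 runs resolve each pair at ~5–6 standard errors.

### A note on run-to-run "independence" of output

It is sometimes said of this conversion that the output series varies
independently of the input series except in mean and SD. Taken literally —
zero correlation of run-to-run output means with run-to-run input means —
that cannot hold in this model and the package does not assert it: each
stage is an *unbiased* average of the previous one, so a run with an
unusually high mean dendritic count necessarily tends to a high field mean
(measured correlation ≈ 0.93 at both 0.4% and 2%). What is true, and what
the tests assert, is that (i) the group-mean series is an unbiased tracker
of the dendritic series, (ii) the output adds stage-sampling noise beyond
the input fluctuation, and (iii) the magnitude of the across-run output SD
is controlled by the activity density, not by anything else in the chain.

## What the generator does and does not emulate

The simulation is open-loop and distributional. It captures: binomial input
statistics under decorrelated (independent, uniform) parallel-fibre
activity; unbiased hierarchical averaging; the resulting mean conservation
and variance contraction; and the dependence of output precision/accuracy
on activity density and group size. It does **not** model spike timing or
burst structure, membrane biophysics, GABA kinetics, 2-D field geometry,
per-granule-cell inhibition, or the closed feedback loop (granule cell
activity responding to inhibition over time) — the self-regulation argument
rests on the open-loop transfer properties. Passing tests therefore speak
to the statistical mechanism, not to biophysical realism of any single
cell.

## Degenerate inputs and edge behaviour

* A density small enough that no fibre is active propagates exact zeros
  through every stage, with zero SD.
* `buildDistribution()` requires *j* > 0 (there is nothing to tabulate at
  zero density); `pmfActiveInputs()` itself accepts *j* = 0 and returns the
  degenerate mass at *k* = 0.
* `convergenceMin = convergenceMax = 30` makes every glomerulus average the
  whole soma population: the output is exactly the somatic mean, with zero
  spread.
* A gap-junction group spanning the whole population is rejected by
  validation (`gapGroupSize` must be below the dendrite count); a finite
  `neighbourhoodWindow` must be at least `gapGroupSize` so every dendrite
  has enough partners.
* Every stage output is a convex combination of its inputs, so each
  stage's range is contained in the previous stage's range; this is
  enforced as a validity invariant of `ConversionResult`.

## A short session

```{r example, eval = FALSE}
res <- runConversion(j = 1, seed = 1L)
stageSummary(res)

ps <- precisionSweep(replicates = 100L, seed = 5L)
perPoint(ps)
plotSweep(ps)

cfg <- loadConfig(system.file("extdata", "example-config.yaml",
                              package = "GolgiEnsemble"))
as1 <- accuracySweep(cfg$experiment$jGrid, nFields = cfg$experiment$nFields,
                     params = cfg$connectivity, config = cfg$ensemble,
                     seed = cfg$experiment$seed)
sweepLinearity(as1)
```
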