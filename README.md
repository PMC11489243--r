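# GolgiEnsemble

A seeded stochastic simulator of the cerebellar granular-layer **Golgi cell
ensemble conversion**: how the density of parallel-fibre activity is
converted, through a chain of random sampling-and-averaging steps, into a
narrow, proportional level of inhibition of granule cells.

## The model

Golgi cells are the interneurons that inhibit granule cells. The package
models one *ensemble* — the Golgi cell population of a sagittal row of three
"fields" (10 cells per field, 3 apical dendrites per cell, so 90 dendrites
and 30 somata), all inhibiting the 700 glomeruli of the middle field.

**Input.** When a fraction *j* (percent) of the general parallel-fibre
population is active, the number of active fibres crossing a single-dendrite
territory is *n* = round(*j*/100 × 175,000). Each active fibre contacts a
given Golgi cell with probability *p* = 0.00342 (1 in ~292), or *p*/3 for a
single one of its 3 apical dendrites. The number of active inputs *k* to a
cell or dendrite is therefore binomial:

    P(k) = C(n, k) p^k (1 − p)^(n−k),   n = round(j/100 · 175000)

evaluated in log space (the factorials are far beyond direct evaluation).

**Conversion chain.** One run draws 90 independent dendritic counts from
that distribution, then averages three times:

1. *Gap-junction equalisation* — each dendrite's value is replaced by the
   mean of a random sample (size 6) of surrounding dendrites, all taken
   simultaneously from the same snapshot. This is the computational reading
   of dendritic gap junctions: charge sharing takes a sample mean.
2. *Somatic integration* — the 90 group means are randomly partitioned into
   pre-assigned triples (one Golgi cell each) and averaged → 30 somatic
   values. On the normalised scale these same numbers are the firing rates.
3. *Glomerular sampling* — each of the 700 glomeruli averages the rates of
   a random subset of 8–12 of the 30 cells (sample size drawn per
   glomerulus), modelling GABA spillover as averaging of afferent rates.

Each stage is an unbiased average, so the mean is conserved down the chain
while the spread contracts (central-limit behaviour, roughly 1/√sample
size). The experiments quantify the two output qualities: **precision**
(spread of the 700 per-glomerulus values within a field) and **accuracy**
(reproducibility of the field mean across fields/runs). Both degrade as *j*
rises — the basis of the conclusion that a sparse parallel-fibre code is
self-stabilising, because conversion fidelity is highest at low density.

## Worked example

```r
library(GolgiEnsemble)

res <- runConversion(j = 1, seed = 1L)
stageSummary(res)
#>        stage   n     mean         sd
#> 1  dendritic  90 1.988889 1.28513056
#> 2      group  90 2.022222 0.47351845
#> 3    somatic  30 2.022222 0.23416200
#> 4 glomerular 700 2.024547 0.06181447
```

At 1% activity a dendrite receives on average 1750 × 0.00342/3 ≈ 2.0 active
inputs. The run above shows the chain at work: the stage means all sit near
2.0 (mean conservation) while the SD collapses from 1.29 across dendrites to
0.06 across glomeruli — inhibition delivered to the middle field is tightly
synchronised and proportional to input density.

```r
ps <- precisionSweep(replicates = 5L, seed = 7L)
perPoint(ps)
#>     j meanOutput   sdWithin
#> 1 0.4  0.7673587 0.05610997
#> 2 0.6  1.1582058 0.06285551
#> ...
#> 9 2.0  3.8871895 0.11024477
```

Mean output rises linearly with *j* while the within-field SD roughly
doubles from 0.4% to 2% active — the precision cost of a denser code.

The same experiments are scriptable from a shell via the thin CLI at
`inst/scripts/golgi-ensemble` (subcommands `table1`, `convert`,
`sweep {precision|accuracy|groupsize}`, `repeat`; YAML/JSON config via
`--config`, flags override the file, every output ships with a JSON
manifest recording the resolved parameters and seeds).

## Documentation

The methods vignette (`vignettes/golgi-ensemble-model.Rmd`) describes the
model assumptions, parameter choices, seeding scheme, numerical decisions
and known limitations in detail.
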