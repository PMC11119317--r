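# icbreedsim

Stochastic simulation of multi-stage line-breeding programs for a binary
cereal-legume intercropping system, built to answer a resource-allocation
question breeders of intercrop varieties face: **at which selection stage
should phenotypic testing switch from cheap monocrop plots to expensive
intercrop combination plots?**

A trial of *n* candidate lines per crop costs *n* monocrop plots but
*n²* intercrop combination plots, so early intercrop testing screens far
fewer lines. Monocrop testing screens many lines but selects for
intercrop performance only indirectly, through the genetic correlation
*R* between a line's monocrop (MC) and intercrop (IC) trait. The package
simulates this trade-off for two classic line-development methods for
self-pollinating crops - doubled haploids (DH) and ear/pod-to-row
selfing (EPR) - over repeated breeding cycles.

## Model

Each crop (a faba-bean-like legume and a triticale-like cereal) is
simulated as 100 homozygous founders on a single diploid chromosome with
2000 segregating sites and a 1-Morgan map. Both traits are controlled by
the same 1000 biallelic QTL; per-QTL additive effects are drawn from a
bivariate standard normal with correlation *R* and rescaled so founder
genetic values (GVs) have mean 0 and variance 1. The GV of an intercrop
combination is the mean of its components' IC GVs,

> g = (g_f + g_t) / 2,

and a plot phenotype adds Gaussian noise with variance sigma_e²/r, where
r is the stage's replication and

> sigma_e² = (1 − h²) sigma_a² / h².

Meiosis follows the Haldane model (Poisson crossovers, no interference).
Every scheme runs three trial stages per cycle under an identical plot
budget - PYT: 784 × 1 rep, AYT: 144 × 2 reps, EYT: 36 × 4 reps - with
truncation selection between stages (in IC mode, on each line's mean
phenotype across its tested partners). The EYT is always an intercrop
trial of 36 combinations from 6 + 6 elite lines, where genetic progress
is measured. See the vignette in `vignettes/` for the full breeding plan,
parameter meanings and design choices.

## Worked example

```r
library(icbreedsim)
sim <- simulate_scheme("EPR", switch_stage = "AYT", h2 = 0.5, R = 0.5,
                       n_cycles = 15, n_replicates = 20, base_seed = 1)
print(sim)
#> Intercrop breeding simulation: EPR scheme, IC testing from AYT
#>   h2 = 0.5  R = 0.5   20 replicates x 15 cycles
#>   final mean IC GV: 2.432  (cycle-1: 1.396 )
#>   converged: no (threshold 0.005 )
summary(sim)$trajectory[c(1:3, 13:15), ]
#>  cycle mean_ic_gv sd_across_replicates genetic_variance
#>      1       1.40                0.607          0.12401
#>      2       1.75                0.738          0.07932
#>      3       1.91                0.834          0.07900
#>     13       2.42                0.906          0.00605
#>     14       2.41                0.888          0.00767
#>     15       2.43                0.884          0.00781
```

The trajectory is the mean IC genetic value of the 36 elite-trial
combinations, in founder genetic standard deviations, averaged over
replicates: progress is fast early (1.40 to 1.91 in three cycles), then
saturates as the genetic variance among elite combinations (last column)
is depleted - none of the schemes preserves variance. `plot(sim)` draws
the trajectory with a replicate band; `simulate_grid()` +
`summarize_grid()` compare scenarios (asymptote, convergence cycle under
the 0.005-increment rule, early-cycle gain rate), and
`inst/scripts/simulate.R` wraps a single scenario run for the shell.

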