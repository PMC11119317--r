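---
title: "Simulating the switch from monocrop to intercrop testing in line breeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the switch from monocrop to intercrop testing in line breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(icbreedsim)
```

## The question the simulator answers

Breeding varieties for intercropping - here a binary cereal-legume system
with a faba-bean-like and a triticale-like component - faces a resource
dilemma. Intercrop (IC) performance of a line can only be measured by
growing it together with partner lines of the other crop, so a trial of
$n$ candidate lines per crop costs $n^2$ combination plots, while monocrop
(MC) trials cost $n$ plots for $n$ lines. Under a fixed phenotyping budget
a breeder must therefore choose the selection stage at which testing
switches from cheap MC plots (which select for IC performance only
indirectly, through the MC-IC genetic correlation $R$) to expensive IC
combination plots (which select for the target trait directly but screen
far fewer lines).

`icbreedsim` simulates this trade-off for two classic line-development
methods for self-pollinating crops - doubled haploids (DH) and
ear/pod-to-row selfing (EPR) - across a grid of trait heritabilities
$h^2$, genetic correlations $R$, and switch stages, and tracks the
genetic progress of IC performance over repeated breeding cycles.

## Genetic model

Each crop's genome is collapsed to a single diploid chromosome (1.1e9 bp
for the legume, 9.9e8 bp for the cereal - the physical sizes are carried
as metadata; all genetics operates on a 1-Morgan genetic map). A founder
population of 100 fully homozygous lines per crop carries 2000 biallelic
segregating sites; per-site allele frequencies are drawn from the U-shaped
Beta(1/2, 1/2) distribution, mimicking a drift-dominated history, and any
monomorphic column is resampled so that every site truly segregates.

1000 of the sites are designated QTL, shared between the MC and the IC
trait. Per-QTL reference-allele effects for the two traits are drawn from
a bivariate standard normal with correlation $R$, so the traits have
identical genetic architecture up to the correlation of their allele
effects. Effects are affinely rescaled so the founder genetic values (GVs)
of each trait have mean 0 and variance 1; correlations are invariant to
this, and it anchors every downstream quantity - gains, variances, the
convergence threshold - to the founder genetic standard deviation as the
unit.

A line's GV is the sum of dosage-weighted QTL effects. The GV of an
intercrop combination is the mean of its two components' IC GVs,

$$ g \;=\; \frac{g_f + g_t}{2}, $$

and a trial entry's phenotype is its GV plus Gaussian noise with variance
$\sigma_e^2 / r$, where $r$ is the stage's plot replication and

$$ \sigma_e^2 \;=\; \frac{(1 - h^2)\,\sigma_a^2}{h^2}, $$

with $\sigma_a^2 = 1$ the founder additive variance. Replication is
simulated as entry-mean noise rather than $r$ separate plot records; for
selection on entry means the two are statistically identical. An IC
combination is phenotyped as a single entity with one noise draw - whether
the two components within one plot share their environmental deviation is
not observable at the entry-mean level, so the simpler convention is used.

Meiosis follows the Haldane model: crossover counts are
Poisson(map length), positions uniform, no interference and no obligate
chiasma. The model is analytically checkable (the test suite verifies
recombinant fractions against $(1 - e^{-2d})/2$), and consistent with the
absence of any stated interference model for this system. DH production
doubles one random gamete per candidate (100% induction success, no
selection); EPR fixation selfs with selection as described below.

## The breeding plan

Every scheme runs three trial stages per cycle under an identical plot
budget:

| stage | plots | design (MC mode) | design (IC mode) |
|-------|-------|------------------|------------------|
| PYT   | 784 x 1 rep | 392 lines/crop | 28 x 28 = 784 combinations |
| AYT   | 144 x 2 reps | 72 lines/crop | 12 x 12 = 144 combinations |
| EYT   | 36 x 4 reps | - | 6 x 6 = 36 combinations |

The *switch stage* (PYT, AYT or EYT) is the first stage run in IC mode;
all later stages are IC mode, and the EYT is always an IC trial - genetic
progress is measured there, as the mean IC GV of the 36 elite
combinations. In IC mode a line's selection score is the mean phenotype
over all its tested partners (an empirical general-mixing-ability score);
truncation selection then advances the top lines per crop, with ties
broken by stable entry order for determinism.

Each cycle starts with 14 crosses per crop, drawn as random non-self
parent pairs (repeats across crosses allowed - the simplest unbiased
mating design). Cycle 1 uses 14 founders sampled per crop; later cycles
recycle the lines that entered the AYT (72 per crop in MC mode, 12 in IC
mode). A configuration switch (`recycle_from = "EYT"`) instead recycles
the 6 + 6 elite lines.

Line fixation between crossing and the PYT:

* **DH**: each of the 14 S0 plants yields 28 DH0 lines (392 per crop), or
  2 lines each (28 per crop) when IC testing starts at the PYT, with no
  selection.
* **EPR**: each S0 plant founds a 350-plant nursery family selfed from S1
  to S4. At each intermediate generation the family is ranked on a visual
  phenotype - the MC trait at $h^2 = 0.1$, one plot - and the top 10%
  (35 plants) are selfed onward, 10 progeny each, keeping the nursery at
  350. The 10% intensity is a package choice: the within-generation
  intensity of visual mass selection is not part of the plan's printed
  counts, and 10% is a realistic nursery roguing rate; it is exposed as
  `epr_select_per_generation` (setting it to the nursery size disables
  intermediate selection entirely). At S4, 8% of the nursery advances:
  the top 28 per family (392 per crop) in MC scenarios, or the top 2 per
  family (28 per crop) when IC testing starts at the PYT. This single
  within-family mechanism reconciles the 8%-rule with both printed
  advancement counts.

## Scenario runs and their summaries

`simulate_scheme()` is the main entry point; each replicate independently
resimulates founders and trait architectures (seed = `base_seed` +
replicate, so different scheme configurations see identical founder
realizations in matched replicates - scenario comparisons are paired).
`simulate_grid()` maps it over a scenario grid, and `summarize_grid()`
reports per scenario:

* the **asymptote** - the final-cycle mean IC GV across replicates;
* the **convergence cycle** - the first cycle at which the
  replicate-averaged trajectory's increment drops below 0.005 founder
  genetic standard deviations (first-hit rule; re-divergence after a hit
  is not rescanned);
* the **early-cycle gain rate** - the mean per-cycle gain over the first
  three cycle transitions.

```{r example}
sim <- simulate_scheme("EPR", switch_stage = "AYT", h2 = 0.5, R = 0.5,
                       n_cycles = 15, n_replicates = 20, base_seed = 1)
summary(sim)
plot(sim)
```

## Problem sizes, numerical choices, degenerate inputs

The package defaults to the full study conditions (100 founders, 1000
QTL, 20 cycles, 100 replicates). The test suite and the acceptance script
run a scaled grid - 13 scenarios at $h^2 = 0.5$, 20 replicates x 15
cycles - which is where the qualitative scheme orderings stabilize; a
full-grid run is a single `simulate_grid()` call away.

Numerical conventions worth knowing:

* $h^2 = 1$ is accepted by `phenotype_settings()` as an exact noiseless
  test mode ($\sigma_e^2 = 0$); `env_variance()` itself rejects
  $h^2 \in \{0, 1\}$.
* $R = 1$ duplicates the MC effect vector exactly (a degenerate test mode
  in which the two traits coincide); any other $|R| \ge 1$ is rejected.
* Zero founder variance at a trait, within-family selection counts
  exceeding the family size, fewer than 2 distinct recycled parents, and
  stage entry counts that do not match the plot budget all raise errors
  rather than propagating silently.
* Haplotypes are stored as raw bytes, site-major, so each line's
  chromosome is contiguous; meiosis copies whole segments between
  crossovers and population genetic values are computed in compiled code.

## What the generator does and does not emulate

The founder generator reproduces the properties the downstream analysis
uses - 100 inbred founders per crop, a fixed number of polymorphic
biallelic sites, a U-shaped allele-frequency spectrum, a known genetic
map - but not the linkage disequilibrium or rare-variant load of a
coalescent population history, and no mutation or selection during that
history. Consequences observed in this engine, documented here because
they shape what passing tests show about real data:

* With unlinked, common-variant founders, the MC-correlated fraction of
  IC genetic variance is consumed within a few cycles of MC selection,
  after which indirect response stalls. Schemes that phenotype IC early
  therefore dominate: in the scaled grid the PYT switch attains the
  highest asymptote for the EPR method at every correlation level, and
  the advantage of late switching appears only for DH at $R = 0.9$.
  Founder histories with long-range linkage and rare favorable alleles
  sustain indirect response longer and can shift this balance toward
  later switching; conclusions about the *optimal* switch stage are
  therefore sensitive to the founder model in a way that the structural
  results (budgets, counts, gain-then-saturation, variance depletion,
  EPR-over-DH ranking) are not.
* Genetic variance among the elite combinations declines toward zero in
  every scenario - none of the schemes preserves variance - so
  trajectories saturate, and with 15-cycle scaled runs some scenarios
  only reach the 0.005 convergence criterion after the simulated horizon.

Also out of scope by design: dominance and epistasis,
genotype-by-environment interaction, multi-trait indexes, tester-based
mixing-ability schemes, genomic selection, and cost accounting beyond the
fixed plot budget.
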