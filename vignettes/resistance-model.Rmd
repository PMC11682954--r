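---
title: "A deterministic two-locus model of Bt resistance evolution under the refuge strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic two-locus model of Bt resistance evolution under the refuge strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btrefuge)
```

## The model

Western corn rootworm (*Diabrotica virgifera virgifera*) is managed with
transgenic maize producing *Bacillus thuringiensis* (Bt) toxins — here
Cry3Bb1 and Gpp34/Tpp35Ab1, grown singly or stacked in a pyramid — alongside
refuges of non-Bt maize that preserve susceptible insects. `btrefuge`
implements a deterministic population-genetic model of how fast resistance
evolves under this strategy.

Resistance to each toxin is controlled by one biallelic locus (alleles R and
S) in a diploid, randomly mating population with one generation per time
step. The model's assumptions: space is implicit; each larva completes
development on a single plant (no movement between plants); mortality other
than Bt selection and fitness costs is negligible; there is no
density-dependent mortality; surviving adults mate at random (appropriate
for blended/integrated refuges rather than spatially distinct block
refuges); the population is effectively infinite, so there is no drift and
the recursion is fully deterministic.

Each generation proceeds in three stages:

1. **Random union of gametes.** The state is the frequency vector of the
   four haplotypes (R₁R₂, R₁S₂, S₁R₂, S₁S₂). Egg genotype frequencies are
   products of gamete frequencies; cis and trans double heterozygotes are
   tracked separately but share a fitness class.
2. **Larval viability selection.** Each unphased genotype class survives
   with the landscape-average fitness
   *w(g) = φ·w_refuge(g) + (1 − φ)·w_Bt(g)*, where φ is the refuge
   proportion. Frequencies are renormalized by mean fitness.
3. **Gamete production.** Adults transmit haplotypes by Mendelian
   segregation; double heterozygotes emit recombinant haplotypes at rate
   *r* (default 0.5, unlinked — the true linkage between the two resistance
   loci is unknown).

Time to resistance is the first 1-based selection cycle at which the
post-selection resistance-allele frequency reaches the threshold (0.5,
inclusive) — at the selected locus for single-toxin maize, at both loci in
the same generation for a pyramid. Runs are censored at 20 generations.
This counting convention is locked by a benchmark: baseline single-toxin
Cry3Bb1 parameters at zero refuge reach the threshold in exactly 6
generations.

## Fitness construction

On Bt maize, homozygous-resistant survival is fixed at *W*~RR~ = 1 and
susceptible survival *W*~SS~ is the literature mean (0.104 for Cry3Bb1,
0.118 for Gpp34/Tpp35Ab1). Heterozygote survival follows from the
inheritance (dominance) of resistance *h* via
*h* = (*W*~RS~ − *W*~SS~)/(*W*~RR~ − *W*~SS~), so
*W*~RS~ = *W*~SS~ + *h*(1 − *W*~SS~). Derived values are carried at full
floating precision; three-decimal values in reports are display rounding.

On refuge maize every genotype survives fully except for fitness costs of
resistance: RR survival is 1 − cost, RS survival is
1 − cost_dominance × cost. Baseline costs (4.1% and 5.55%) are recessive
(cost_dominance = 0); the high-cost variant (15%) is nonrecessive with
cost_dominance = 0.4 (a 6% heterozygote cost). Costs never alter survival
on Bt maize.

Pyramid survival is multiplicative across loci in each habitat: the Bt
survival of a two-locus genotype is the product of its per-locus survivals
(so pyramid *W*~SS,SS~ = 0.104 × 0.118 ≈ 0.012), and refuge costs likewise
combine as the product of per-locus cost factors (the sources specify
per-locus costs only; multiplicativity is the consistent default). A
single-toxin cultivar is a degenerate pyramid whose second locus is neutral
(`neutral_locus()`), so one engine serves both cases.

```{r fitness}
cry <- locus_params(w_ss = 0.104, h = 0.375, cost = 0.041, p0 = 0.001,
                    label = "Cry3Bb1")
locus_fitness(cry)
```

## Parameters

| Parameter | Meaning | Units | Default / baseline |
|---|---|---|---|
| `w_ss` | SS survival on Bt maize relative to non-Bt | proportion | 0.104 (Cry3Bb1), 0.118 (Gpp34/Tpp35Ab1) |
| `h` | inheritance (dominance) of resistance | 0–1 | 0.375 / 0.36; bounds 0.14, 0.73 |
| `cost` | RR survival reduction on refuge | proportion | 0.041 / 0.0555; variants 0, 0.15 |
| `cost_dominance` | fraction of cost expressed in RS | 0–1 | 0 (recessive); 0.4 in the high-cost variant |
| `p0` | initial R-allele frequency | frequency | 0.001 (common assumption); realistic 0.2 / 0.075 |
| `refuge_prop` (φ) | proportion of plants that are non-Bt | proportion | swept 0–1 in 0.01 steps |
| `threshold` | R frequency defining resistance | frequency | 0.5, inclusive |
| `max_generations` | censoring cap | generations | 20 |
| `r` | recombination fraction between loci | 0–0.5 | 0.5 (unlinked) |
| `mode` | recursion mode | — | `"exact"`; `"le"` for the published calibration |

The six study scenarios (`scenario_spec(1:6)`) vary initial frequencies
(common 0.001 vs realistic 0.2/0.075), inheritance (0.14 vs 0.73 at both
loci), and costs (none vs high nonrecessive), each with two single-toxin
arms and two pyramid arms (without and with previous Cry3Bb1 resistance).
`previous_resistance_sweep()` re-runs a scenario's pyramid with initial
Cry3Bb1 frequencies 0.2, 0.35, 0.5 and 0.8, holding Gpp34/Tpp35Ab1 at
0.075, with the single-toxin Gpp34/Tpp35Ab1 sweep as reference.

## Exact-gamete versus linkage-equilibrium mode

The recursion has two modes. `mode = "exact"` tracks the full phased gamete
vector. This is the defensible default: blending Bt and refuge habitats
makes two-locus fitness non-multiplicative, so selection generates linkage
disequilibrium (LD), and the exact recursion is the correct dynamics under
the stated assumptions. `mode = "le"` re-imposes linkage equilibrium on the
gamete pool every generation — the behaviour of recursions that track only
allele frequencies, a common formulation for this class of model.

The two modes give identical single-toxin results and differ by a few grid
steps in pyramid refuge requirements. Calibration against the published
benchmark decides which mode reproduces the original analysis: under
`mode = "le"`, with "delaying resistance by 20 generations" read as the
criterion not being met before generation 20, the minimum refuge across the
four previous-resistance pyramid arms spans exactly 0.46–0.66 (the
acceptance suite recomputes this); `mode = "exact"` gives 0.48–0.66. The
package therefore uses `"le"` when reproducing the published curves and
`"exact"` for new analyses; the difference itself measures how much
selection-generated LD matters at a given parameter set.

```{r ttr}
time_to_resistance(cry, sim_config(refuge_prop = 0))
```

## Numerical choices and degenerate inputs

- Refuge grids are generated by integer index (i/100), never by repeated
  addition, so grid points are exact and serialize as two-decimal strings.
- The threshold comparison is inclusive (frequency ≥ 0.5 counts).
- A censored run reports `generations = 20` with `censored = TRUE`,
  distinguishing "resistant at generation 20" from "not resistant within
  20".
- Zero mean fitness (e.g. `w_ss = 0` at φ = 0 with no resistance alleles)
  raises an explicit extinction error of class `btrefuge_extinction`
  rather than dividing by zero.
- Gamete production uses a closed-form haplotype-margin identity; it is
  verified to 1e−12 against an independent brute-force enumeration of all
  ordered matings (`mating_table_oracle()`).
- All arithmetic is double precision; nothing in the engine is stochastic.

## The synthetic-parameter generator

`sample_scenarios()` draws seeded random two-locus parameter sets from
ranges bracketing the empirical literature values (`w_ss` ∈ [0.01, 0.5],
`h` ∈ [0, 1], `cost` ∈ [0, 0.2], `p0` ∈ [1e−4, 0.5]), with fixed edge cases
(recessive and dominant inheritance, zero cost, boundary initial
frequencies) guaranteed in every batch. It emulates the *structure* of
parameter sets only — it does not simulate field data, sampling error or
bioassay noise, because the model fits nothing to data. Passing property
tests on these draws therefore demonstrates internal correctness of the
genetics (conservation, neutrality, segregation, LD decay, monotonicities),
not agreement with any particular field population.

The test suite runs the property checks on batches of 60–100 draws with
short refuge grids, and the full 101-point grid only for the published
benchmarks; the whole suite completes in well under a minute.

## A caution on cost monotonicity

Increasing fitness costs delays resistance when the increase applies to the
locus under selection in a single-toxin run, or to both loci of a pyramid.
Raising the cost at *one* locus of a pyramid, however, can advance the
joint time to resistance by a generation: the cheaper survival lost by
R₁ carriers in the refuge lowers mean refuge fitness, which shifts the
population's selective weight toward the Bt habitat and accelerates
evolution at the *other* locus. The property tests assert the two forms
that hold; the one-locus exception is a real feature of the model, not
numerical error.

## Limitations

Finite-population drift, spatially explicit refuges, larval movement,
density-dependent mortality, nonrandom mating (protandry, block refuges),
sublethal effects and dose–response variation are all outside the model.
The two toxins are assumed to act multiplicatively; if their joint
mortality is less than multiplicative, pyramid durability is overstated.
The recombination fraction between the two resistance loci is unknown and
defaults to unlinked. Monogenic resistance per toxin is assumed even though
the underlying genetics may be oligogenic or polygenic; monogenic models
are the conservative convention for resistance-management projections.
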