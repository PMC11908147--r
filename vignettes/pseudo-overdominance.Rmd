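---
title: "Simulating pseudo-overdominance in diploids and autotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pseudo-overdominance in diploids and autotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`podsim` is a forward-in-time Wright–Fisher simulator built to study
*pseudo-overdominance* (POD): the apparent heterozygote advantage that
emerges when recombination is too rare to separate recessive deleterious
mutations that have accumulated on complementary haplotypes.  Once two or
more complementary high-load haplotype classes dominate a population,
heterozygous combinations mask all of the load while homozygous
combinations express a large share of it, and intermediate, stable allele
frequencies are maintained by selection rather than drift.

The simulated organism carries a single linear chromosome of `L` base
pairs (1 Mb by default) and is either diploid or autotetraploid.  Each
generation:

1. **Parent sampling.** The population is of constant size `N` with
   discrete, non-overlapping generations.  Each of the `N` offspring draws
   two parents independently, individual `i` with probability
   $w_i / \sum_j w_j$.  By default the two draws are independent, so
   incidental selfing can occur (the behaviour of the common
   forward-simulation engines; it can be switched off).
2. **Meiosis.** A diploid gamete is one recombinant chromosome.  An
   autotetraploid gamete carries *two* chromosomes: the four homologs are
   partitioned uniformly at random into two bivalents (all three perfect
   matchings equally likely — strictly bivalent, tetrasomic inheritance),
   and each bivalent independently contributes one recombinant chromatid
   chosen by a fair coin.  Multivalents and double reduction are excluded
   by construction.  Crossovers per bivalent are Poisson with mean
   $\rho L$, placed uniformly on the $L-1$ inter-base boundaries with no
   interference.
3. **Mutation.** Each gamete chromosome receives a Poisson($\mu L$) number
   of new mutations at uniform positions.  Every mutation is a distinct,
   uniquely identified allele: two hits at the same site are *not* the
   same allele and never jointly homozygous.  All mutations share the
   selection coefficient `s` of the run.
4. **Fitness.** Mutations are fully recessive and act multiplicatively:
   $$w = \prod_{i \in H} (1 + s_i), \qquad s_i \in (-1, 0],$$
   where $H$ is the set of mutations present on **all** `ploidy` copies.
   A mutation absent from even one copy contributes nothing.  This is the
   root of the ploidy effect: at frequency $p$ a locus is fully homozygous
   with probability $p^2$ in diploids but $p^4$ in tetraploids.
5. **Substitutions.** Mutations present on every chromosome in the
   population are fixed; they no longer respond to selection and are
   removed from all haplotypes (counted in `n_substitutions`), so fitness
   always reflects segregating load only.

Populations start **mutation-free** — there is no burn-in, because the
object of study is precisely the approach to (and nature of) the
mutation–selection–drift equilibrium after a population is founded, e.g.
following the strong bottleneck of polyploid formation.

## Parameters

| Parameter | Meaning | Units | Typical values |
|---|---|---|---|
| `N` | population size | individuals | 100–500 |
| `ploidy` | chromosome copies per individual | — | 2 or 4 |
| `L` | chromosome length | bp | 1e6 |
| `mu` | mutation rate | per bp per generation | 5e-9–1e-7 |
| `rho` | recombination rate | per bp per generation | 1e-10–1e-7 |
| `s` | selection coefficient (shared, fully recessive) | — | −0.0005 to −0.2 |
| `generations` | run length | generations | 5,000–10,000 |

Genome-wide rates are the products $\mu L$ and $\rho L$: with the
defaults, `mu = 1e-7` means 0.1 new mutations per gamete chromosome per
generation, and `rho = 1e-10` means crossover is effectively absent
(expected $10^{-4}$ per meiosis).  Note that $\rho = 10^{-7}$ corresponds
to 0.1 — not 1 — expected crossovers per chromosome per generation; the
per-bp × length semantics is used throughout.

## Summary statistics and POD classification

Each generation records the mean (and sd) of offspring fitness, the mean
fitness of the `2N` chosen parents counted with multiplicity, the **median
frequency of segregating mutations**, and segregating/substitution counts.
Under POD the median allele frequency equilibrates at intermediate values
(roughly 30–40%), because most segregating mutations ride on a small
number of complementary haplotype classes; without POD it stays near
0–10% and fluctuates by drift.

`classify_pod()` therefore requires the trajectory to be *intermediate
and stable* over an assessment window (default: final 1,000 generations):
window mean ≥ `freq_threshold` (default 0.2) **and** window sd ≤
`stability_threshold` × mean (default 0.25).  The frequency threshold
sits between the two observed regimes; the stability clause rejects
small-population drift excursions, which can reach intermediate
frequencies transiently (especially in diploids, which have half as many
chromosomes) without POD being the cause.  Both thresholds are plain
function arguments and are recorded in every sweep row.

Closed-form companions to the simulator, used in its validation:

* `expected_homozygote_fraction(p, k)` $= p^k + (1-p)^k$, the probability
  that a random-union offspring is fully homozygous for either haplotype
  at a biallelic locus — 52% at $p = 0.4$ for diploids versus 15.52% for
  tetraploids.
* `bivalent_gamete_distribution(c)` — the exact gamete law of a tetraploid
  parent with `c` focal copies under random bivalent pairing (AAAa →
  {1: 1/2, 2: 1/2}; AAaa → {0: 1/6, 1: 2/3, 2: 1/6}).
* `cross_high_load_fraction(c1, c2)` — the probability that an offspring
  of a given cross is fully homozygous for the focal haplotype.  Over all
  heterozygous tetraploid parent pairs this ranges from 0 to 25%
  (maximum at AAAa × AAAa), against ~50% of offspring homozygous for
  either haplotype in an equilibrium diploid heterozygote cross.

`expected_homozygote_fraction()` deliberately uses independent-copy
(tetrasomic Hardy–Weinberg) composition; the bivalent-aware cross
operations answer parent-conditioned questions, and the two agree in the
aggregate.

## What the simulator emulates — and what it does not

The generator *is* the study system: all inputs are parameter
configurations, and every quantitative claim the package tests is a
property of these simulations, not of any empirical data set.  Passing
tests demonstrate internal consistency (engine versus closed-form laws,
versus reference R implementations, and versus classical neutral-theory
expectations) and reproduction of the simulated regimes; they say nothing
about real genomes, where selection coefficients vary across sites,
dominance is rarely all-or-nothing, chromosomes are multiple and
structured, and demography is not constant.  Specific simplifications:
one chromosome; a single constant `s` per run (no distribution of fitness
effects); full recessivity (`h = 0`); no beneficial mutations; strictly
bivalent meiosis with no double reduction and no crossover interference;
no sexes, migration or demographic change.

## Numerical and design choices

* **Fitness formula.** `w = ∏(1 + s)` over homozygous mutations with `s`
  stored negative — the standard forward-simulator convention, and the
  only reading under which fitness declines as recessive load accumulates.
* **Identity-based homozygosity.** Homozygosity compares mutation ids,
  never positions; simultaneous hits at one site stack as distinct
  alleles.  Positions only route recombination.
* **Crossover placement.** Breakpoints live on inter-base boundaries; a
  mutation at position `p` goes left of breakpoint `b` iff `p < b`.  A
  boundary hit an even number of times in one meiosis cancels (no net
  exchange), so plans always carry strictly increasing breakpoints.
* **Median convention.** The median allele frequency of an even number of
  segregating mutations is the mean of the two central values (R's
  `median()`); with nothing segregating it is defined as 0.  Population
  fitness sd uses the `n − 1` denominator.
* **Fresh randomization per gamete.** Every gamete draws its own bivalent
  pairing, crossover plans and chromatid coins; there is no shared tetrad
  bookkeeping between the two gametes of one parent.
* **Reproducibility.** A run with a seed saves and restores the session
  RNG state, so `wf_run()` is pure; all engine randomness flows through
  R's generator, making trajectories byte-identical across repeats of
  (seed, parameters, package version).  Sweep runs derive one seed per
  (combination, replicate) from the base seed, so sweeps are resumable
  and order-independent.
* **Generation indexing.** Row `g` of a trajectory describes the
  population *after* the `g`-th reproduction event; generation 0 is the
  mutation-free founder population and is not a row.
* **Degenerate inputs.** All-zero fitness would make parent sampling
  undefined and raises an error (unreachable for `s > −1`); `rho = 0` and
  `mu = 0` are exact no-ops rather than limits; `N = 1` populations are
  rejected at parameter validation.
* **Engine.** The generation loop is compiled (C++ via Rcpp), as is usual
  for forward simulators; the exported R operations
  (`compute_fitness()`, `make_gamete()`, `recombine()`, …) are reference
  implementations of the same semantics and the test suite cross-checks
  the two routes on shared fixtures.

## Replication and problem sizes

Equilibrium quantities here are only meaningful as cross-replicate
averages: under the illustrative POD parameters (`N = 100, mu = 1e-7,
s = -0.005, rho = 1e-10`) individual replicates settle into different
numbers of surviving complementary haplotype classes — two classes put
the window median near 0.47, three near 0.31 — and which basin a
replicate reaches is a matter of drift.  The package's validation suite
therefore follows a 10-replicates-per-parameter-combination protocol for
its equilibrium checks, run to generation 5,000 (equilibrium onset is
around generation 2,500 at these parameters) and assessed over the final
1,000 generations; `scripts/acceptance.R` uses 40 replicates per ploidy
for tighter estimates.  Post-equilibrium trajectories continue to coarsen
slowly (three-class states occasionally merging to two), so windows taken
late in longer runs sit slightly higher than windows at generation
5,000.  Full-scale grids in the style of the sweep defaults (720
combinations × 10 replicates × 10,000 generations) are supported by
`run_sweep()` with resumable, incremental output, but are multi-hour
computations; the shipped tests exercise the sweep machinery on reduced
grids and verify directional claims on single cells.

## Limitations

Beyond the modelling simplifications above: the engine keeps the whole
population in memory (fine for `N ≤ 1000` at these mutation rates); there
is no tree-sequence recording, no linked-neutral-diversity statistics
(π, LD), and no recombination-modifier machinery.  The VCF export is a
minimal, self-describing dialect (synthetic REF/ALT alleles, `S=` INFO
field, `ploidy`-allele unphased genotypes) intended for interchange with
variant tooling, not a reference-based call set.
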