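---
title: "Modelling diatom microevolution across bloom cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diatom microevolution across bloom cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatomsim)
```

## The model

`diatomsim` simulates the neutral microevolution of a bloom-forming diatom
population, individual by individual and day by day. The design choices
mirror the biology of diplontic planktonic diatoms such as
*Pseudo-nitzschia multistriata*:

* **Genome.** One chromosome (default 10^5 bp) carrying five microsatellite
  loci at random, non-overlapping coordinates fixed once per experiment.
  A locus is a 1–6 bp motif repeated 5–50 times; its allele is the repeat
  count, so a diploid individual is described by ten small integers. No
  nucleotide sequence is represented: with neutrality, only the repeat
  counts matter.
* **Demography.** A carrying capacity that switches between 10^2
  individuals (stationary phase, 335 days/year) and 10^5 (bloom, 30
  days/year). Every day, after reproduction, the population is sampled
  uniformly down to the capacity in force. This sampling is the only loss
  term; deaths, grazing and nutrient dynamics are not modelled explicitly,
  and the bloom calendar is identical every year.
* **Clonal phase.** Two binary fissions per day during blooms, one every
  five days otherwise. Each daughter cell mutates each (locus, homolog)
  slot independently with probability `mut_rate`.
* **Sexual phase.** Once per year, on the middle day of the bloom, a
  fraction `sex_rate` of cells is paired at random; each pair is consumed
  and replaced by two zygotes built from independent meiotic gametes.
  Crossover breakpoints are Bernoulli per base (`rec_rate`), uniform along
  the chromosome, and never fall inside a repeat tract.

Everything is neutral: no genotype ever affects division, mating or
survival. Selection-like patterns in the output (for instance the rise in
mean heterozygosity when a bottleneck removes low-heterozygosity clones)
are purely statistical consequences of sampling.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `mut_rate` | mutation probability per locus, homolog and division | 10^-3 | bracketed by the study grid 10^-4–10^-2, centred near the empirical microsatellite rate of ~3×10^-3 |
| `rec_rate` | breakpoint probability per base at meiosis | 10^-6 | protist-scale; grid spans 10^-8–10^-2 |
| `sex_rate` | fraction of cells engaging in the annual sexual event | 0.35 | middle of the observed 20–50 % range |
| `K_stationary`, `K_bloom` | carrying capacities (cells) | 10^2, 10^5 | in-situ density contrast between phases |
| `bloom_len`, `bloom_start` | bloom window (days, day-of-year) | 30, 1 | one-month bloom; calendar position is arbitrary and configurable |
| `sex_day` | 1-based bloom-day of the sexual event | 15 | end of the bloom's exponential phase |
| `burn_in_years`, `sample_years` | unmonitored / monitored years | 11, 5 | populations mature before measurement |

The `"desk"` profile (`K_bloom = 10^4`, 2 + 2 years) preserves every
structural feature — capacity switching, the division schedule, one sex
event per bloom, the two sampling cadences — at roughly 1/60 of the
computing cost; it is the scale the test-suite experiments and the
acceptance script use (36 runs of 1460 days each complete in about two
minutes on one CPU).

## Design decisions in the open corners

Several ingredients are under-determined by the biology and had to be
fixed; these are the package's own choices, configurable where noted.

* **Mutation model.** Repeat counts change by exactly ±1 with equal
  probability (the classical single-step stepwise mutation model for
  microsatellites), *reflecting* at the [5, 50] bounds: a downward step at
  5 lands on 6, an upward step at 50 on 49. Reflection keeps the state
  space closed without an absorbing edge.
* **Breakpoint exclusion zone.** The interval protected from crossovers is
  each locus's *maximal* extent (`motif_len × 50` bases), regardless of the
  current allele. This keeps the recombination machinery independent of
  per-individual state: a breakpoint map is valid for every genotype.
* **Breakpoint law.** One Bernoulli trial per inter-base position, i.e.
  Binomial(`chrom_len`, `rec_rate`) breakpoints per gamete, duplicates
  collapsed; positions inside an exclusion zone are redrawn uniformly.
  Gamete assembly walks left to right, switching source homolog at each
  breakpoint — well defined at loci because breakpoints cannot fall inside
  them.
* **Founder population.** 10^2 individuals with every repeat count drawn
  uniformly on [5, 50]; replicates of one condition share the founder (and
  the chromosome layout) and diverge only through per-day randomness.
  Maximal initial diversity lets the burn-in prune towards quasi-
  equilibrium rather than build diversity from nothing.
* **Sex-day bookkeeping.** Clonal division still happens on the sex day;
  participants are then consumed by mating, and with two offspring per
  pair the census is unchanged by sex. Odd participant counts are rounded
  down. If fewer than two participants are requested the event is skipped.
* **Division timing.** Stationary-phase divisions occur on absolute days
  divisible by five (deterministic), not as a 0.2 daily probability per
  cell; trajectories stay comparable across replicates.
* **The fourth recombination regime.** The factorial grid uses
  {10^-8, 10^-6, 10^-4, 10^-2}; 10^-6 completes a four-regime ladder and is
  the value of the high-resolution runs.

## Metrics and analysis layer

`A` sums distinct alleles over loci (a single total, convenient as one PCA
column); `G` counts distinct phase-invariant multilocus genotypes; `H` is
*observed* heterozygosity — the fraction of heterozygous individuals
averaged over loci, which is what a per-individual simulation naturally
yields and what the bottleneck-sampling argument concerns — not expected
heterozygosity from allele frequencies; `R = (G−1)/(N−1)` (undefined and
reported as `NA` for N < 2; such days are dropped from index matrices).

The binomial deviance dissimilarity between day profiles of allele
presence/absence uses the standard ecological formulation
(`vegan::vegdist(method = "binomial")`, with 0·log 0 ≡ 0); on binary data
it reduces to log 2 times the number of mismatched presences, which the
tests exploit as a closed-form oracle. PCA of the day × {A, G, H, R}
matrix centres and, by default, *scales* the columns — the indices have
incommensurate units — via singular value decomposition (`prcomp`);
scaling is switchable. nMDS minimises Kruskal stress-1 by iterative
monotone regression from multiple random starts (`vegan::metaMDS`, 20
starts, 300 iterations; deterministic given a seed).

### The three-stage bloom signature

With daily within-bloom sampling, `bloom_signature()` operationalises the
three stages of the within-bloom trajectory of R as sign conditions:

1. *drop* — the minimum of R over the first five bloom days falls below
   the last pre-bloom value (the census explodes faster than new MLGs
   appear);
2. *rise and spike* — positive least-squares slope from bloom day 5 to the
   day before sex, and R higher the day after the sexual event than the
   day before it (the spike is structurally impossible in clonal runs,
   where no event occurs);
3. *decay* — strictly negative slope from two days after sex to the bloom
   end (drift erodes the freshly created diversity).

The five-day drop window and the ±1-day spike window are this package's
operationalisation and are configurable. The decay condition is strict
(`< 0`) rather than non-positive so that a constant series raises no flag.

## What the generator does and does not emulate

The simulator reproduces the boom–bust census trajectory, the clonal/sexual
alternation, stepwise microsatellite evolution, recombination that respects
repeat tracts, and neutral daily bottlenecks. It does **not** emulate
environmental forcing, variable bloom phenology, spatial structure, mating
types, cell-size reduction, or any form of selection. Passing tests
therefore show that the *neutral demographic machinery* produces the
documented qualitative signatures; they say nothing about selective or
environmental contributions to real bloom genetics.

One scale effect deserves emphasis. Clonal lineages inherit both homologs,
so obligate-clonal populations keep the founder's heterozygosity almost
frozen, while sexual populations re-pair homologs towards the
Hardy–Weinberg level implied by current allele frequencies. Starting from
a maximally diverse founder, the Hardy–Weinberg level itself decays while
drift at K = 10^2 removes alleles, so during the early transient sexual
runs *lose* heterozygosity faster than clonal ones. The long-run contrast
— sexual populations maintaining or gaining H relative to clonal ones —
is an equilibrium property that needs the full burn-in horizon; at the
desk scale (2-year burn-in) the acceptance script reports the transient,
where the contrast at the lower mutation rates has the opposite sign.

## Numerical notes and degenerate inputs

* Mutation uses a Binomial draw of the number of mutated slots followed by
  position sampling without replacement — exactly equivalent to independent
  Bernoulli trials per slot, at a fraction of the cost.
* Layout placement rejection-samples locus starts and raises a clear error
  when the chromosome cannot hold five disjoint maximal intervals.
* `regulate()` never up-samples; extinction (impossible under the default
  schedules, since regulation of a non-empty population keeps at least one
  cell) aborts with the day number.
* All run-level randomness flows from three named seeds (layout, founder,
  process); per-run process seeds in `run_experiment()` are derived
  deterministically from (condition index, replicate), and every
  seed-setting helper restores the caller's RNG state.
* Metric functions reject empty populations; `R` is `NA` for N < 2;
  zero-variance columns are dropped (with a warning) before scaled PCA.

## Problem sizes used by the test suite

Unit tests run on toy layouts (2-locus, 2 kb chromosomes) and populations
of tens of cells; oracle comparisons use 10^4 meiotic gametes against a
brute-force per-base simulator, 10^3 binary fuzz cases for the
dissimilarity, 500 replicate drift trajectories at K = 20 against an
independently coded single-locus simulator, and ≥10^5 breakpoint draws for
the exclusion property. The end-to-end experiments use the desk profile
with 6 replicates per condition. These sizes were chosen so the whole
suite exercises every contract in a few minutes while keeping Monte-Carlo
standard errors well below the effect sizes being asserted.

## Known limitations

* Repeat-count homoplasy is unavoidable in a bounded stepwise model:
  identical alleles need not be identical by descent, so A and G are
  conservative diversity measures.
* The annual calendar is rigid; desynchronised or skipped blooms, and
  supra-annual sex, are out of scope.
* Observed heterozygosity is reported per day from the full census at
  capacity, not from a field-style subsample; field estimates would add
  sampling noise that the model does not represent.
* The desk profile's short burn-in measures transient, not equilibrium,
  heterozygosity trends (see above).
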