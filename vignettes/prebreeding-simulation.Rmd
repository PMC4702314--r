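---
title: "Simulating genomic pre-breeding programs from maize landraces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic pre-breeding programs from maize landraces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Elite maize germplasm carries only a fraction of the genetic variation
present in landrace populations. A pre-breeding program tries to open
that reservoir: screen thousands of heterogeneous landrace accessions,
pick the most promising seeds, and improve the resulting *pre-bridging
germplasm* by recurrent genomic selection until it is good enough to
cross into elite material. Because such a program takes years and the
design space is large, the design questions — how to initiate the
germplasm, how much to genotype and phenotype, how many landraces to
keep — are best answered by stochastic simulation before any field work.

`prebreedsim` implements that simulation end to end and the analysis
layer used to compare designs. Three initiation approaches are
modeled:

* **Landrace** — initiate from the best seeds of the best accessions;
* **LandraceDH** — as above, but fix each selected seed as a doubled
  haploid first;
* **LandraceElite** — initiate from testcrosses of the selected seeds
  to the elite hybrid, so the germplasm starts with 50% elite genome.

A discovery phase (stages T, A, S) trains a ridge-regression
(RR-BLUP) prediction equation on a landrace × elite testcross
population, selects accessions, and then seeds within accessions. An
improvement phase (cycles C1–C4) recurrently selects a synthetic
population of 10 plants, with optional testcross phenotyping of spare
seeds to retrain the equation; because testcross phenotypes take two
generations, a retrained equation is only usable in the next cycle.

## The simulated world

**Founders.** Haplotypes are sampled per chromosome from the standard
neutral coalescent with recombination (msprime backend, invoked as a
subprocess) at an effective population size `Ne` of 1,000 or 100,000.
The genome is maize-like: 10 chromosomes of 2 Morgans. Genetic
coordinates are used directly (1 cM ≡ 10 kb at 10⁻⁶ recombination per
bp); the mutation rate (default 10⁻⁶ per bp) is chosen so the locus
budget is met comfortably at the lower `Ne`, and is recorded in the
panel metadata. Segregating sites with minor allele frequency below
0.05 are discarded, the rest are thinned uniformly at random to the
budget, and QTL positions are drawn among the retained loci, disjoint
from the candidate GBS markers.

**Identity tracking.** Every individual stores, per chromosome and
haplotype, a piecewise-constant *founder-origin track* instead of an
allele vector. Meiosis (Haldane model: Poisson crossover count with
mean equal to the map length in Morgans, uniform positions, no
interference, no obligate crossover) splices tracks; alleles are read
from the founder panel on demand. This makes identity-by-descent
exact — the 1 cM segment kinship is computed from the tracks
themselves, not estimated from markers — and keeps meiosis cheap
enough to run thousands of accessions in plain R plus two small C++
kernels.

**Landrace accessions.** Each accession is founded from 4 random
founder haplotypes and propagated for 10 generations as a pool of 20
plants under mixed selfing/outcrossing. The selfing rate solves the
mixed-mating equilibrium for the target inbreeding `F` (0.3 or 0.9),
with a correction of order `1/(2N)` for the heterozygote excess that
enforced outcrossing induces in a finite pool. Realized inbreeding is
estimated as excess homozygosity relative to the accession's own
allele frequencies; a small residual downward bias (about 0.03 at
`F = 0.3`) remains from identity disequilibrium and the ratio
estimator, within the ±0.05 band the package tests.

**Elite package.** Two closed sub-populations of 50 plants are drawn
from the founder panel and improved by five generations of truncation
selection (top 10%) on true breeding value; the best plant of each is
fixed as a doubled haploid and the elite hybrid is their F1. This
construction is deliberately minimal: it enriches the elite genome for
favorable QTL alleles in marker contexts that differ from the landrace
linkage phase, which is the mechanism behind the negative
first-cycle prediction accuracy of the LandraceElite approach, without
modeling a full elite breeding history. An elite hybrid could equally
be constructed directly from hand-picked haplotypes; explicit
selection was chosen because it produces the repulsion-phase linkage
disequilibrium the phenomenon requires, rather than assuming it.

**Trait and phenotypes.** The trait is additive with 1,000 QTL
genome-wide and standard-normal allele-substitution effects. The
environmental variance is set once per scenario and replicate so that
the testcross heritability in the initial training population equals
the scenario's `h²` (0.25 or 0.50), then held fixed for all later
phenotyping, including improvement-phase retraining. Heritability is
defined on the testcross phenotype because that is the phenotype the
program regresses; no dominance, epistasis, genotype × environment, or
plot replication is modeled.

**Genotyping.** The two platforms are GBS with 10,000 markers at 10x
coverage and GBS with 100,000 markers at 1x. Read counts are Poisson
per locus and individual; derived-allele reads are binomial with a
0.005 per-read miscall rate. The reported genotype is the posterior
mean dosage under a Hardy–Weinberg prior at the cohort's allele
frequency — continuous dosages, never hard calls, because the 1x
platform is only usable that way. Loci with zero reads are flagged
missing and mean-imputed, keeping the ridge design matrix complete.

**Prediction.** Marker effects solve the ridge problem with
`lambda = m(1 - h²)/h²`, the standard RR-BLUP shrinkage at the known
scenario heritability (the alternative, REML re-estimation per
training set, was not adopted: with 20–60 record retraining sets it is
unstable and the study design fixes `h²` anyway). The system is solved
in the dual when n < m. The regressor is always the *parent seed*
genotype; the phenotype is its testcross.

## Scale and determinism

Defaults are the full-scale conditions of the simulated program: 3,000 accessions, up to
100,000 markers, 3,456-scenario factorial, 10 replicates. A single
`scale` parameter shrinks population sizes (accessions, founder
haplotypes, locus and marker budgets) proportionally while leaving the
nine factor levels untouched, and a separate `marker_scale` lets desk
runs trade panel density against runtime. The package's own tests run
at `scale` 0.02–0.1: 60–300 accessions, 2,000–10,000 markers,
`Ne = 1,000`, ten replicates for the approach comparison — sizes at
which one replicate takes on the order of a minute. At those sizes the
qualitative full-scale behaviors (the ~0.5 starting merit
and negative first-cycle accuracy of LandraceElite, the near-zero
elite kinship of the Landrace approach, the collapse of final merit
without retraining, the T > A > S accuracy ordering) reproduce
reliably; exact full-scale means do not, and are not asserted.

Every stochastic step derives its seed deterministically from one
master seed per (scenario, replicate), so `run_grid()` reruns
identically, including the msprime subprocess. Ties in EBV ranking are
broken by stable index order.

```{r}
library(prebreedsim)
cfg <- default_config(scale = 0.1)
world <- build_world(Ne = 1000, F_within = 0.3, cfg, seed = 42)
scn <- scenario("Landrace", 1000, 0.3, 0.5, "GBS1x@100K",
                seeds_per_landrace = 1, n_selected_landraces = 40,
                tested_seeds_per_landrace = 10, n_synthetic_phenotypes = 60)
run_scenario(world, scn, seed = 7)
```

## Stage metrics

* **Merit** — mean TBV of a germplasm, shifted and scaled so landraces
  average 0 and the elite hybrid is 1. Computed on: T, the phenotyped
  training seeds; A, the seed pools of the selected accessions; S and
  C1–C4, the 10 selected units of the stage.
* **Accuracy** — Pearson correlation of EBV and TBV. At T it is the
  in-sample accuracy of the training seeds; at A the accession-level
  correlation of mean training-seed EBV with mean accession TBV across
  all accessions; at S and C1–C4 it is computed over the full
  genotyped candidate cohort of the stage (the 400–3,200 tested seeds,
  or the 100 synthetic seeds), not the 10 survivors — a correlation
  over a 10-individual truncated sample measures selection-induced
  range restriction rather than prediction quality, so the candidate
  cohort is the informative definition.
* **Kinship with the elite hybrid** — share of 1 cM bins whose
  founder-origin function is identical between a germplasm haplotype
  and an elite-hybrid haplotype, averaged over the four haplotype
  pairs and individuals. Identity is by descent through the tracked
  origins; an allele-sequence (IBS) mode exists as a config
  alternative but inflates kinship at low founder diversity, where the
  same haplotype recurs by state.
* **Heterozygosity** — mean over individuals and the frozen set of
  sites segregating in the initial landrace population (capped at
  5,000 sites for metric speed; the cap is a uniform random draw fixed
  per world).

`response_in_gsd()` converts a merit trajectory into genetic standard
deviations of the landrace population, total and per season, under a
configurable seasons-per-approach map (6 seasons for Landrace and
LandraceElite, 9 for LandraceDH by default); season bookkeeping is a
reporting convention, not a simulated quantity.

## Decision analysis

`marginal_effects()` fits one-way linear models per design factor and
reports level means, 2.5/97.5% quantiles over scenarios × replicates,
and a compact letter display from pooled-variance pairwise t tests at
`alpha = 0.01`. `build_tree()` grows a regression tree in the
conditional-inference style: at each node the factor with the smallest
one-way permutation F-test p-value is chosen (1,000 permutations by
default, seeded); a split happens only when that p-value clears
`alpha`, into the two level groups maximizing the between-group sum of
squares — order-preserving groupings for ordinal factors, all
bipartitions for unordered ones — subject to a minimum leaf size.
Permutation testing was chosen over the classical F distribution
because stage metrics over a factorial of scenarios are neither
normal nor homoscedastic; binary splits were chosen because multiway
splitting adds nothing a deeper binary tree cannot express. The tree
round-trips through JSON and renders as indented text.

## What the generator does and does not emulate

The generator reproduces the *structure* of the study system: founder
diversity scaling with `Ne`, within-accession inbreeding, an elite
genome enriched for favorable alleles in a foreign linkage phase,
coverage-dependent GBS dosage uncertainty, and the two-generation
phenotyping lag. It does not attempt demographic realism of Mexican
landrace history, selective sweeps, structural variation,
multi-allelic loci, genetic load, or restriction-site dropout and
batch effects in GBS. Passing tests therefore show that the breeding
logic and statistics behave correctly under a clean polygenic
additive world — not that real landrace programs will achieve the
simulated gains.

## Numerical choices and degenerate inputs

* Ridge systems are solved by dense Cholesky-backed `solve()`; dual
  and primal agree to 10⁻⁸ on test problems. A constant phenotype
  yields zero effects and the mean as intercept rather than a
  singular system.
* Constant EBV or TBV vectors make accuracy undefined; it is reported
  as missing, never coerced to 0.
* Zero-read genotypes are missing and imputed; with an error rate of
  0 the posterior is degenerate on the concordant classes, handled by
  clamping the error likelihood at 10⁻¹².
* The segment grid must tile every chromosome exactly; a 0.3 cM grid
  on 200 cM chromosomes is rejected rather than silently truncated.
* `random_mate()` refuses a single plant (selfing of synthetic plants
  is not modeled; excluding it matches maize practice, though either
  convention would be defensible), and accession
  mating handles selfing through its own mixed-mating scheme.
* One open point in the source material — whether "identical genome
  segments" meant IBD or IBS — is resolved as IBD via origin tracks,
  which reproduces the analytic 0.25 F1 expectation exactly and keeps
  the metric independent of marker density.

## Known limitations

Realized within-accession inbreeding is biased low by up to ~0.03 at
intermediate targets (see above). The desk-scale founder simulation
uses `Ne = 1,000`; `Ne = 100,000` with the full map is supported but
slow with the exact coalescent, so full-scale grid runs are a
cluster-sized undertaking. Accuracy at stage
S conditions on a preselected cohort and is therefore not comparable
across designs that preselect differently — the LandraceElite S-stage
accuracy in particular is computed on the same landrace-seed cohort as
the other approaches, because units are chosen among landrace seeds
before testcrossing.
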