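---
title: "Simulating breeding programs with breedsim: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating breeding programs with breedsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsim)
```

## The simulation model

`breedsim` simulates the recurrent operations of a genomic-selection
breeding program on diploid, phased genomes. A population of n individuals
is a rank-3 binary array of shape (n, m, 2): m markers, two haplotypes per
individual, alleles coded 0/1. All static parameters live in a
`GeneticMap`: per-marker chromosome, genetic position in centimorgans (or a
per-interval recombination probability directly), and a (t, m) matrix of
additive marker effects for t traits, optionally with per-trait
heritabilities.

### Meiotic recombination

Crossovers are modeled as a Poisson process along each chromosome with no
interference. At marker resolution the exact marginal of that process is a
first-order Markov chain over the indicator of the contributing haplotype:
the chain starts uniformly at the first marker of each chromosome and
switches between adjacent markers with the interval's recombination
probability. Centimorgan distances are converted with the Haldane mapping
function,

$$ r = \tfrac{1}{2}\left(1 - e^{-2\delta/100}\right), $$

the unique mapping consistent with Poisson crossover counts: r equals the
probability of an odd number of crossovers in an interval of $\delta$ cM.
The tests verify this identity against a truncated Poisson series to
1e-12, and verify empirically that simulated gametes recover every
interval's recombination fraction. An alternative "direct probability"
reading of small cM intervals ($r \approx \delta/100$) differs from Haldane
only in second order; Haldane was chosen because it is exact at all
distances and invertible (`haldaneInverse()`). Maps that already contain
per-interval probabilities are used verbatim.

One realized meiosis is materialized as a *recombination mask*
(`recombinationMasks()`), a binary vector choosing a haplotype at every
marker. Masks are the bridge between the hard simulator and the
differentiable relaxation below. Chromosome starts are re-randomized by an
independent fair flip, which makes masks on different chromosomes exactly
independent — the implementation draws one Bernoulli column per marker in
O(m) vectorized steps.

`cross()` produces one offspring per parent pair from two independent
gametes; `randomCrosses()` samples pairs uniformly with replacement across
crosses but requires the two parents within a pair to be distinct
(biparental mating); `diallel()` mates every unordered pair of distinct
parents — n(n−1)/2 crosses, so 10 parents with 10 offspring per cross give
450 offspring and 20 parents give 1900. `doubleHaploid()` samples one
gamete per offspring and duplicates it onto both haplotypes, returning the
(n, dh, m, 2) line-structured array; `dhToPopulation()` flattens it
line-major.

### Breeding values and phenotypes

`gebv()` contracts the (t, m) effect matrix with the (n, m, 2) genome
array — multiply along markers, sum-reduce over markers and ploidy — via a
single dosage-by-effects matrix product. Phenotypes add two non-genetic
components:

$$ P_{i\tau e} = G_{i\tau} + z_e\, g_{i\tau} + \varepsilon_{i\tau e}, $$

with $z_e \sim N(0,1)$ one draw per environment and $g$ the individual's
value on a *fixed* random additive genotype-by-environment trait: a
standard-normal marker-effect vector drawn once per simulation
(`gxeEffects()`), contracted with the genome, then centered and scaled.
Three aspects of this model were genuinely open and are package decisions:

* **Calibration population.** Heritability is an operational target:
  variances are calibrated on the population passed as `calibration`
  (default: the scored population itself), so that
  $\mathrm{Var}(G)/\mathrm{Var}(P) = h^2$ there. This makes $h^2$ a
  testable quantity; the tests recover targets 0.1/0.4/0.9 within ±0.05 at
  n = 2000.
* **Variance split.** The non-genetic variance
  $V_g (1-h^2)/h^2$ is split evenly between the G×E and residual
  components unless `gxeRatio` says otherwise. If the G×E trait is
  monomorphic in the calibration population its share folds into the
  residual.
* **Scope of the environment scalar.** $z_e$ multiplies only the G×E term;
  residual noise is drawn independently per environment. Letting $z_e$
  also rescale the residual would conflate evaluation accuracy with
  environment quality.

With $h^2 = 1$ both components vanish and the phenotype equals the GEBV
exactly.

### Selection

`selectTop()` implements truncation selection under a pluggable score
function (any map from a population to n finite scores). Ties break toward
the lower original index, making selection deterministic and
seed-independent; selected indices are returned ascending, so `k = n` is
the identity. Built-in scores:

* `scoreGEBV()` — a linear index over per-trait GEBVs (equal weights by
  default; the score-function contract is one scalar per individual).
* `scoreOHV()` — optimal haploid value: twice the sum over genome segments
  of the better haplotype's summed effect contribution, i.e. the breeding
  value of the best doubled haploid the individual could produce. The
  default segmentation is one segment per chromosome; `blockSize` cuts
  chromosomes into fixed-size marker blocks for the finer-grained variant
  (finer segments can only raise the score). OHV ≥ GEBV always, with
  equality exactly on full homozygotes.
* `scorePhenotype()` — the mean simulated phenotype across `nEnvs`
  environments; at low heritability this is low-accuracy visual selection.
  Averaging over an explicit environment count (rather than a single
  draw) was chosen so that stage accuracy is controlled by two orthogonal
  dials, $h^2$ and `nEnvs`.

### The differentiable crossing relaxation

`softCross()` generalizes crossing to continuous parent choices: a
(k, n, 2) weight array gives, per cross and parent slot, a point on the
n-simplex; the "soft parent" is the weights-weighted average of all
genomes, and a recombination mask sampled once per gamete is applied to it.
Holding masks fixed, the output is linear in the weights (a pathwise
estimator treats the masks as fixed samples), so gradients for
weight-based cross optimization are exact and can be supplied by any
autodiff backend or a hand-coded adjoint. At one-hot weights with shared
masks the relaxation reproduces `cross()` bit-exactly — the vertex
consistency the tests check on 100 random instances. Weights outside the
simplex by more than 1e-8 are rejected, never renormalized, since silent
renormalization would corrupt optimizer steps. Soft (real-valued) genomes
may be fed back through `genomeArray` for chained relaxed crosses.

## The reference inbred schema

`runSchema()` executes a program typical for an inbred species: F0
founders (fully homozygous by default), F1 from random biparental crosses,
doubled-haploid induction, then head rows (HDRW) and preliminary, advanced
and elite yield trials (PYT/AYT/EYT) with shrinking sizes and rising
accuracy. The default `schemaConfig()` uses 50 founders, 200 F1 crosses
and 100 DH per line — 20 000 DH lines entering HDRW. Stage sizes after
selection (500/50/10/5) and stage heritabilities (0.1/0.4/0.6/0.8) are not
fixed by the program's published description, which specifies only the
shape — a large nursery shrinking to a handful of elite lines under
increasing accuracy — so they are package defaults, fully exposed in the
config. The G×E marker-effect vector is drawn once per run and shared by
all stages. An optional diallel pre-step (`f0Diallel`) can regenerate F0
from a parent set; it is off by default because the runner takes founders
as given.

```{r schema, eval = FALSE}
map <- makeMap(10, 100, heritability = 0.4, seed = 1)  # 1000 markers
res <- runSchema(schemaConfig(), map, seed = 1)
res$report
```

The tested properties are the qualitative trajectory, not numeric parity
with any other stochastic simulator: the EYT mean genetic value exceeds the
F0 mean in at least 19 of 20 seeded runs, genetic variance at EYT does not
exceed the DH-stage variance in the median over seeds, and a scaling
factor multiplies every stage size exactly.

## Synthetic data: what it does and does not emulate

`makeMap()` and `makeFounders()` generate all test inputs in code. Founder
haplotypes are drawn site-independently at a given allele frequency — no
linkage disequilibrium, no coalescent structure, no mutation — with an
inbred mode (both haplotypes identical) for DH-style founders. This is the
simplest structure that satisfies every tested property: recombination,
segregation, contraction identities and selection response do not depend
on founder LD. Consequently, passing tests demonstrate the correctness of
the operators, not realism of founder haplotype structure; analyses whose
conclusions hinge on LD decay or rare-variant sharing need real genotypes
imported through the phased-VCF path.

## Numerical and interface choices

* **Problem sizes.** Statistical tests use sizes at which 4-standard-
  deviation binomial bands are decisive: 1e5 gametes for the 10 cM
  recombination check, 1e4 selfed offspring for 1:2:1 segregation,
  n = 2000 with 60 environments for heritability recovery, and 20 schema
  runs at the full 20 000-DH configuration.
* **Determinism.** Every stochastic function takes an optional `seed`,
  scoped with `withr::local_seed` so the caller's RNG state is untouched;
  identical seeds reproduce identical arrays.
* **Validation over coercion.** Loaders reject rather than repair:
  unsorted map positions, unphased or multi-allelic VCF genotypes,
  non-binary genomes, out-of-simplex weights and undersized founder sets
  are errors, because silent fixes desynchronize marker indices or corrupt
  downstream statistics.
* **Degenerate inputs.** Single-marker chromosomes carry no interval
  probability (`NA`); empty populations (n = 0) round-trip through the
  native container; a monomorphic calibration population yields zero
  non-genetic variance and phenotype ≡ GEBV.
* **Containers.** The native population container is a single-object
  binary file (RDS) holding the genome array and ids, giving bit-exact
  round trips; phased VCF (REF→0, single ALT→1, `a|b` → (a, b)) is the
  interchange format. Genotype phasing itself is delegated to external
  software.

## Known limitations

Traits are strictly additive — no dominance or epistasis; the simulator
targets self- or open-pollinated diploid species (no autopolyploid
meiosis, no sex-specific recombination, no heterotic-group hybrid
breeding); crossover interference models other than Poisson (e.g. Kosambi)
are not implemented; and physical (bp) coordinates are carried only
nominally through VCF export.
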