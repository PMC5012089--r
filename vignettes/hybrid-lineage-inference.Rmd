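---
title: "Inferring clonal hybrid lineages and their origins in a gynogenetic fish complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal hybrid lineages and their origins in a gynogenetic fish complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gynolin)
```

## The biological system and the inference problem

Gynogenetic (sperm-dependent) hybrids, such as *Chrosomus eos-neogaeus*
dace, are all-female clones: a hybridization event between a maternal
species female and a host (paternal) species male founds a **lineage**
whose members all carry the founding multilocus genotype, modified only
by subsequent microsatellite mutation. Because the clones need host sperm
to trigger embryogenesis, hybrids co-occur with the sexual host. Two
contrasting histories can generate a regional assemblage of lineages:
postglacial **dispersal** of a few old clones, or repeated **in-situ
hybridization** in the modern landscape. The two histories leave
different signatures: in-situ lineages are diverse, narrowly distributed
(strong spatial autocorrelation of assemblage composition at short
distances), and their host-derived haplome matches the genetic make-up
of the sympatric host population.

This package implements the complete inference chain needed to
discriminate the scenarios from co-sampled host and hybrid genotypes:

1. **Lineage calling** from multi-ploidy microsatellite genotypes
   (`cluster_diploid_lineages()`, `assign_triploids()`),
2. **Clonal structure**: stepwise-mutation distances, neighbor-joining
   trees, divergence summaries, accumulation curves,
3. **Diversity and spatial statistics**: multiplicative
   alpha/beta/gamma partition, LCBD, Mantel tests and correlograms,
4. **Host population genetics**: gene diversity, HWE/LD permutation
   tests, Weir–Cockerham theta, Michalakis–Excoffier rho_ST with the
   allele-size permutation test, hierarchical AMOVA, chord distances,
   PCA,
5. **Assignment** of each lineage's host haplome to candidate host
   populations,
6. a seeded **synthetic-data generator** that reproduces the structure
   these analyses assume, with ground truth for recovery tests.

## Genotype model

Alleles are stored as integer **repeat counts** (fragment sizes convert
via `size_to_repeat()`, which refuses off-ladder sizes), so a stepwise
mutation is exactly one unit. Loci fall in three classes: `host_specific`
(amplify only the host genome), `dual_distinguishable` (both genomes,
parental alleles resolvable) and `dual_overlapping` (both genomes,
ranges overlap — excluded from every haplome-resolved computation). The
copy-number table implied by the reproductive system
(`expected_allele_counts()`) drives validation: sexual hosts are diploid
everywhere; diploid hybrids are hemizygous at host-specific loci and
carry one host + one maternal allele at dual loci; triploids carry one
extra sperm-derived host haplome. A locus is either fully typed or
missing; missing loci are excluded pairwise, never listwise, and a
partially filled locus is rejected with row-level diagnostics.

## Lineage calling

The clonal distance between two genotypes is, per locus, the minimum
over allele pairings of the summed absolute repeat differences
(haplome-aware). For a one-dimensional ground metric the optimal pairing
of equal-size multisets is the sorted-order pairing, so the
implementation is exact; the test suite still checks it against
exhaustive enumeration over pairings, which is feasible because ploidy
never exceeds three.

Diploid hybrids are clustered by single linkage, joining two genotypes
only if (i) their clonal distance is at most `max_step_distance`
(default 6 steps), (ii) they differ at no more than `max_variable_loci`
loci (default 3), and (iii) they share the mitochondrial haplotype —
clones inherit the maternal mitochondrion, so differing haplotypes
cannot descend from one event. The defaults reflect the
order-of-magnitude gap observed in this system between within-lineage
variation (a few steps, one or a few loci) and among-lineage divergence
(tens of steps); they are parameters, not constants, and the pairwise
distance matrix is returned so users can verify a gap in their own data.
Consensus genotypes take the per-slot modal allele, with ties broken
deterministically to the numerically lowest allele.

Triploids contain their lineage's full diploid genotype plus one sperm
allele per locus, so they are folded in by containment: a triploid
matches a lineage when the consensus alleles embed in its allele
multisets at every shared locus within `tolerance_steps` (default 2,
absorbing one post-formation mutation). A strictly closest lineage wins;
an exact tie is *not* auto-assigned — the triploid founds a singleton
lineage flagged `ambiguous` with the candidates reported. This keeps the
partition property (every hybrid belongs to exactly one lineage) while
making ambiguity visible instead of resolving it arbitrarily. Unmatched
triploids found new lineages; when two or more unmatched triploids share
their clonal core, the sperm alleles differ and per-locus multiset
intersection recovers the clone's host haplome, but a lineage known only
from a single triploid is flagged unresolved: its clonal host allele and
the sperm allele cannot be discriminated, and such lineages are excluded
from assignment.

## Diversity and spatial statistics

Beta diversity uses the multiplicative Whittaker partition
`beta = gamma / alpha` with `alpha` the mean per-site lineage richness;
the three regional values printed for this system are mutually
consistent under exactly this partition, which motivated the choice.
LCBD follows the total-community-variance decomposition: the
site-by-lineage matrix is converted to a dissimilarity matrix with the
quantitative Jaccard (Ružička) coefficient `1 - sum(min)/sum(max)`,
Gower-centered, and each site's diagonal share of the total sum of
squares is its contribution (they sum to 1 by construction). P-values
permute each lineage's abundances independently across sites. When a
permutation empties a site its distances to other empty sites are taken
as 0 (identical composition); a degenerate matrix with no variance at
all returns the uniform value 1/n.

Mantel correlograms use equal-width distance classes with the class
count from Sturges' rule applied to the number of pairwise distances,
a per-class standardized Mantel statistic sign-flipped so positive
values mean nearby sites are more similar, two-sided permutation tests,
and the progressive Holm correction (class k corrected among the first
k classes, reading from the shortest distance outward); a simultaneous
Holm variant is available via `progressive = FALSE`. Equal-width binning
is the default because nothing in this system argues for equal-frequency
classes. Correlogram r values of two regions are compared with Fisher's
z on the per-class pair counts; since pairwise distances are not
independent samples, that comparison is reported as indicative, not
exact.

## Host population genetics

Theta (Weir–Cockerham) and rho_ST (Michalakis–Excoffier) share one
nested ANOVA engine over populations / individuals / gene copies.
Applied to allele indicator variables and combined as a ratio of summed
variance components over loci and alleles, the engine reproduces the
closed-form Weir–Cockerham estimator exactly (the suite checks this to
machine precision); applied to allele sizes it yields rho_ST. A
two-allele locus makes size an affine transform of the indicator, so
rho_ST equals theta identically there — a useful internal consistency
check that holds exactly in this implementation. Negative variance
components are retained in the estimator ratios (classical behaviour)
but truncated to zero in AMOVA percentage tables; both are reported.
The allele-size permutation test (p-rho_ST) permutes the size labels
among each locus' allelic states (20,000 permutations by default) and
rejects when observed rho_ST exceeds the permutation distribution —
evidence that stepwise mutation, not drift alone, drives
differentiation. Pairwise differentiation significance permutes
individuals between the pair, with sequential Bonferroni (Holm) applied
across the pairwise table. The HWE statistic is Fis with two-sided
extremeness under allele shuffling; linkage disequilibrium uses a
G statistic on the two-locus genotype table under permutation; global
tests combine loci with Fisher's method. PCA operates on individual
allele-indicator vectors (copies/2), column-centered with mean
imputation of missing loci — individual-level rather than
population-level coding, so overlapping population clouds remain
visible.

## Assignment

Reference allele frequencies come from host individuals only (hybrids
never contribute), optionally pooling nearby sites via an explicit map —
pooling is exposed rather than automated because which sites form one
"population" is a study decision. The likelihood of a lineage's host
haplome in a population is the product over loci of the allele's sample
frequency, with absent alleles floored at 1e-5; the cited
frequency-based method is formulated for diploids, and its haploid
adaptation (one allele per locus) is this package's own, since hybrids
carry a single host haplome. No leave-one-out correction is applied:
lineages are not members of the reference samples. Percentage scores
normalize likelihoods across candidates (computed in log space);
simulation probabilities rank the observed log-likelihood among 10,000
haplomes drawn from the population's own frequencies.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the analyses assume: two
regions of sites; host populations drawn from Balding–Nichols
frequencies around Dirichlet ancestral frequencies, with the divergence
parameter `fst` directly targeting the expected theta (0.05 by default,
matching the weak structure typical of postglacially connected fish
populations); per site a Poisson number (`lambda_hyb = 1.5`) of founding
hybridization events, each pairing a host haplome from the local
population (or, with probability `p_dispersed`, a distant one) with a
maternal haplome from one shared pool — the maternal species is nearly
absent from such systems, so its internal structure is unobservable and
deliberately not modelled; `clonal_generations = 200` rounds of strictly
symmetric ±1-step mutation at rate `mu = 5e-4` per allele per generation
(an order-of-magnitude microsatellite placeholder — the study system
provides no estimate — chosen so that within-lineage variants differ by
a few steps at one or a few loci, as observed); triploid formation with
probability `tau = 0.3` by adding a locally drawn sperm haplome; and
per-site samples of 15 hosts and 12 hybrids, matching the study's
per-site scale. The default panel mirrors the study's marker classes:
four host-specific microsatellites, a dual distinguishable
microsatellite, a dual distinguishable intron indel (not mutated by the
SMM process), and a dual-overlapping microsatellite. Repeat-count walks
reflect at one repeat so counts never reach zero.

What the generator does **not** emulate: genotyping error and allelic
dropout, null alleles, non-stepwise mutations, linkage, selection,
spatially explicit dispersal kernels, or ecological dynamics between
clones and hosts. Passing recovery tests on these simulations therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to the artefacts of real fragment data.

## Numerical and design choices

- All stochastic routines take explicit seeds; the pipeline derives
  per-stage streams from one root seed, so identical configs produce
  byte-identical output bundles.
- Permutation p-values use the add-one convention
  `(count + 1)/(n + 1)`, so no test can return zero.
- Neighbor joining is implemented natively with a deterministic
  tie-break (the lexicographically lowest label pair wins among equal
  Q values), making the tree invariant to input order; negative branch
  lengths are clamped to zero with the deficit moved to the adjacent
  branch. The implementation is cross-checked against the standard ape
  implementation on tie-free matrices.
- Consensus ties break to the lowest allele; containment ties are
  flagged, not guessed (see above).
- An optional gate on the intron allele for lineage merging is exposed
  implicitly through `max_variable_loci`/locus selection rather than as
  a dedicated flag; the mitochondrial gate is always on.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the chain end-to-end
on simulations of 2 regions × 10 sites (15 hosts and 12 hybrids per
site, ~20–40 true lineages), with permutation counts reduced to
99–2,000 where only calibration, not fine p-value resolution, is being
checked; production defaults remain at the conventional 999/1,000/
10,000/20,000. Recovery properties asserted on these simulations
include: exact truth recovery (adjusted Rand index 1) without mutation;
theta and rho_ST within 0.02 of zero under panmixia; nominal type-I
error for the correlogram (after Holm) and the allele-size permutation
test; top-score assignment accuracy of at least 90% for in-situ
lineages under strong structure (theta ≈ 0.15, ten resolvable loci,
reference samples of 25 — the upper end of the study's per-site
sampling, mirroring its pooling of sympatric sites) and chance-level
accuracy under panmixia.

## Known limitations

- The clustering thresholds are heuristics for a system with a clear
  within/among divergence gap; data without such a gap need the emitted
  distance matrix inspected before trusting the partition.
- Fisher's z on correlogram classes ignores the non-independence of
  pairwise distances.
- rho_ST standard errors (jackknife) and exact MCMC HWE tests are out
  of scope, as are Bayesian assignment criteria.
- The star-likeness of a tree is left to judgement:
  the package reports within/among ratios and the tree, but defines no
  formal star test.
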