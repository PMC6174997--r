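---
title: "Dissecting recombination-rate genetic architecture in NAM populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting recombination-rate genetic architecture in NAM populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namrecomb)
```

## The scientific problem

In a nested association mapping (NAM) population, a set of diverse founder
lines is each crossed to one common parent and the progeny are inbred by
single seed descent (SSD) to recombinant inbred lines (RILs). Every RIL
genome is a mosaic of the two parental genomes, and each mosaic junction
records a meiotic crossover (CO) that occurred somewhere in the selfing
pedigree. Counting these junctions per RIL turns recombination itself into a
quantitative trait: the total crossover count (TCO), and its pericentromeric
(pCO) and distal (dCO) components, can be mapped like any other phenotype.
This package implements that entire analysis — crossover calling from RIL
genotype matrices, phenotype construction, single-family composite interval
mapping (CIM) with permutation thresholds, joint cross-family mapping with
nested family effects, cis/trans classification of the detected loci,
additivity of stacked alleles, and the population-genetic corollaries
(deleterious-load stratification by recombination, founder LD versus meiotic
recombination, crossovers in identity-by-descent tracts) — together with a
forward simulator of NAM populations so that every stage can be validated
against known ground truth.

## The forward simulator

### Meiosis model

Crossovers are drawn as a homogeneous Poisson process on genetic distance
(Haldane model): on a chromosome segment of length $\ell$ cM with intensity
multiplier $m$, the number of COs per meiosis is Poisson with mean
$m\,\ell/100$. There is no interference and no obligate crossover. This
choice keeps every downstream expectation in closed form — map distances are
meiotic cM by definition, the recombination fraction between two markers is
Haldane's $r = \tfrac12(1 - e^{-d/50})$, and the junction density of a fully
inbred selfed line approaches the classical limit of 2 junctions per Morgan.
Genetic maps estimated *from* RIL data are expanded relative to this meiotic
scale (the RIL recombination fraction is $R = 2r/(1+2r)$); the simulator's
coordinates are always meiotic, and the thinning experiment
(`thinning_experiment()`) applies the inverse expansion $r = R/(2-2R)$
explicitly when re-estimating map length from RIL genotypes.

Haplotypes are represented as exact breakpoint lists (step functions of
ancestry), so crossover positions are continuous and truth is available at
cM resolution, independent of any marker grid. A family simulation starts
from the F1 (heterozygous at every founder-divergent locus, since both
parents are fully inbred) and performs `n_generations - 1` selfing meioses
per lineage, two independent gametes per selfing. Residual heterozygosity
per locus is $(1/2)^{g}$ after $g$ selfing meioses — 1/64 at F7, matching
the generation structure of typical NAM RIL panels.

Two "truth" tallies are recorded per RIL. The *observable* crossover count
is the number of parental-phase switches of the final homozygous mosaic
(residual heterozygous tracts dropped, exactly what genotype data can show
once het calls are treated as missing). The *junction* count is the
per-strand junction tally of classical junction theory, which approaches 2
per Morgan at full inbreeding; at F7 the observable count sits a few percent
below it because residual heterozygosity still hides part of the junctions.
Tests against the 2-per-Morgan limit use the junction tally; everything
phenotypic uses the observable count, as in real data.

### Recombination modifiers

A modifier locus (`modifier_spec()`) carries a high allele that changes the
crossover intensity of every meiosis of a carrier plant: a region's
multiplier is $1 + \sum_l \beta_l n_l$, where $n_l \in \{0, 1, 2\}$ is the
number of high alleles the meiotic plant currently carries at locus $l$
(a heterozygote carries one — modifiers segregate between heterozygous and
homozygous states during inbreeding, so their influence waxes and wanes
along the pedigree). Scope can be global (a trans-acting modifier),
restricted to one chromosome (a cis signal, e.g. a local map-length or
divergence polymorphism), or restricted to the pericentromeric two-thirds of
every arm. The RIL-level crossover effect of a modifier is emergent, not
asserted: early-generation meioses contribute about half of all surviving
junctions and occur while the modifier is still heterozygous in every
lineage, which dilutes the final difference between carrier and non-carrier
RILs to roughly $0.3 \times 4 L \beta$ crossovers ($L$ in Morgans) rather
than the naive $4 L \beta$. All calibrations below were therefore done
empirically, with one large simulation per scenario.

### What the generator does not emulate

Sequence-level artifacts (reads, tag presence/absence calling), crossover
interference, selection during inbreeding, and divergence-dependent local
recombination suppression are not modeled. Passing tests therefore show
that the estimators recover what this generative model encodes; they do not
certify behavior under interference or segregation distortion.

## Crossover calling and phenotypes

A crossover is a change of parental genotype phase supported by at least
`k` consecutive informative markers (default `k = 2`). Per RIL and
chromosome the caller drops missing and heterozygous calls, compresses the
remainder into maximal same-phase runs, deletes runs shorter than `k` —
including terminal runs, so a lone discordant first or last marker is
treated as genotyping error rather than crossover — merges adjacent equal
phases, and emits one crossover per remaining transition, localized at the
genetic midpoint between the flanking informative markers. Under a
per-marker error rate $\varepsilon$ on $M$ markers, each isolated error
adds two phase switches under `k = 1` and none under `k = 2`, so the two
rules differ by about $2\varepsilon M$ calls per RIL — the quantitative
signature that motivates the conservative two-marker default. The price of
`k = 2` is censoring: a genuine double crossover whose inner run spans a
single marker is deleted, so called counts and marker-effect estimates are
attenuated at high CO density relative to marker density. The package
reports this honestly rather than correcting for it; the vignette's
benchmark scenarios keep CO density moderate relative to marker spacing for
exactly this reason.

Phenotypes are assembled per RIL: TCO, per-chromosome counts, and the
pericentromeric/distal split. Each chromosome arm is divided at the point
two-thirds of the way from the centromere to the telomere (distal fraction
1/3 by default, configurable); a breakpoint exactly on the boundary counts
as pericentromeric. RILs whose genotype missingness exceeds 10% of markers
are flagged and excluded from mapping. TCO = pCO + dCO = the sum of
per-chromosome counts, always.

Redundant markers are collapsed into map-contiguous bins: consecutive
markers join a bin when they agree at every jointly typed RIL and share at
least `min_overlap` (default 15) typed RILs; the delegate is the member
with the fewest missing calls. Contiguity matters: chance pattern matches
between distant markers (possible when every RIL has an even number of COs
between them) must not fuse across an observed crossover. Crossover calls
with `k = 1` are exactly invariant under delegation; `k = 2` calls are not,
because a collapsed bin can no longer provide two map-ordered supporting
markers — the package requires two genuine map-ordered markers, redundant
or not.

## Single-family QTL mapping

The scan is regression-based (Haley–Knott) composite interval mapping. The
expected alternate-parent dosage at any position follows from the two-state
Markov structure of a selfed-RIL genome with RIL-expanded transition
probabilities $R = 2r/(1+2r)$; at a typed marker it equals the observed
call, with both flanks missing it is 1/2. Cofactors are chosen by forward
selection/backward elimination on partial-F p-values (0.01 in and out);
at each grid position (1 cM step) cofactors within a 10 cM window are
omitted and LOD $= (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ is
computed against the cofactor-only model. Genome-wide thresholds are
permutation order statistics: the $\lceil(1-\alpha)P\rceil$-th largest of
$P$ max-LOD values over phenotype permutations, with the original cofactors
retained (reselecting per permutation is supported in principle but costs
an order of magnitude and changes thresholds little at these sizes).

Peaks above the threshold are reported with 2-LOD support intervals. Two
peaks on one chromosome are distinct only when they are at least 20 cM
apart *and* the profile dips at least 2 LOD below the lower of them in
between; requiring both suppresses linkage shadows of a strong peak, which
would otherwise satisfy a distance-only rule. Because cofactors outside
the 10 cM window are still linked to the peak in RIL LD, they absorb part
of the allele effect and can drag the apparent peak toward the edge of
their exclusion window; declared QTL are
therefore re-read off a profile of their chromosome computed without
same-chromosome cofactors — detection decisions still come from the plain
CIM profile. Effects are signed so that positive means the common parent's
allele increases the trait, and their magnitude is the fitted difference
between the two homozygous classes.

## Joint cross-family mapping

All families share the common parent, so loci can be modeled jointly on a
shared map with family intercepts and family-nested allele effects (each
family's alternate founder contributes its own allele). `joint_stepwise()`
performs forward selection: a candidate locus enters as a block of
family-nested expected dosages and is admitted when its partial F-test
p-value beats `p_enter` ($10^{-4}$ by default). `joint_scan()` is the
interval-mapping analogue: at each grid position the family-intercept model
is compared with the family-nested dosage model, with thresholds from
permutations within family labels. Per-locus allele-effect series summarize
the share of families in which the common parent's allele increases the
trait and flag allelic series (both signs present). Joint mapping pools
evidence for alleles shared across families and sharpens localization; it
has correspondingly less power for family-private alleles — both sides of
that trade-off are exercised in the test suite.

## Cis/trans classification and additivity

A detected QTL may act genome-wide (trans) or only on its own chromosome
(cis — e.g. a polymorphism that locally changes map length). Following the
leave-chromosome-out logic, the phenotype is recomputed without the QTL
chromosome's crossovers (for pCO/dCO, without the respective arm-region of
that chromosome), the entire mapping round is repeated with a fresh 5%
permutation threshold, and the QTL is called trans if a significant peak
recurs with a support interval intersecting the original one.

Additivity of stacked alleles is tested by counting, per RIL, the
recombination-increasing alleles at the peak markers (orientation from each
QTL's effect sign) and regressing the phenotype on the count; a significant
positive slope declares additivity, and the per-class means expose the
dosage response. With one QTL this reduces exactly to the two-class mean
difference.

## Load, LD and IBD contrasts

Crossover breakpoints are binned into equal-width genetic bins per
chromosome. Bins overlapping the distal 10% of the scaled chromosome are
the "high-recombining" class (overlap, not midpoint, so coarse bins cannot
empty the class). The deleterious-load contrast compares the proportion of
deleterious SNPs between the high-recombining bins and the rest with a
one-sided Fisher exact test of reduced load where recombination is high.
Founder LD per bin is the mean pairwise squared Pearson correlation of
allele indicators across founder lines (monomorphic markers excluded; bins
with fewer than two usable markers dropped), and its correlation with
per-bin crossover counts is Pearson's $r$ with a t-based p-value. The IBD
contrast classifies regions by overlap with IBD tracts and compares
per-region crossover counts with a Mann–Whitney U test; `U` counts pairs in
which the non-IBD region exceeds the IBD region (ties half), so small `U`
means more crossovers in IBD regions, and the default one-sided alternative
tests for exactly that.

## Benchmark study conditions

The `benchmark_*()` functions freeze the package's validation scenarios;
`scripts/acceptance.R` runs them end to end. The conditions were chosen
once, on power grounds, before freezing:

* **Caller fidelity** — one 100 cM chromosome at 0.1 cM marker spacing, 60
  noise-free F7 RILs (per-RIL `k = 1` calls equal simulator truth), and a
  4 × 100 cM genome with ~2000 markers, 150 RILs and error rate 0.005
  (the `k=1`–`k=2` excess tracks $2\varepsilon M$).
* **Junction accumulation** — 12 × 200 cM (24 Morgans), 2000 F7 RILs; mean
  per-strand junctions within 5% of 48.
* **QTL recovery** — 12 × 100 cM at 1 marker/cM, 150 RILs, 20 replicates,
  one founder-carried global suppressor ($\beta = -0.37$), calibrated on a
  1200-RIL run to a +4 crossover common-parent effect on the called-TCO
  scale. A suppressor (rather than an enhancer) keeps CO density moderate,
  which limits two-marker-rule censoring and keeps the carrier class's
  variance low; on a wheat-scale 21-Morgan genome the same +4 effect would
  be underpowered at $n = 150$ because the trait's meiotic Poisson variance
  grows with map length while a single simulated QTL leaves nothing for the
  CIM cofactors to absorb — unlike real multi-QTL data.
* **Cis/trans** — 200 + 6 × 100 cM at 0.5 cM spacing, 200 RILs, 20
  replicates per class; trans = global suppressor ($\beta = -0.40$), cis =
  own-chromosome intensity inflation ($\beta = +3.0$) on the 200 cM
  chromosome.
* **Additivity** — 10 × 100 cM at 0.5 cM spacing; four equal-magnitude
  modifiers ($\beta = \mp 0.33$; one suppressor, three enhancers, so the
  multiplier stays positive and the mean trait level stays moderate),
  realizing ≈ 3.25 crossovers per favorable allele on the called scale
  (the calibration constant, measured once on 5400 simulated RILs and
  frozen); the slope from a 1200-RIL family (large enough that sampling
  error is small against the ±25% recovery band, so the check probes the
  estimator rather than the draw) is judged against that constant. Under
  honest meiotic Poisson noise the $R^2$ of
  this regression (reported by `benchmark_additivity()`)
  stays well below what multi-QTL field data can show: the residual
  variance is tied to the mean crossover count, which must be large enough
  to carry four ±3 effects, so high allele-stacking $R^2$ values reflect
  the lower residual variance of real multi-QTL families, not an
  attainable property of this null-plus-four-loci model. The pericentromeric-scope check uses
  a 5 × 100 cM genome, 400 RILs and $\beta = +1$.
* **Null calibration** — 3 × 100 cM, 100 RILs, 60 modifier-free scans at
  the permuted 5% threshold; and 20 within-family-permuted joint stepwise
  runs at $p_{\mathrm{enter}} = 10^{-4}$.
* **Load enrichment** — 20 replicates of 10,000 SNPs at odds ratio 2
  (and 1 for the null), deleterious probability 0.06 in high-recombining
  bins, of the order of genome-wide deleterious-to-coding SNP ratios.

Problem sizes are desk-scale by design: they are the smallest sizes at
which each property is comfortably identifiable, and the whole suite runs
in minutes on one core.

## Numerical notes and limitations

Projection bases are rank-truncated QR factorizations, so collinear
cofactors never break a scan; residual sums of squares are floored at
machine epsilon before forming LOD ratios (a perfectly fitting model gives
a large finite LOD, and a constant phenotype gives LOD 0 everywhere).
Permutation thresholds require $P\alpha \ge 1$ and error otherwise. All
intervals are half-open $[start, end)$ on 0-based cM floats; a breakpoint
exactly on an arm-partition boundary is pericentromeric; touching regions
do not overlap. Determinism is strict: every stochastic function takes a
seed, derived per stage from one master seed, and identical seeds give
bit-identical outputs.

Known limitations: double crossovers within one marker interval are
undetectable by construction, and the two-marker rule additionally censors
double crossovers spanning a single marker, biasing called counts and
effects downward at high CO density; no interference model is offered; the
joint scan is a family-stratified regression approximation to inclusive
composite interval mapping, not a reimplementation of any specific
software's numerics; and IBD tracts are injected by the simulator, not
inferred from data.
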