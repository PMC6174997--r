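# namrecomb

Genetic architecture of meiotic recombination rate in nested association
mapping (NAM) populations of inbred lines.

In a NAM panel, diverse founders are each crossed to one common parent and
selfed by single seed descent to recombinant inbred lines (RILs). Every RIL
genome is a mosaic of the two parental genomes, and each mosaic junction
records a meiotic crossover. Counting those junctions per RIL turns
recombination itself into a mappable quantitative trait: the total
crossover count (TCO) and its pericentromeric (pCO) and distal (dCO)
components. `namrecomb` implements the full analysis:

* **Crossover calling** from markers × RILs genotype matrices by the
  *k*-consecutive-marker phase-change rule (`call_crossovers()`, default
  `k = 2`: a phase switch must be supported by two consecutive informative
  markers, so isolated mis-genotyped markers are not counted as crossovers).
* **Phenotyping**: TCO / pCO / dCO per RIL, with chromosome arms split at
  the point 2/3 of the way from centromere to telomere
  (`summarize_phenotypes()`, `arm_partition()`), marker-redundancy collapse
  into delegate markers, breakpoint distributions on the 0–1 chromosome
  scale, map summaries, and a marker-thinning experiment that re-estimates
  map length via `r = R/(2-2R)` and Haldane's map function.
* **Single-family QTL mapping**: regression (Haley–Knott) composite
  interval mapping with stepwise cofactor selection, genome-wide
  permutation thresholds, peak calling with 2-LOD support intervals, and
  effects signed so that positive means the common parent's allele
  increases the trait (`scan_family()`, `cim_scan()`, `find_qtl()`).
* **Joint cross-family mapping** with family intercepts and family-nested
  allele effects (`joint_stepwise()`, `joint_scan()`,
  `allele_effect_series()`).
* **Architecture post-analyses**: cis/trans classification by
  leave-chromosome-out phenotype recomputation and rescanning
  (`classify_cis_trans()`), additivity of stacked favorable alleles
  (`additivity_analysis()`), region merging and overlap accounting
  (`merge_regions()`, `overlap_summary()`).
* **Load / LD / IBD contrasts**: deleterious-SNP enrichment outside the
  high-recombining distal bins by one-sided Fisher test
  (`load_contrast()`), founder LD (mean pairwise r²) per recombination bin
  and its correlation with crossover counts (`ld_per_bin()`,
  `ld_recomb_correlation()`), and a Mann–Whitney contrast of crossover
  counts in IBD versus non-IBD regions (`ibd_co_contrast()`).
* **A forward NAM simulator** (`simulate_founders()`,
  `simulate_ssd_family()`, `simulate_nam()`, `modifier_spec()`,
  `add_genotyping_noise()`, `simulate_annotation()`): Poisson (Haldane)
  crossovers on exact cM coordinates, recombination-modifier loci whose
  intensity effect acts through the meiotic plant's current genotype
  (global, single-chromosome, or pericentromeric scope), residual
  heterozygosity `(1/2)^g`, IBD tracts copied from the common parent, and
  genotyping error/missingness — with full ground truth (breakpoints,
  junction counts, modifier dosages) for every RIL.
* **End-to-end orchestration**: `run_pipeline()` executes
  simulate → phenotype → scans → joint mapping → cis/trans → additivity →
  regions → load/LD/IBD from one (optionally YAML) configuration and
  writes deterministic TSV reports.

The core model: a selfed-RIL genome is a two-state Markov chain on parental
phase with transition probability `R = 2r/(1+2r)` between markers at
Haldane recombination fraction `r = (1 − exp(−d/50))/2`; the scan regresses
the trait on the conditional expected alternate-parent dosage at each grid
position with marker cofactors outside a 10 cM window, and
`LOD = (n/2)·log10(RSS₀/RSS₁)`.

## File formats

Genotype matrices are TSV, first column `marker`, remaining columns RIL
ids; calls are `A` (homozygous common parent), `B` (homozygous alternate
founder), `H` (heterozygous; re-coded missing on load by default), `N`
(missing). Maps are TSV with `marker`, `chrom`, `cM` (optionally `Mb`,
`bin`). Coordinates are 0-based cM floats; intervals half-open
`[start, end)`. See `load_genotypes()`, `load_map()`, `write_results()`.
VCF/PLINK import is out of scope; export such data to the matrix format
above (one row per biallelic marker, calls re-coded against the common
parent) with your favorite toolchain.

## Worked example

Simulate a small NAM family segregating a global recombination modifier,
call crossovers, and map the modifier:

```r
library(namrecomb)

gm <- build_genome_model(
  data.frame(name = sprintf("chr%02d", 1:12), length_cM = 100),
  markers_per_chrom = 101)
panel <- simulate_founders(gm, n_founders = 3, maf_law = 0.5, seed = 7)
panel$geno[2, ] <- 1L - panel$geno[1, ]   # make founder F01 fully divergent

mod <- modifier_spec("chr03", 50, beta = -0.37, scope = "global",
                     carriers = "F01")    # founder-carried suppressor
fam <- simulate_ssd_family(panel, "F01", n_rils = 150, n_generations = 7,
                           modifiers = list(mod), seed = 11)

cos  <- call_crossovers(fam$genos, k = 2)
ph   <- summarize_phenotypes(cos, arm_partition(gm), fam$genos)
print(ph)
fs   <- scan_family(ph$tco, fam$genos, n_perm = 200, seed = 13)
print(fs)
```

Output:

```
Phenotypes for 150 RILs (0 excluded): mean TCO 13.19 (pCO 8.88, dCO 4.31)
CIM scan of 'tco' (family CPxF01): 150 RILs, 1212 positions, 1 cofactor(s)
Max LOD 8.95 at chr03 50.0 cM (effect +4.97)
Permutation threshold: LOD 3.02; 1 QTL declared
 trait family chrom peak_cM      lod   effect ci_lo ci_hi threshold alpha
   tco CPxF01 chr03      50 8.953438 4.973492    49    56  3.022198  0.05
```

The family averages 13.2 called crossovers per RIL: the genome is 12
Morgans, the founder's suppressor allele pulls the count below the neutral
F7 expectation, and the two-marker rule censors part of the close double
crossovers. The scan declares one QTL at the true locus (chr03, 50 cM)
with a 2-LOD support interval of 49–56 cM; the effect +5.0 means the
common parent's allele increases TCO by about five crossovers in this
replicate — the suppressor is founder-carried, so the common-parent allele
is the recombination-increasing one. Classify it as trans-acting
(the signal survives removal of its own chromosome's crossovers):

```r
ct <- classify_cis_trans(fs$qtl[1, ], fam$genos, cos, arm_partition(gm),
                         trait = "tco", n_perm = 200, seed = 17)
print(ct)
```

```
QTL chr03 @ 50.0 cM (tco): trans-acting (re-detected: TRUE)
```

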