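Package: namrecomb
Title: Genetic Architecture of Recombination Rate Variation in NAM Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting the genetic architecture of meiotic
    recombination rate in nested association mapping (NAM) populations of
    inbred lines. Calls crossovers from RIL genotype matrices using a
    k-consecutive-marker phase-change rule, builds total, pericentromeric and
    distal crossover phenotypes, maps recombination-modifier QTL by composite
    interval mapping with permutation thresholds and by joint cross-family
    regression with nested family effects, classifies QTL as cis- or
    trans-acting by leave-chromosome-out phenotype recomputation, tests
    additivity of stacked alleles, and contrasts deleterious-allele load,
    founder linkage disequilibrium and identity-by-descent against the
    recombination landscape. Includes a forward simulator of NAM families of
    single-seed-descent RILs with known recombination-modifier loci so that
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
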