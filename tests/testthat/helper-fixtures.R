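# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files.

toy_model <- function(n_chrom = 3L, length_cM = 100, markers = 101L,
                      centromere = NULL) {
  ch <- data.frame(name = sprintf("c%d", seq_len(n_chrom)),
                   length_cM = length_cM, stringsAsFactors = FALSE)
  if (!is.null(centromere)) ch$centromere_cM <- centromere
  build_genome_model(ch, markers_per_chrom = markers)
}

# Panel whose single founder differs from the common parent at every marker,
# so every marker is informative in the family cross.
divergent_panel <- function(model, n_founders = 2L, seed = 1L) {
  panel <- simulate_founders(model, n_founders, maf_law = 0.5,
                             ibd_fraction = 0, seed = seed)
  for (i in seq_len(n_founders - 1L))
    panel$geno[i + 1L, ] <- 1L - panel$geno[1L, ]
  panel
}

# Hand-built single-chromosome genotype object from a character matrix with
# entries "A", "B", "H", "N"; markers at the given cM positions.
geno_from_strings <- function(calls, cM = NULL, chrom = "c1") {
  codes <- c(A = 0L, H = 1L, B = 2L)
  m <- matrix(unname(codes[calls]), nrow = nrow(calls))
  cM <- cM %||% (seq_len(nrow(calls)) - 1)
  markers <- data.frame(marker = sprintf("m%02d", seq_len(nrow(calls))),
                        chrom = chrom, cM = cM, stringsAsFactors = FALSE)
  namrecomb:::new_ril_genotypes(
    family = "toy", common = "P1", founder = "P2", markers = markers,
    geno = m, rils = sprintf("r%02d", seq_len(ncol(calls))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, expr) namrecomb:::with_seed(seed, expr)
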