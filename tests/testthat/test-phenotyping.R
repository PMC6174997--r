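test_that("redundant markers collapse into bins with least-missing delegates", {
  # consecutive markers: m1 == m2 (one bin); m3 agrees on its overlap but
  # has missing calls; m4 differs at one shared RIL and starts a new bin
  calls <- matrix(c(
    "A", "A", "B", "B", "A", "A",   # m1
    "A", "A", "B", "B", "A", "A",   # m2
    "A", "N", "B", "B", "N", "N",   # m3 agrees with m1/m2 where typed
    "A", "B", "B", "B", "A", "A"),  # m4 differs from m1 at r2
    nrow = 4, byrow = TRUE)
  g <- geno_from_strings(calls)
  bins <- collapse_redundant_markers(g, min_overlap = 3)
  expect_equal(bins$bin[1], bins$bin[2])
  expect_equal(bins$bin[1], bins$bin[3])   # chained through the overlap
  expect_false(bins$bin[4] == bins$bin[1])
  # delegate is the member with the fewest missing calls
  b1 <- bins[bins$bin == bins$bin[1], ]
  expect_equal(b1$marker[b1$delegate], "m01")
  # raising the overlap requirement splits the missing-heavy m3 off
  bins2 <- collapse_redundant_markers(g, min_overlap = 4)
  expect_false(bins2$bin[3] == bins2$bin[1])

  # crossover calls are invariant under collapse for noise-free, fully
  # typed data (F15: residual heterozygosity negligible)
  gm <- toy_model(1, markers = 51)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 30, 15, seed = 4)
  bins3 <- collapse_redundant_markers(fam$genos, min_overlap = 5)
  dg <- delegate_genotypes(fam$genos, bins3)
  # k = 1: every phase transition survives deduplication exactly (k = 2
  # additionally requires two map-ordered markers, which a collapsed bin
  # can no longer provide, so only k = 1 is collapse-invariant)
  co_full <- call_crossovers(fam$genos, k = 1)
  co_del <- call_crossovers(dg, k = 1)
  tab <- function(co) table(factor(co$ril, levels = fam$genos$rils))
  expect_equal(as.integer(tab(co_full)), as.integer(tab(co_del)))
})

test_that("the k-marker phase-change rule calls crossovers as specified", {
  # P1 P1 P1 P2 P2 with k = 2: one CO between markers 3 and 4
  g <- geno_from_strings(matrix(c("A", "A", "A", "B", "B"), 5, 1))
  co <- call_crossovers(g, k = 2)
  expect_equal(nrow(co), 1L)
  expect_equal(co$left_marker, "m03")
  expect_equal(co$right_marker, "m04")
  expect_equal(co$breakpoint_cM, 2.5)
  expect_equal(co$phase_from, 0L)
  expect_equal(co$phase_to, 2L)

  # P1 P1 P2 P1 P1: the singleton P2 is an error under k = 2 (0 COs) but
  # two COs under k = 1
  g2 <- geno_from_strings(matrix(c("A", "A", "B", "A", "A"), 5, 1))
  expect_equal(nrow(call_crossovers(g2, k = 2)), 0L)
  expect_equal(nrow(call_crossovers(g2, k = 1)), 2L)

  # missing calls are skipped; CO localized between flanking informative
  # markers with midpoint breakpoint
  g3 <- geno_from_strings(matrix(c("A", "A", "N", "B", "B"), 5, 1))
  co3 <- call_crossovers(g3, k = 2)
  expect_equal(co3$left_marker, "m02")
  expect_equal(co3$right_marker, "m04")
  expect_equal(co3$breakpoint_cM, 2)

  # heterozygous calls are treated as missing
  g4 <- geno_from_strings(matrix(c("A", "A", "H", "B", "B"), 5, 1))
  expect_equal(nrow(call_crossovers(g4, k = 2)), 1L)

  # terminal runs shorter than k are dropped, not called: a lone
  # discordant first or last marker is treated as genotyping error
  g5 <- geno_from_strings(matrix(c("B", "A", "A", "A", "A"), 5, 1))
  expect_equal(nrow(call_crossovers(g5, k = 2)), 0L)
  g6 <- geno_from_strings(matrix(c("A", "N", "B", "B", "B"), 5, 1))
  expect_equal(nrow(call_crossovers(g6, k = 2)), 0L)
  expect_equal(nrow(call_crossovers(g6, k = 1)), 1L)

  expect_warning(call_crossovers(geno_from_strings(matrix("A", 1, 1)), k = 2),
                 "fewer than k")
})

test_that("count(k=2) <= count(k=1) and the error excess matches 2*eps*M", {
  gm <- toy_model(2, markers = 201)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 60, 7, seed = 9)
  noisy <- add_genotyping_noise(fam$genos, 0.01, 0.02, seed = 10)
  k1 <- table(factor(call_crossovers(noisy, k = 1)$ril,
                     levels = noisy$rils))
  k2 <- table(factor(call_crossovers(noisy, k = 2)$ril,
                     levels = noisy$rils))
  expect_true(all(as.integer(k2) <= as.integer(k1)))
  M <- mean(colSums(!is.na(noisy$geno)))
  excess <- mean(as.integer(k1) - as.integer(k2))
  expect_lt(abs(excess - 2 * 0.01 * M) / (2 * 0.01 * M), 0.25)
})

test_that("phenotype tables conserve TCO across partitions and chromosomes", {
  gm <- toy_model(3, markers = 101)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 40, 7, seed = 6)
  cos <- call_crossovers(fam$genos)
  part <- arm_partition(gm)
  ph <- summarize_phenotypes(cos, part, fam$genos)
  expect_equal(ph$tco, ph$pco + ph$dco)
  expect_equal(ph$tco, ph$n_c1 + ph$n_c2 + ph$n_c3)
  expect_equal(sum(ph$tco), nrow(cos))
  expect_true(all(ph$tco >= 0))

  # region assignment: breakpoint far out on the arm is distal, boundary is
  # pericentromeric
  toy <- structure(
    data.frame(ril = c("r1", "r1", "r1"), chrom = "c1",
               left_marker = "x", right_marker = "y",
               left_cM = c(94, 50, 100 / 6), right_cM = c(96, 52, 100 / 6),
               breakpoint_cM = c(95, 51, 100 / 6),
               phase_from = 0L, phase_to = 2L, stringsAsFactors = FALSE),
    class = c("crossover_set", "data.frame"), rils = "r1", chroms = "c1")
  ph2 <- summarize_phenotypes(toy, part)
  expect_equal(ph2$dco, 1L)   # only the 95 cM breakpoint is distal
  expect_equal(ph2$pco, 2L)   # 51 cM and the exact 1/3 boundary are peri

  # missingness exclusion flag
  fam$genos$geno[, 1] <- NA
  ph3 <- summarize_phenotypes(cos, part, fam$genos, missing_threshold = 0.10)
  expect_true(ph3$excluded[1])
  expect_false(any(ph3$excluded[-1]))
})

test_that("region exclusion recomputes phenotypes exactly", {
  gm <- toy_model(3, markers = 51)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 30, 7, seed = 8)
  cos <- call_crossovers(fam$genos)
  part <- arm_partition(gm)
  ph <- summarize_phenotypes(cos, part)
  ex <- exclude_regions(cos, part, exclude_chrom = "c1")
  expect_equal(ex$tco, ph$tco - ph$n_c1)
  # excluding nothing is the identity
  ex0 <- exclude_regions(cos, part)
  expect_equal(ex0$tco, ph$tco)
  # excluding one chromosome's pericentromeric region only drops its pCOs
  exp2 <- exclude_regions(cos, part,
                          exclude_region = data.frame(chrom = "c2",
                                                      region = "pericentromeric"))
  distal <- namrecomb:::is_distal(part, cos$chrom, cos$breakpoint_cM)
  drop_n <- table(factor(cos$ril[cos$chrom == "c2" & !distal],
                         levels = attr(cos, "rils")))
  expect_equal(exp2$pco, ph$pco - as.integer(drop_n))
  expect_equal(exp2$dco, ph$dco)
  expect_error(exclude_regions(cos, part, exclude_chrom = "c9"), "unknown")
})

test_that("breakpoint distributions histogram on the 0-1 scale", {
  gm <- toy_model(2, markers = 51)
  empty <- call_crossovers(simulate_ssd_family(divergent_panel(gm), "F01",
                                               2, 2, seed = 1)$genos)
  empty <- empty[0, , drop = FALSE]
  attr(empty, "rils") <- "r1"; attr(empty, "chroms") <- c("c1", "c2")
  class(empty) <- c("crossover_set", "data.frame")
  bd0 <- breakpoint_distribution(empty, gm)
  expect_equal(sum(bd0$counts), 0L)

  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 300, 7, seed = 3)
  cos <- call_crossovers(fam$genos)
  bd <- breakpoint_distribution(cos, gm, n_bins = 10)
  expect_equal(sum(bd$counts), nrow(cos))
  # uniform intensity: fraction distal ~ 1/3
  expect_lt(abs(bd$fraction_distal - 1 / 3),
            3 * sqrt(1 / 3 * 2 / 3 / nrow(cos)))
})

test_that("map summaries aggregate per chromosome and genome", {
  map <- data.frame(marker = sprintf("m%d", 1:6),
                    chrom = rep(c("1A", "1D"), each = 3),
                    cM = c(0, 60, 120, 0, 40, 80),
                    Mb = c(0, 300, 600, 0, 250, 500))
  ms <- map_summary(map, genome_of = c("1A" = "A", "1D" = "D"))
  expect_equal(ms$chromosomes$length_cM, c(120, 80))
  expect_equal(ms$chromosomes$cM_per_Mb, c(0.2, 0.16))
  expect_equal(ms$genomes$length_cM[ms$genomes$genome == "A"], 120)
  ms2 <- map_summary(map[, 1:3])
  expect_true(all(is.na(ms2$chromosomes$cM_per_Mb)))
})

test_that("marker thinning shortens re-estimated maps by missing double COs", {
  gm <- toy_model(2, length_cM = 150, markers = 151)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 150, 7, seed = 13)
  p <- nrow(fam$genos$geno)
  full <- thinning_experiment(fam$genos, p, n_reps = 2, seed = 1)
  expect_equal(full$mean_cM, full$full_cM)
  thin <- thinning_experiment(fam$genos, round(p / 6), n_reps = 8, seed = 2)
  expect_lt(thin$mean_cM, full$full_cM)
  thin2 <- thinning_experiment(fam$genos, round(p / 6), n_reps = 8, seed = 2)
  expect_identical(thin$lengths_cM, thin2$lengths_cM)
  expect_error(thinning_experiment(fam$genos, p + 1), "exceeds")
  # full-density estimate recovers the true map length within a few percent
  expect_lt(abs(full$full_cM - 300) / 300, 0.1)
})
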