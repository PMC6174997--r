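test_that("founder panels are homozygous, deterministic, and frequency-calibrated", {
  gm <- toy_model(2, markers = 201)
  p1 <- simulate_founders(gm, 6, maf_law = 0.5, ibd_fraction = 0, seed = 7)
  p2 <- simulate_founders(gm, 6, maf_law = 0.5, ibd_fraction = 0, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$geno %in% c(0L, 1L)))
  expect_error(simulate_founders(gm, 1, seed = 1), "at least 2")

  # per-locus allele frequency ~ Binomial(n_lines, 0.5): grand mean within
  # 3 SE of 0.5
  f <- colMeans(p1$geno)
  se <- sqrt(0.25 / (6 * ncol(p1$geno)))
  expect_lt(abs(mean(f) - 0.5), 3 * se)
})

test_that("IBD tracts copy the common parent's haplotype at target fraction", {
  gm <- toy_model(3, markers = 201)
  p <- simulate_founders(gm, 8, maf_law = 0.5, ibd_fraction = 0.2,
                         seed = 3)
  expect_gte(nrow(p$ibd), 20)
  G <- sum(gm$chrom$length_cM)
  realized <- sum(p$ibd$end_cM - p$ibd$start_cM) / (G * 7)
  expect_lt(abs(realized - 0.2) / 0.2, 0.2)
  # inside every tract the founder equals the common parent
  for (j in seq_len(nrow(p$ibd))) {
    sel <- gm$markers$chrom == p$ibd$chrom[j] &
      gm$markers$cM >= p$ibd$start_cM[j] & gm$markers$cM < p$ibd$end_cM[j]
    expect_equal(p$geno[p$ibd$founder[j], sel], p$geno["CP", sel])
  }
})

test_that("meiosis draws Poisson crossovers and recombines haplotypes", {
  gm <- toy_model(1, length_cM = 100, markers = 11)
  pl <- f1_plant(gm)
  n_co <- replicate(600, nrow(simulate_meiosis(pl, gm)$crossovers))
  # E[#CO] = L / 100 = 1 per meiosis
  expect_lt(abs(mean(n_co) - 1), 3 * sqrt(1 / 600))

  # doubling the intensity in the pericentromeric region only doubles that
  # region's expectation, leaving the distal thirds untouched
  part <- arm_partition(gm)
  reg <- list(c1 = data.frame(
    start = c(0, part$distal_left_end, part$distal_right_start),
    end = c(part$distal_left_end, part$distal_right_start, 100),
    mult = c(1, 2, 1)))
  cos <- replicate(600, {
    co <- simulate_meiosis(pl, gm, reg)$crossovers$cM
    c(peri = sum(co >= part$distal_left_end & co <= part$distal_right_start),
      dist = sum(co < part$distal_left_end | co > part$distal_right_start))
  })
  expect_lt(abs(mean(cos["peri", ]) - 2 * 200 / 3 / 100),
            3 * sqrt(4 / 3 / 600))
  expect_lt(abs(mean(cos["dist", ]) - 100 / 3 / 100),
            3 * sqrt(1 / 3 / 600))

  # a fully homozygous parent yields a gamete identical to its haplotype
  hom <- lapply(pl, function(h) list(h1 = h$h1, h2 = h$h1))
  names(hom) <- names(pl)
  g <- simulate_meiosis(hom, gm, seed = 5)$gamete
  expect_identical(g$c1$start, pl$c1$h1$start)
  expect_length(g$c1$br, 0L)
})

test_that("SSD families show the expected residual heterozygosity and junctions", {
  gm <- toy_model(2, length_cM = 150, markers = 151)
  panel <- divergent_panel(gm)
  fam <- simulate_ssd_family(panel, "F01", n_rils = 120, n_generations = 7,
                             seed = 11)
  # residual heterozygosity per locus ~ (1/2)^6 = 1/64
  het <- mean(fam$genos$geno == 1L)
  expect_lt(abs(het - 1 / 64), 3 * sqrt((1 / 64) / length(fam$genos$geno)))
  # Haldane-Waterman junction accumulation: F7 mean within ~6% of 2/Morgan
  expect_lt(abs(mean(fam$truth$tco) - 2 * 3 * (1 - 2^-6)), 0.35)
  expect_error(simulate_ssd_family(panel, "F01", 5, n_generations = 1),
               ">= 2")
  mod_off <- modifier_spec("c1", 500, beta = 0.1, carriers = "F01")
  expect_error(simulate_ssd_family(panel, "F01", 5, modifiers = list(mod_off)),
               "off the map")
  # determinism
  fam2 <- simulate_ssd_family(panel, "F01", n_rils = 120, n_generations = 7,
                              seed = 11)
  expect_identical(fam$genos$geno, fam2$genos$geno)
  expect_identical(fam$truth, fam2$truth)
})

test_that("modifier dosage acts on each meiosis and lifts junction counts", {
  gm <- toy_model(4, length_cM = 100, markers = 26)
  panel <- divergent_panel(gm)
  base <- simulate_ssd_family(panel, "F01", 400, 7, seed = 3)
  mod <- modifier_spec("c1", 50, beta = 0.10, scope = "global",
                       carriers = "F01")
  up <- simulate_ssd_family(panel, "F01", 400, 7, list(mod), seed = 4)
  ratio <- mean(up$truth$tco) / mean(base$truth$tco)
  # one allele on average through inbreeding: ~ +10% junctions
  expect_gt(ratio, 1.04)
  expect_lt(ratio, 1.17)
  # dosage truth is 0/1/2 and mostly fixed at F7
  expect_true(all(up$truth$dosages %in% c(0, 1, 2)))
  expect_gt(mean(up$truth$dosages[, 1] != 1), 0.95)
})

test_that("genotyping noise flips and masks calls at the requested rates", {
  gm <- toy_model(2, markers = 251)
  panel <- divergent_panel(gm)
  fam <- simulate_ssd_family(panel, "F01", 200, 7, seed = 2)
  expect_identical(add_genotyping_noise(fam$genos, 0, 0), fam$genos)
  noisy <- add_genotyping_noise(fam$genos, 0.01, 0.05, seed = 8)
  n <- sum(!is.na(fam$genos$geno))
  flips <- sum(noisy$geno != fam$genos$geno, na.rm = TRUE)
  expect_lt(abs(flips - 0.01 * n), 4 * sqrt(0.01 * n))
  miss <- sum(is.na(noisy$geno)) - sum(is.na(fam$genos$geno))
  expect_lt(abs(miss - 0.05 * n), 4 * sqrt(0.05 * n))
  noisy2 <- add_genotyping_noise(fam$genos, 0.01, 0.05, seed = 8)
  expect_identical(noisy$geno, noisy2$geno)
  expect_error(add_genotyping_noise(fam$genos, -0.1, 0), "0, 1")
})

test_that("annotation simulation reproduces the requested enrichment odds", {
  gm <- toy_model(2, markers = 51)
  bins <- recomb_bins(
    call_crossovers(simulate_ssd_family(divergent_panel(gm), "F01", 40, 7,
                                        seed = 1)$genos),
    gm, bin_cM = 10)
  bins <- define_high_recomb_regions(bins, 10)
  expect_error(simulate_annotation(bins, enrichment_odds = 0), "> 0")
  expect_equal(nrow(simulate_annotation(bins, 2, n_snps = 0)), 0L)

  ann <- simulate_annotation(bins, enrichment_odds = 2, n_snps = 10000,
                             p_high = 0.06, seed = 5)
  hi <- bins$high_recomb[match(ann$bin, bins$bin)]
  odds <- function(x) mean(x) / (1 - mean(x))
  emp_or <- odds(ann$deleterious[!hi]) / odds(ann$deleterious[hi])
  expect_gt(emp_or, 1.45)
  expect_lt(emp_or, 2.75)

  # theta = 1: proportion difference within 3 SE of zero
  ann0 <- simulate_annotation(bins, 1, n_snps = 10000, seed = 6)
  hi0 <- bins$high_recomb[match(ann0$bin, bins$bin)]
  d <- mean(ann0$deleterious[hi0]) - mean(ann0$deleterious[!hi0])
  se <- sqrt(0.06 * 0.94 * (1 / sum(hi0) + 1 / sum(!hi0)))
  expect_lt(abs(d), 3 * se)
})
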