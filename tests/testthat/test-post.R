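test_that("region merging honours half-open intervals and multiplicity", {
  m <- merge_regions(data.frame(chrom = "c1", start = c(0, 5),
                                end = c(10, 15), family = c("f1", "f2")))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 15))
  expect_equal(m$multiplicity, 2L)

  m2 <- merge_regions(data.frame(chrom = "c1", start = c(0, 20),
                                 end = c(10, 30), family = c("f1", "f2")))
  expect_equal(nrow(m2), 2L)

  # touching half-open intervals do not merge
  m3 <- merge_regions(data.frame(chrom = "c1", start = c(0, 10),
                                 end = c(10, 20), family = c("f1", "f2")))
  expect_equal(nrow(m3), 2L)

  expect_error(merge_regions(data.frame(chrom = "c1", start = 5, end = 1)),
               "malformed")

  # idempotent and order-invariant
  iv <- data.frame(chrom = rep(c("c1", "c2"), each = 3),
                   start = c(0, 8, 30, 2, 1, 50),
                   end = c(10, 20, 40, 6, 3, 60),
                   family = c("a", "b", "a", "c", "a", "b"))
  m4 <- merge_regions(iv)
  m5 <- merge_regions(iv[sample(nrow(iv)), ])
  expect_equal(as.data.frame(m4), as.data.frame(m5))
  m6 <- merge_regions(data.frame(chrom = m4$chrom, start = m4$start,
                                 end = m4$end, family = seq_len(nrow(m4))))
  expect_equal(m6$start, m4$start)
  expect_equal(m6$end, m4$end)
})

test_that("overlap percentages are directional and integer-rounded", {
  a <- data.frame(chrom = "c1", start = seq(0, 190, by = 10) * 10,
                  end = seq(0, 190, by = 10) * 10 + 50)
  a <- a[1:20, ]
  # build b to intersect exactly 13 of the 20 a-regions
  b <- data.frame(chrom = "c1", start = a$start[1:13] + 10,
                  end = a$start[1:13] + 20)
  ov <- overlap_summary(a, b)
  expect_equal(ov$a_in_b, 13L)
  expect_equal(ov$pct_a_in_b, 65)
  expect_equal(ov$pct_b_in_a, 100)

  disj <- data.frame(chrom = "c9", start = 0, end = 1)
  ov0 <- overlap_summary(a, disj)
  expect_equal(ov0$pct_a_in_b, 0)
  ovi <- overlap_summary(a, a)
  expect_equal(ovi$pct_a_in_b, 100)
  expect_equal(ovi$pct_b_in_a, 100)
})

test_that("additivity regression recovers class structure", {
  gm <- toy_model(2, markers = 51)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 120, 7, seed = 5)
  g <- fam$genos
  # synthetic phenotype built from two favorable founder alleles,
  # 3 units each, plus noise
  pk1 <- which(g$markers$chrom == "c1" & g$markers$cM == 50)
  pk2 <- which(g$markers$chrom == "c2" & g$markers$cM == 50)
  x1 <- g$geno[pk1, ] / 2
  x2 <- g$geno[pk2, ] / 2
  set.seed(8)
  y <- 10 + 3 * x1 + 3 * x2 + rnorm(120, sd = 2)
  qtl <- data.frame(trait = "tco", family = "toy", chrom = c("c1", "c2"),
                    peak_cM = 50, lod = 10, effect = c(-3, -3),
                    ci_lo = 40, ci_hi = 60, threshold = 3, alpha = 0.05)
  ad <- additivity_analysis(qtl, g, y)
  expect_lt(abs(ad$slope - 3) / 3, 0.25)
  expect_gt(ad$r2, 0.3)
  expect_lt(ad$p, 1e-4)
  # a single QTL reduces to the two-class mean difference
  ad1 <- additivity_analysis(qtl[1, ], g, y)
  keep <- !is.na(g$geno[pk1, ]) & g$geno[pk1, ] != 1L & !is.na(y)
  cls <- tapply(y[keep], g$geno[pk1, keep], mean)
  expect_equal(ad1$slope, unname(cls["2"] - cls["0"]), tolerance = 1e-9)
  # null phenotype: no additivity signal
  set.seed(9)
  ad0 <- additivity_analysis(qtl, g, rnorm(120))
  expect_lt(ad0$r2, 0.1)
  # degenerate input: single class errors
  gg <- g
  gg$geno[pk1, ] <- 0L
  gg$geno[pk2, ] <- 0L
  expect_error(additivity_analysis(qtl, gg, y), "one allele-count class")
})

test_that("cis/trans classification validates its inputs", {
  gm <- toy_model(2, markers = 26)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 30, 7, seed = 2)
  cos <- call_crossovers(fam$genos)
  part <- arm_partition(gm)
  qtl <- data.frame(trait = "tco", family = "toy", chrom = "c9",
                    peak_cM = 50, lod = 5, effect = 2, ci_lo = 40,
                    ci_hi = 60, threshold = 3, alpha = 0.05)
  expect_error(classify_cis_trans(qtl, fam$genos, cos, part), "absent")
})
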