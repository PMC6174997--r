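test_that("expected RIL dosage follows the two-state Markov chain", {
  # typed marker: dosage equals the call
  expect_equal(ril_genotype_prob(0, 2L, 5, 0L), 1)
  expect_equal(ril_genotype_prob(0, 0L, 5, 2L), 0)
  # both flanks missing: family prior 1/2
  expect_equal(ril_genotype_prob(NA, NA, NA, NA), 0.5)
  # P1 ... P1 flanks at 1 cM spacing, midpoint: < 0.01, and equal to the
  # exhaustive two-interval chain computed independently
  d <- 0.5
  r <- 0.5 * (1 - exp(-d / 50))
  R <- 2 * r / (1 + 2 * r)
  Tm <- matrix(c(1 - R, R, R, 1 - R), 2, 2)
  num <- Tm[1, 2] * Tm[2, 1]
  den <- Tm[1, 1] * Tm[1, 1] + num
  expect_lt(num / den, 0.01)
  expect_equal(ril_genotype_prob(d, 0L, d, 0L), num / den, tolerance = 1e-12)
  # single flank: RIL-expanded recombination fraction
  expect_equal(ril_genotype_prob(10, 2L, NA, NA),
               1 - namrecomb:::ril_R(10), tolerance = 1e-12)
  # dosage always within [0, 1]
  set.seed(1)
  dl <- runif(200, 0, 50); dr <- runif(200, 0, 50)
  a <- sample(c(0L, 2L), 200, TRUE); b <- sample(c(0L, 2L), 200, TRUE)
  p <- ril_genotype_prob(dl, a, dr, b)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("CIM LOD matches direct regression and respects the sign convention", {
  calls <- matrix(rep(c("A", "B"), each = 4), nrow = 1)
  calls <- rbind(calls, calls, calls)   # 3 identical markers
  g <- geno_from_strings(calls, cM = c(0, 5, 10))
  y <- c(5.1, 4.9, 5.2, 4.8, 9.1, 8.9, 9.2, 8.8)
  expect_error(cim_scan(y, g), "fewer than 10")
  g12 <- geno_from_strings(calls[, c(seq_len(8), seq_len(4))],
                           cM = c(0, 5, 10))
  y12 <- c(y, y[1:4] + 0.05)
  sc <- cim_scan(y12, g12, step_cM = 5)
  # oracle: direct two-model regression at the typed marker
  x <- c(rep(0, 4), rep(1, 4), rep(0, 4))
  rss0 <- sum(stats::resid(stats::lm(y12 ~ 1))^2)
  rss1 <- sum(stats::resid(stats::lm(y12 ~ x))^2)
  lod_direct <- (12 / 2) * log10(rss0 / rss1)
  expect_equal(sc$profile$lod[sc$profile$cM == 5], lod_direct,
               tolerance = 1e-8)
  # alternate-parent carriers have the higher y, so the common-parent
  # oriented effect is negative
  expect_lt(sc$profile$effect[sc$profile$cM == 5], 0)
  # LOD is invariant to affine rescaling of the phenotype
  sc2 <- cim_scan(3 * y12 + 7, g12, step_cM = 5)
  expect_equal(sc2$profile$lod, sc$profile$lod, tolerance = 1e-8)
  # constant phenotype: LOD identically zero
  sc0 <- cim_scan(rep(2, 12), g12, step_cM = 5)
  expect_true(all(sc0$profile$lod == 0))
})

test_that("stepwise cofactor selection is conservative, powered, deterministic", {
  gm <- toy_model(1, markers = 50)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 200, 7, seed = 2)
  cand <- fam$genos$markers$marker
  # null phenotype: empty set in >= 85% of seeded replicates
  empty <- vapply(1:30, function(i) {
    set.seed(300 + i)
    y <- rnorm(200)
    length(suppressMessages(select_cofactors(y, fam$genos,
                                             candidates = cand))) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.85)
  # a 1-SD marker effect is picked up (within tight linkage of the marker)
  pk <- 25L
  x <- fam$genos$geno[pk, ] / 2
  set.seed(77)
  y <- rnorm(200) + x
  cof <- suppressMessages(select_cofactors(y, fam$genos, candidates = cand))
  expect_gt(length(cof), 0L)
  hit_cM <- fam$genos$markers$cM[match(cof, fam$genos$markers$marker)]
  expect_true(any(abs(hit_cM - fam$genos$markers$cM[pk]) <= 10))
  # deterministic
  expect_identical(cof, suppressMessages(
    select_cofactors(y, fam$genos, candidates = cand)))
})

test_that("permutation thresholds are order statistics of max-LOD", {
  gm <- toy_model(1, markers = 21)
  fam <- simulate_ssd_family(divergent_panel(gm), "F01", 40, 7, seed = 3)
  set.seed(9)
  y <- rnorm(40)
  thr <- permutation_threshold(y, fam$genos, n_perm = 40, alpha = 0.1,
                               seed = 4)
  mx <- attr(thr, "max_lods")
  expect_length(mx, 40L)
  expect_equal(as.numeric(thr), sort(mx)[ceiling(0.9 * 40)])
  thr2 <- permutation_threshold(y, fam$genos, n_perm = 40, alpha = 0.1,
                                seed = 4)
  expect_equal(as.numeric(thr), as.numeric(thr2))
  # stricter alpha can only raise the threshold on the same permutation set
  thr3 <- permutation_threshold(y, fam$genos, n_perm = 40, alpha = 0.05,
                                seed = 4)
  expect_gte(as.numeric(thr3), as.numeric(thr))
  expect_error(permutation_threshold(y, fam$genos, n_perm = 100,
                                     alpha = 0.001), "unresolvable")
})

test_that("peak finding yields 2-LOD support intervals and splits far peaks", {
  prof <- data.frame(chrom = "c1", cM = 0:100,
                     lod = pmax(8 - 0.15 * abs(0:100 - 47.5), 0))
  q <- find_qtl(prof, threshold = 6, drop = 2)
  expect_equal(nrow(q), 1L)
  expect_equal(q$peak_cM, 47)  # grid point nearest the apex
  # 2-LOD interval: lod >= peak - 2 within ~13.3 cM of the apex
  expect_lte(q$ci_lo, 35)
  expect_gte(q$ci_hi, 60)
  expect_true(q$ci_lo <= q$peak_cM && q$peak_cM <= q$ci_hi)

  # everything below threshold: empty result
  expect_equal(nrow(find_qtl(prof, threshold = 10)), 0L)

  # two peaks 60 cM apart with a deep valley: two QTL
  lod2 <- pmax(7 - 0.5 * abs(0:100 - 20), 0) +
    pmax(6 - 0.5 * abs(0:100 - 80), 0)
  q2 <- find_qtl(data.frame(chrom = "c1", cM = 0:100, lod = lod2),
                 threshold = 4)
  expect_equal(nrow(q2), 2L)
  expect_equal(sort(q2$peak_cM), c(20, 80))
})
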