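toy_bins <- function(seed = 1L, n_rils = 150L) {
  gm <- toy_model(2, markers = 101)
  fam <- simulate_ssd_family(divergent_panel(gm, seed = seed), "F01",
                             n_rils, 7, seed = seed + 1L)
  cos <- call_crossovers(fam$genos)
  list(model = gm, bins = recomb_bins(cos, gm, bin_cM = 10), cos = cos)
}

test_that("recombination bins and the distal-10% rule behave as defined", {
  tb <- toy_bins()
  bins <- tb$bins
  expect_equal(sum(bins$n_co), nrow(tb$cos))
  expect_error(define_high_recomb_regions(bins, 0), "0, 50")
  expect_error(define_high_recomb_regions(bins, 50), "0, 50")
  b2 <- define_high_recomb_regions(bins, 10)
  expect_true(all(b2$high_recomb[b2$scaled_mid < 0.1]))
  expect_false(any(b2$high_recomb[b2$scaled_mid >= 0.1 &
                                    b2$scaled_mid <= 0.9]))
  # under uniform intensity the captured fraction is about 2 x 10%
  expect_lt(abs(attr(b2, "co_fraction_captured") - 0.2), 0.06)
})

test_that("the load contrast equals the exhaustive hypergeometric tail", {
  bins <- data.frame(bin = 1:2, chrom = "c1", start = c(0, 50),
                     end = c(50, 100), scaled_mid = c(0.05, 0.75),
                     n_co = c(50, 5), high_recomb = c(TRUE, FALSE))
  ann <- data.frame(
    bin = c(rep(1L, 200), rep(2L, 200)),
    deleterious = c(rep(1L, 10), rep(0L, 190), rep(1L, 30), rep(0L, 170)))
  res <- load_contrast(ann, bins)
  expect_equal(res$prop_high, 10 / 200)
  expect_equal(res$prop_low, 30 / 200)
  # brute-force hypergeometric tail: P(X <= 10) drawing 200 of the 400
  # SNPs (40 deleterious in total) into the high class
  p_oracle <- sum(stats::dhyper(0:10, 40, 360, 200))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)

  # equal proportions: no signal
  ann0 <- data.frame(bin = rep(1:2, each = 100),
                     deleterious = rep(c(1L, 0L, 1L, 0L), c(10, 90, 10, 90)))
  expect_gt(load_contrast(ann0, bins)$p, 0.05)
  # arithmetic: 10 deleterious / 110 total
  ann1 <- data.frame(bin = rep(1:2, c(110, 10)),
                     deleterious = c(rep(1L, 10), rep(0L, 100), rep(1L, 5),
                                     rep(0L, 5)))
  expect_equal(load_contrast(ann1, bins)$prop_high, 0.0909, tolerance = 1e-3)
  expect_error(load_contrast(ann1[ann1$bin == 1, ], bins), "no SNPs")
})

test_that("per-bin LD is the mean pairwise squared correlation of founders", {
  gm <- toy_model(1, markers = 41)
  panel <- simulate_founders(gm, 12, maf_law = 0.5, ibd_fraction = 0,
                             seed = 4)
  bins <- data.frame(bin = 1:2, chrom = "c1", start = c(0, 50),
                     end = c(50, 100), scaled_mid = c(0.25, 0.75),
                     n_co = c(3, 3))
  # duplicated column pair gives r2 = 1
  panel$geno[, 2] <- panel$geno[, 1]
  out <- suppressMessages(ld_per_bin(panel, bins))
  expect_true(all(out$r2 >= 0 & out$r2 <= 1, na.rm = TRUE))
  # independent markers across n founders: E[r2] ~ 1/(n-1)
  big <- simulate_founders(toy_model(1, markers = 401), 12, maf_law = 0.5,
                           ibd_fraction = 0, seed = 5)
  bb <- data.frame(bin = 1L, chrom = "c1", start = 0, end = 100,
                   scaled_mid = 0.5, n_co = 1)
  r2 <- suppressMessages(ld_per_bin(big, bb))$r2
  expect_lt(abs(r2 - 1 / 11), 0.02)
  # a bin whose markers are all monomorphic is dropped with a message
  mono <- panel
  sel <- gm$markers$cM >= 50
  mono$geno[, sel] <- 0L
  expect_message(out2 <- ld_per_bin(mono, bins), "dropped")
  expect_true(is.na(out2$r2[2]))
  expect_false(is.na(out2$r2[1]))
})

test_that("LD-recombination correlation uses Pearson r with t-based p", {
  bins <- data.frame(bin = 1:3, chrom = "c1", start = 0, end = 1,
                     scaled_mid = 0.5, n_co = c(1, 5, 9),
                     r2 = c(0.9, 0.5, 0.1))
  res <- ld_recomb_correlation(bins)
  expect_equal(res$r, -1, tolerance = 1e-9)
  expect_error(ld_recomb_correlation(bins[1:2, ]), "fewer than 3")
  bins$r2 <- 0.5
  expect_error(ld_recomb_correlation(bins), "zero variance")
  # permuted labels: near-zero correlation on average
  set.seed(3)
  rr <- replicate(200, {
    b <- data.frame(bin = 1:10, n_co = rpois(10, 5), r2 = runif(10))
    ld_recomb_correlation(b)$r
  })
  expect_lt(abs(mean(rr)), 0.05)
})

test_that("IBD vs non-IBD crossover contrast matches brute-force U", {
  # toy: regions with counts {1,2} (IBD) vs {3,4} (non-IBD)
  cos <- structure(data.frame(
    ril = "r1", chrom = "c1",
    left_marker = "x", right_marker = "y", left_cM = 0, right_cM = 1,
    breakpoint_cM = c(rep(5, 1), rep(15, 2), rep(25, 3), rep(35, 4)),
    phase_from = 0L, phase_to = 2L),
    class = c("crossover_set", "data.frame"), rils = "r1", chroms = "c1")
  regions <- data.frame(chrom = "c1", start = c(0, 10, 20, 30),
                        end = c(10, 20, 30, 40))
  ibd <- data.frame(chrom = "c1", start_cM = c(0, 10), end_cM = c(10, 20))
  res <- ibd_co_contrast(cos, regions, ibd, alternative = "greater")
  expect_equal(res$counts_ibd, c(1, 2))
  expect_equal(res$counts_non, c(3, 4))
  # brute force: pairs (ibd, non) with non > ibd, ties half
  U_bf <- sum(outer(res$counts_ibd, res$counts_non,
                    function(a, b) (b > a) + 0.5 * (b == a)))
  expect_equal(res$U, U_bf)
  # identical samples {2,2} vs {2,2}, two-sided: p ~ 1
  cos2 <- cos[1:8, , drop = FALSE]
  attr(cos2, "rils") <- attr(cos, "rils")
  attr(cos2, "chroms") <- attr(cos, "chroms")
  class(cos2) <- class(cos)
  cos2$breakpoint_cM <- rep(c(5, 15, 25, 35), each = 2)
  res2 <- ibd_co_contrast(cos2, regions, ibd, alternative = "two.sided")
  expect_gt(res2$p, 0.9)
  expect_error(ibd_co_contrast(cos, regions,
                               data.frame(chrom = "c9", start_cM = 0,
                                          end_cM = 1)), "empty")
})

test_that("doubled crossover intensity in IBD tracts is detected", {
  gm <- toy_model(2, length_cM = 200, markers = 201)
  panel <- divergent_panel(gm)
  # mark alternating 20 cM tracts as IBD and double intensity inside them
  ibd <- data.frame(chrom = rep(c("c1", "c2"), each = 5),
                    start_cM = rep(seq(0, 160, by = 40), 2),
                    end_cM = rep(seq(20, 200, by = 40), 2))
  reg <- lapply(split(ibd, ibd$chrom), function(d) {
    br <- sort(unique(c(0, d$start_cM, d$end_cM, 200)))
    data.frame(start = br[-length(br)], end = br[-1],
               mult = rep_len(c(2, 1), length(br) - 1))
  })
  co <- do.call(rbind, lapply(1:300, function(i) {
    simulate_meiosis(f1_plant(gm), gm, reg, seed = 1000 + i)$crossovers
  }))
  cos <- structure(
    data.frame(ril = "r", chrom = co$chrom, left_marker = "x",
               right_marker = "y", left_cM = 0, right_cM = 0,
               breakpoint_cM = co$cM, phase_from = 0L, phase_to = 2L),
    class = c("crossover_set", "data.frame"), rils = "r",
    chroms = c("c1", "c2"))
  regions <- data.frame(chrom = rep(c("c1", "c2"), each = 20),
                        start = rep(seq(0, 190, by = 10), 2),
                        end = rep(seq(10, 200, by = 10), 2))
  res <- ibd_co_contrast(cos, regions, ibd, alternative = "greater")
  expect_gt(res$mean_ibd, res$mean_non)
  expect_lt(res$p, 0.01)
})
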