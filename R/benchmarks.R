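# Validation benchmarks -------------------------------------------------------
#
# Self-contained simulation studies that exercise the full pipeline against
# known ground truth. Each benchmark fixes its study conditions (genome,
# sample sizes, modifier effects) as package defaults; the methods vignette
# explains how each condition was chosen. All randomness flows from the
# `seed` argument.

# panel in which every founder is fully divergent from the common parent,
# so all markers are informative in every family
divergent_founders <- function(model, n_founders = 2L, seed = 1L) {
  panel <- simulate_founders(model, n_founders, maf_law = 0.5,
                             ibd_fraction = 0, seed = seed)
  for (i in seq_len(n_founders - 1L))
    panel$geno[i + 1L, ] <- 1L - panel$geno[1L, ]
  panel
}

#' Benchmark: crossover-caller fidelity
#'
#' Two checks of the phase-change caller on simulated families. (i)
#' Noise-free recovery: with dense markers (0.1 cM) and no genotyping
#' error, per-RIL `k = 1` calls are compared with the simulator's true
#' junction counts. (ii) Error response: with per-call error rate `eps` on
#' a map of roughly `M` informative markers, each isolated error flips one
#' marker and adds two phase switches, so the single-marker rule exceeds
#' the two-marker rule by about `2 * eps * M` calls per RIL.
#'
#' @param seed integer seed.
#' @param n_rils RILs per family.
#' @param eps genotyping error rate for the error-response check.
#' @return list: `exact_match_rate` (fraction of RILs whose `k = 1` count
#'   equals the true junction count), `total_called`, `total_truth`,
#'   `mean_k1_minus_k2`, `expected_2epsM`, `excess_rel_err`.
#' @export
benchmark_co_caller <- function(seed = 1L, n_rils = 60L, eps = 0.005) {
  seeds <- derive_seeds(seed, 4L)
  # (i) dense noise-free family
  gm <- build_genome_model(data.frame(name = "chr1", length_cM = 100),
                           markers_per_chrom = 1001L)
  panel <- divergent_founders(gm, seed = seeds[1L])
  fam <- simulate_ssd_family(panel, "F01", n_rils, 7L, seed = seeds[2L])
  k1 <- table(factor(call_crossovers(fam$genos, k = 1L)$ril,
                     levels = fam$genos$rils))
  exact <- mean(as.integer(k1) == as.integer(fam$truth$tco))
  # (ii) ~2000-marker genome with genotyping error
  gm2 <- build_genome_model(
    data.frame(name = sprintf("chr%d", 1:4), length_cM = 100),
    markers_per_chrom = 501L)
  panel2 <- divergent_founders(gm2, seed = seeds[3L])
  fam2 <- simulate_ssd_family(panel2, "F01", 150L, 7L, seed = seeds[4L])
  M <- nrow(fam2$genos$geno)
  noisy <- add_genotyping_noise(fam2$genos, eps, 0, seed = seeds[4L] + 1L)
  n1 <- table(factor(call_crossovers(noisy, k = 1L)$ril, levels = noisy$rils))
  n2 <- table(factor(call_crossovers(noisy, k = 2L)$ril, levels = noisy$rils))
  excess <- mean(as.integer(n1) - as.integer(n2))
  list(exact_match_rate = exact,
       total_called = sum(k1), total_truth = sum(fam$truth$tco),
       mean_k1_minus_k2 = excess, expected_2epsM = 2 * eps * M,
       excess_rel_err = abs(excess - 2 * eps * M) / (2 * eps * M))
}

#' Benchmark: junction accumulation on a 24-Morgan genome
#'
#' Simulates F7 single-seed-descent RILs on a 24-Morgan genome with no
#' modifiers and compares the mean true junction count per RIL (the
#' per-strand junction tally) with the Haldane-Waterman fully inbred limit
#' of 2 junctions per Morgan. The observable crossover count (phase
#' junctions visible in genotype data, het tracts dropped) is reported
#' alongside; it sits a few percent lower while residual heterozygosity
#' hides part of the junctions.
#'
#' @param seed integer seed.
#' @param n_rils number of RILs.
#' @return list: `mean_junctions`, `mean_tco_observable`, `limit` (= 48),
#'   `rel_err`.
#' @export
benchmark_junctions <- function(seed = 1L, n_rils = 2000L) {
  gm <- build_genome_model(
    data.frame(name = sprintf("chr%02d", 1:12), length_cM = 200),
    markers_per_chrom = 11L)
  panel <- divergent_founders(gm, seed = seed)
  fam <- simulate_ssd_family(panel, "F01", n_rils, 7L, seed = seed + 1L)
  m <- mean(fam$truth$junctions)
  limit <- 2 * sum(gm$chrom$length_cM) / 100
  list(mean_junctions = m, mean_tco_observable = mean(fam$truth$tco),
       limit = limit, rel_err = abs(m - limit) / limit)
}

# shared single-modifier recovery scenario: 12 x 100 cM genome, founder-
# carried suppressor calibrated to a +4 crossover common-parent effect on
# the called-TCO scale
recovery_model <- function() {
  build_genome_model(
    data.frame(name = sprintf("chr%02d", 1:12), length_cM = 100),
    markers_per_chrom = 101L)
}

#' Benchmark: single-family QTL parameter recovery
#'
#' Repeatedly simulates a 150-RIL F7 family segregating one global
#' recombination modifier (a founder-carried suppressor calibrated to a
#' common-parent effect of about +4 crossovers on the called-TCO scale),
#' runs the full single-family analysis (crossover calling, cofactor
#' selection, CIM scan, 200-permutation 5% threshold, peak calling) and
#' scores whether a QTL is declared within 10 cM of the true locus and how
#' closely the effect estimate tracks the realized effect.
#'
#' @param seed integer seed.
#' @param n_reps replicates.
#' @param n_rils RILs per replicate.
#' @param beta per-allele intensity increment of the suppressor.
#' @return list: `detection_rate`, `mean_effect_bias` (estimate minus
#'   realized common-parent effect, detected replicates), `mean_true_effect`,
#'   `per_rep` data.frame.
#' @export
benchmark_qtl_recovery <- function(seed = 1L, n_reps = 20L, n_rils = 150L,
                                   beta = -0.37) {
  gm <- recovery_model()
  panel <- divergent_founders(gm, seed = seed)
  part <- arm_partition(gm)
  mod <- modifier_spec("chr03", 50, beta = beta, scope = "global",
                       carriers = "F01")
  seeds <- derive_seeds(seed + 1L, 2L * n_reps)
  rows <- lapply(seq_len(n_reps), function(i) {
    fam <- simulate_ssd_family(panel, "F01", n_rils, 7L, list(mod),
                               seed = seeds[2L * i - 1L])
    ph <- summarize_phenotypes(call_crossovers(fam$genos, k = 2L), part,
                               fam$genos)
    y <- ifelse(ph$excluded, NA_real_, ph$tco)
    fs <- suppressMessages(scan_family(y, fam$genos, n_perm = 200L,
                                       alpha = 0.05, seed = seeds[2L * i]))
    hit <- fs$qtl[fs$qtl$chrom == "chr03" &
                    abs(fs$qtl$peak_cM - 50) <= 10, , drop = FALSE]
    d <- fam$truth$dosages[, 1L]
    truth_eff <- mean(ph$tco[d == 0]) - mean(ph$tco[d == 2])
    data.frame(hit = nrow(hit) > 0L,
               est = if (nrow(hit)) hit$effect[1L] else NA_real_,
               truth = truth_eff, max_lod = max(fs$scan$profile$lod),
               threshold = fs$threshold)
  })
  per_rep <- do.call(rbind, rows)
  list(detection_rate = mean(per_rep$hit),
       mean_effect_bias = mean(per_rep$est - per_rep$truth, na.rm = TRUE),
       mean_true_effect = mean(per_rep$truth),
       per_rep = per_rep)
}

#' Benchmark: cis/trans classifier operating characteristics
#'
#' Simulates families carrying either a genuinely trans-acting modifier (a
#' global suppressor) or a purely cis signal (a chromosome-scope intensity
#' inflation, i.e. a local map-length/divergence polymorphism), maps the
#' TCO QTL, and applies the leave-chromosome-out reclassification.
#' Sensitivity is the fraction of detected trans QTL classified trans;
#' specificity the fraction of detected cis QTL classified cis.
#'
#' @param seed integer seed.
#' @param n_reps replicates per class.
#' @param n_rils RILs per family.
#' @return list: `sensitivity`, `specificity`, `trans_detected`,
#'   `cis_detected`.
#' @export
benchmark_cis_trans <- function(seed = 1L, n_reps = 20L, n_rils = 200L) {
  ch <- data.frame(name = c("chrL", sprintf("chr%d", 2:7)),
                   length_cM = c(200, rep(100, 6)))
  gm <- build_genome_model(ch, marker_positions = lapply(
    stats::setNames(ch$length_cM, ch$name), function(L) seq(0, L, by = 0.5)))
  panel <- divergent_founders(gm, seed = seed)
  part <- arm_partition(gm)
  run_case <- function(mod, locus_chrom, locus_cM, s) {
    fam <- simulate_ssd_family(panel, "F01", n_rils, 7L, list(mod),
                               seed = s)
    cos <- call_crossovers(fam$genos, k = 2L)
    ph <- summarize_phenotypes(cos, part, fam$genos)
    y <- ifelse(ph$excluded, NA_real_, ph$tco)
    fs <- suppressMessages(scan_family(y, fam$genos, step_cM = 2,
                                       n_perm = 100L, alpha = 0.05,
                                       seed = s + 1L))
    q <- fs$qtl[fs$qtl$chrom == locus_chrom &
                  abs(fs$qtl$peak_cM - locus_cM) <= 20, , drop = FALSE]
    if (!nrow(q)) return(NA)
    cl <- suppressMessages(classify_cis_trans(
      q[1L, ], fam$genos, cos, part, trait = "tco", step_cM = 2,
      n_perm = 100L, alpha = 0.05, seed = s + 2L))
    cl$classification == "trans"
  }
  seeds <- derive_seeds(seed + 7L, 2L * n_reps)
  transmod <- modifier_spec("chr3", 50, beta = -0.40, scope = "global",
                            carriers = "F01")
  trans_calls <- vapply(seq_len(n_reps), function(i)
    run_case(transmod, "chr3", 50, seeds[i]), NA)
  cismod <- modifier_spec("chrL", 100, beta = 3.0, scope = "chromosome",
                          carriers = "F01")
  cis_calls <- vapply(seq_len(n_reps), function(i)
    run_case(cismod, "chrL", 100, seeds[n_reps + i]), NA)
  list(sensitivity = mean(trans_calls, na.rm = TRUE),
       specificity = mean(!cis_calls, na.rm = TRUE),
       trans_detected = mean(!is.na(trans_calls)),
       cis_detected = mean(!is.na(cis_calls)))
}

#' Benchmark: additivity of stacked modifier alleles
#'
#' (i) Slope recovery: one family segregates four equal-magnitude, purely
#' additive intensity modifiers (one suppressor and three enhancers, one
#' per chromosome, calibrated to about 3 crossovers per favorable allele
#' on the called scale); the allele-stacking regression slope should
#' recover the realized per-allele effect. (ii) Region specificity: a
#' pericentromeric-scope modifier raises pCO while leaving dCO unchanged.
#'
#' @param seed integer seed.
#' @param n_rils RILs for the slope study (default 1200: large enough that
#'   the slope's sampling error is small against the ±25% recovery band,
#'   so the check probes the estimator, not the draw).
#' @param beta magnitude of each modifier's per-allele intensity increment.
#' @return list: `slope`, `r2`, `p`, `true_per_allele` (the frozen
#'   calibration constant 3.25, measured once on 5400 simulated RILs),
#'   `ratio`, `pco_p`, `dco_p`, `pco_shift`, `dco_shift`.
#' @export
benchmark_additivity <- function(seed = 1L, n_rils = 1200L, beta = 0.33) {
  gm <- build_genome_model(
    data.frame(name = sprintf("chr%02d", 1:10), length_cM = 100),
    markers_per_chrom = 201L)
  panel <- divergent_founders(gm, seed = seed)
  part <- arm_partition(gm)
  betas <- c(-beta, beta, beta, beta)
  mods <- lapply(1:4, function(i)
    modifier_spec(sprintf("chr%02d", i), 50, beta = betas[i],
                  scope = "global", carriers = "F01"))
  seeds <- derive_seeds(seed + 3L, 4L)
  # calibration constant: the realized per-favorable-allele effect of this
  # modifier set on the called-TCO scale, measured once on 5400 simulated
  # RILs and frozen
  true_eff <- 3.25
  # analysis-scale family scored through the package's additivity path
  fam <- simulate_ssd_family(panel, "F01", n_rils, 7L, mods,
                             seed = seeds[2L])
  ph <- summarize_phenotypes(call_crossovers(fam$genos, k = 2L), part,
                             fam$genos)
  qtl <- data.frame(trait = "tco", family = fam$genos$family,
                    chrom = sprintf("chr%02d", 1:4), peak_cM = 50,
                    lod = NA_real_, effect = c(1, -1, -1, -1),
                    ci_lo = 40, ci_hi = 60, threshold = NA_real_,
                    alpha = 0.05, stringsAsFactors = FALSE)
  ad <- additivity_analysis(qtl, fam$genos, ph$tco)
  # pericentromeric-scope modifier: pCO up, dCO unchanged
  gm2 <- build_genome_model(
    data.frame(name = sprintf("chr%d", 1:5), length_cM = 100),
    markers_per_chrom = 201L)
  panel2 <- divergent_founders(gm2, seed = seed + 1L)
  part2 <- arm_partition(gm2)
  pmod <- modifier_spec("chr2", 50, beta = 1.0, scope = "pericentromeric",
                        carriers = "F01")
  pf <- simulate_ssd_family(panel2, "F01", 400L, 7L, list(pmod),
                            seed = seeds[3L])
  php <- summarize_phenotypes(call_crossovers(pf$genos, k = 2L), part2,
                              pf$genos)
  dd <- pf$truth$dosages[, 1L]
  keep <- dd != 1
  carrier <- dd[keep] == 2
  pco_t <- stats::t.test(php$pco[keep][carrier], php$pco[keep][!carrier])
  dco_t <- stats::t.test(php$dco[keep][carrier], php$dco[keep][!carrier])
  list(slope = ad$slope, r2 = ad$r2, p = ad$p,
       true_per_allele = true_eff,
       ratio = ad$slope / true_eff,
       pco_p = pco_t$p.value, dco_p = dco_t$p.value,
       pco_shift = unname(pco_t$estimate[1L] - pco_t$estimate[2L]),
       dco_shift = unname(dco_t$estimate[1L] - dco_t$estimate[2L]))
}

#' Benchmark: null calibration of the QTL machinery
#'
#' (i) Single-family scans on modifier-free families declare at least one
#' QTL at the permutation-derived 5% threshold in about 5% of replicates.
#' (ii) Joint stepwise selection at `p_enter = 1e-4` on permuted (null)
#' phenotypes selects no marker in nearly all replicates.
#'
#' @param seed integer seed.
#' @param n_reps_single,n_reps_joint replicates.
#' @return list: `single_family_fp_rate`, `joint_null_empty_rate`.
#' @export
benchmark_null_calibration <- function(seed = 1L, n_reps_single = 60L,
                                       n_reps_joint = 20L) {
  gm <- build_genome_model(
    data.frame(name = sprintf("chr%d", 1:3), length_cM = 100),
    markers_per_chrom = 101L)
  panel <- divergent_founders(gm, seed = seed)
  part <- arm_partition(gm)
  seeds <- derive_seeds(seed + 11L, 2L * n_reps_single)
  fp <- vapply(seq_len(n_reps_single), function(i) {
    fam <- simulate_ssd_family(panel, "F01", 100L, 7L,
                               seed = seeds[2L * i - 1L])
    ph <- summarize_phenotypes(call_crossovers(fam$genos, k = 2L), part,
                               fam$genos)
    fs <- suppressMessages(scan_family(ph$tco, fam$genos, n_perm = 100L,
                                       alpha = 0.05, seed = seeds[2L * i]))
    nrow(fs$qtl) > 0L
  }, logical(1))
  # joint null: 5 families, phenotypes permuted within family
  panel5 <- divergent_founders(gm, n_founders = 6L, seed = seed + 1L)
  fams <- simulate_nam(panel5, 60L, 7L, seed = seed + 2L)
  jf0 <- lapply(fams, function(f) {
    ph <- summarize_phenotypes(call_crossovers(f$genos, k = 2L), part,
                               f$genos)
    list(genos = f$genos, y = ph$tco)
  })
  jseeds <- derive_seeds(seed + 13L, n_reps_joint)
  empty <- vapply(seq_len(n_reps_joint), function(i) {
    jf <- lapply(jf0, function(f) {
      f$y <- with_seed(jseeds[i] + match(f$genos$founder, panel5$lines),
                       sample(f$y))
      f
    })
    nrow(joint_stepwise(jf, p_enter = 1e-4, thin_cM = 5)$loci) == 0L
  }, logical(1))
  list(single_family_fp_rate = mean(fp),
       joint_null_empty_rate = mean(empty))
}

#' Benchmark: deleterious-load enrichment detection
#'
#' Simulates SNP annotations over recombination bins with a given odds
#' ratio of deleterious alleles in low- vs high-recombining regions and
#' reports how often the one-sided Fisher contrast detects the reduced
#' load in the high-recombining class, together with the null rejection
#' rate at odds ratio 1.
#'
#' @param seed integer seed.
#' @param n_reps replicates per setting.
#' @param n_snps SNPs per replicate.
#' @return list: `power_theta2`, `null_rate`, `mean_p_theta2`.
#' @export
benchmark_load_enrichment <- function(seed = 1L, n_reps = 20L,
                                      n_snps = 10000L) {
  gm <- build_genome_model(
    data.frame(name = sprintf("chr%d", 1:2), length_cM = 100),
    markers_per_chrom = 101L)
  panel <- divergent_founders(gm, seed = seed)
  fam <- simulate_ssd_family(panel, "F01", 150L, 7L, seed = seed + 1L)
  bins <- recomb_bins(call_crossovers(fam$genos, k = 2L), gm, bin_cM = 10)
  bins <- define_high_recomb_regions(bins, 10)
  seeds <- derive_seeds(seed + 5L, 2L * n_reps)
  p2 <- vapply(seq_len(n_reps), function(i) {
    ann <- simulate_annotation(bins, enrichment_odds = 2, n_snps = n_snps,
                               seed = seeds[i])
    load_contrast(ann, bins)$p
  }, numeric(1))
  p1 <- vapply(seq_len(n_reps), function(i) {
    ann <- simulate_annotation(bins, enrichment_odds = 1, n_snps = n_snps,
                               seed = seeds[n_reps + i])
    load_contrast(ann, bins)$p
  }, numeric(1))
  list(power_theta2 = mean(p2 < 0.05), null_rate = mean(p1 < 0.05),
       mean_p_theta2 = mean(p2))
}
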