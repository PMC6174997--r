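# Deleterious load, founder LD and IBD versus recombination -------------------

#' Build recombination bins from crossover breakpoints
#'
#' Divides every chromosome into equal-width genetic bins and counts the
#' crossover breakpoints falling in each (half-open bins; the last bin is
#' closed). The scaled position of a bin midpoint on its chromosome drives
#' the distal-end classification used by the load contrast.
#'
#' @param cos a `crossover_set`.
#' @param model a `genome_model`.
#' @param bin_cM bin width in cM.
#' @return data.frame of class `bin_table`: `bin`, `chrom`, `start`, `end`,
#'   `scaled_mid`, `n_co`.
#' @export
recomb_bins <- function(cos, model, bin_cM = 10) {
  out <- lapply(seq_len(nrow(model$chrom)), function(i) {
    nm <- model$chrom$name[i]
    L <- model$chrom$length_cM[i]
    br <- unique(c(seq(0, L, by = bin_cM), L))
    bp <- cos$breakpoint_cM[cos$chrom == nm]
    cnt <- as.integer(table(cut(bp, br, include.lowest = TRUE, right = FALSE)))
    data.frame(chrom = nm, start = br[-length(br)], end = br[-1L],
               scaled_start = br[-length(br)] / L, scaled_end = br[-1L] / L,
               scaled_mid = (br[-length(br)] + br[-1L]) / 2 / L,
               n_co = cnt, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(bin = seq_len(nrow(res)), res)
  structure(res, class = c("bin_table", "data.frame"))
}

#' Flag high-recombining (distal) bins
#'
#' Flags bins whose scaled chromosome position lies within `distal_pct`
#' percent of either chromosome end — the "high-recombining regions" used
#' for the genetic-load contrast — and reports the fraction of all
#' crossovers those bins capture (in wheat-like data the 10% distal ends
#' carry the large majority of crossovers).
#'
#' @param bins a `bin_table` (or data.frame with `scaled_mid`, `n_co`).
#' @param distal_pct percent of the scaled chromosome near each end
#'   (in (0, 50)).
#' @return `bins` with a logical `high_recomb` column; attribute
#'   `co_fraction_captured`.
#' @export
define_high_recomb_regions <- function(bins, distal_pct = 10) {
  if (distal_pct <= 0 || distal_pct >= 50)
    stop_val("'distal_pct' must be in (0, 50)")
  f <- distal_pct / 100
  bins$high_recomb <- if (all(c("scaled_start", "scaled_end") %in%
                                names(bins))) {
    # a bin is "high" when it overlaps either distal band
    bins$scaled_start < f | bins$scaled_end > 1 - f
  } else {
    bins$scaled_mid < f | bins$scaled_mid > 1 - f
  }
  attr(bins, "co_fraction_captured") <-
    if (sum(bins$n_co) > 0) sum(bins$n_co[bins$high_recomb]) / sum(bins$n_co)
    else NA_real_
  bins
}

#' Simulate a SNP annotation table with load enrichment
#'
#' Distributes SNPs over the recombination bins and flags each as
#' (putatively) deleterious with a class-dependent probability: the odds of
#' deleterious in low-recombination bins are `enrichment_odds` times the
#' odds in high-recombination bins (`enrichment_odds = 1` gives a uniform
#' rate), emulating the accumulation of deleterious variants where
#' recombination — and hence selection efficiency — is low.
#'
#' @param bins a `bin_table` with a `high_recomb` column (see
#'   [define_high_recomb_regions()]).
#' @param enrichment_odds odds ratio theta (> 0) of deleterious in low- vs
#'   high-recombination bins.
#' @param n_snps number of SNPs to place.
#' @param p_high deleterious probability in high-recombination bins
#'   (default 0.06, of the order of genome-wide deleterious-to-total coding
#'   SNP ratios).
#' @param seed integer seed.
#' @return data.frame with `snp`, `bin`, `deleterious` (0/1).
#' @export
simulate_annotation <- function(bins, enrichment_odds = 1, n_snps = 1000L,
                                p_high = 0.06, seed = NULL) {
  if (enrichment_odds <= 0) stop_val("'enrichment_odds' must be > 0")
  if (!"high_recomb" %in% names(bins))
    stop_val("bins lack 'high_recomb'; run define_high_recomb_regions() first")
  if (n_snps == 0L)
    return(data.frame(snp = character(), bin = integer(),
                      deleterious = integer(), stringsAsFactors = FALSE))
  odds_h <- p_high / (1 - p_high)
  p_low <- (enrichment_odds * odds_h) / (1 + enrichment_odds * odds_h)
  run <- function() {
    b <- sample(bins$bin, n_snps, replace = TRUE)
    hi <- bins$high_recomb[match(b, bins$bin)]
    del <- stats::rbinom(n_snps, 1L, ifelse(hi, p_high, p_low))
    data.frame(snp = sprintf("snp%06d", seq_len(n_snps)), bin = b,
               deleterious = del, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Deleterious-load contrast between high- and low-recombining regions
#'
#' Compares the proportion of deleterious among all SNPs in the
#' high-recombining bins against the rest of the genome with a one-sided
#' Fisher exact test of the hypothesis that high-recombining regions carry
#' proportionally fewer deleterious alleles (reduced genetic load where
#' selection is efficient).
#'
#' @param annotation data.frame with `bin`, `deleterious` (0/1).
#' @param bins a `bin_table` with `high_recomb`.
#' @return list with the 2x2 `table` (rows high/low, cols del/non-del),
#'   `prop_high`, `prop_low`, `odds_ratio`, `p` (one-sided).
#' @export
load_contrast <- function(annotation, bins) {
  hi <- bins$high_recomb[match(annotation$bin, bins$bin)]
  if (anyNA(hi)) stop_val("annotation refers to unknown bin(s)")
  d <- annotation$deleterious
  tab <- matrix(c(sum(d[hi] == 1L), sum(d[hi] == 0L),
                  sum(d[!hi] == 1L), sum(d[!hi] == 0L)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("high", "low"), c("del", "nondel")))
  if (any(rowSums(tab) == 0L)) stop_val("one region class holds no SNPs")
  ft <- stats::fisher.test(tab, alternative = "less")
  list(table = tab,
       prop_high = tab[1L, 1L] / sum(tab[1L, ]),
       prop_low = tab[2L, 1L] / sum(tab[2L, ]),
       odds_ratio = unname(ft$estimate),
       p = ft$p.value)
}

#' Mean pairwise LD (r-squared) per recombination bin
#'
#' Squared Pearson correlation of allele indicators across the founder
#' lines, averaged over all marker pairs inside each bin. Monomorphic
#' markers are excluded; bins with fewer than two usable markers are
#' dropped (with a message).
#'
#' @param panel a `founder_panel` (uses all lines' haplotypes).
#' @param bins a `bin_table`.
#' @return `bins` with columns `r2` and `n_markers_ld` (dropped bins have
#'   `NA` r2).
#' @export
ld_per_bin <- function(panel, bins) {
  mk <- panel$model$markers
  r2 <- rep(NA_real_, nrow(bins))
  nm_ld <- integer(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    last <- bins$end[i] >= panel$model$chrom$length_cM[
      chrom_row(panel$model, bins$chrom[i])]
    sel <- which(mk$chrom == bins$chrom[i] & mk$cM >= bins$start[i] &
                   (mk$cM < bins$end[i] | (last & mk$cM <= bins$end[i])))
    if (!length(sel)) next
    G <- panel$geno[, sel, drop = FALSE]
    poly <- apply(G, 2L, function(x) stats::sd(x) > 0)
    G <- G[, poly, drop = FALSE]
    nm_ld[i] <- ncol(G)
    if (ncol(G) < 2L) next
    cc <- stats::cor(G)^2
    r2[i] <- mean(cc[upper.tri(cc)])
  }
  dropped <- sum(nm_ld < 2L)
  if (dropped) message("ld_per_bin: ", dropped,
                       " bin(s) with < 2 polymorphic markers dropped")
  bins$r2 <- r2
  bins$n_markers_ld <- nm_ld
  bins
}

#' Correlation of per-bin LD with meiotic recombination
#'
#' Pearson correlation (with its t-distribution p-value) between the mean
#' pairwise founder r-squared of each bin and the meiotic crossover count
#' of the same bin. Historic recombination erodes LD, so bins recombining
#' often in the families are expected to show low founder LD — a negative
#' correlation.
#'
#' @param bins a `bin_table` with `r2` and `n_co` columns.
#' @return list with `r`, `p`, `n_bins`.
#' @export
ld_recomb_correlation <- function(bins) {
  ok <- !is.na(bins$r2)
  if (sum(ok) < 3L) stop_val("fewer than 3 bins with defined r2")
  if (stats::sd(bins$r2[ok]) == 0 || stats::sd(bins$n_co[ok]) == 0)
    stop_val("zero variance in r2 or crossover counts")
  ct <- stats::cor.test(bins$r2[ok], bins$n_co[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = sum(ok))
}

#' Crossover counts in IBD versus non-IBD regions
#'
#' Splits a set of genomic regions by whether they overlap (half-open
#' sense) an identity-by-descent tract with the common parent, and
#' compares the per-region crossover counts of the two classes with a
#' Mann-Whitney U test. `U` counts the pairs (IBD region, non-IBD region)
#' in which the non-IBD count exceeds the IBD count (ties count one half),
#' so small U means more crossovers in IBD regions; the default
#' alternative `"greater"` tests for more crossovers in IBD regions.
#'
#' @param cos a `crossover_set`.
#' @param regions data.frame `chrom`, `start`, `end` (e.g. bins of
#'   [recomb_bins()]).
#' @param ibd data.frame `chrom`, `start_cM`, `end_cM` of IBD tracts (e.g.
#'   from a `founder_panel`).
#' @param alternative `"greater"` (IBD regions have more crossovers),
#'   `"less"`, or `"two.sided"`.
#' @return list with `U`, `p`, `n_ibd`, `n_non`, `mean_ibd`, `mean_non`,
#'   `counts_ibd`, `counts_non`.
#' @export
ibd_co_contrast <- function(cos, regions, ibd,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  is_ibd <- vapply(seq_len(nrow(regions)), function(i) {
    any(ibd$chrom == regions$chrom[i] & ibd$start_cM < regions$end[i] &
          regions$start[i] < ibd$end_cM)
  }, logical(1))
  cnt <- vapply(seq_len(nrow(regions)), function(i) {
    sum(cos$chrom == regions$chrom[i] & cos$breakpoint_cM >= regions$start[i] &
          cos$breakpoint_cM < regions$end[i])
  }, numeric(1))
  a <- cnt[is_ibd]; b <- cnt[!is_ibd]
  if (!length(a) || !length(b)) stop_val("one of the region classes is empty")
  if (stats::sd(c(a, b)) == 0) {
    # fully tied: no evidence either way
    p <- 1
    W <- length(a) * length(b) / 2
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
    W <- unname(wt$statistic)
  }
  # wilcox.test's statistic counts pairs where the IBD count exceeds the
  # non-IBD count; report the complementary orientation (see docs)
  U <- length(a) * length(b) - W
  list(U = U, p = p, n_ibd = length(a), n_non = length(b),
       mean_ibd = mean(a), mean_non = mean(b), counts_ibd = a,
       counts_non = b)
}
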