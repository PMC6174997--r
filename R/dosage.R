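# Expected-dosage model for RIL genotypes ------------------------------------
#
# A selfed-RIL genome is, marker to marker, a two-state Markov chain on the
# parental phases with transition probability equal to the RIL-expanded
# recombination fraction R = 2r / (1 + 2r), where r is the meiotic Haldane
# recombination fraction r = (1 - exp(-d / 50)) / 2 at map distance d cM.
# The expected alternate-parent dosage at any map position, conditional on
# the nearest flanking observed calls, follows from that chain; this is the
# Haley-Knott regression input used throughout the scans.

haldane_r <- function(d_cM) 0.5 * (1 - exp(-pmax(d_cM, 0) / 50))

ril_R <- function(d_cM) {
  r <- haldane_r(d_cM)
  2 * r / (1 + 2 * r)
}

#' Expected alternate-allele dosage at a test position
#'
#' Conditional probability that a RIL carries the alternate (non-common)
#' parent's phase at a map position, given the observed calls at the
#' nearest informative flanking markers. At a typed marker the dosage
#' equals the observed call; with both flanks missing it falls back to the
#' 1/2 prior of an F-infinity selfed RIL.
#'
#' @param left_cM,right_cM distances (cM, >= 0) to the flanking informative
#'   markers; use `NA` for an absent flank.
#' @param left_call,right_call observed calls at the flanks, coded 0 (common
#'   parent) or 2 (alternate); `NA` for an absent flank.
#' @return expected alternate dosage in \[0, 1\] (vectorized).
#' @export
ril_genotype_prob <- function(left_cM, left_call, right_cM, right_call) {
  n <- max(length(left_cM), length(right_cM))
  a <- rep_len(ifelse(is.na(left_call), NA_real_, left_call / 2), n)
  b <- rep_len(ifelse(is.na(right_call), NA_real_, right_call / 2), n)
  Rl <- rep_len(ril_R(left_cM), n)
  Rr <- rep_len(ril_R(right_cM), n)
  trans <- function(from, R, to) ifelse(from == to, 1 - R, R)
  out <- rep(0.5, n)
  both <- !is.na(a) & !is.na(b)
  num <- trans(a[both], Rl[both], 1) * trans(1, Rr[both], b[both])
  den <- num + trans(a[both], Rl[both], 0) * trans(0, Rr[both], b[both])
  out[both] <- num / den
  lo <- !is.na(a) & is.na(b)
  out[lo] <- ifelse(a[lo] == 1, 1 - Rl[lo], Rl[lo])
  ro <- is.na(a) & !is.na(b)
  out[ro] <- ifelse(b[ro] == 1, 1 - Rr[ro], Rr[ro])
  out
}

# Expected alternate dosage for every RIL at arbitrary map positions.
# `positions` is a data.frame(chrom, cM); returns an n_rils x n_pos matrix.
# Heterozygous calls are treated as missing (phase-uninformative).
dosage_grid <- function(genos, positions) {
  n <- length(genos$rils)
  npos <- nrow(positions)
  D <- matrix(0.5, nrow = n, ncol = npos)
  g <- genos$geno
  g[g == 1L] <- NA_integer_
  for (nm in unique(positions$chrom)) {
    sel <- which(genos$markers$chrom == nm)
    o <- order(genos$markers$cM[sel])
    sel <- sel[o]
    pm <- genos$markers$cM[sel]
    pj <- which(positions$chrom == nm)
    pt <- positions$cM[pj]
    for (r in seq_len(n)) {
      x <- g[sel, r]
      obs <- which(!is.na(x))
      if (!length(obs)) next
      po <- pm[obs]
      vo <- x[obs]
      li <- findInterval(pt, po)
      ri <- li + 1L
      lc <- ifelse(li >= 1L, vo[pmax(li, 1L)], NA_integer_)
      ld <- ifelse(li >= 1L, pt - po[pmax(li, 1L)], NA_real_)
      rc <- ifelse(ri <= length(obs), vo[pmin(ri, length(obs))], NA_integer_)
      rd <- ifelse(ri <= length(obs), po[pmin(ri, length(obs))] - pt, NA_real_)
      D[r, pj] <- ril_genotype_prob(ld, lc, rd, rc)
    }
  }
  D
}

# Regular scan grid over the mapped extent of each chromosome.
scan_grid <- function(markers, step_cM = 1) {
  out <- lapply(unique(markers$chrom), function(nm) {
    p <- markers$cM[markers$chrom == nm]
    data.frame(chrom = nm,
               cM = unique(c(seq(min(p), max(p), by = step_cM), max(p))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
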