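#' Collapse redundant markers into bins with delegate markers
#'
#' In dense RIL genotype data many markers carry identical segregation
#' information within a family. Two markers belong to the same bin when
#' their calls agree at every RIL where both are non-missing and they share
#' at least `min_overlap` jointly non-missing RILs, chained along the map.
#' The delegate of each bin is the member with the fewest missing calls
#' (ties broken by map order), mirroring common genetic-map pre-processing
#' where one representative marker per recombination bin is used for map
#' construction.
#'
#' @param genos a `ril_genotypes` object.
#' @param min_overlap minimum number of jointly non-missing RILs for two
#'   markers to be declared redundant (default 15).
#' Bins are map-contiguous: only chains of consecutive markers merge, so a
#' recombination bin is an interval of the map and crossover calls on the
#' delegate set are identical to calls on the full matrix for noise-free
#' data (chance pattern matches between distant markers never fuse across
#' an observed crossover).
#'
#' @return data.frame with one row per marker: `marker`, `chrom`, `cM`,
#'   `bin` (integer id), `delegate` (logical), `n_missing`.
#' @export
collapse_redundant_markers <- function(genos, min_overlap = 15L) {
  if (min_overlap < 1L) stop_val("'min_overlap' must be >= 1")
  g <- genos$geno
  p <- nrow(g)
  bin <- integer(p)
  nxt <- 0L
  for (nm in unique(genos$markers$chrom)) {
    idx <- which(genos$markers$chrom == nm)
    idx <- idx[order(genos$markers$cM[idx])]
    nxt <- nxt + 1L
    bin[idx[1L]] <- nxt
    if (length(idx) > 1L) for (a in 2L:length(idx)) {
      ia <- idx[a]
      # compatible with every member of the current (open) bin
      members <- idx[seq_len(a - 1L)][bin[idx[seq_len(a - 1L)]] == nxt]
      ok <- any(vapply(members, function(ib) {
        both <- !is.na(g[ia, ]) & !is.na(g[ib, ])
        sum(both) >= min_overlap && all(g[ia, both] == g[ib, both])
      }, logical(1)))
      ok <- ok && all(vapply(members, function(ib) {
        both <- !is.na(g[ia, ]) & !is.na(g[ib, ])
        all(g[ia, both] == g[ib, both])
      }, logical(1)))
      if (!ok) nxt <- nxt + 1L
      bin[ia] <- nxt
    }
  }
  bin <- match(bin, unique(bin))
  n_missing <- rowSums(is.na(g))
  delegate <- logical(p)
  for (b in unique(bin)) {
    members <- which(bin == b)
    delegate[members[which.min(n_missing[members])]] <- TRUE
  }
  data.frame(marker = genos$markers$marker, chrom = genos$markers$chrom,
             cM = genos$markers$cM, bin = bin, delegate = delegate,
             n_missing = n_missing, stringsAsFactors = FALSE)
}

#' Restrict genotypes to delegate markers
#'
#' @param genos a `ril_genotypes` object.
#' @param bins output of [collapse_redundant_markers()].
#' @return a `ril_genotypes` object containing only delegate markers.
#' @export
delegate_genotypes <- function(genos, bins) {
  keep <- which(bins$delegate)
  new_ril_genotypes(genos$family, genos$common, genos$founder,
                    genos$markers[keep, , drop = FALSE],
                    genos$geno[keep, , drop = FALSE], genos$rils)
}
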