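# Haplotype mosaics -----------------------------------------------------------
#
# Within one NAM family every RIL chromosome is a mosaic of two ancestries:
# the common parent (1) and the alternate founder (2). A haplotype is stored
# as a canonical alternating step function: `start` is the ancestry of the
# leftmost segment and `br` the sorted breakpoints, each of which flips the
# ancestry. Crossover positions are drawn in cM so all closed-form Poisson /
# Haldane expectations apply exactly.

new_mosaic <- function(start) list(start = as.integer(start), br = numeric())

mosaic_at <- function(mo, x) {
  k <- findInterval(x, mo$br)
  ((mo$start - 1L + k) %% 2L) + 1L
}

# Recombine two parental haplotypes at crossover points `co` (cM, within
# (0, L)). The gamete starts on a random chromatid and switches at each CO.
meiosis_gamete <- function(h1, h2, co, L) {
  first <- if (stats::runif(1) < 0.5) 1L else 2L
  if (!length(co)) return(if (first == 1L) h1 else h2)
  co <- sort(co)
  pts <- sort(c(h1$br, h2$br, co))
  mids <- (c(0, pts) + c(pts, L)) / 2
  active <- ((first - 1L + findInterval(mids, co)) %% 2L) + 1L
  anc <- ifelse(active == 1L, mosaic_at(h1, mids), mosaic_at(h2, mids))
  n <- length(anc)
  flip <- anc[-1L] != anc[-n]
  list(start = as.integer(anc[1L]), br = pts[flip])
}

# Draw crossover positions on one chromosome from a piecewise-constant
# intensity given by parallel vectors (start, end, mult); the expected CO
# count in a region is mult * (end - start) / 100 (1 CO per Morgan at
# mult = 1, i.e. Haldane's no-interference model).
draw_crossovers <- function(start, end, mult) {
  len <- end - start
  n <- stats::rpois(length(len), pmax(mult, 0) * pmax(len, 0) / 100)
  tot <- sum(n)
  if (!tot) return(numeric())
  sort(rep.int(start, n) + stats::runif(tot) * rep.int(len, n))
}

# Diploid genotype (0 = hom common, 1 = het, 2 = hom alternate) of a
# haplotype pair at positions x.
pair_genotype_at <- function(h1, h2, x) {
  (mosaic_at(h1, x) == 2L) + (mosaic_at(h2, x) == 2L)
}

# True phase junctions of the final (near-inbred) mosaic: positions where the
# homozygous genotype switches parental phase, scored after dropping residual
# heterozygous tracts (mirroring how crossovers are observable in RIL
# genotype data, where het calls are treated as missing).
pair_truth_junctions <- function(h1, h2, L) {
  pts <- sort(unique(c(h1$br, h2$br)))
  bounds_lo <- c(0, pts)
  bounds_hi <- c(pts, L)
  mids <- (bounds_lo + bounds_hi) / 2
  g <- pair_genotype_at(h1, h2, mids)
  keep <- which(g != 1L)
  if (length(keep) < 2L) return(numeric())
  gk <- g[keep]
  tr <- which(gk[-1L] != gk[-length(gk)])
  if (!length(tr)) return(numeric())
  (bounds_hi[keep[tr]] + bounds_lo[keep[tr + 1L]]) / 2
}

#' Simulate a single meiosis
#'
#' Draws crossovers along each chromosome of a diploid parent as a homogeneous
#' Poisson process on genetic distance (Haldane model: no interference, no
#' obligate crossover; expected count = multiplier x length / 100) and
#' returns one gamete together with the true crossover positions.
#'
#' @param parent a plant as produced by [f1_plant()] or a previous selfing
#'   step: a named list (one element per chromosome) of haplotype pairs
#'   `list(h1, h2)`.
#' @param model a [build_genome_model()] object.
#' @param intensity_multiplier a single positive number applied genome-wide,
#'   or a named list (by chromosome) of data.frames `(start, end, mult)`
#'   giving a piecewise-constant intensity.
#' @param seed optional integer seed.
#' @return list with `gamete` (named list of haplotype mosaics) and
#'   `crossovers` (data.frame `chrom`, `cM` of the realized CO positions).
#' @export
simulate_meiosis <- function(parent, model, intensity_multiplier = 1,
                             seed = NULL) {
  run <- function() {
    gam <- vector("list", nrow(model$chrom))
    names(gam) <- model$chrom$name
    cos <- list()
    for (i in seq_len(nrow(model$chrom))) {
      nm <- model$chrom$name[i]
      L <- model$chrom$length_cM[i]
      reg <- if (is.list(intensity_multiplier) &&
                 !is.data.frame(intensity_multiplier)) {
        intensity_multiplier[[nm]]
      } else if (is.data.frame(intensity_multiplier)) {
        intensity_multiplier
      } else {
        data.frame(start = 0, end = L, mult = as.numeric(intensity_multiplier))
      }
      if (any(reg$mult <= 0)) stop_val("intensity multiplier must be > 0")
      co <- draw_crossovers(reg$start, reg$end, reg$mult)
      gam[[i]] <- meiosis_gamete(parent[[nm]]$h1, parent[[nm]]$h2, co, L)
      if (length(co)) cos[[length(cos) + 1L]] <-
          data.frame(chrom = nm, cM = co, stringsAsFactors = FALSE)
    }
    list(gamete = gam,
         crossovers = if (length(cos)) do.call(rbind, cos)
         else data.frame(chrom = character(), cM = numeric()))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' F1 plant of a common-parent x founder cross
#'
#' One haplotype of pure common-parent ancestry and one of pure founder
#' ancestry on every chromosome: heterozygous at every founder-divergent
#' locus, as both parents are fully inbred.
#'
#' @inheritParams simulate_meiosis
#' @return a plant (named list of `list(h1, h2)` per chromosome).
#' @export
f1_plant <- function(model) {
  pl <- lapply(seq_len(nrow(model$chrom)),
               function(i) list(h1 = new_mosaic(1L), h2 = new_mosaic(2L)))
  names(pl) <- model$chrom$name
  pl
}
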