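#' Build per-RIL crossover phenotypes
#'
#' Summarizes a crossover set into the traits used for QTL mapping: the
#' total crossover count (TCO), per-chromosome counts, and the counts of
#' pericentromeric (pCO) and distal (dCO) crossovers assigned by breakpoint
#' position against an [arm_partition()] (a breakpoint exactly on the
#' distal/pericentromeric boundary counts as pericentromeric). RILs whose
#' genotype data exceed the missingness threshold are flagged `excluded`
#' (their counts are still reported) so QTL mapping can drop them.
#'
#' @param cos a `crossover_set`.
#' @param partition an `arm_partition`.
#' @param genos optional `ril_genotypes` used to compute missingness flags;
#'   without it no RIL is flagged.
#' @param missing_threshold maximum tolerated fraction of missing genotype
#'   calls per RIL (default 0.10).
#' @return An object of class `phenotype_table`: data.frame with `ril`,
#'   `tco`, `pco`, `dco`, one `n_<chrom>` column per chromosome, and
#'   `excluded`. Always `tco = pco + dco = sum over chromosomes`.
#' @export
summarize_phenotypes <- function(cos, partition, genos = NULL,
                                 missing_threshold = 0.10) {
  rils <- attr(cos, "rils")
  chroms <- attr(cos, "chroms")
  if (nrow(cos)) {
    i <- match(cos$chrom, partition$chrom)
    if (anyNA(i)) stop_val("partition does not cover chromosome(s): ",
                           paste(unique(cos$chrom[is.na(i)]), collapse = ", "))
    if (any(cos$breakpoint_cM < 0 | cos$breakpoint_cM > partition$length_cM[i]))
      stop_val("breakpoint outside its chromosome; inconsistent inputs")
  }
  rf <- factor(cos$ril, levels = rils)
  tco <- as.integer(table(rf))
  distal <- if (nrow(cos)) is_distal(partition, cos$chrom, cos$breakpoint_cM)
            else logical()
  dco <- as.integer(table(rf[distal]))
  pco <- as.integer(table(rf[!distal]))
  ph <- data.frame(ril = rils, tco = tco, pco = pco, dco = dco,
                   stringsAsFactors = FALSE)
  for (nm in chroms)
    ph[[paste0("n_", nm)]] <- as.integer(table(rf[cos$chrom == nm]))
  ph$excluded <- FALSE
  if (!is.null(genos)) {
    miss <- colSums(is.na(genos$geno)) / nrow(genos$geno)
    ph$excluded <- miss[match(rils, genos$rils)] > missing_threshold
  }
  structure(ph, class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "Phenotypes for %d RILs (%d excluded): mean TCO %.2f (pCO %.2f, dCO %.2f)\n",
    nrow(x), sum(x$excluded), mean(x$tco), mean(x$pco), mean(x$dco)))
  invisible(x)
}

#' Recompute phenotypes after excluding chromosomes or arm regions
#'
#' Used by the cis/trans classification: the contribution of the chromosome
#' (for TCO) or of the pericentromeric/distal portion of a chromosome (for
#' pCO/dCO) harboring a QTL is removed from every RIL's phenotype before
#' rescanning.
#'
#' @param cos a `crossover_set`.
#' @param partition an `arm_partition`.
#' @param exclude_chrom character vector of chromosomes whose crossovers are
#'   dropped entirely.
#' @param exclude_region optional data.frame (`chrom`, `region`) with region
#'   `"pericentromeric"` or `"distal"`: drops only that arm-region's
#'   crossovers of that chromosome.
#' @inheritParams summarize_phenotypes
#' @return a `phenotype_table` on the reduced crossover set.
#' @export
exclude_regions <- function(cos, partition, exclude_chrom = character(),
                            exclude_region = NULL, genos = NULL,
                            missing_threshold = 0.10) {
  chroms <- attr(cos, "chroms")
  unknown <- setdiff(exclude_chrom, chroms)
  if (length(unknown)) stop_val("unknown chromosome(s): ",
                                paste(unknown, collapse = ", "))
  drop <- cos$chrom %in% exclude_chrom
  if (!is.null(exclude_region) && nrow(exclude_region) && nrow(cos)) {
    if (any(!exclude_region$chrom %in% chroms))
      stop_val("unknown chromosome in 'exclude_region'")
    distal <- is_distal(partition, cos$chrom, cos$breakpoint_cM)
    for (j in seq_len(nrow(exclude_region))) {
      want_distal <- identical(exclude_region$region[j], "distal")
      drop <- drop | (cos$chrom == exclude_region$chrom[j] &
                        distal == want_distal)
    }
  }
  kept <- cos[!drop, , drop = FALSE]
  attr(kept, "rils") <- attr(cos, "rils")
  attr(kept, "chroms") <- chroms
  class(kept) <- class(cos)
  summarize_phenotypes(kept, partition, genos, missing_threshold)
}

#' Distribution of crossover breakpoints on the scaled chromosome
#'
#' Expresses every breakpoint on a 0-1 scale along its chromosome and
#' histograms them, pooling chromosomes (optionally per sub-genome). Also
#' reports the fraction of crossovers falling in the distal arm thirds.
#'
#' @param cos a `crossover_set`.
#' @param model a `genome_model` (provides chromosome lengths).
#' @param n_bins number of equal-width bins on \[0, 1\].
#' @param partition optional `arm_partition` for the distal fraction
#'   (default: computed from `model` with distal fraction 1/3).
#' @return list with `counts` (length `n_bins`, sums to the total CO count),
#'   `breaks`, `scaled` (per-CO scaled positions), and `fraction_distal`.
#' @export
breakpoint_distribution <- function(cos, model, n_bins = 20L,
                                    partition = NULL) {
  partition <- partition %||% arm_partition(model)
  if (!nrow(cos)) {
    return(list(counts = rep(0L, n_bins),
                breaks = seq(0, 1, length.out = n_bins + 1L),
                scaled = numeric(), fraction_distal = NA_real_))
  }
  L <- model$chrom$length_cM[chrom_row(model, cos$chrom)]
  scaled <- pmin(cos$breakpoint_cM / L, 1)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(scaled, breaks, include.lowest = TRUE)))
  frac <- mean(is_distal(partition, cos$chrom, cos$breakpoint_cM))
  list(counts = counts, breaks = breaks, scaled = scaled,
       fraction_distal = frac)
}

#' Per-chromosome and per-genome map summaries
#'
#' Map length (last minus first marker position), marker counts, and
#' cM-per-Mb ratios when physical positions are available, aggregated per
#' chromosome and per sub-genome class.
#'
#' @param map data.frame with `marker`, `chrom`, `cM` and optionally `Mb`.
#' @param genome_of optional named vector mapping chromosome to sub-genome
#'   label; defaults to a single genome "A".
#' @return list with `chromosomes` and `genomes` data.frames (`length_cM`,
#'   `n_markers`, `length_Mb`, `cM_per_Mb`; the genome table sums lengths
#'   and reports length-weighted cM/Mb).
#' @export
map_summary <- function(map, genome_of = NULL) {
  chroms <- unique(map$chrom)
  has_mb <- "Mb" %in% names(map) && !all(is.na(map$Mb))
  per <- do.call(rbind, lapply(chroms, function(nm) {
    m <- map[map$chrom == nm, ]
    len <- max(m$cM) - min(m$cM)
    mb <- if (has_mb && !all(is.na(m$Mb))) max(m$Mb, na.rm = TRUE) -
      min(m$Mb, na.rm = TRUE) else NA_real_
    data.frame(chrom = nm, length_cM = len, n_markers = nrow(m),
               length_Mb = mb,
               cM_per_Mb = if (!is.na(mb) && mb > 0) len / mb else NA_real_,
               stringsAsFactors = FALSE)
  }))
  gm <- if (is.null(genome_of)) rep("A", nrow(per)) else
    unname(genome_of[per$chrom])
  per$genome <- gm
  gen <- do.call(rbind, lapply(unique(gm), function(g) {
    p <- per[per$genome == g, ]
    data.frame(genome = g, length_cM = sum(p$length_cM),
               n_markers = sum(p$n_markers),
               length_Mb = if (all(is.na(p$length_Mb))) NA_real_
               else sum(p$length_Mb, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  gen$cM_per_Mb <- ifelse(is.na(gen$length_Mb), NA_real_,
                          gen$length_cM / gen$length_Mb)
  list(chromosomes = per, genomes = gen)
}

#' Marker-thinning experiment: map length re-estimated at reduced density
#'
#' Randomly subsamples markers to a target count and re-estimates the
#' genetic map length from the RIL genotypes: the adjacent-marker
#' recombinant fraction R observed among RILs is de-expanded to the meiotic
#' recombination fraction r = R / (2 - 2R) (inverse of the RIL expansion
#' R = 2r / (1 + 2r)) and converted to Haldane map distance
#' d = -50 ln(1 - 2r). Thinning loses double crossovers, so mean estimated
#' length decreases with density — the mechanism proposed for the shorter
#' D-genome maps of sparsely genotyped wheat families.
#'
#' @param genos a `ril_genotypes` object.
#' @param target_marker_count markers retained per replicate (must not
#'   exceed the available markers; at least 2 per chromosome are kept).
#' @param n_reps number of random subsamples.
#' @param seed integer seed.
#' @return list with `lengths_cM` (per-replicate total estimated length),
#'   `mean_cM`, `sd_cM`, and `full_cM` (estimate at full density).
#' @export
thinning_experiment <- function(genos, target_marker_count, n_reps = 15L,
                                seed = NULL) {
  p <- nrow(genos$geno)
  if (target_marker_count > p)
    stop_val("'target_marker_count' exceeds available markers (", p, ")")
  est_len <- function(idx) {
    tot <- 0
    for (nm in unique(genos$markers$chrom)) {
      sel <- idx[genos$markers$chrom[idx] == nm]
      sel <- sel[order(genos$markers$cM[sel])]
      if (length(sel) < 2L) next
      g <- genos$geno[sel, , drop = FALSE]
      g[g == 1L] <- NA_integer_
      for (j in seq_len(length(sel) - 1L)) {
        a <- g[j, ]; b <- g[j + 1L, ]
        ok <- !is.na(a) & !is.na(b)
        if (!sum(ok)) next
        R <- mean(a[ok] != b[ok])
        R <- min(R, 0.95)          # guard: R -> 1 is off-scale
        r <- R / (2 - 2 * R)
        r <- min(r, 0.4999)
        tot <- tot + (-50 * log(1 - 2 * r))
      }
    }
    tot
  }
  run <- function() {
    lens <- vapply(seq_len(n_reps), function(i)
      est_len(sort(sample.int(p, target_marker_count))), numeric(1))
    list(lengths_cM = lens, mean_cM = mean(lens), sd_cM = stats::sd(lens),
         full_cM = est_len(seq_len(p)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
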