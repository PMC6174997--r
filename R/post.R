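#' Merge QTL support intervals into unique non-overlapping regions
#'
#' Union-merges overlapping intervals (half-open, `[start, end)`: touching
#' intervals do not overlap) on each chromosome and counts the distinct
#' source families per merged region. Idempotent and order-invariant.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `family` (defaults to one pseudo-family per row).
#' @return data.frame of class `region_set`: `chrom`, `start`, `end`,
#'   `multiplicity` (distinct source families), `n_intervals`.
#' @export
merge_regions <- function(intervals) {
  if (!nrow(intervals))
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), multiplicity = integer(),
                                n_intervals = integer(),
                                stringsAsFactors = FALSE),
                     class = c("region_set", "data.frame")))
  if (any(intervals$start > intervals$end))
    stop_val("malformed interval: start > end")
  fam <- if ("family" %in% names(intervals)) as.character(intervals$family)
         else as.character(seq_len(nrow(intervals)))
  out <- list()
  for (nm in sort(unique(intervals$chrom))) {
    d <- intervals[intervals$chrom == nm, , drop = FALSE]
    f <- fam[intervals$chrom == nm]
    o <- order(d$start, d$end)
    d <- d[o, , drop = FALSE]; f <- f[o]
    cs <- d$start[1L]; ce <- d$end[1L]; members <- f[1L]; cnt <- 1L
    flush <- function() data.frame(chrom = nm, start = cs, end = ce,
                                   multiplicity = length(unique(members)),
                                   n_intervals = cnt,
                                   stringsAsFactors = FALSE)
    if (nrow(d) > 1L) for (i in 2L:nrow(d)) {
      if (d$start[i] < ce) {          # half-open: touching does not merge
        ce <- max(ce, d$end[i])
        members <- c(members, f[i]); cnt <- cnt + 1L
      } else {
        out[[length(out) + 1L]] <- flush()
        cs <- d$start[i]; ce <- d$end[i]; members <- f[i]; cnt <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("region_set", "data.frame"))
}

#' Directional overlap between two region sets
#'
#' A region of set A "overlaps" set B when it intersects (half-open sense)
#' any region of B. Percentages are rounded to integers, matching how such
#' overlaps are conventionally reported.
#'
#' @param a,b region sets (data.frames with `chrom`, `start`, `end`).
#' @return list with `n_a`, `n_b`, `a_in_b`, `b_in_a`, `pct_a_in_b`,
#'   `pct_b_in_a`.
#' @export
overlap_summary <- function(a, b) {
  hits <- function(x, y) {
    if (!nrow(x)) return(0L)
    sum(vapply(seq_len(nrow(x)), function(i) {
      any(y$chrom == x$chrom[i] & y$start < x$end[i] & x$start[i] < y$end)
    }, logical(1)))
  }
  ab <- hits(a, b); ba <- hits(b, a)
  list(n_a = nrow(a), n_b = nrow(b), a_in_b = ab, b_in_a = ba,
       pct_a_in_b = if (nrow(a)) round(100 * ab / nrow(a)) else NA_real_,
       pct_b_in_a = if (nrow(b)) round(100 * ba / nrow(b)) else NA_real_)
}

#' Classify a QTL as cis- or trans-acting
#'
#' Recomputes the trait after removing the crossover contribution of the
#' chromosome harboring the QTL (for TCO; for pCO/dCO only the respective
#' arm-region of that chromosome is removed), repeats the full mapping
#' round — cofactor reselection, scan, fresh 5% permutation threshold —
#' and calls the QTL trans-acting if a significant peak recurs at the
#' original locus (its new support interval intersecting the original
#' one), cis-acting otherwise. A trans QTL affects recombination
#' genome-wide, so its signal survives the removal of its own chromosome's
#' phenotype contribution; a cis effect (e.g. a local map-length or
#' divergence polymorphism) does not.
#'
#' @param qtl one row of a `qtl_table`.
#' @param genos the family's `ril_genotypes`.
#' @param cos the family's `crossover_set`.
#' @param partition an `arm_partition`.
#' @param trait `"tco"`, `"pco"` or `"dco"`.
#' @param missing_threshold RIL exclusion threshold for the recomputed
#'   phenotype.
#' @param n_perm,alpha re-permutation settings (alpha fixed at 5% mirrors
#'   the reference procedure).
#' @param seed integer seed.
#' @param ... passed to [scan_family()].
#' @return list of class `cis_trans_call`: `qtl`, `classification`
#'   (`"cis"`/`"trans"`), `redetected`, `rescan` (the `family_scan`).
#' @export
classify_cis_trans <- function(qtl, genos, cos, partition, trait = "tco",
                               missing_threshold = 0.10, n_perm = 200L,
                               alpha = 0.05, seed = NULL, ...) {
  if (!qtl$chrom %in% attr(cos, "chroms"))
    stop_val("QTL chromosome absent from crossover set: ", qtl$chrom)
  ph <- if (trait == "tco") {
    exclude_regions(cos, partition, exclude_chrom = qtl$chrom,
                    genos = genos, missing_threshold = missing_threshold)
  } else {
    region <- if (trait == "pco") "pericentromeric" else "distal"
    exclude_regions(cos, partition,
                    exclude_region = data.frame(chrom = qtl$chrom,
                                                region = region,
                                                stringsAsFactors = FALSE),
                    genos = genos, missing_threshold = missing_threshold)
  }
  y <- ifelse(ph$excluded, NA_real_, ph[[trait]])
  rescan <- scan_family(y, genos, trait = paste0(trait, "_excl"),
                        n_perm = n_perm, alpha = alpha, seed = seed, ...)
  hit <- rescan$qtl[rescan$qtl$chrom == qtl$chrom &
                      rescan$qtl$ci_lo <= qtl$ci_hi &
                      rescan$qtl$ci_hi >= qtl$ci_lo, , drop = FALSE]
  redet <- nrow(hit) > 0L
  structure(list(qtl = qtl, classification = if (redet) "trans" else "cis",
                 redetected = redet, rescan = rescan),
            class = "cis_trans_call")
}

#' @export
print.cis_trans_call <- function(x, ...) {
  cat(sprintf("QTL %s @ %.1f cM (%s): %s-acting (re-detected: %s)\n",
              x$qtl$chrom, x$qtl$peak_cM, x$qtl$trait, x$classification,
              x$redetected))
  invisible(x)
}

#' Additivity of stacked recombination-favoring alleles
#'
#' Counts, per RIL, the recombination-increasing alleles at the peak
#' markers of a family's QTL (orientation taken from each QTL's effect
#' sign: the common parent's allele is favorable when the effect is
#' positive) and regresses the phenotype on that count. A significant
#' positive slope declares additivity; the per-class means expose the
#' allele-dosage response.
#'
#' @param qtl a `qtl_table` with at least one row (>= 2 rows for the
#'   published use; one QTL reduces to a two-group comparison).
#' @param genos the family's `ril_genotypes`.
#' @param y phenotype per RIL (`NA` = excluded).
#' @return list of class `additivity_fit`: `slope`, `r2`, `p`,
#'   `class_means` (data.frame `n_favorable`, `n`, `mean`), `max_diff`
#'   (difference between extreme class means), `n`.
#' @export
additivity_analysis <- function(qtl, genos, y) {
  if (!nrow(qtl)) stop_val("no QTL supplied")
  counts <- rep(0L, length(genos$rils))
  keep <- rep(TRUE, length(genos$rils))
  for (i in seq_len(nrow(qtl))) {
    sel <- which(genos$markers$chrom == qtl$chrom[i])
    if (!length(sel)) stop_val("no markers on QTL chromosome ", qtl$chrom[i])
    pk <- sel[which.min(abs(genos$markers$cM[sel] - qtl$peak_cM[i]))]
    g <- genos$geno[pk, ]
    keep <- keep & !is.na(g) & g != 1L
    fav_is_common <- qtl$effect[i] >= 0
    counts <- counts + ifelse(is.na(g), 0L,
                              if (fav_is_common) as.integer(g == 0L)
                              else as.integer(g == 2L))
  }
  keep <- keep & !is.na(y)
  cc <- counts[keep]; yy <- y[keep]
  if (length(unique(cc)) < 2L)
    stop_val("all usable RILs fall in one allele-count class")
  fit <- stats::lm(yy ~ cc)
  sm <- summary(fit)
  cm <- stats::aggregate(yy, list(n_favorable = cc), mean)
  names(cm)[2L] <- "mean"
  cm$n <- as.integer(table(factor(cc, levels = cm$n_favorable)))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2L, 4L],
                 class_means = cm[, c("n_favorable", "n", "mean")],
                 max_diff = max(cm$mean) - min(cm$mean),
                 n = length(yy)),
            class = "additivity_fit")
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat(sprintf(
    "Additivity: slope %.2f per favorable allele (R2 = %.3f, p = %.3g, n = %d)\n",
    x$slope, x$r2, x$p, x$n))
  print(x$class_means, row.names = FALSE)
  invisible(x)
}
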