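#' Call crossovers from RIL genotypes by parental phase change
#'
#' Scores one crossover per change of parental genotype phase supported by at
#' least `k` consecutive informative markers. Per RIL and chromosome the
#' algorithm drops missing (and heterozygous) calls, compresses the
#' remaining calls into maximal same-phase runs, deletes runs shorter than
#' `k` markers (including terminal runs: a lone discordant first or last
#' marker is treated as genotyping error, not crossover), merges adjacent
#' equal phases, and emits one crossover per remaining phase transition,
#' localized between the flanking informative markers of the adjoining
#' retained runs with the breakpoint at the genetic midpoint of that
#' interval. `k = 2` (the default) is robust to isolated mis-genotyped or
#' misplaced markers; `k = 1` counts every phase switch. For any input,
#' the `k = 2` count is less than or equal to the `k = 1` count.
#'
#' @param genos a `ril_genotypes` object. Heterozygous calls are treated as
#'   missing (the expected residual-het handling for near-inbred RILs).
#' @param map optional map data.frame (`marker`, `chrom`, `cM`) overriding
#'   the map carried by `genos`; markers must be map-ordered per chromosome.
#' @param k support: number of consecutive markers required to establish a
#'   phase (>= 1).
#' @return An object of class `crossover_set`: data.frame with columns
#'   `ril`, `chrom`, `left_marker`, `right_marker`, `left_cM`, `right_cM`,
#'   `breakpoint_cM`, `phase_from`, `phase_to` (phases coded 0 = common
#'   parent, 2 = alternate founder). Attributes `rils` and `chroms` retain
#'   the full RIL and chromosome sets so RILs with zero crossovers are not
#'   lost downstream.
#' @export
call_crossovers <- function(genos, map = NULL, k = 2L) {
  if (k < 1L) stop_val("'k' must be >= 1")
  mp <- map %||% genos$markers
  ord <- match(genos$markers$marker, mp$marker)
  if (anyNA(ord))
    stop_val("genotype markers missing from map: ",
             paste(utils::head(genos$markers$marker[is.na(ord)], 5), collapse = ", "))
  g <- genos$geno
  g[g == 1L] <- NA_integer_
  chroms <- unique(mp$chrom)
  out <- list()
  for (nm in chroms) {
    sel <- which(genos$markers$chrom == nm)
    if (!length(sel)) next
    pos <- genos$markers$cM[sel]
    o <- order(pos)
    sel <- sel[o]; pos <- pos[o]
    if (length(sel) < k) {
      warning("chromosome ", nm, " has fewer than k informative markers; ",
              "no crossovers called", call. = FALSE)
      next
    }
    for (r in seq_along(genos$rils)) {
      x <- g[sel, r]
      obs <- which(!is.na(x))
      if (length(obs) < 2L) next
      runs <- rle(x[obs])
      keep <- runs$lengths >= k
      if (sum(keep) < 2L) next
      # indices (into obs) of run starts/ends, for retained runs
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      vals <- runs$values[keep]
      rs <- starts[keep]; re <- ends[keep]
      # merge adjacent retained runs with equal phase
      m <- rle(vals)
      n_m <- length(m$values)
      if (n_m < 2L) next
      me <- cumsum(m$lengths)
      ms <- me - m$lengths + 1L
      left_i <- obs[re[me[-n_m]]]   # last marker of left merged run
      right_i <- obs[rs[ms[-1L]]]   # first marker of right merged run
      out[[length(out) + 1L]] <- data.frame(
        ril = genos$rils[r], chrom = nm,
        left_marker = genos$markers$marker[sel[left_i]],
        right_marker = genos$markers$marker[sel[right_i]],
        left_cM = pos[left_i], right_cM = pos[right_i],
        breakpoint_cM = (pos[left_i] + pos[right_i]) / 2,
        phase_from = m$values[-n_m], phase_to = m$values[-1L],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ril = character(), chrom = character(),
               left_marker = character(), right_marker = character(),
               left_cM = numeric(), right_cM = numeric(),
               breakpoint_cM = numeric(), phase_from = integer(),
               phase_to = integer(), stringsAsFactors = FALSE)
  structure(res, class = c("crossover_set", "data.frame"),
            rils = genos$rils, chroms = chroms)
}

#' @export
print.crossover_set <- function(x, ...) {
  cat(sprintf("Crossover set: %d crossovers in %d RILs (%d with >= 1 CO)\n",
              nrow(x), length(attr(x, "rils")), length(unique(x$ril))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}
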