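#' Build a genome model for NAM simulation and analysis
#'
#' A genome model holds the chromosome layout (genetic length, centromere
#' position, optional physical length, genome-class label such as the wheat
#' A/B/D sub-genomes) together with an ordered marker grid per chromosome.
#' All downstream stages (meiosis simulation, crossover calling, QTL scans)
#' share this coordinate system. Genetic positions are meiotic centimorgans:
#' 100 cM corresponds to one expected crossover per meiosis per chromosome
#' segment of that length.
#'
#' @param chromosomes data.frame with columns `name`, `length_cM`, and
#'   optionally `centromere_cM` (default: midpoint), `length_Mb`, `genome`
#'   (sub-genome label, default "A").
#' @param markers_per_chrom integer; number of equally spaced markers per
#'   chromosome (first at 0 cM, last at `length_cM`). Ignored for a
#'   chromosome listed in `marker_positions`.
#' @param marker_positions optional named list (by chromosome name) of numeric
#'   cM positions overriding the uniform grid.
#'
#' @return An object of class `genome_model`: a list with `chrom`
#'   (data.frame, one row per chromosome, including `cM_per_Mb` when physical
#'   lengths are given) and `markers` (data.frame with `marker`, `chrom`,
#'   `cM`, and `Mb` when derivable by linear interpolation).
#' @examples
#' gm <- build_genome_model(
#'   data.frame(name = c("1A", "2A"), length_cM = 100),
#'   markers_per_chrom = 51)
#' gm
#' @export
build_genome_model <- function(chromosomes, markers_per_chrom = 101L,
                               marker_positions = NULL) {
  if (!is.data.frame(chromosomes) || nrow(chromosomes) < 1L)
    stop_val("'chromosomes' must be a data.frame with at least one row")
  if (!all(c("name", "length_cM") %in% names(chromosomes)))
    stop_val("'chromosomes' needs columns 'name' and 'length_cM'")
  ch <- data.frame(
    name = as.character(chromosomes$name),
    genome = as.character(chromosomes$genome %||% rep("A", nrow(chromosomes))),
    length_cM = as.numeric(chromosomes$length_cM),
    stringsAsFactors = FALSE
  )
  ch$centromere_cM <- as.numeric(chromosomes$centromere_cM %||% (ch$length_cM / 2))
  ch$length_Mb <- as.numeric(chromosomes$length_Mb %||% rep(NA_real_, nrow(ch)))
  if (anyDuplicated(ch$name)) stop_val("duplicate chromosome names")
  if (any(!is.finite(ch$length_cM)) || any(ch$length_cM <= 0))
    stop_val("chromosome genetic lengths must be positive")
  bad <- ch$centromere_cM < 0 | ch$centromere_cM > ch$length_cM |
    !is.finite(ch$centromere_cM)
  if (any(bad))
    stop_val("centromere position outside chromosome: ",
             paste(ch$name[bad], collapse = ", "))
  ch$cM_per_Mb <- ifelse(is.na(ch$length_Mb), NA_real_,
                         ch$length_cM / ch$length_Mb)

  mk <- lapply(seq_len(nrow(ch)), function(i) {
    nm <- ch$name[i]
    pos <- if (!is.null(marker_positions) && nm %in% names(marker_positions)) {
      sort(as.numeric(marker_positions[[nm]]))
    } else {
      if (markers_per_chrom < 2L) stop_val("need >= 2 markers per chromosome")
      seq(0, ch$length_cM[i], length.out = markers_per_chrom)
    }
    if (length(pos) < 2L) stop_val("need >= 2 markers per chromosome")
    if (any(pos < 0 | pos > ch$length_cM[i]))
      stop_val("marker positions outside chromosome ", nm)
    if (is.unsorted(pos)) stop_val("marker positions must be non-decreasing")
    data.frame(
      marker = sprintf("%s_m%04d", nm, seq_along(pos)),
      chrom = nm, cM = pos,
      Mb = if (is.na(ch$length_Mb[i])) NA_real_ else
        pos / ch$length_cM[i] * ch$length_Mb[i],
      stringsAsFactors = FALSE
    )
  })
  structure(list(chrom = ch, markers = do.call(rbind, mk)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "Genome model: %d chromosome(s), %.0f cM total, %d markers\n",
    nrow(x$chrom), sum(x$chrom$length_cM), nrow(x$markers)))
  print(x$chrom, row.names = FALSE)
  invisible(x)
}

chrom_row <- function(model, chrom) {
  i <- match(chrom, model$chrom$name)
  if (any(is.na(i))) stop_val("unknown chromosome: ",
                              paste(chrom[is.na(i)], collapse = ", "))
  i
}

#' Partition chromosome arms into distal and pericentromeric regions
#'
#' Each arm is split at the point two-thirds of the way from the centromere
#' to the telomere: the outer third of the arm is "distal", the inner
#' two-thirds "pericentromeric". A breakpoint exactly on the boundary is
#' assigned to the pericentromeric class. The fraction of the arm called
#' distal is configurable (default 1/3).
#'
#' @param model a `genome_model`, or a data.frame with `name`, `length_cM`,
#'   `centromere_cM`.
#' @param distal_fraction fraction of each arm, measured from the telomere,
#'   classified as distal.
#' @return data.frame of class `arm_partition` with one row per chromosome:
#'   `chrom`, `centromere_cM`, `length_cM`, `distal_left_end` (left-arm
#'   distal region is `[0, distal_left_end)`) and `distal_right_start`
#'   (right-arm distal region is `(distal_right_start, length_cM]`).
#' @export
arm_partition <- function(model, distal_fraction = 1/3) {
  ch <- if (inherits(model, "genome_model")) model$chrom else model
  if (distal_fraction <= 0 || distal_fraction >= 1)
    stop_val("'distal_fraction' must be in (0, 1)")
  out <- data.frame(
    chrom = ch$name,
    centromere_cM = ch$centromere_cM,
    length_cM = ch$length_cM,
    distal_left_end = ch$centromere_cM * distal_fraction,
    distal_right_start = ch$centromere_cM +
      (ch$length_cM - ch$centromere_cM) * (1 - distal_fraction),
    stringsAsFactors = FALSE
  )
  class(out) <- c("arm_partition", "data.frame")
  out
}

# Region class of positions on one chromosome: TRUE = distal, FALSE = peri.
# Boundary positions count as pericentromeric.
is_distal <- function(partition, chrom, cM) {
  i <- match(chrom, partition$chrom)
  if (any(is.na(i))) stop_val("chromosome missing from partition: ",
                              paste(unique(chrom[is.na(i)]), collapse = ", "))
  cM < partition$distal_left_end[i] | cM > partition$distal_right_start[i]
}
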