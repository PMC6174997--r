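new_ril_genotypes <- function(family, common, founder, markers, geno, rils) {
  stopifnot(nrow(geno) == nrow(markers), ncol(geno) == length(rils))
  rownames(geno) <- markers$marker
  colnames(geno) <- rils
  structure(list(family = family, common = common, founder = founder,
                 markers = markers, geno = geno, rils = rils),
            class = "ril_genotypes")
}

#' @export
print.ril_genotypes <- function(x, ...) {
  cat(sprintf(
    "RIL genotypes, family '%s' (%s x %s): %d markers x %d RILs; %.1f%% missing, %.1f%% het\n",
    x$family, x$common, x$founder, nrow(x$geno), ncol(x$geno),
    100 * mean(is.na(x$geno)), 100 * mean(x$geno == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Simulate one NAM family of single-seed-descent RILs
#'
#' Forward-simulates a common-parent x founder cross selfed by single seed
#' descent: the F1 is heterozygous at all founder-divergent loci and each of
#' the `n_generations - 1` selfing meioses draws Poisson crossovers on the
#' genetic map (two independent gametes per selfing). Recombination-modifier
#' loci act on the crossover intensity of each meiosis through the meiotic
#' plant's current genotype at the modifier loci (one high allele in a
#' heterozygote), so their RIL-level crossover effect is emergent. Residual
#' heterozygosity per locus is `(1/2)^(n_generations - 1)` in expectation
#' (1/64 at F7).
#'
#' @param panel a [simulate_founders()] panel.
#' @param founder name of the alternate founder line crossed to the common
#'   parent.
#' @param n_rils number of RILs (independent lineages).
#' @param n_generations F generation of the final RILs (F7 means six selfing
#'   meioses from the F1); must be >= 2.
#' @param modifiers list of [modifier_spec()] objects.
#' @param base_intensity genome-wide baseline intensity multiplier.
#' @param distal_fraction arm fraction used for pericentromeric-scope
#'   modifiers (see [arm_partition()]).
#' @param seed integer seed.
#' @return list with `genos` (a `ril_genotypes` object on the family's
#'   informative markers), and `truth`: `breakpoints` (data.frame `ril`,
#'   `chrom`, `cM` of the observable phase junctions of the final mosaic,
#'   heterozygous tracts dropped), `tco` (named integer count of those
#'   junctions per RIL), `junctions` (per-strand junction count of one
#'   final haplotype, the classical junction-theory tally),
#'   and `dosages` (RILs x modifiers matrix of final high-allele counts,
#'   0/1/2).
#' @export
simulate_ssd_family <- function(panel, founder, n_rils, n_generations = 7L,
                                modifiers = list(), base_intensity = 1,
                                distal_fraction = 1/3, seed = NULL) {
  if (n_generations < 2L) stop_val("'n_generations' must be >= 2")
  if (!founder %in% panel$lines) stop_val("unknown founder: ", founder)
  model <- panel$model
  validate_modifiers(modifiers, model)
  part <- arm_partition(model, distal_fraction)
  n_mod <- length(modifiers)
  # high-allele count contributed by an ancestry (1 = common, 2 = founder)
  carrier <- vapply(modifiers, function(m)
    c(panel$common %in% m$carriers, founder %in% m$carriers), logical(2))
  has_peri <- n_mod > 0 &&
    any(vapply(modifiers, function(m) m$scope == "pericentromeric", logical(1)))

  # static per-chromosome region layout and modifier applicability
  layouts <- lapply(seq_len(nrow(model$chrom)), function(i) {
    nm <- model$chrom$name[i]
    L <- model$chrom$length_cM[i]
    if (has_peri) {
      dl <- part$distal_left_end[i]
      dr <- part$distal_right_start[i]
      bounds <- data.frame(start = c(0, dl, dr), end = c(dl, dr, L))
      peri <- c(FALSE, TRUE, FALSE)
    } else {
      bounds <- data.frame(start = 0, end = L)
      peri <- FALSE
    }
    applies <- lapply(seq_len(nrow(bounds)), function(j) {
      which(vapply(modifiers, function(m) {
        switch(m$scope,
               global = TRUE,
               chromosome = identical(m$target_chrom, nm),
               pericentromeric = peri[j])
      }, logical(1)))
    })
    list(name = nm, start = bounds$start, end = bounds$end, applies = applies)
  })
  mod_chrom <- vapply(modifiers, `[[`, character(1), "chrom")
  mod_cM <- vapply(modifiers, `[[`, numeric(1), "cM")
  betas <- vapply(modifiers, `[[`, numeric(1), "beta")

  run <- function() {
    rils <- sprintf("RIL%04d", seq_len(n_rils))
    inf <- which(panel$geno[founder, ] != panel$geno[panel$common, ])
    markers <- model$markers[inf, , drop = FALSE]
    geno <- matrix(NA_integer_, nrow = length(inf), ncol = n_rils)
    bp <- vector("list", n_rils)
    junc <- integer(n_rils)
    dos <- matrix(0L, nrow = n_rils, ncol = n_mod,
                  dimnames = list(rils, if (n_mod) sprintf(
                    "mod_%s_%.1fcM", mod_chrom, mod_cM) else NULL))
    for (r in seq_len(n_rils)) {
      plant <- f1_plant(model)
      for (gen in seq_len(n_generations - 1L)) {
        n_high <- if (n_mod) vapply(seq_len(n_mod), function(l) {
          h <- plant[[mod_chrom[l]]]
          carrier[mosaic_at(h$h1, mod_cM[l]), l] +
            carrier[mosaic_at(h$h2, mod_cM[l]), l]
        }, numeric(1)) else numeric()
        nxt <- plant
        for (i in seq_along(layouts)) {
          lay <- layouts[[i]]
          mult <- base_intensity * (1 + vapply(lay$applies, function(ap)
            if (length(ap)) sum(betas[ap] * n_high[ap]) else 0, numeric(1)))
          L <- model$chrom$length_cM[i]
          h <- plant[[i]]
          nxt[[i]] <- list(
            h1 = meiosis_gamete(h$h1, h$h2,
                                draw_crossovers(lay$start, lay$end, mult), L),
            h2 = meiosis_gamete(h$h1, h$h2,
                                draw_crossovers(lay$start, lay$end, mult), L))
        }
        plant <- nxt
      }
      # truth + genotypes from the final haplotype pair
      jx <- lapply(seq_along(plant), function(i)
        pair_truth_junctions(plant[[i]]$h1, plant[[i]]$h2,
                             model$chrom$length_cM[i]))
      nj <- lengths(jx)
      # per-strand junction tally of classical junction theory (2/Morgan in
      # the fully inbred limit); part of it is hidden from genotype data
      # while residual heterozygosity persists
      junc[r] <- sum(vapply(plant, function(h) length(h$h1$br), integer(1)))
      bp[[r]] <- list(chrom = rep(model$chrom$name, nj),
                      cM = as.numeric(unlist(jx, use.names = FALSE)) %||%
                        numeric())
      if (n_mod) dos[r, ] <- vapply(seq_len(n_mod), function(l) {
        h <- plant[[mod_chrom[l]]]
        carrier[mosaic_at(h$h1, mod_cM[l]), l] +
          carrier[mosaic_at(h$h2, mod_cM[l]), l]
      }, numeric(1))
      for (i in seq_len(nrow(model$chrom))) {
        sel <- which(markers$chrom == model$chrom$name[i])
        if (!length(sel)) next
        geno[sel, r] <- pair_genotype_at(plant[[i]]$h1, plant[[i]]$h2,
                                         markers$cM[sel])
      }
    }
    nbp <- vapply(bp, function(b) length(b$cM), integer(1))
    breakpoints <- data.frame(
      ril = rep(rils, nbp),
      chrom = unlist(lapply(bp, `[[`, "chrom"), use.names = FALSE) %||%
        character(),
      cM = unlist(lapply(bp, `[[`, "cM"), use.names = FALSE) %||% numeric(),
      stringsAsFactors = FALSE)
    tco <- table(factor(breakpoints$ril, levels = rils))
    list(genos = new_ril_genotypes(
           family = paste0(panel$common, "x", founder),
           common = panel$common, founder = founder,
           markers = markers, geno = geno, rils = rils),
         truth = list(breakpoints = breakpoints,
                      tco = stats::setNames(as.integer(tco), rils),
                      junctions = stats::setNames(junc, rils),
                      dosages = dos))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Add genotyping error and missingness to a RIL genotype matrix
#'
#' Each non-missing call is independently flipped with probability
#' `error_rate` (homozygous calls switch parental phase; a heterozygous call
#' becomes a random homozygote) and then masked to missing with probability
#' `missing_rate`. Zero rates return the input unchanged.
#'
#' @param genos a `ril_genotypes` object.
#' @param error_rate,missing_rate probabilities in \[0, 1\].
#' @param seed integer seed; identical seeds give identical noise patterns.
#' @return a `ril_genotypes` object.
#' @export
add_genotyping_noise <- function(genos, error_rate, missing_rate, seed = NULL) {
  check_prob(error_rate, "error_rate")
  check_prob(missing_rate, "missing_rate")
  if (error_rate == 0 && missing_rate == 0) return(genos)
  run <- function() {
    g <- genos$geno
    obs <- which(!is.na(g))
    if (error_rate > 0 && length(obs)) {
      flip <- obs[stats::runif(length(obs)) < error_rate]
      if (length(flip)) {
        old <- g[flip]
        new <- ifelse(old == 0L, 2L, ifelse(old == 2L, 0L,
                      2L * stats::rbinom(length(old), 1L, 0.5)))
        g[flip] <- as.integer(new)
      }
    }
    if (missing_rate > 0 && length(obs)) {
      g[obs[stats::runif(length(obs)) < missing_rate]] <- NA_integer_
    }
    genos$geno <- g
    genos
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a full NAM population
#'
#' Crosses every non-common line of a founder panel to the common parent and
#' simulates one SSD RIL family per cross, optionally adding genotyping
#' noise. Per-family seeds are derived deterministically from `seed`.
#'
#' @inheritParams simulate_ssd_family
#' @param error_rate,missing_rate genotyping noise applied to every family.
#' @param founders which founder lines to use (default: all non-common
#'   lines).
#' @return named list (by founder) of [simulate_ssd_family()] results; the
#'   `genos` element of each family has noise applied, while `truth` refers
#'   to the noise-free mosaics.
#' @export
simulate_nam <- function(panel, n_rils, n_generations = 7L, modifiers = list(),
                         base_intensity = 1, error_rate = 0, missing_rate = 0,
                         founders = NULL, seed = 1L) {
  founders <- founders %||% setdiff(panel$lines, panel$common)
  seeds <- derive_seeds(seed, 2L * length(founders))
  out <- vector("list", length(founders))
  names(out) <- founders
  for (i in seq_along(founders)) {
    fam <- simulate_ssd_family(panel, founders[i], n_rils, n_generations,
                               modifiers, base_intensity, seed = seeds[2L * i - 1L])
    fam$genos <- add_genotyping_noise(fam$genos, error_rate, missing_rate,
                                      seed = seeds[2L * i])
    out[[i]] <- fam
  }
  out
}
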