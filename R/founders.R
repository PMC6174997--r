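#' Simulate a panel of inbred NAM founders
#'
#' Draws one fully homozygous biallelic haplotype per line at every marker of
#' the genome model. Line 1 is the common parent to which every family is
#' crossed. Optionally, identity-by-descent (IBD) tracts shared with the
#' common parent are injected into the other founders: within a tract the
#' founder's haplotype is copied from the common parent, emulating shared
#' ancestry between the common parent and the diverse founders.
#'
#' @param model a [build_genome_model()] object.
#' @param n_founders total number of lines including the common parent
#'   (>= 2).
#' @param maf_law per-marker alternate allele frequency: a single number or a
#'   function `f(n)` returning `n` frequencies.
#' @param ibd_fraction target fraction of each founder's genome that is IBD
#'   with the common parent (0 disables tract injection).
#' @param mean_tract_cM mean length of an IBD tract (exponentially
#'   distributed, clipped to the chromosome).
#' @param seed integer seed; identical seeds give identical panels.
#' @return An object of class `founder_panel`: list with `lines` (names,
#'   common parent first), `common`, `geno` (lines x markers 0/1 matrix),
#'   `ibd` (data.frame `founder`, `chrom`, `start_cM`, `end_cM`, half-open
#'   intervals), and the `model`.
#' @export
simulate_founders <- function(model, n_founders, maf_law = 0.5,
                              ibd_fraction = 0, mean_tract_cM = 25,
                              seed = NULL) {
  if (n_founders < 2L) stop_val("need at least 2 lines (common parent + 1)")
  check_prob(ibd_fraction, "ibd_fraction")
  run <- function() {
    nm <- nrow(model$markers)
    p <- if (is.function(maf_law)) maf_law(nm) else rep(as.numeric(maf_law), nm)
    if (length(p) != nm || any(p < 0 | p > 1))
      stop_val("'maf_law' must yield one frequency in [0,1] per marker")
    lines <- c("CP", sprintf("F%02d", seq_len(n_founders - 1L)))
    geno <- matrix(stats::rbinom(n_founders * nm, 1L, rep(p, each = n_founders)),
                   nrow = n_founders, ncol = nm,
                   dimnames = list(lines, model$markers$marker))
    ibd <- data.frame(founder = character(), chrom = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      stringsAsFactors = FALSE)
    if (ibd_fraction > 0) {
      G <- sum(model$chrom$length_cM)
      tr <- list()
      for (f in lines[-1L]) {
        # accumulate tracts until the merged length reaches the target;
        # the last tract is capped at the remaining length so the realized
        # fraction tracks the requested one
        target <- ibd_fraction * G
        ch <- character(); st <- numeric(); en <- numeric()
        repeat {
          d <- if (length(ch))
            merge_regions(data.frame(chrom = ch, start = st, end = en,
                                     family = f, stringsAsFactors = FALSE))
          else NULL
          cur <- if (is.null(d)) 0 else sum(d$end - d$start)
          if (cur >= target - 1e-9) break
          ci <- sample.int(nrow(model$chrom), 1L,
                           prob = model$chrom$length_cM)
          L <- model$chrom$length_cM[ci]
          len <- min(max(stats::rexp(1L, 1 / mean_tract_cM), 1), L,
                     max(target - cur, 1))
          s <- stats::runif(1L, 0, L - len)
          ch <- c(ch, model$chrom$name[ci])
          st <- c(st, s); en <- c(en, s + len)
        }
        tr[[f]] <- data.frame(founder = f, chrom = d$chrom,
                              start_cM = d$start, end_cM = d$end,
                              stringsAsFactors = FALSE)
        for (j in seq_len(nrow(tr[[f]]))) {
          sel <- model$markers$chrom == d$chrom[j] &
            model$markers$cM >= d$start[j] & model$markers$cM < d$end[j]
          geno[f, sel] <- geno["CP", sel]
        }
      }
      ibd <- do.call(rbind, unname(tr))
    }
    structure(list(lines = lines, common = "CP", geno = geno, ibd = ibd,
                   model = model),
              class = "founder_panel")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("Founder panel: %d lines (common parent '%s'), %d markers\n",
              length(x$lines), x$common, ncol(x$geno)))
  if (nrow(x$ibd)) {
    G <- sum(x$model$chrom$length_cM)
    frac <- sum(x$ibd$end_cM - x$ibd$start_cM) /
      (G * (length(x$lines) - 1L))
    cat(sprintf("IBD with common parent: %d tracts, mean genome fraction %.3f\n",
                nrow(x$ibd), frac))
  }
  invisible(x)
}

#' Specify a recombination-modifier locus
#'
#' A modifier is a biallelic locus whose high allele multiplies the crossover
#' intensity of every meiosis of a plant that carries it. The multiplier for
#' a region is `1 + sum(beta_l * n_high_l)` over the modifiers acting on that
#' region, where `n_high` is the number of high alleles carried (0, 1 or 2;
#' a heterozygous plant carries one, honouring the fact that modifiers
#' segregate between heterozygous and homozygous states during inbreeding).
#' The realized RIL-level crossover-count effect is emergent: it accumulates
#' over the whole selfing pedigree and is measured, not asserted.
#'
#' @param chrom,cM map location of the modifier locus.
#' @param beta additive intensity increment per high allele (dimensionless;
#'   may be negative as long as all achievable multipliers stay positive).
#' @param scope `"global"` (all chromosomes), `"chromosome"` (only
#'   `target_chrom`, by default the modifier's own chromosome: a cis-acting
#'   map-length polymorphism), or `"pericentromeric"` (only the inner
#'   two-thirds of every arm).
#' @param carriers character vector of panel line names carrying the high
#'   allele (may include the common parent `"CP"`).
#' @param target_chrom chromosome affected when `scope = "chromosome"`.
#' @return list of class `modifier_spec`.
#' @export
modifier_spec <- function(chrom, cM, beta,
                          scope = c("global", "chromosome", "pericentromeric"),
                          carriers, target_chrom = chrom) {
  scope <- match.arg(scope)
  structure(list(chrom = chrom, cM = cM, beta = beta, scope = scope,
                 carriers = carriers, target_chrom = target_chrom),
            class = "modifier_spec")
}

validate_modifiers <- function(modifiers, model) {
  for (m in modifiers) {
    i <- match(m$chrom, model$chrom$name)
    if (is.na(i)) stop_val("modifier locus on unknown chromosome ", m$chrom)
    if (m$cM < 0 || m$cM > model$chrom$length_cM[i])
      stop_val("modifier locus off the map: ", m$chrom, " ", m$cM)
  }
  betas <- vapply(modifiers, `[[`, numeric(1), "beta")
  if (length(betas) && 1 + 2 * sum(pmin(betas, 0)) <= 0)
    stop_val("modifier effects allow a non-positive intensity multiplier")
  invisible(TRUE)
}
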