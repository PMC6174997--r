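# Composite interval mapping -------------------------------------------------
#
# Regression (Haley-Knott) interval mapping with marker cofactors: at each
# grid position the trait is regressed on the expected alternate-parent
# dosage plus the selected cofactor markers, omitting cofactors within
# `window_cM` of the test position.
# LOD = (n/2) * log10(RSS_reduced / RSS_full).
# The additive effect is reported with the common-parent-positive sign
# convention: positive effect means the common parent's allele increases
# the trait; its magnitude is the fitted difference between the two
# homozygous classes.

# Orthonormal column basis of a design matrix (rank-safe).
ortho_basis <- function(X) {
  qd <- qr(X)
  qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
}

rss_given_basis <- function(Q, Y) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

# Core engine shared by the scan, the permutation thresholds and the joint
# machinery: precomputes the dosage grid and per-position projection bases
# so that scanning any number of phenotype vectors is a matrix product.
cim_prepare <- function(genos, cofactors = NULL, window_cM = 10,
                        step_cM = 1, grid = NULL) {
  grid <- grid %||% scan_grid(genos$markers, step_cM)
  D <- dosage_grid(genos, grid)
  cof <- cofactors %||% character()
  ci <- match(cof, genos$markers$marker)
  if (anyNA(ci)) stop_val("unknown cofactor marker(s): ",
                          paste(cof[is.na(ci)], collapse = ", "))
  C <- if (length(ci))
    dosage_grid(genos, data.frame(chrom = genos$markers$chrom[ci],
                                  cM = genos$markers$cM[ci]))
  else matrix(numeric(), nrow = length(genos$rils), ncol = 0L)
  cof_chrom <- genos$markers$chrom[ci]
  cof_cM <- genos$markers$cM[ci]
  keep_of <- function(j) which(!(cof_chrom == grid$chrom[j] &
                                   abs(cof_cM - grid$cM[j]) < window_cM))
  list(grid = grid, D = D, C = C, cofactors = cof, keep_of = keep_of,
       window_cM = window_cM, step_cM = step_cM)
}

# LOD profiles for a matrix of phenotypes (columns). Returns list with
# `lod` (npos x ncol) and, for the first column, `effect` and `df_resid`.
cim_profiles <- function(prep, Y, usable) {
  Y <- as.matrix(Y)[usable, , drop = FALSE]
  n <- nrow(Y)
  npos <- nrow(prep$grid)
  lod <- matrix(0, npos, ncol(Y))
  effect <- numeric(npos)
  df_resid <- integer(npos)
  one <- rep(1, n)
  cacheQ <- new.env(parent = emptyenv())
  for (j in seq_len(npos)) {
    keep <- prep$keep_of(j)
    key <- paste0("k", paste(keep, collapse = ","))
    Qr <- get0(key, envir = cacheQ)
    if (is.null(Qr)) {
      Qr <- ortho_basis(cbind(one, prep$C[usable, keep, drop = FALSE]))
      assign(key, Qr, envir = cacheQ)
    }
    x <- prep$D[usable, j]
    Qf <- ortho_basis(cbind(one, prep$C[usable, keep, drop = FALSE], x))
    rss_r <- pmax(rss_given_basis(Qr, Y), .Machine$double.eps)
    rss_f <- pmax(rss_given_basis(Qf, Y), .Machine$double.eps)
    lod[j, ] <- pmax((n / 2) * log10(rss_r / rss_f), 0)
    # signed effect for the first phenotype column
    xr <- x - Qr %*% crossprod(Qr, x)
    sx <- sum(xr^2)
    b <- if (sx > 1e-10) sum(xr * Y[, 1L]) / sx else 0
    effect[j] <- -b
    df_resid[j] <- n - ncol(Qf)
  }
  list(lod = lod, effect = effect, df_resid = df_resid)
}

#' Composite interval mapping scan of one family
#'
#' Scans a regular cM grid over the family's genetic map, regressing the
#' trait on the expected alternate-parent dosage at each position with the
#' selected cofactor markers as covariates; cofactors within `window_cM` of
#' the test position are omitted from the model at that position.
#'
#' @param y numeric phenotype per RIL (e.g. TCO); `NA` entries (excluded
#'   RILs) are dropped.
#' @param genos a `ril_genotypes` object.
#' @param cofactors character vector of cofactor marker ids (see
#'   [select_cofactors()]).
#' @param window_cM cofactor exclusion window around the test position
#'   (default 10 cM).
#' @param step_cM grid step (default 1 cM).
#' @param trait label stored on the result.
#' @return An object of class `cim_scan`: list with `profile` (data.frame
#'   `chrom`, `cM`, `lod`, `effect`, `df_resid`), `cofactors`, `n`,
#'   `trait`, and the scan settings. Positive `effect` means the common
#'   parent's allele increases the trait; the magnitude is the difference
#'   between homozygous classes.
#' @export
cim_scan <- function(y, genos, cofactors = NULL, window_cM = 10, step_cM = 1,
                     trait = "tco") {
  usable <- which(!is.na(y))
  if (length(usable) < 10L) stop_val("fewer than 10 usable RILs")
  prep <- cim_prepare(genos, cofactors, window_cM, step_cM)
  pr <- cim_profiles(prep, matrix(y, ncol = 1L), usable)
  structure(list(
    profile = data.frame(chrom = prep$grid$chrom, cM = prep$grid$cM,
                         lod = pr$lod[, 1L], effect = pr$effect,
                         df_resid = pr$df_resid, stringsAsFactors = FALSE),
    cofactors = prep$cofactors, n = length(usable), trait = trait,
    window_cM = window_cM, step_cM = step_cM, family = genos$family),
    class = "cim_scan")
}

#' @export
print.cim_scan <- function(x, ...) {
  pk <- x$profile[which.max(x$profile$lod), ]
  cat(sprintf(
    "CIM scan of '%s' (family %s): %d RILs, %d positions, %d cofactor(s)\n",
    x$trait, x$family, x$n, nrow(x$profile), length(x$cofactors)))
  cat(sprintf("Max LOD %.2f at %s %.1f cM (effect %+.2f)\n",
              pk$lod, pk$chrom, pk$cM, pk$effect))
  invisible(x)
}

#' @export
summary.cim_scan <- function(object, threshold = NULL, drop = 2,
                             min_separation_cM = 20, ...) {
  if (is.null(threshold)) {
    print(object)
    return(invisible(object))
  }
  find_qtl(object, threshold, drop, min_separation_cM)
}

#' @export
plot.cim_scan <- function(x, threshold = NULL, ...) {
  pr <- x$profile
  chroms <- unique(pr$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(nm)
    max(pr$cM[pr$chrom == nm]) + 5, numeric(1))))
  names(offs) <- c(chroms, "end")
  xx <- pr$cM + offs[pr$chrom]
  graphics::plot(xx, pr$lod, type = "n", xlab = "map position (cM)",
                 ylab = "LOD", main = sprintf("CIM scan: %s", x$trait), ...)
  for (nm in chroms) {
    sel <- pr$chrom == nm
    graphics::lines(xx[sel], pr$lod[sel])
  }
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Select cofactor markers by stepwise regression
#'
#' Forward selection / backward elimination of marker covariates with
#' partial-F p-value thresholds for inclusion and exclusion (default 0.01
#' for both). When more candidates than a third of the observations are
#' offered, candidates are pre-thinned by marginal p-value ranking (noted
#' via message). Deterministic given its inputs.
#'
#' @inheritParams cim_scan
#' @param candidates marker ids to consider (default: all markers, thinned
#'   to at most one per `thin_cM` centimorgans to avoid collinear
#'   neighbours).
#' @param p_in,p_out partial-F p thresholds for inclusion / retention.
#' @param thin_cM candidate spacing (default 5 cM).
#' @return character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(y, genos, candidates = NULL, p_in = 0.01,
                             p_out = 0.01, thin_cM = 5) {
  usable <- which(!is.na(y))
  yy <- y[usable]
  n <- length(yy)
  if (is.null(candidates)) {
    keep <- unlist(lapply(unique(genos$markers$chrom), function(nm) {
      sel <- which(genos$markers$chrom == nm)
      sel <- sel[order(genos$markers$cM[sel])]
      last <- -Inf
      take <- logical(length(sel))
      for (i in seq_along(sel)) {
        if (genos$markers$cM[sel[i]] - last >= thin_cM) {
          take[i] <- TRUE
          last <- genos$markers$cM[sel[i]]
        }
      }
      sel[take]
    }))
    candidates <- genos$markers$marker[keep]
  }
  ci <- match(candidates, genos$markers$marker)
  if (anyNA(ci)) stop_val("unknown candidate marker(s)")
  M <- dosage_grid(genos, data.frame(chrom = genos$markers$chrom[ci],
                                     cM = genos$markers$cM[ci]))[usable, ,
                                                                 drop = FALSE]
  colnames(M) <- candidates
  if (ncol(M) > floor(n / 3)) {
    # marginal screen to keep the design well under n
    pm <- apply(M, 2L, function(x) {
      if (stats::sd(x) < 1e-9) return(1)
      f <- summary(stats::lm(yy ~ x))$fstatistic
      stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
    })
    keepn <- order(pm)[seq_len(floor(n / 3))]
    message("select_cofactors: pre-thinned ", ncol(M), " candidates to ",
            length(keepn), " by marginal p ranking")
    M <- M[, sort(keepn), drop = FALSE]
  }
  sel <- character()
  one <- rep(1, n)
  repeat {
    changed <- FALSE
    # forward step
    X <- cbind(one, M[, sel, drop = FALSE])
    Q <- ortho_basis(X)
    rss0 <- sum(yy^2) - sum(crossprod(Q, yy)^2)
    df1 <- n - ncol(Q) - 1L
    if (df1 > 0) {
      cand <- setdiff(colnames(M), sel)
      if (length(cand)) {
        Mr <- M[, cand, drop = FALSE] - Q %*% crossprod(Q, M[, cand, drop = FALSE])
        yr <- yy - Q %*% crossprod(Q, yy)
        ss <- colSums(Mr^2)
        gain <- ifelse(ss > 1e-10, colSums(Mr * as.vector(yr))^2 / ss, 0)
        rss1 <- pmax(rss0 - gain, .Machine$double.eps)
        pv <- stats::pf((rss0 - rss1) / (rss1 / df1), 1, df1,
                        lower.tail = FALSE)
        best <- which.min(pv)
        if (pv[best] < p_in) {
          sel <- c(sel, cand[best])
          changed <- TRUE
        }
      }
    }
    # backward step: drop the weakest retained cofactor if p > p_out
    if (length(sel) > 0L) {
      X <- cbind(one, M[, sel, drop = FALSE])
      Qf <- ortho_basis(X)
      rssf <- sum(yy^2) - sum(crossprod(Qf, yy)^2)
      dff <- n - ncol(Qf)
      pv <- vapply(seq_along(sel), function(k) {
        Q0 <- ortho_basis(cbind(one, M[, sel[-k], drop = FALSE]))
        rss0k <- sum(yy^2) - sum(crossprod(Q0, yy)^2)
        stats::pf((rss0k - rssf) / (rssf / dff), 1, dff, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the phenotype against the genotypes `n_perm` times, records the
#' genome-wide maximum LOD of each permuted scan (reusing the originally
#' selected cofactors), and returns the `ceiling((1 - alpha) * n_perm)`-th
#' order statistic — e.g. the 950th largest of 1000 max-LODs at alpha 0.05.
#'
#' @inheritParams cim_scan
#' @param n_perm number of permutations; must satisfy
#'   `n_perm * alpha >= 1`.
#' @param alpha genome-wide significance level.
#' @param seed integer seed.
#' @param prep optional precomputed [cim_prepare()] engine (internal reuse).
#' @return the LOD threshold (single number), with attribute `max_lods`.
#' @export
permutation_threshold <- function(y, genos, cofactors = NULL, n_perm = 1000L,
                                  alpha = 0.05, window_cM = 10, step_cM = 1,
                                  seed = NULL, prep = NULL) {
  if (n_perm * alpha < 1)
    stop_val("n_perm * alpha < 1: the (1 - alpha) quantile is unresolvable")
  usable <- which(!is.na(y))
  yy <- y[usable]
  prep <- prep %||% cim_prepare(genos, cofactors, window_cM, step_cM)
  run <- function() {
    Y <- vapply(seq_len(n_perm), function(i) sample(yy),
                numeric(length(yy)))
    lod <- cim_profiles(prep, Y, seq_along(yy))$lod
    mx <- apply(lod, 2L, max)
    thr <- sort(mx)[ceiling((1 - alpha) * n_perm)]
    attr(thr, "max_lods") <- mx
    thr
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Locate QTL peaks and 2-LOD support intervals in a scan profile
#'
#' Peaks are local maxima above the threshold; two peaks on one chromosome
#' are distinct only when they are at least `min_separation_cM` apart and
#' the profile dips at least `drop` LOD below the lower peak between them
#' (a linkage shadow of a strong peak satisfies neither). The support
#' interval of a peak is the contiguous run of grid positions around it
#' with LOD >= peak - `drop` (2-LOD intervals by default).
#'
#' @param scan a `cim_scan` object (or a data.frame profile with `chrom`,
#'   `cM`, `lod`, and optionally `effect`).
#' @param threshold genome-wide LOD threshold (e.g. from
#'   [permutation_threshold()]).
#' @param drop LOD drop defining the support interval (default 2).
#' @param min_separation_cM minimum peak separation (default 20 cM).
#' @param alpha significance level recorded on the result.
#' @return data.frame of class `qtl_table`: `trait`, `family`, `chrom`,
#'   `peak_cM`, `lod`, `effect`, `ci_lo`, `ci_hi`, `threshold`, `alpha`
#'   (zero rows when nothing exceeds the threshold).
#' @export
find_qtl <- function(scan, threshold, drop = 2, min_separation_cM = 20,
                     alpha = 0.05) {
  pr <- if (inherits(scan, "cim_scan")) scan$profile else scan
  trait <- if (inherits(scan, "cim_scan")) scan$trait else "trait"
  family <- if (inherits(scan, "cim_scan")) scan$family else NA_character_
  res <- list()
  for (nm in unique(pr$chrom)) {
    p <- pr[pr$chrom == nm, ]
    p <- p[order(p$cM), ]
    n <- nrow(p)
    avail <- rep(TRUE, n)
    repeat {
      cand <- which(avail & p$lod >= threshold)
      if (!length(cand)) break
      pk <- cand[which.max(p$lod[cand])]
      pklod <- p$lod[pk]
      # support interval: contiguous run with lod >= peak - drop
      lo <- pk
      while (lo > 1L && p$lod[lo - 1L] >= pklod - drop) lo <- lo - 1L
      hi <- pk
      while (hi < n && p$lod[hi + 1L] >= pklod - drop) hi <- hi + 1L
      res[[length(res) + 1L]] <- data.frame(
        trait = trait, family = family, chrom = nm, peak_cM = p$cM[pk],
        lod = pklod, effect = if ("effect" %in% names(p)) p$effect[pk]
        else NA_real_,
        ci_lo = p$cM[lo], ci_hi = p$cM[hi], threshold = as.numeric(threshold),
        alpha = alpha, stringsAsFactors = FALSE)
      # a further peak q on this chromosome counts as distinct only when it
      # is at least min_separation_cM from this peak and the profile dips
      # at least `drop` below q somewhere in between (linkage shadows of a
      # strong peak satisfy neither); mask everything else
      for (dir in c(-1L, 1L)) {
        run_min <- pklod
        q <- pk
        repeat {
          q <- q + dir
          if (q < 1L || q > n) break
          run_min <- min(run_min, p$lod[q])
          sep_ok <- abs(p$cM[q] - p$cM[pk]) >= min_separation_cM
          valley_ok <- run_min <= p$lod[q] - drop
          if (!(sep_ok && valley_ok)) avail[q] <- FALSE
        }
      }
      avail[pk] <- FALSE
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(trait = character(), family = character(), chrom = character(),
               peak_cM = numeric(), lod = numeric(), effect = numeric(),
               ci_lo = numeric(), ci_hi = numeric(), threshold = numeric(),
               alpha = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$peak_cM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' One-stop single-family QTL analysis
#'
#' Convenience wrapper reproducing the per-family mapping recipe: stepwise
#' cofactor selection, CIM scan, permutation threshold, and peak calling
#' with 2-LOD support intervals.
#'
#' @inheritParams cim_scan
#' @inheritParams permutation_threshold
#' @inheritParams find_qtl
#' @param p_in,p_out cofactor stepwise thresholds.
#' @return list of class `family_scan` with `scan` (a `cim_scan`),
#'   `threshold`, and `qtl` (a `qtl_table`).
#' @export
scan_family <- function(y, genos, trait = "tco", window_cM = 10, step_cM = 1,
                        p_in = 0.01, p_out = 0.01, n_perm = 200L,
                        alpha = 0.05, drop = 2, min_separation_cM = 20,
                        seed = NULL) {
  cof <- select_cofactors(y, genos, p_in = p_in, p_out = p_out)
  prep <- cim_prepare(genos, cof, window_cM, step_cM)
  usable <- which(!is.na(y))
  if (length(usable) < 10L) stop_val("fewer than 10 usable RILs")
  pr <- cim_profiles(prep, matrix(y, ncol = 1L), usable)
  scan <- structure(list(
    profile = data.frame(chrom = prep$grid$chrom, cM = prep$grid$cM,
                         lod = pr$lod[, 1L], effect = pr$effect,
                         df_resid = pr$df_resid, stringsAsFactors = FALSE),
    cofactors = cof, n = length(usable), trait = trait,
    window_cM = window_cM, step_cM = step_cM, family = genos$family),
    class = "cim_scan")
  thr <- permutation_threshold(y, genos, cof, n_perm, alpha,
                               window_cM, step_cM, seed = seed, prep = prep)
  qtl <- find_qtl(scan, thr, drop, min_separation_cM, alpha)
  # Refine declared peaks on a same-chromosome-cofactor-free profile:
  # cofactors beyond the scan window but still linked to the peak absorb
  # part of the allele effect, shrinking the estimate and dragging the
  # apparent peak toward the cofactor's exclusion window. Detection uses
  # the CIM profile; position, support interval and effect of a declared
  # QTL are read off the clean interval-mapping profile of its chromosome.
  if (nrow(qtl)) {
    yy <- y[usable]
    cof_chrom <- genos$markers$chrom[match(cof, genos$markers$marker)]
    for (ch in unique(qtl$chrom)) {
      prep2 <- cim_prepare(genos, cof[cof_chrom != ch], window_cM, step_cM,
                           grid = prep$grid[prep$grid$chrom == ch, ,
                                            drop = FALSE])
      pr2 <- cim_profiles(prep2, matrix(y, ncol = 1L), usable)
      for (i in which(qtl$chrom == ch)) {
        near <- which(abs(prep2$grid$cM - qtl$peak_cM[i]) <=
                        min_separation_cM)
        pk <- near[which.max(pr2$lod[near, 1L])]
        pklod <- pr2$lod[pk, 1L]
        lo <- pk
        while (lo > 1L && pr2$lod[lo - 1L, 1L] >= pklod - drop) lo <- lo - 1L
        hi <- pk
        while (hi < nrow(prep2$grid) && pr2$lod[hi + 1L, 1L] >= pklod - drop)
          hi <- hi + 1L
        qtl$peak_cM[i] <- prep2$grid$cM[pk]
        qtl$ci_lo[i] <- prep2$grid$cM[lo]
        qtl$ci_hi[i] <- prep2$grid$cM[hi]
        qtl$effect[i] <- pr2$effect[pk]
      }
    }
  }
  structure(list(scan = scan, threshold = as.numeric(thr), qtl = qtl),
            class = "family_scan")
}

#' @export
print.family_scan <- function(x, ...) {
  print(x$scan)
  cat(sprintf("Permutation threshold: LOD %.2f; %d QTL declared\n",
              x$threshold, nrow(x$qtl)))
  if (nrow(x$qtl)) print(as.data.frame(x$qtl), row.names = FALSE)
  invisible(x)
}
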