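# Joint cross-family mapping -------------------------------------------------
#
# NAM-style joint mapping: all families share one parent, so loci are
# modelled on a shared map coordinate system with family intercepts and
# family-nested allele effects (the alternate founder allele differs per
# family, so each family gets its own effect relative to the common
# parent). Missing marker dosages are imputed from flanking markers via the
# RIL Markov model (dosage_grid).

# Stack family phenotypes/dosage matrices on a shared candidate grid.
joint_stack <- function(families, positions) {
  ys <- list(); fam <- list(); Ds <- list(); keep_fam <- character()
  for (nm in names(families)) {
    f <- families[[nm]]
    usable <- which(!is.na(f$y))
    if (!length(usable)) {
      warning("family ", nm, " has zero usable RILs; dropped", call. = FALSE)
      next
    }
    ys[[nm]] <- f$y[usable]
    fam[[nm]] <- rep(nm, length(usable))
    Ds[[nm]] <- dosage_grid(f$genos, positions)[usable, , drop = FALSE]
    keep_fam <- c(keep_fam, nm)
  }
  if (length(keep_fam) < 2L) stop_val("need at least 2 usable families")
  list(y = unlist(ys, use.names = FALSE),
       family = factor(unlist(fam, use.names = FALSE), levels = keep_fam),
       D = do.call(rbind, Ds), families = keep_fam, positions = positions)
}

# Family-nested dosage columns for one candidate position.
nested_cols <- function(D_col, family) {
  lv <- levels(family)
  X <- matrix(0, length(D_col), length(lv))
  for (k in seq_along(lv)) {
    sel <- family == lv[k]
    X[sel, k] <- D_col[sel]
  }
  colnames(X) <- lv
  X
}

#' Joint stepwise regression across NAM families
#'
#' Forward selection of loci on a shared map: each locus enters the model
#' as family-nested alternate-allele dosage effects on top of family
#' intercepts, and is admitted when the partial F-test p-value of its
#' nested block beats `p_enter` (default 1e-4). Selection stops when no
#' candidate qualifies. Model R-squared is non-decreasing along the
#' forward path by construction.
#'
#' @param families named list; each element has `genos` (a `ril_genotypes`)
#'   and `y` (phenotype per RIL, `NA` = excluded).
#' @param positions candidate loci as a data.frame (`chrom`, `cM`);
#'   default: the first family's map thinned to `thin_cM` spacing.
#' @param p_enter entry p-value threshold.
#' @param thin_cM default candidate spacing (cM).
#' @param max_loci safety cap on selected loci.
#' @return object of class `joint_model`: list with `loci` (data.frame
#'   `chrom`, `cM`, `p_enter_step`, `r2_path`), `effects` (data.frame
#'   `chrom`, `cM`, `family`, `effect`, common-parent-positive sign),
#'   `r2`, `n`, `families`, `p_enter`.
#' @export
joint_stepwise <- function(families, positions = NULL, p_enter = 1e-4,
                           thin_cM = 5, max_loci = 25L) {
  if (is.null(positions)) {
    mk <- families[[1L]]$genos$markers
    positions <- scan_grid(mk, thin_cM)
  }
  st <- joint_stack(families, positions)
  y <- st$y
  n <- length(y)
  Ffam <- stats::model.matrix(~ st$family)
  sel <- integer()
  pvals <- numeric()
  r2path <- numeric()
  tss <- sum((y - mean(y))^2)
  Xcur <- Ffam
  repeat {
    Q <- ortho_basis(Xcur)
    rss0 <- sum(y^2) - sum(crossprod(Q, y)^2)
    cand <- setdiff(seq_len(nrow(positions)), sel)
    if (!length(cand) || length(sel) >= max_loci) break
    best_p <- Inf; best_j <- NA_integer_; best_rank <- 0L; best_rss <- NA_real_
    for (j in cand) {
      Xc <- nested_cols(st$D[, j], st$family)
      Xr <- Xc - Q %*% crossprod(Q, Xc)
      qd <- qr(Xr)
      rk <- qd$rank
      if (rk == 0L) next
      Qc <- qr.Q(qd)[, seq_len(rk), drop = FALSE]
      rss1 <- rss0 - sum(crossprod(Qc, y)^2)
      df2 <- n - ncol(Q) - rk
      if (df2 <= 0) next
      Fst <- ((rss0 - rss1) / rk) / (rss1 / df2)
      p <- stats::pf(Fst, rk, df2, lower.tail = FALSE)
      if (p < best_p) {
        best_p <- p; best_j <- j; best_rank <- rk; best_rss <- rss1
      }
    }
    if (!is.finite(best_p) || best_p >= p_enter) break
    sel <- c(sel, best_j)
    pvals <- c(pvals, best_p)
    r2path <- c(r2path, 1 - best_rss / tss)
    Xcur <- cbind(Xcur, nested_cols(st$D[, best_j], st$family))
  }
  # final fit for per-family effects
  effects <- data.frame(chrom = character(), cM = numeric(),
                        family = character(), effect = numeric(),
                        stringsAsFactors = FALSE)
  r2 <- {
    Q <- ortho_basis(Xcur)
    rss <- sum(y^2) - sum(crossprod(Q, y)^2)
    1 - rss / tss
  }
  if (length(sel)) {
    Xb <- do.call(cbind, lapply(sel, function(j)
      nested_cols(st$D[, j], st$family)))
    fit <- stats::lm.fit(cbind(Ffam, Xb), y)
    cf <- fit$coefficients[-seq_len(ncol(Ffam))]
    effects <- data.frame(
      chrom = rep(positions$chrom[sel], each = length(st$families)),
      cM = rep(positions$cM[sel], each = length(st$families)),
      family = rep(st$families, times = length(sel)),
      effect = -unname(cf),     # positive = common-parent allele increases y
      stringsAsFactors = FALSE)
  }
  structure(list(
    loci = data.frame(chrom = positions$chrom[sel], cM = positions$cM[sel],
                      p_enter_step = pvals, r2_path = r2path,
                      stringsAsFactors = FALSE),
    effects = effects, r2 = r2, n = n, families = st$families,
    p_enter = p_enter), class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf(
    "Joint stepwise model: %d locus/loci over %d families (n = %d), R2 = %.3f\n",
    nrow(x$loci), length(x$families), x$n, x$r2))
  if (nrow(x$loci)) print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Joint family-stratified interval scan
#'
#' At each grid position, compares the family-intercepts-only model with
#' the model adding family-nested expected dosages:
#' LOD = (n/2) log10(RSS0/RSS1). The genome-wide threshold is obtained by
#' permuting phenotypes within families. The reported effect is the pooled
#' (across-family) allele effect with the common-parent-positive sign.
#'
#' @inheritParams joint_stepwise
#' @param step_cM grid step (0.1 cM mirrors high-resolution joint scans;
#'   coarser steps change peaks by less than the step size).
#' @param n_perm,alpha permutation threshold settings.
#' @param seed integer seed.
#' @return list of class `joint_scan` with `profile` (`chrom`, `cM`, `lod`,
#'   `effect`), `threshold`, `qtl` (a `qtl_table`), `n`.
#' @export
joint_scan <- function(families, step_cM = 0.1, n_perm = 200L, alpha = 0.05,
                       drop = 2, min_separation_cM = 20, seed = NULL) {
  mk <- families[[1L]]$genos$markers
  grid <- scan_grid(mk, step_cM)
  st <- joint_stack(families, grid)
  y <- st$y
  n <- length(y)
  Ffam <- stats::model.matrix(~ st$family)
  Q0 <- ortho_basis(Ffam)
  run <- function() {
    Yp <- vapply(seq_len(n_perm), function(i) {
      yp <- y
      for (lv in levels(st$family)) {
        sel <- which(st$family == lv)
        yp[sel] <- y[sample(sel)]
      }
      yp
    }, numeric(n))
    Y <- cbind(y, Yp)
    rss0 <- colSums(Y^2) - colSums(crossprod(Q0, Y)^2)
    lod <- matrix(0, nrow(grid), ncol(Y))
    effect <- numeric(nrow(grid))
    for (j in seq_len(nrow(grid))) {
      Xc <- nested_cols(st$D[, j], st$family)
      Qf <- ortho_basis(cbind(Ffam, Xc))
      rss1 <- pmax(colSums(Y^2) - colSums(crossprod(Qf, Y)^2),
                   .Machine$double.eps)
      lod[j, ] <- pmax((n / 2) * log10(rss0 / rss1), 0)
      x <- st$D[, j]
      xr <- x - Q0 %*% crossprod(Q0, x)
      sx <- sum(xr^2)
      effect[j] <- if (sx > 1e-10) -sum(xr * y) / sx else 0
    }
    thr <- sort(apply(lod[, -1L, drop = FALSE], 2L, max))[
      ceiling((1 - alpha) * n_perm)]
    profile <- data.frame(chrom = grid$chrom, cM = grid$cM, lod = lod[, 1L],
                          effect = effect, stringsAsFactors = FALSE)
    qtl <- find_qtl(profile, thr, drop, min_separation_cM, alpha)
    if (nrow(qtl)) qtl$trait <- "joint"
    structure(list(profile = profile, threshold = thr, qtl = qtl, n = n,
                   families = st$families), class = "joint_scan")
  }
  if (n_perm * alpha < 1)
    stop_val("n_perm * alpha < 1: the (1 - alpha) quantile is unresolvable")
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.joint_scan <- function(x, ...) {
  pk <- x$profile[which.max(x$profile$lod), ]
  cat(sprintf(
    "Joint scan over %d families (n = %d): max LOD %.2f at %s %.1f cM; threshold %.2f\n",
    length(x$families), x$n, pk$lod, pk$chrom, pk$cM, x$threshold))
  if (nrow(x$qtl)) print(as.data.frame(x$qtl), row.names = FALSE)
  invisible(x)
}

#' Per-QTL allele-effect series across families
#'
#' For every locus of a joint model, tabulates the per-family allele
#' effects, the share of families in which the common parent's allele
#' increases the trait, and whether the effect direction is consistent
#' (both signs present flags an allelic series).
#'
#' @param model a `joint_model`.
#' @return data.frame with `chrom`, `cM`, `n_families`,
#'   `share_common_positive`, `consistent`.
#' @export
allele_effect_series <- function(model) {
  if (!nrow(model$effects))
    return(data.frame(chrom = character(), cM = numeric(),
                      n_families = integer(), share_common_positive = numeric(),
                      consistent = logical(), stringsAsFactors = FALSE))
  sp <- split(model$effects,
              paste(model$effects$chrom, model$effects$cM, sep = "@"))
  out <- do.call(rbind, lapply(sp, function(e) {
    ef <- e$effect[!is.na(e$effect)]
    data.frame(chrom = e$chrom[1L], cM = e$cM[1L], n_families = length(ef),
               share_common_positive = mean(ef > 0),
               consistent = !(any(ef > 0) && any(ef < 0)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
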