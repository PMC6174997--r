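# End-to-end synthetic NAM replay ---------------------------------------------

default_config <- function() {
  list(
    genome = list(
      chromosomes = data.frame(name = c("1A", "2A", "3A"), length_cM = 100,
                               stringsAsFactors = FALSE),
      markers_per_chrom = 101L),
    founders = list(n_founders = 4L, maf = 0.5, ibd_fraction = 0.10),
    families = list(n_rils = 100L, n_generations = 7L),
    modifiers = list(),
    noise = list(error_rate = 0.002, missing_rate = 0.02),
    phenotype = list(k = 2L, distal_fraction = 1/3, missing_threshold = 0.10),
    scan = list(alpha = 0.05, n_perm = 100L, window_cM = 10, step_cM = 1,
                drop = 2, min_separation_cM = 20),
    joint = list(p_enter = 1e-4, step_cM = 1, n_perm = 100L),
    load = list(bin_cM = 10, distal_pct = 10, n_snps = 5000L,
                enrichment_odds = 2, p_high = 0.06),
    traits = c("tco", "pco", "dco"),
    seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML configuration mirroring the arguments of the pipeline stages; any
#' omitted key falls back to the package default. The documented keys are
#' `genome` (`chromosomes`: list of `name`/`length_cM`/`centromere_cM`/
#' `length_Mb`/`genome`; `markers_per_chrom`), `founders` (`n_founders`,
#' `maf`, `ibd_fraction`), `families` (`n_rils`, `n_generations`),
#' `modifiers` (list of `chrom`, `cM`, `beta`, `scope`, `carriers`),
#' `noise`, `phenotype`, `scan`, `joint`, `load`, `traits`, `seed`.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$genome$chromosomes))
    cfg$genome$chromosomes <-
      do.call(rbind, lapply(cfg$genome$chromosomes, function(ch)
        data.frame(name = ch$name, length_cM = ch$length_cM,
                   centromere_cM = ch$centromere_cM %||% (ch$length_cM / 2),
                   genome = ch$genome %||% "A",
                   length_Mb = ch$length_Mb %||% NA_real_,
                   stringsAsFactors = FALSE)))
  cfg
}

merge_config <- function(cfg) {
  def <- default_config()
  for (k in names(def)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
    else if (is.list(def[[k]]) && !is.data.frame(def[[k]]))
      for (k2 in names(def[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- def[[k]][[k2]]
  }
  cfg
}

validate_config <- function(cfg, model) {
  a <- cfg$scan$alpha
  if (any(a <= 0 | a >= 1)) stop_val("scan alpha must lie in (0, 1)")
  if (cfg$scan$n_perm * min(a) < 1)
    stop_val("scan n_perm too small for alpha ", min(a),
             ": need n_perm >= ", ceiling(1 / min(a)))
  mods <- lapply(cfg$modifiers, function(m)
    if (inherits(m, "modifier_spec")) m else
      modifier_spec(m$chrom, m$cM, m$beta, m$scope %||% "global",
                    m$carriers, m$target_chrom %||% m$chrom))
  validate_modifiers(mods, model)
  mods
}

#' Run the full synthetic NAM analysis pipeline
#'
#' Executes every stage on a simulated NAM population with known ground
#' truth: genome/founder simulation, SSD family simulation with
#' recombination modifiers and genotyping noise, crossover calling and
#' phenotyping, single-family CIM scans for the requested traits with
#' permutation thresholds, joint stepwise mapping, cis/trans
#' classification of the detected TCO QTL, additivity analysis in families
#' with more than one QTL, region merging/overlap accounting, and the
#' deleterious-load / founder-LD / IBD contrasts. Fully deterministic for
#' a given seed.
#'
#' @param config configuration list (see [read_pipeline_config()]) or path
#'   to a YAML file; omitted keys use package defaults (3 families x 100
#'   F7 RILs on a 3 x 100 cM genome).
#' @param out_dir optional directory: all tables are written as TSV with a
#'   manifest via [write_results()].
#' @return object of class `nam_report`: named list of sections `config`,
#'   `map`, `phenotypes`, `family_qtl`, `joint`, `cis_trans`,
#'   `additivity`, `regions`, `load_ld_ibd`, `truth`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  cfg <- merge_config(cfg)
  model <- build_genome_model(cfg$genome$chromosomes,
                              cfg$genome$markers_per_chrom)
  mods <- validate_config(cfg, model)
  seeds <- derive_seeds(cfg$seed, 8L)
  part <- arm_partition(model, cfg$phenotype$distal_fraction)

  panel <- simulate_founders(model, cfg$founders$n_founders,
                             maf_law = cfg$founders$maf,
                             ibd_fraction = cfg$founders$ibd_fraction,
                             seed = seeds[1L])
  fams <- simulate_nam(panel, cfg$families$n_rils, cfg$families$n_generations,
                       mods, error_rate = cfg$noise$error_rate,
                       missing_rate = cfg$noise$missing_rate,
                       seed = seeds[2L])

  # phenotyping
  genome_of <- stats::setNames(model$chrom$genome, model$chrom$name)
  phen <- list(); cosets <- list()
  for (nm in names(fams)) {
    cos <- call_crossovers(fams[[nm]]$genos, k = cfg$phenotype$k)
    cosets[[nm]] <- cos
    phen[[nm]] <- summarize_phenotypes(cos, part, fams[[nm]]$genos,
                                       cfg$phenotype$missing_threshold)
  }
  all_cos <- do.call(rbind, lapply(names(cosets), function(nm) {
    d <- as.data.frame(cosets[[nm]])
    d$family <- rep(nm, nrow(d))
    d
  }))

  # single-family scans
  scan_seeds <- derive_seeds(seeds[3L], length(fams) * length(cfg$traits))
  qtl_rows <- list(); si <- 0L
  scans <- list()
  for (nm in names(fams)) {
    for (tr in cfg$traits) {
      si <- si + 1L
      y <- ifelse(phen[[nm]]$excluded, NA_real_, phen[[nm]][[tr]])
      fs <- tryCatch(
        scan_family(y, fams[[nm]]$genos, trait = tr,
                    window_cM = cfg$scan$window_cM,
                    step_cM = cfg$scan$step_cM, n_perm = cfg$scan$n_perm,
                    alpha = min(cfg$scan$alpha), drop = cfg$scan$drop,
                    min_separation_cM = cfg$scan$min_separation_cM,
                    seed = scan_seeds[si]),
        error = function(e) {
          warning("scan failed for family ", nm, " trait ", tr, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(fs)) next
      scans[[paste(nm, tr, sep = ".")]] <- fs
      if (nrow(fs$qtl)) {
        q <- fs$qtl; q$family <- nm
        qtl_rows[[length(qtl_rows) + 1L]] <- q
      }
    }
  }
  family_qtl <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    find_qtl(data.frame(chrom = character(), cM = numeric(), lod = numeric()),
             Inf)

  # joint mapping (TCO)
  jf <- lapply(names(fams), function(nm)
    list(genos = fams[[nm]]$genos,
         y = ifelse(phen[[nm]]$excluded, NA_real_, phen[[nm]]$tco)))
  names(jf) <- names(fams)
  jm <- joint_stepwise(jf, p_enter = cfg$joint$p_enter)
  js <- joint_scan(jf, step_cM = cfg$joint$step_cM,
                   n_perm = cfg$joint$n_perm, alpha = min(cfg$scan$alpha),
                   seed = seeds[4L])

  # cis/trans for detected TCO QTL
  ct_seeds <- derive_seeds(seeds[5L], max(1L, nrow(family_qtl)))
  cis_trans <- list()
  tcoq <- family_qtl[family_qtl$trait == "tco", , drop = FALSE]
  for (i in seq_len(nrow(tcoq))) {
    nm <- tcoq$family[i]
    cl <- tryCatch(
      classify_cis_trans(tcoq[i, ], fams[[nm]]$genos, cosets[[nm]], part,
                         trait = "tco", n_perm = cfg$scan$n_perm,
                         alpha = min(cfg$scan$alpha), seed = ct_seeds[i],
                         step_cM = cfg$scan$step_cM),
      error = function(e) NULL)
    if (!is.null(cl))
      cis_trans[[length(cis_trans) + 1L]] <- data.frame(
        family = nm, chrom = tcoq$chrom[i], peak_cM = tcoq$peak_cM[i],
        classification = cl$classification, stringsAsFactors = FALSE)
  }
  cis_trans <- if (length(cis_trans)) do.call(rbind, cis_trans) else
    data.frame(family = character(), chrom = character(),
               peak_cM = numeric(), classification = character(),
               stringsAsFactors = FALSE)

  # additivity in families with > 1 TCO QTL
  additivity <- list()
  for (nm in unique(tcoq$family)) {
    q <- tcoq[tcoq$family == nm, , drop = FALSE]
    if (nrow(q) < 2L) next
    y <- ifelse(phen[[nm]]$excluded, NA_real_, phen[[nm]]$tco)
    ad <- tryCatch(additivity_analysis(q, fams[[nm]]$genos, y),
                   error = function(e) NULL)
    if (!is.null(ad))
      additivity[[length(additivity) + 1L]] <- data.frame(
        family = nm, n_qtl = nrow(q), slope = ad$slope, r2 = ad$r2,
        p = ad$p, max_diff = ad$max_diff, stringsAsFactors = FALSE)
  }
  additivity <- if (length(additivity)) do.call(rbind, additivity) else
    data.frame(family = character(), n_qtl = integer(), slope = numeric(),
               r2 = numeric(), p = numeric(), max_diff = numeric(),
               stringsAsFactors = FALSE)

  # region merging and single-family vs joint overlap
  fam_regions <- if (nrow(tcoq))
    merge_regions(data.frame(chrom = tcoq$chrom, start = tcoq$ci_lo,
                             end = tcoq$ci_hi, family = tcoq$family,
                             stringsAsFactors = FALSE))
  else merge_regions(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  joint_regions <- if (nrow(js$qtl))
    merge_regions(data.frame(chrom = js$qtl$chrom, start = js$qtl$ci_lo,
                             end = js$qtl$ci_hi, family = "joint",
                             stringsAsFactors = FALSE))
  else merge_regions(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  ovl <- overlap_summary(joint_regions, fam_regions)

  # load / LD / IBD
  cos_all <- structure(all_cos, class = class(cosets[[1L]]),
                       rils = unique(unlist(lapply(cosets, attr, "rils"))),
                       chroms = model$chrom$name)
  bins <- recomb_bins(cos_all, model, cfg$load$bin_cM)
  bins <- define_high_recomb_regions(bins, cfg$load$distal_pct)
  ann <- simulate_annotation(bins, cfg$load$enrichment_odds,
                             cfg$load$n_snps, cfg$load$p_high,
                             seed = seeds[6L])
  load_res <- load_contrast(ann, bins)
  bins <- suppressMessages(ld_per_bin(panel, bins))
  ld_cor <- tryCatch(ld_recomb_correlation(bins), error = function(e)
    list(r = NA_real_, p = NA_real_, n_bins = 0L))
  ibd_res <- if (nrow(panel$ibd))
    tryCatch(ibd_co_contrast(cos_all, bins, panel$ibd),
             error = function(e) NULL)
  else NULL

  # truth vs estimate
  truth <- do.call(rbind, lapply(names(fams), function(nm) {
    data.frame(family = nm, mean_true_tco = mean(fams[[nm]]$truth$tco),
               mean_called_tco = mean(phen[[nm]]$tco),
               expected_f_inf = 2 * sum(model$chrom$length_cM) / 100,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config = cfg, map = map_summary(model$markers, genome_of),
    phenotypes = phen, family_qtl = family_qtl,
    joint = list(stepwise = jm, scan = js,
                 effect_series = allele_effect_series(jm)),
    cis_trans = cis_trans, additivity = additivity,
    regions = list(family = fam_regions, joint = joint_regions,
                   overlap = ovl),
    load_ld_ibd = list(bins = bins, contrast = load_res, ld = ld_cor,
                       ibd = ibd_res),
    truth = truth,
    scans = scans, crossovers = cosets, families = fams, panel = panel,
    partition = part), class = "nam_report")

  if (!is.null(out_dir)) {
    truth_bp <- do.call(rbind, lapply(names(fams), function(nm)
      cbind(family = nm, fams[[nm]]$truth$breakpoints)))
    truth_dos <- do.call(rbind, lapply(names(fams), function(nm) {
      d <- fams[[nm]]$truth$dosages
      if (!ncol(d)) return(NULL)
      data.frame(family = nm, ril = rep(rownames(d), ncol(d)),
                 modifier = rep(colnames(d), each = nrow(d)),
                 dosage = as.vector(d), stringsAsFactors = FALSE)
    }))
    tabs <- list(
      truth_breakpoints = truth_bp,
      truth_modifier_dosages = truth_dos %||%
        data.frame(family = character(), ril = character(),
                   modifier = character(), dosage = numeric()),
      ibd_tracts = panel$ibd,
      map_chromosomes = report$map$chromosomes,
      map_genomes = report$map$genomes,
      phenotypes = do.call(rbind, lapply(names(phen), function(nm)
        cbind(family = nm, as.data.frame(phen[[nm]])))),
      family_qtl = as.data.frame(family_qtl),
      joint_loci = jm$loci, joint_effects = jm$effects,
      joint_scan_qtl = as.data.frame(js$qtl),
      cis_trans = cis_trans, additivity = additivity,
      regions_family = as.data.frame(fam_regions),
      regions_joint = as.data.frame(joint_regions),
      bins = as.data.frame(bins), truth = truth)
    for (nm in names(fams))
      tabs[[paste0("map_", nm)]] <- fams[[nm]]$genos$markers
    write_results(tabs, out_dir)
    for (nm in names(fams))
      write_genotypes(fams[[nm]]$genos,
                      file.path(out_dir, paste0("genotypes_", nm, ".tsv")))
  }
  report
}

#' @export
print.nam_report <- function(x, ...) {
  cat("Synthetic NAM pipeline report\n")
  cat(sprintf("  families: %d x %d RILs, genome %.0f cM\n",
              length(x$phenotypes), nrow(x$phenotypes[[1L]]),
              sum(x$map$chromosomes$length_cM)))
  cat(sprintf("  mean called TCO: %.2f (F-infinity expectation %.1f)\n",
              mean(x$truth$mean_called_tco), x$truth$expected_f_inf[1L]))
  cat(sprintf("  single-family QTL: %d; joint loci: %d; trans calls: %d/%d\n",
              nrow(x$family_qtl), nrow(x$joint$stepwise$loci),
              sum(x$cis_trans$classification == "trans"), nrow(x$cis_trans)))
  cat(sprintf("  load contrast: prop(high) %.4f vs prop(low) %.4f, p = %.3g\n",
              x$load_ld_ibd$contrast$prop_high,
              x$load_ld_ibd$contrast$prop_low, x$load_ld_ibd$contrast$p))
  invisible(x)
}
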