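# Tabular formats ------------------------------------------------------------
#
# All on-disk formats are TSV, UTF-8, LF. Genotype calls use the single-
# character codes A (homozygous common parent), B (homozygous alternate
# founder), H (heterozygous), N (missing); internally these are the integers
# 0 / 2 / 1 / NA. Genetic coordinates are 0-based cM floats and all
# intervals are half-open [start, end).

GENO_CODES <- c(A = 0L, H = 1L, B = 2L)

#' Read a RIL genotype matrix
#'
#' Expects a TSV whose first column (`marker`) holds marker ids and whose
#' remaining header fields are RIL ids; cells are coded A/B/H/N. By default
#' heterozygous calls are re-coded to missing, the standard treatment for
#' near-inbred RILs where residual heterozygotes are rare and phase
#' information is what matters.
#'
#' @param path file path.
#' @param recode_het recode H to missing (default TRUE).
#' @param family,common,founder optional metadata attached to the object.
#' @param map optional map data.frame supplying `chrom`/`cM` per marker; if
#'   omitted the markers carry placeholder coordinates until a map is
#'   attached with [attach_map()].
#' @return a `ril_genotypes` object.
#' @export
load_genotypes <- function(path, recode_het = TRUE, family = basename(path),
                           common = "P1", founder = "P2", map = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop_val("genotype file has no data rows: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rils <- hdr[-1L]
  n <- length(rils)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n + 1L)
  if (length(bad))
    stop_val("ragged genotype row at line ", bad[1L] + 1L, " of ", path)
  markers <- vapply(rows, `[[`, character(1), 1L)
  dup <- markers[duplicated(markers)]
  if (length(dup))
    stop_val("duplicate marker id(s): ", paste(unique(dup), collapse = ", "))
  cells <- matrix(unlist(lapply(rows, `[`, -1L)), nrow = length(rows),
                  byrow = TRUE)
  unknown <- setdiff(unique(as.vector(cells)), c(names(GENO_CODES), "N"))
  if (length(unknown)) {
    ln <- which(apply(cells, 1L, function(z) any(z %in% unknown)))[1L]
    stop_val("unknown genotype code '", unknown[1L], "' at line ", ln + 1L,
             " of ", path)
  }
  g <- matrix(GENO_CODES[as.vector(cells)], nrow = nrow(cells))
  if (recode_het) g[g == 1L] <- NA_integer_
  mk <- if (!is.null(map)) {
    i <- match(markers, map$marker)
    if (anyNA(i)) stop_val("marker(s) absent from map: ",
                           paste(utils::head(markers[is.na(i)], 5), collapse = ", "))
    data.frame(marker = markers, chrom = map$chrom[i], cM = map$cM[i],
               stringsAsFactors = FALSE)
  } else {
    data.frame(marker = markers, chrom = "un", cM = seq_along(markers) - 1,
               stringsAsFactors = FALSE)
  }
  new_ril_genotypes(family, common, founder, mk, g, rils)
}

#' Write a RIL genotype matrix
#'
#' Inverse of [load_genotypes()] (up to H calls already recoded to N):
#' writing and re-reading is the identity.
#'
#' @param genos a `ril_genotypes` object.
#' @param path output file.
#' @export
write_genotypes <- function(genos, path) {
  sym <- c("A", "H", "B")
  cells <- matrix(ifelse(is.na(genos$geno), "N", sym[genos$geno + 1L]),
                  nrow = nrow(genos$geno))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("marker", genos$rils), collapse = "\t"),
               vapply(seq_len(nrow(cells)), function(i)
                 paste(c(genos$markers$marker[i], cells[i, ]), collapse = "\t"),
                 character(1))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a genetic map table
#'
#' TSV with columns `marker`, `chrom`, `cM` and optionally `Mb`, `bin`.
#' Positions must be non-decreasing within each chromosome unless
#' `auto_sort` is set.
#'
#' @param path file path.
#' @param auto_sort sort positions within chromosome instead of erroring on
#'   unsorted input.
#' @return data.frame sorted by chromosome and position.
#' @export
load_map <- function(path, auto_sort = FALSE) {
  mp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% names(mp)))
    stop_val("map needs columns ", paste(need, collapse = ", "))
  if (!is.numeric(mp$cM)) stop_val("map column 'cM' is not numeric")
  if (anyDuplicated(mp$marker))
    stop_val("duplicate marker id(s) in map")
  for (nm in unique(mp$chrom)) {
    sel <- mp$chrom == nm
    if (is.unsorted(mp$cM[sel])) {
      if (!auto_sort) stop_val("unsorted positions on chromosome ", nm,
                               " (set auto_sort = TRUE to sort)")
      mp[sel, ] <- mp[sel, ][order(mp$cM[sel]), ]
    }
  }
  mp[order(match(mp$chrom, unique(mp$chrom))), , drop = FALSE]
}

#' Attach map coordinates to a genotype object
#'
#' Resolves every genotype marker against a map table, erroring with the
#' names of unresolvable markers, and orders markers by map position.
#'
#' @param genos a `ril_genotypes` object.
#' @param map a map data.frame as from [load_map()].
#' @return a `ril_genotypes` with chromosome/cM coordinates set.
#' @export
attach_map <- function(genos, map) {
  i <- match(genos$markers$marker, map$marker)
  if (anyNA(i))
    stop_val("genotype marker(s) absent from map: ",
             paste(utils::head(genos$markers$marker[is.na(i)], 5),
                   collapse = ", "))
  mk <- data.frame(marker = genos$markers$marker, chrom = map$chrom[i],
                   cM = map$cM[i], stringsAsFactors = FALSE)
  o <- order(match(mk$chrom, unique(map$chrom)), mk$cM)
  new_ril_genotypes(genos$family, genos$common, genos$founder,
                    mk[o, , drop = FALSE], genos$geno[o, , drop = FALSE],
                    genos$rils)
}

#' Write a set of result tables with a manifest
#'
#' Writes every table as TSV with a deterministic column order, floats at
#' fixed precision (6 significant digits), and a `MANIFEST.tsv` listing each
#' file with its row count. Re-running on identical inputs yields
#' byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_val("cannot create output directory: ", out_dir)
  stopifnot(length(names(tables)) == length(tables))
  fmt <- function(x) {
    if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  }
  manifest <- data.frame(file = character(), rows = integer(),
                         stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    fn <- paste0(nm, ".tsv")
    cols <- lapply(tb, fmt)
    lines <- c(paste(names(tb), collapse = "\t"),
               if (nrow(tb)) do.call(paste, c(cols, sep = "\t")))
    con <- file(file.path(out_dir, fn), open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    manifest <- rbind(manifest, data.frame(file = fn, rows = nrow(tb),
                                           stringsAsFactors = FALSE))
  }
  con <- file(file.path(out_dir, "MANIFEST.tsv"), open = "wb")
  writeLines(c("file\trows", paste(manifest$file, manifest$rows, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(manifest)
}
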