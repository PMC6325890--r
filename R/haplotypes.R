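#' Generate a founder haplotype panel
#'
#' Builds the base population haplotype panel from which all founders are
#' sampled: a set of phased biallelic haplotypes per chromosome, with genetic
#' map positions in Morgans. Per-locus allele frequencies are drawn from a
#' configurable spectrum and alleles are then assigned independently per
#' haplotype; loci that come out monomorphic are resampled so that every locus
#' in the panel segregates.
#'
#' The default spectrum, `"neutral-sfs"`, has density proportional to `1/x` on
#' a truncated frequency interval, the classical neutral site-frequency
#' spectrum shape. `"uniform"` draws frequencies uniformly on the same
#' interval and `"beta"` from a truncated Beta(`beta_shape1`, `beta_shape2`).
#' The truncation interval is `[1/(2H), 1 - 1/(2H)]` for `H` haplotypes.
#'
#' @param n_haplotypes Number of base haplotypes per chromosome (>= 2).
#' @param n_chromosomes Number of chromosomes.
#' @param loci_per_chromosome Number of segregating loci per chromosome.
#' @param frequency_model Allele-frequency spectrum: `"neutral-sfs"`,
#'   `"uniform"` or `"beta"`.
#' @param beta_shape1,beta_shape2 Shape parameters for the `"beta"` spectrum.
#' @param chromosome_length Genetic length of each chromosome in Morgans.
#' @param max_retries Maximum number of redraws for a locus that comes out
#'   monomorphic before failing.
#' @param meta Optional named list of free-form metadata recorded on the
#'   panel (e.g. an effective-population-size history or mutation rate that
#'   the frequency spectrum is meant to emulate).
#' @return An object of class `hap_panel`: a list with `alleles` (one
#'   `n_haplotypes x loci` 0/1 matrix per chromosome), `map` (one vector of
#'   Morgan positions per chromosome), and `chromosome_length`.
#' @export
#' @examples
#' set.seed(1)
#' panel <- sim_haplotype_panel(20, 2, 50)
#' panel
sim_haplotype_panel <- function(n_haplotypes = 400,
                                n_chromosomes = 10,
                                loci_per_chromosome = 1000,
                                frequency_model = c("neutral-sfs", "uniform", "beta"),
                                beta_shape1 = 0.5,
                                beta_shape2 = 0.5,
                                chromosome_length = 1,
                                max_retries = 100L,
                                meta = list()) {
  n_haplotypes <- .check_count(n_haplotypes, "n_haplotypes", min = 2L)
  n_chromosomes <- .check_count(n_chromosomes, "n_chromosomes")
  loci_per_chromosome <- .check_count(loci_per_chromosome, "loci_per_chromosome")
  frequency_model <- match.arg(frequency_model)
  stopifnot(chromosome_length >= 0)

  alleles <- vector("list", n_chromosomes)
  map <- vector("list", n_chromosomes)
  for (chr in seq_len(n_chromosomes)) {
    map[[chr]] <- .sim_map(loci_per_chromosome, chromosome_length)
    alleles[[chr]] <- .sim_alleles(
      n_haplotypes, loci_per_chromosome, frequency_model,
      beta_shape1, beta_shape2, max_retries
    )
  }
  names(alleles) <- names(map) <- paste0("chr", seq_len(n_chromosomes))
  new_hap_panel(alleles, map, chromosome_length,
    frequency_model = frequency_model, meta = meta
  )
}

.sim_map <- function(n_loci, len) {
  if (len == 0) {
    if (n_loci > 1) {
      abort("a chromosome of genetic length 0 can carry at most one locus")
    }
    return(0)
  }
  pos <- sort(runif(n_loci, 0, len))
  while (anyDuplicated(pos)) pos <- sort(runif(n_loci, 0, len))
  pos
}

.sample_freq <- function(n, model, lo, hi, s1, s2) {
  switch(model,
    "neutral-sfs" = lo * (hi / lo)^runif(n),
    "uniform" = runif(n, lo, hi),
    "beta" = qbeta(runif(n, pbeta(lo, s1, s2), pbeta(hi, s1, s2)), s1, s2)
  )
}

#' Density of a panel's allele-frequency spectrum
#'
#' Direct numeric evaluation of the spectrum density used by
#' [sim_haplotype_panel()], on the truncated support `[1/(2H), 1 - 1/(2H)]`.
#' Useful for checking the realised frequency distribution of a panel.
#'
#' @param x Frequencies at which to evaluate the density.
#' @param n_haplotypes Panel size defining the truncation interval.
#' @inheritParams sim_haplotype_panel
#' @return Density values, zero outside the support.
#' @export
frequency_spectrum_density <- function(x, n_haplotypes = 400,
                                       frequency_model = c("neutral-sfs", "uniform", "beta"),
                                       beta_shape1 = 0.5, beta_shape2 = 0.5) {
  frequency_model <- match.arg(frequency_model)
  lo <- 1 / (2 * n_haplotypes)
  hi <- 1 - lo
  d <- switch(frequency_model,
    "neutral-sfs" = 1 / (x * log(hi / lo)),
    "uniform" = rep(1 / (hi - lo), length(x)),
    "beta" = stats::dbeta(x, beta_shape1, beta_shape2) /
      (pbeta(hi, beta_shape1, beta_shape2) - pbeta(lo, beta_shape1, beta_shape2))
  )
  d[x < lo | x > hi] <- 0
  d
}

.sim_alleles <- function(n_hap, n_loci, model, s1, s2, max_retries) {
  lo <- 1 / (2 * n_hap)
  hi <- 1 - lo
  draw <- function(k) {
    f <- .sample_freq(k, model, lo, hi, s1, s2)
    matrix(rbinom(n_hap * k, 1L, rep(f, each = n_hap)), nrow = n_hap, ncol = k)
  }
  m <- draw(n_loci)
  for (try in seq_len(max_retries)) {
    cs <- colSums(m)
    mono <- which(cs == 0L | cs == n_hap)
    if (length(mono) == 0) return(m)
    m[, mono] <- draw(length(mono))
  }
  cs <- colSums(m)
  if (any(cs == 0L | cs == n_hap)) {
    abort("failed to obtain a segregating locus within `max_retries` redraws")
  }
  m
}

new_hap_panel <- function(alleles, map, chromosome_length,
                          frequency_model = NA_character_, meta = list()) {
  structure(
    list(
      alleles = alleles, map = map,
      chromosome_length = chromosome_length,
      frequency_model = frequency_model, meta = meta
    ),
    class = "hap_panel"
  )
}

#' Validate the invariants of a haplotype panel
#'
#' Checks that alleles are 0/1, every locus segregates, and map positions are
#' strictly increasing and bounded by the chromosome length. Called by the
#' constructors and the importer; errors on the first violation.
#'
#' @param panel A `hap_panel`.
#' @return The panel, invisibly.
#' @export
validate_hap_panel <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  if (length(panel$alleles) != length(panel$map)) {
    abort("panel has mismatched `alleles` and `map` lengths")
  }
  for (chr in seq_along(panel$alleles)) {
    a <- panel$alleles[[chr]]
    pos <- panel$map[[chr]]
    if (ncol(a) != length(pos)) {
      abort(sprintf("chromosome %d: allele matrix and map disagree on locus count", chr))
    }
    if (!all(a == 0L | a == 1L)) {
      abort(sprintf("chromosome %d: alleles must all be 0 or 1", chr))
    }
    cs <- colSums(a)
    if (any(cs == 0L | cs == nrow(a))) {
      abort(sprintf("chromosome %d: non-segregating locus present", chr))
    }
    if (length(pos) > 1 && any(diff(pos) <= 0)) {
      abort(sprintf("chromosome %d: map positions must be strictly increasing", chr))
    }
    if (any(pos < 0) || any(pos > panel$chromosome_length)) {
      abort(sprintf("chromosome %d: map positions outside [0, chromosome_length]", chr))
    }
  }
  invisible(panel)
}

#' @export
print.hap_panel <- function(x, ...) {
  nl <- vapply(x$alleles, ncol, integer(1))
  cat(sprintf(
    "<hap_panel> %d haplotypes, %d chromosomes (%s loci), %.3g Morgan each\n",
    nrow(x$alleles[[1]]), length(x$alleles),
    if (length(unique(nl)) == 1) as.character(nl[1]) else paste(range(nl), collapse = "-"),
    x$chromosome_length
  ))
  if (!is.na(x$frequency_model)) {
    cat(sprintf("  frequency model: %s\n", x$frequency_model))
  }
  invisible(x)
}

#' Number of haplotypes, chromosomes and loci of a panel
#'
#' @param panel A `hap_panel`.
#' @return A named list with `n_haplotypes`, `n_chromosomes` and `n_loci`
#'   (per-chromosome vector).
#' @export
panel_dim <- function(panel) {
  list(
    n_haplotypes = nrow(panel$alleles[[1]]),
    n_chromosomes = length(panel$alleles),
    n_loci = vapply(panel$alleles, ncol, integer(1))
  )
}

#' Write a haplotype panel to plain-text files
#'
#' The haplotype matrix file has one header row of locus ids
#' (`<chrom>_<index>`) and one whitespace-delimited row of 0/1 alleles per
#' haplotype. The companion map file has three columns: chromosome, locus id,
#' and position in centimorgans.
#'
#' @param panel A `hap_panel`.
#' @param path Path for the haplotype matrix file.
#' @param map_path Path for the companion map file.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path, map_path) {
  chrs <- names(panel$alleles) %||% paste0("chr", seq_along(panel$alleles))
  ids <- unlist(lapply(seq_along(chrs), function(i) {
    paste0(chrs[i], "_", seq_along(panel$map[[i]]))
  }))
  m <- do.call(cbind, panel$alleles)
  colnames(m) <- ids
  write.table(m,
    file = path, quote = FALSE, sep = " ",
    row.names = FALSE, col.names = TRUE
  )
  map <- data.frame(
    chrom = rep(chrs, vapply(panel$map, length, integer(1))),
    id = ids,
    cM = unlist(panel$map) * 100
  )
  write.table(map,
    file = map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Import founder haplotypes from a file
#'
#' Reads a phased haplotype panel either from a plain 0/1 haplotype matrix
#' (rows = haplotypes, header row of locus ids; genetic positions from a
#' companion map file as written by [write_haplotypes()]) or from a phased
#' diploid VCF (two haplotypes per sample; genotypes must use the phased
#' separator `|`). Loci that do not segregate in the imported panel are
#' dropped with a message; the number of dropped loci is recorded in the
#' `dropped_loci` attribute.
#'
#' @param path Path to the haplotype matrix or VCF file.
#' @param format `"matrix"` or `"vcf"`.
#' @param map For `"matrix"`, path to the companion map file (required).
#'   For `"vcf"`, optional: when absent, physical positions are converted to
#'   Morgans at 1 cM/Mb.
#' @param chromosome_length Genetic chromosome length in Morgans; defaults to
#'   the smallest round Morgan count covering the map.
#' @return A validated `hap_panel`.
#' @export
import_haplotypes <- function(path, format = c("matrix", "vcf"), map = NULL,
                              chromosome_length = NULL) {
  format <- match.arg(format)
  switch(format,
    matrix = .import_hap_matrix(path, map, chromosome_length),
    vcf = .import_hap_vcf(path, map, chromosome_length)
  )
}

.drop_monomorphic <- function(alleles, map) {
  dropped <- 0L
  for (chr in seq_along(alleles)) {
    cs <- colSums(alleles[[chr]])
    keep <- cs > 0L & cs < nrow(alleles[[chr]])
    dropped <- dropped + sum(!keep)
    alleles[[chr]] <- alleles[[chr]][, keep, drop = FALSE]
    map[[chr]] <- map[[chr]][keep]
  }
  if (dropped > 0) {
    message(sprintf("import_haplotypes: dropped %d non-segregating locus/loci", dropped))
  }
  empty <- vapply(alleles, ncol, integer(1)) == 0L
  if (any(empty)) {
    alleles <- alleles[!empty]
    map <- map[!empty]
  }
  list(alleles = alleles, map = map, dropped = dropped)
}

.finish_import <- function(alleles, map, chromosome_length, dropped) {
  if (length(alleles) == 0) abort("no segregating loci left after import")
  len <- chromosome_length %||% max(1, ceiling(max(unlist(map))))
  panel <- new_hap_panel(alleles, map, len)
  attr(panel, "dropped_loci") <- dropped
  validate_hap_panel(panel)
  panel
}

.import_hap_matrix <- function(path, map, chromosome_length) {
  if (is.null(map)) abort("`map` (companion map file) is required for format = \"matrix\"")
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE))
  if (!all(m == 0 | m == 1)) {
    bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "haplotype matrix entry at row %d, locus '%s' is not 0/1",
      bad[1], colnames(m)[bad[2]]
    ))
  }
  storage.mode(m) <- "integer"
  mp <- read.table(map, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(mp) < 3) abort("map file must have 3 columns: chrom, id, cM")
  names(mp)[1:3] <- c("chrom", "id", "cM")
  missing <- setdiff(colnames(m), mp$id)
  if (length(missing) > 0) {
    abort(sprintf("locus '%s' missing from the map file", missing[1]))
  }
  mp <- mp[match(colnames(m), mp$id), ]
  chrs <- unique(mp$chrom)
  alleles <- lapply(chrs, function(ch) {
    sel <- which(mp$chrom == ch)
    sel <- sel[order(mp$cM[sel])]
    m[, sel, drop = FALSE]
  })
  pos <- lapply(chrs, function(ch) sort(mp$cM[mp$chrom == ch]) / 100)
  names(alleles) <- names(pos) <- as.character(chrs)
  d <- .drop_monomorphic(alleles, pos)
  .finish_import(d$alleles, d$map, chromosome_length, d$dropped)
}

.import_hap_vcf <- function(path, map, chromosome_length) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required to import VCF haplotypes")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  site_id <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  biallelic <- !grepl(",", fix[, "ALT"])
  if (any(!biallelic)) {
    message(sprintf("import_haplotypes: dropped %d non-biallelic site(s)", sum(!biallelic)))
    gt <- gt[biallelic, , drop = FALSE]
    fix <- fix[biallelic, , drop = FALSE]
    site_id <- site_id[biallelic]
  }
  bad <- !grepl("^[01]\\|[01]$", gt)
  dim(bad) <- dim(gt)
  unphased <- which(bad, arr.ind = TRUE)
  if (nrow(unphased) > 0) {
    i <- unphased[1, 1]
    j <- unphased[1, 2]
    abort(sprintf(
      "unphased or non-diploid genotype '%s' at site %s (sample %s)",
      gt[i, j], site_id[i], colnames(gt)[j]
    ))
  }
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  # rows = haplotypes: sample1 hap1, sample1 hap2, sample2 hap1, ...
  haps <- matrix(0L, nrow = 2 * ncol(gt), ncol = nrow(gt))
  haps[seq(1, nrow(haps), by = 2), ] <- t(h1)
  haps[seq(2, nrow(haps), by = 2), ] <- t(h2)

  chrom <- fix[, "CHROM"]
  bp <- as.numeric(fix[, "POS"])
  if (!is.null(map)) {
    mp <- read.table(map, header = TRUE, stringsAsFactors = FALSE)
    names(mp)[1:3] <- c("chrom", "id", "cM")
    key <- match(site_id, mp$id)
    if (anyNA(key)) abort(sprintf("site '%s' missing from the map file", site_id[which(is.na(key))[1]]))
    pos_m <- mp$cM[key] / 100
  } else {
    pos_m <- bp * 1e-8 # 1 cM/Mb
  }
  chrs <- unique(chrom)
  alleles <- lapply(chrs, function(ch) {
    sel <- which(chrom == ch)
    sel <- sel[order(pos_m[sel])]
    haps[, sel, drop = FALSE]
  })
  pos <- lapply(chrs, function(ch) sort(pos_m[chrom == ch]))
  names(alleles) <- names(pos) <- as.character(chrs)
  d <- .drop_monomorphic(alleles, pos)
  .finish_import(d$alleles, d$map, chromosome_length, d$dropped)
}
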