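#' Cohorts of diploid individuals
#'
#' A `cohort` holds a set of diploid individuals of one generation: per
#' chromosome, one matrix of maternally inherited and one of paternally
#' inherited haplotypes (rows = individuals), plus sex, id and, once
#' computed, the true breeding value of each individual. An "individual" is
#' simply a cohort of size one, so all gene-drop operations share one
#' representation.
#'
#' @param maternal,paternal Lists (one per chromosome) of 0/1 allele
#'   matrices, rows = individuals.
#' @param sex Character vector, `"male"`/`"female"`.
#' @param id Character vector of unique ids.
#' @param generation Integer generation index.
#' @param tbv Optional numeric vector of true breeding values.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(maternal, paternal, sex, id, generation, tbv = NULL) {
  structure(
    list(
      maternal = maternal, paternal = paternal,
      sex = sex, id = id,
      generation = as.integer(generation), tbv = tbv
    ),
    class = "cohort"
  )
}

#' @rdname new_cohort
#' @param cohort A `cohort`.
#' @export
cohort_size <- function(cohort) length(cohort$id)

#' Validate cohort invariants
#'
#' Both gamete sets must cover identical locus sets and row counts must agree
#' with the number of individuals.
#'
#' @param cohort A `cohort`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- cohort_size(cohort)
  if (length(cohort$maternal) != length(cohort$paternal)) {
    abort("maternal and paternal gametes cover different chromosome sets")
  }
  for (chr in seq_along(cohort$maternal)) {
    if (!identical(dim(cohort$maternal[[chr]]), dim(cohort$paternal[[chr]]))) {
      abort(sprintf("chromosome %d: maternal/paternal locus sets differ", chr))
    }
    if (nrow(cohort$maternal[[chr]]) != n) {
      abort(sprintf("chromosome %d: haplotype rows do not match cohort size", chr))
    }
  }
  if (length(cohort$sex) != n || !all(cohort$sex %in% c("male", "female"))) {
    abort("`sex` must be 'male'/'female' for every individual")
  }
  if (anyDuplicated(cohort$id)) abort("individual ids must be unique")
  invisible(cohort)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> generation %d: %d individuals (%d male, %d female), %d chromosomes\n",
    x$generation, cohort_size(x), sum(x$sex == "male"), sum(x$sex == "female"),
    length(x$maternal)
  ))
  if (!is.null(x$tbv)) {
    cat(sprintf("  TBV: mean %.4f, sd %.4f\n", mean(x$tbv), sd(x$tbv)))
  }
  invisible(x)
}

#' Extract a subset of individuals from a cohort
#'
#' @param cohort A `cohort`.
#' @param i Row indices, logical mask, or ids.
#' @return A `cohort` with the selected individuals.
#' @export
cohort_subset <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$id)
  new_cohort(
    maternal = lapply(cohort$maternal, function(m) m[i, , drop = FALSE]),
    paternal = lapply(cohort$paternal, function(m) m[i, , drop = FALSE]),
    sex = cohort$sex[i], id = cohort$id[i],
    generation = cohort$generation,
    tbv = if (!is.null(cohort$tbv)) cohort$tbv[i]
  )
}

#' Sample founder individuals from a haplotype panel
#'
#' Each founder draws, independently for every chromosome, two haplotypes
#' uniformly with replacement from the panel. This is how the base
#' generation of the nucleus is constituted from the base haplotypes.
#'
#' @param panel A `hap_panel`.
#' @param n Number of founders.
#' @param generation Generation index to stamp on the cohort.
#' @param sex Optional sex vector; default alternates male/female so the
#'   cohort has an exact half-half split when `n` is even.
#' @param id Optional id vector.
#' @return A `cohort` of founders.
#' @export
#' @examples
#' set.seed(1)
#' p <- sim_haplotype_panel(10, 2, 20)
#' founders <- sample_founders(p, 6, generation = -22)
#' founders
sample_founders <- function(panel, n, generation = -22L, sex = NULL, id = NULL) {
  n <- .check_count(n, "n")
  dim <- panel_dim(panel)
  sex <- sex %||% rep_len(c("male", "female"), n)
  id <- id %||% sprintf("G%d_%d", generation, seq_len(n))
  pick <- function() lapply(panel$alleles, function(a) {
    a[sample.int(nrow(a), n, replace = TRUE), , drop = FALSE]
  })
  cohort <- new_cohort(
    maternal = pick(), paternal = pick(),
    sex = sex, id = id, generation = generation
  )
  validate_cohort(cohort)
}

#' @rdname sample_founders
#' @param panel A `hap_panel`.
#' @param single_id,single_sex Id and sex for the single founder.
#' @export
sample_founder <- function(panel, single_id, single_sex, generation = -22L) {
  sample_founders(panel, 1L, generation = generation, sex = single_sex, id = single_id)
}

# Meiosis for a batch of gametes on one chromosome (compiled kernel).
#
# M, P: parental haplotype matrices (rows = parents); pos: Morgan positions;
# len: chromosome length in Morgans; rows: parent row per gamete (one gamete
# per entry, so repeated rows give independent meioses).
.meiosis <- function(M, P, pos, len, rows) {
  storage.mode(M) <- "integer"
  storage.mode(P) <- "integer"
  .meiosis_cpp(M, P, as.numeric(pos), len, as.integer(rows))
}

# Pure-R reference implementation of the same sampling scheme, retained as
# an independent check of the compiled kernel.
.meiosis_r <- function(M, P, pos, len, rows) {
  n <- length(rows)
  L <- length(pos)
  Mi <- M[rows, , drop = FALSE]
  Pi <- P[rows, , drop = FALSE]
  start <- sample.int(2L, n, replace = TRUE) - 1L
  k <- if (len > 0) rpois(n, len) else integer(n)
  switches <- matrix(0L, n, L)
  for (kk in unique(k[k > 0L])) {
    idx <- which(k == kk)
    cx <- matrix(runif(length(idx) * kk, 0, len), length(idx), kk)
    cnt <- matrix(0L, length(idx), L)
    for (j in seq_len(kk)) {
      cnt <- cnt + outer(cx[, j], pos, "<")
    }
    switches[idx, ] <- cnt
  }
  use_pat <- (start + switches) %% 2L == 1L
  out <- Mi
  out[use_pat] <- Pi[use_pat]
  out
}

#' Form a gamete from a parent by meiosis
#'
#' Per chromosome, the number of crossovers is Poisson with mean equal to the
#' chromosome's genetic length in Morgans, crossover positions are uniform on
#' the genetic map (no interference), and the starting parental haplotype is
#' chosen with probability 1/2.
#'
#' @param parent A `cohort`; the gamete is formed from individual `which`.
#' @param map List of Morgan position vectors, one per chromosome.
#' @param chromosome_length Genetic chromosome length in Morgans.
#' @param which Index of the parent within the cohort.
#' @return A list with one allele vector per chromosome (class `gamete`).
#' @export
make_gamete <- function(parent, map, chromosome_length, which = 1L) {
  stopifnot(inherits(parent, "cohort"))
  g <- lapply(seq_along(parent$maternal), function(chr) {
    drop(.meiosis(
      parent$maternal[[chr]], parent$paternal[[chr]],
      map[[chr]], chromosome_length, rows = which
    ))
  })
  names(g) <- names(parent$maternal)
  structure(g, class = "gamete")
}

# Batch offspring construction: one maternal gamete from dams[dam_rows],
# one paternal gamete from sires[sire_rows].
.make_offspring <- function(dams, sires, dam_rows, sire_rows, sexes, map,
                            chromosome_length, generation, id = NULL) {
  n <- length(dam_rows)
  stopifnot(length(sire_rows) == n, length(sexes) == n)
  maternal <- vector("list", length(dams$maternal))
  paternal <- vector("list", length(dams$maternal))
  for (chr in seq_along(maternal)) {
    maternal[[chr]] <- .meiosis(
      dams$maternal[[chr]], dams$paternal[[chr]],
      map[[chr]], chromosome_length, dam_rows
    )
    paternal[[chr]] <- .meiosis(
      sires$maternal[[chr]], sires$paternal[[chr]],
      map[[chr]], chromosome_length, sire_rows
    )
  }
  names(maternal) <- names(paternal) <- names(dams$maternal)
  new_cohort(
    maternal = maternal, paternal = paternal,
    sex = sexes, id = id %||% sprintf("G%d_%d", generation, seq_len(n)),
    generation = generation
  )
}

#' Mate a dam and a sire
#'
#' Each offspring receives one freshly formed gamete from each parent. With
#' the `"alternating"` sex policy, offspring sexes alternate male, female,
#' male, ... so a litter of two contains exactly one of each sex.
#'
#' @param dam,sire Single-individual `cohort`s (female and male).
#' @param n_offspring Litter size.
#' @param map List of Morgan position vectors per chromosome.
#' @param chromosome_length Genetic chromosome length in Morgans.
#' @param sex_assignment `"alternating"` or `"random"`.
#' @param generation Generation stamp for the offspring (default: dam's + 1).
#' @return A `cohort` of offspring.
#' @export
mate <- function(dam, sire, n_offspring, map, chromosome_length,
                 sex_assignment = c("alternating", "random"),
                 generation = NULL) {
  sex_assignment <- match.arg(sex_assignment)
  if (!all(dam$sex == "female")) abort("`dam` must be female")
  if (!all(sire$sex == "male")) abort("`sire` must be male")
  n_offspring <- .check_count(n_offspring, "n_offspring")
  generation <- generation %||% (dam$generation + 1L)
  sexes <- switch(sex_assignment,
    alternating = rep_len(c("male", "female"), n_offspring),
    random = sample(c("male", "female"), n_offspring, replace = TRUE)
  )
  .make_offspring(
    dams = dam, sires = sire,
    dam_rows = rep(1L, n_offspring), sire_rows = rep(1L, n_offspring),
    sexes = sexes, map = map, chromosome_length = chromosome_length,
    generation = generation
  )
}
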