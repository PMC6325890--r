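#' Advance a nucleus cohort by one generation
#'
#' One cycle of recurrent genomic selection: all males are evaluated with a
#' fresh genomic pseudo-test at `genomic_accuracy`, the best `n_sires` become
#' the sires of the next generation, and every female is kept as a dam. Each
#' dam is mated once, to a sire drawn uniformly at random from the selected
#' sires, and contributes exactly `cohort_size / n_dams` offspring (two, in
#' the standard configurations). Offspring sexes alternate so every
#' generation has an exact half-half sex split.
#'
#' @param cohort Current `cohort`, with an exact sex split.
#' @param architecture A `trait_arch` (used to compute offspring TBVs).
#' @param map Genetic map (list of Morgan position vectors per chromosome).
#' @param chromosome_length Chromosome length in Morgans.
#' @param n_sires Number of sires selected (default 50).
#' @param genomic_accuracy Accuracy of the genomic test used for parent
#'   selection.
#' @param cohort_size Size of the next generation; default: same as current.
#' @return A list with `cohort` (the next generation, TBVs filled in),
#'   `sire_id` and `sire_mean_tbv` (the selected sires and their mean TBV).
#' @export
advance_generation <- function(cohort, architecture, map, chromosome_length,
                               n_sires = 50L, genomic_accuracy = 0.5,
                               cohort_size = NULL) {
  n_sires <- .check_count(n_sires, "n_sires")
  cohort <- add_tbv(cohort, architecture)
  male_rows <- which(cohort$sex == "male")
  dam_rows <- which(cohort$sex == "female")
  if (length(male_rows) < n_sires) {
    abort(sprintf(
      "cannot select %d sires from %d males", n_sires, length(male_rows)
    ))
  }
  cohort_size <- cohort_size %||% cohort_size(cohort)
  n_dams <- length(dam_rows)
  off_per_dam <- cohort_size / n_dams
  if (off_per_dam != round(off_per_dam)) {
    abort("`cohort_size` must be a multiple of the number of dams")
  }

  test <- pseudo_ebv(
    setNames(cohort$tbv[male_rows], cohort$id[male_rows]),
    genomic_accuracy,
    stage = "parent-selection"
  )
  sire_rows <- male_rows[.top_idx(test$ebv, test$id, n_sires)]

  # one sire per dam's litter, drawn uniformly from the selected sires
  sire_of_dam <- sire_rows[sample.int(n_sires, n_dams, replace = TRUE)]
  dam_rep <- rep(dam_rows, each = off_per_dam)
  sire_rep <- rep(sire_of_dam, each = off_per_dam)
  sexes <- rep_len(c("male", "female"), cohort_size)

  nxt <- .make_offspring(
    dams = cohort, sires = cohort,
    dam_rows = dam_rep, sire_rows = sire_rep, sexes = sexes,
    map = map, chromosome_length = chromosome_length,
    generation = cohort$generation + 1L
  )
  nxt <- add_tbv(nxt, architecture)
  list(
    cohort = nxt,
    sire_id = cohort$id[sire_rows],
    sire_mean_tbv = mean(cohort$tbv[sire_rows])
  )
}

#' Run the recurrent-selection nucleus
#'
#' Simulates the nucleus breeding program: founders at `first_generation`
#' are sampled from the base haplotype panel, then each generation 50 sires
#' (by genomic pseudo-test) and all dams are selected and mated until
#' `last_generation`. Generations `first_generation + 1, ..., 0` are the
#' historical phase; generations `1, ..., last_generation` are the future
#' phase in which dissemination strategies are compared. Merit is expressed
#' in units of the `base_generation` cohort's TBV standard deviation,
#' centred on that cohort's mean (the standardisation is frozen there).
#'
#' Per-generation male TBVs are retained so that dissemination strategies
#' (which test and select among nucleus males) can be evaluated after the
#' run without storing genomes; set `keep_cohorts = TRUE` to keep full
#' cohorts (memory-hungry at scale).
#'
#' @param panel A `hap_panel` of founder haplotypes.
#' @param architecture A `trait_arch`.
#' @param cohort_size Individuals per generation (1,000 small / 5,000 big).
#' @param n_sires Sires selected per generation.
#' @param genomic_accuracy Accuracy of the genomic test.
#' @param first_generation,last_generation Generation range; the default
#'   -22..20 gives 42 generations of selection.
#' @param base_generation Generation whose cohort defines the merit scale.
#' @param keep_cohorts Keep full cohorts? Default `FALSE`.
#' @param seed Optional seed set at the start of the run.
#' @return An object of class `nucleus_run`: `generations` (a tibble of
#'   per-generation summaries), `male_tbvs` (named list of per-generation
#'   male TBV vectors), `base` (a `base_scale`), `params`, and optionally
#'   `cohorts`.
#' @export
#' @examples
#' set.seed(1)
#' p <- sim_haplotype_panel(40, 3, 50)
#' a <- sim_trait_architecture(p)
#' run <- run_nucleus(p, a,
#'   cohort_size = 100, n_sires = 10,
#'   first_generation = -4, last_generation = 4, base_generation = 0
#' )
#' run
run_nucleus <- function(panel, architecture, cohort_size = 1000L,
                        n_sires = 50L, genomic_accuracy = 0.5,
                        first_generation = -22L, last_generation = 20L,
                        base_generation = 0L, keep_cohorts = FALSE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(first_generation < last_generation)
  if (base_generation < first_generation || base_generation > last_generation) {
    abort("`base_generation` must lie within the simulated generation range")
  }
  gens <- seq.int(first_generation, last_generation)
  cohort <- sample_founders(panel, cohort_size, generation = first_generation)
  cohort <- add_tbv(cohort, architecture)

  n_gen <- length(gens)
  male_tbvs <- vector("list", n_gen)
  cohorts <- if (keep_cohorts) vector("list", n_gen)
  rec <- vector("list", n_gen)
  base <- NULL
  sires <- list(sire_id = NA_character_, sire_mean_tbv = NA_real_)

  for (g in seq_along(gens)) {
    males <- cohort$sex == "male"
    male_tbvs[[g]] <- setNames(cohort$tbv[males], cohort$id[males])
    if (keep_cohorts) cohorts[[g]] <- cohort
    if (gens[g] == base_generation) {
      # a degenerate base cohort (zero TBV variance, e.g. a null trait)
      # leaves merit uncentred on a unit scale instead of erroring
      base <- if (sd(cohort$tbv) == 0) {
        structure(list(mean = mean(cohort$tbv), sd = 1), class = "base_scale")
      } else {
        base_scale(cohort)
      }
    }
    rec[[g]] <- tibble(
      generation = gens[g],
      n = cohort_size(cohort),
      n_males = sum(males),
      mean_tbv = mean(cohort$tbv),
      sd_tbv = sd(cohort$tbv),
      male_mean_tbv = mean(cohort$tbv[males]),
      male_sd_tbv = sd(cohort$tbv[males]),
      genic_var = genic_variance(cohort, architecture),
      sire_mean_tbv = NA_real_
    )
    if (g < n_gen) {
      step <- advance_generation(
        cohort, architecture, panel$map, panel$chromosome_length,
        n_sires = n_sires, genomic_accuracy = genomic_accuracy
      )
      rec[[g]]$sire_mean_tbv <- step$sire_mean_tbv
      cohort <- step$cohort
    }
  }

  generations <- dplyr::bind_rows(rec)
  generations$merit_std <- (generations$male_mean_tbv - base$mean) / base$sd
  names(male_tbvs) <- as.character(gens)
  if (keep_cohorts) names(cohorts) <- as.character(gens)

  structure(
    list(
      generations = generations,
      male_tbvs = male_tbvs,
      base = base,
      cohorts = cohorts,
      params = list(
        cohort_size = cohort_size, n_sires = n_sires,
        genomic_accuracy = genomic_accuracy,
        first_generation = first_generation,
        last_generation = last_generation,
        base_generation = base_generation,
        map = panel$map, chromosome_length = panel$chromosome_length
      )
    ),
    class = "nucleus_run"
  )
}

#' @export
print.nucleus_run <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<nucleus_run> generations %d..%d, %d per cohort, %d sires, genomic accuracy %.2f\n",
    p$first_generation, p$last_generation, p$cohort_size, p$n_sires,
    p$genomic_accuracy
  ))
  cat(sprintf(
    "  standardized male-cohort merit: %.2f (gen 0) -> %.2f (gen %d)\n",
    x$generations$merit_std[x$generations$generation == 0],
    x$generations$merit_std[nrow(x$generations)], p$last_generation
  ))
  invisible(x)
}

#' Per-year rate of standardized genetic gain
#'
#' Slope of the regression of the standardized male-cohort mean merit on
#' generation (one generation = one calendar year), over the given window.
#'
#' @param run A `nucleus_run`.
#' @param generations Window over which to fit (default the future phase,
#'   1..20).
#' @return Slope in base genetic standard deviations per year.
#' @export
gain_rate <- function(run, generations = NULL) {
  generations <- generations %||%
    seq.int(1L, run$params$last_generation)
  d <- run$generations[run$generations$generation %in% generations, ]
  unname(coef(lm(merit_std ~ generation, data = d))[2])
}

#' Export a nucleus-run summary as CSV
#'
#' @param run A `nucleus_run`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_nucleus_summary <- function(run, path) {
  utils::write.csv(run$generations, path, row.names = FALSE)
  invisible(path)
}
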