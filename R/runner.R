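#' The scenario grid of the simulation study
#'
#' Expands the full map of dissemination scenarios: per population size and
#' genomic-test accuracy, 3 conventional strategies (top 50/200/500 males),
#' 6 two-stage surrogate-sire testing designs and 18 three-stage designs,
#' each surrogate design with 1 or 5 donors — 51 scenarios per size and
#' accuracy, 102 per accuracy across the two sizes. All surrogate designs
#' draw on the same total budget of 14,000 test progeny: two-stage designs
#' allocate it to a single progeny test (progeny per candidate rounded where
#' 14,000 is not divisible by the candidate count); three-stage designs
#' split it 2,000/4,000/6,000 at S1 (100, 200 or 400 candidates) with the
#' remainder at S2 (10 or 20 candidates).
#'
#' @param sizes Population sizes to include: `"small"` (1,000 per
#'   generation) and/or `"big"` (5,000).
#' @param accuracies Genomic-test accuracies (default 0.5, 0.7, 0.9).
#' @param donors Donor counts for surrogate designs (default 1 and 5).
#' @param h2 Heritability governing progeny-test accuracies.
#' @param total_progeny Progeny-test budget (default 14,000).
#' @return A tibble with one scenario per row, validated for budget
#'   consistency.
#' @export
#' @examples
#' g <- scenario_grid("small", 0.5)
#' nrow(g) # 51
scenario_grid <- function(sizes = c("small", "big"),
                          accuracies = c(0.5, 0.7, 0.9),
                          donors = c(1L, 5L),
                          h2 = 0.25,
                          total_progeny = 14000L) {
  sizes <- match.arg(sizes, c("small", "big"), several.ok = TRUE)
  two_stage_candidates <- c(14L, 28L, 56L, 112L, 224L, 448L)
  two_stage <- tibble(
    kind = "ss_two_stage",
    s1_candidates = two_stage_candidates,
    s1_progeny = as.integer(round(total_progeny / two_stage_candidates)),
    s2_candidates = NA_integer_, s2_progeny = NA_integer_
  )
  three_stage <- tidyr::expand_grid(
    s1_budget = c(2000L, 4000L, 6000L),
    s1_candidates = c(100L, 200L, 400L),
    s2_candidates = c(10L, 20L)
  )
  three_stage <- dplyr::mutate(three_stage,
    kind = "ss_three_stage",
    s1_progeny = as.integer(.data$s1_budget / .data$s1_candidates),
    s2_progeny = as.integer((total_progeny - .data$s1_budget) / .data$s2_candidates)
  )
  surrogate <- dplyr::bind_rows(
    two_stage,
    dplyr::select(three_stage, -"s1_budget")
  )
  surrogate <- tidyr::expand_grid(surrogate, n_donors = as.integer(donors))
  conventional <- tibble(
    kind = "conventional", n_males = c(50L, 200L, 500L),
    s1_candidates = NA_integer_, s1_progeny = NA_integer_,
    s2_candidates = NA_integer_, s2_progeny = NA_integer_,
    n_donors = NA_integer_
  )
  cells <- dplyr::bind_rows(conventional, surrogate)
  grid <- tidyr::expand_grid(
    size = sizes, accuracy = accuracies,
    dplyr::distinct(cells)
  )
  grid <- dplyr::mutate(grid,
    h2 = ifelse(.data$kind == "conventional", NA_real_, h2),
    lag_years = dplyr::case_when(
      kind == "ss_three_stage" ~ 4.5,
      TRUE ~ 3.5
    ),
    cohort_size = ifelse(.data$size == "small", 1000L, 5000L),
    scenario_id = paste0(
      .data$size, "_a", .data$accuracy, "_",
      ifelse(.data$kind == "conventional",
        sprintf("conv%d", .data$n_males),
        ifelse(.data$kind == "ss_two_stage",
          sprintf("ss2_%dx%d_d%d", .data$s1_candidates, .data$s1_progeny, .data$n_donors),
          sprintf(
            "ss3_%dx%d_%dx%d_d%d", .data$s1_candidates, .data$s1_progeny,
            .data$s2_candidates, .data$s2_progeny, .data$n_donors
          )
        )
      )
    )
  )
  grid <- dplyr::relocate(grid, "scenario_id")
  validate_scenario_grid(grid, total_progeny)
  grid
}

#' Validate budget consistency of a scenario grid
#'
#' Every surrogate scenario must spend the whole progeny budget: exactly for
#' stage allocations that divide it, and to the nearest whole progeny per
#' candidate otherwise (e.g. 224 candidates get round(14000/224) = 63 each).
#' Errors naming the first offending scenario.
#'
#' @param grid A tibble as produced by [scenario_grid()].
#' @param total_progeny The progeny budget.
#' @return The grid, invisibly.
#' @export
validate_scenario_grid <- function(grid, total_progeny = 14000L) {
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    if (row$kind == "conventional") next
    s1 <- row$s1_candidates * row$s1_progeny
    if (row$kind == "ss_two_stage") {
      ok <- row$s1_progeny == round(total_progeny / row$s1_candidates)
    } else {
      s2 <- row$s2_candidates * row$s2_progeny
      ok <- (s1 + s2) == total_progeny
      ok <- ok && row$s2_candidates <= row$s1_candidates
    }
    if (!ok) {
      abort(sprintf(
        "scenario '%s' violates the %d-progeny budget", row$scenario_id, total_progeny
      ))
    }
  }
  invisible(grid)
}

# strategy_spec from one grid row
.strategy_from_row <- function(row) {
  if (row$kind == "conventional") {
    strategy_conventional(row$n_males, lag_years = row$lag_years)
  } else if (row$kind == "ss_two_stage") {
    strategy_surrogate(row$s1_candidates, row$s1_progeny,
      n_donors = row$n_donors, h2 = row$h2, lag_years = row$lag_years
    )
  } else {
    strategy_surrogate(row$s1_candidates, row$s1_progeny,
      row$s2_candidates, row$s2_progeny,
      n_donors = row$n_donors, h2 = row$h2, lag_years = row$lag_years
    )
  }
}

# One replicate: nucleus run + reference + all strategies, paired.
# Returns per-strategy YGG rows, a nucleus summary row and (optionally)
# window trajectories.
.evaluate_replicate <- function(seed, cohort_size, genomic_accuracy,
                                strategies, n_haplotypes, n_chromosomes,
                                loci_per_chromosome, window = 11:20,
                                n_sires = 50L, keep_trajectories = FALSE) {
  set.seed(seed)
  panel <- sim_haplotype_panel(n_haplotypes, n_chromosomes, loci_per_chromosome)
  arch <- sim_trait_architecture(panel)
  run <- run_nucleus(panel, arch,
    cohort_size = cohort_size, n_sires = n_sires,
    genomic_accuracy = genomic_accuracy
  )

  # shared conventional top-50 series: the YGG reference (diluted) and its
  # undiluted counterpart, from one pseudo-test draw (paired comparison)
  ser <- conventional_merit_series(run, 50L, genomic_accuracy)
  std <- (ser$merit - run$base$mean) / run$base$sd
  dil <- dilute(std)
  keep <- !is.na(dil)
  reference <- tibble(
    source_generation = ser$generation[keep],
    year = ser$generation[keep] + 3.5,
    merit = dil[keep]
  )
  undiluted <- tibble(
    source_generation = ser$generation,
    year = ser$generation + 3.5,
    merit = std
  )

  ygg_rows <- purrr::imap(strategies, function(strat, label) {
    traj <- commercial_trajectory(run, strat, accuracy = genomic_accuracy, window = window)
    y <- ygg(traj, reference, window = window)
    tibble(
      strategy = label, kind = strat$kind, lag_years = strat$lag_years,
      ygg = as.numeric(y)
    )
  })
  ygg_tbl <- dplyr::bind_rows(ygg_rows)
  ygg_tbl$seed <- seed

  trajectories <- NULL
  if (keep_trajectories) {
    trajectories <- dplyr::bind_rows(c(
      list(
        reference = dplyr::mutate(reference, strategy = "reference-conv50"),
        undiluted = dplyr::mutate(undiluted, strategy = "conv50-undiluted")
      ),
      purrr::imap(strategies, function(strat, label) {
        traj <- commercial_trajectory(run, strat, accuracy = genomic_accuracy, window = window)
        dplyr::mutate(
          dplyr::select(
            as_tibble(traj),
            "source_generation", "year", "merit"
          ),
          strategy = label
        )
      })
    ))
    trajectories$seed <- seed
  }

  nucleus_row <- tibble(
    seed = seed,
    gain_rate = gain_rate(run),
    dilution_lag = as.numeric(ygg(undiluted, reference, window = window)),
    base_sd = run$base$sd,
    final_merit = run$generations$merit_std[nrow(run$generations)]
  )
  list(ygg = ygg_tbl, nucleus = nucleus_row, trajectories = trajectories)
}

#' Replicated comparison of dissemination strategies
#'
#' Runs `n_replicates` independent nucleus simulations for one population
#' size and genomic-test accuracy and evaluates a set of strategies against
#' the conventional top-50 reference within each replicate (paired design:
#' all strategies in a replicate share the nucleus run and the reference).
#' This is the workhorse behind [run_experiment()] and the reproduction of
#' the study's headline numbers.
#'
#' @param size `"small"` (1,000 per generation) or `"big"` (5,000).
#' @param genomic_accuracy Accuracy of the genomic test (0.5, 0.7 or 0.9 in
#'   the study grid).
#' @param strategies Named list of `strategy_spec`s to evaluate.
#' @param n_replicates Number of independent replicates.
#' @param seed Root seed; per-replicate seeds are derived from it.
#' @param n_haplotypes,n_chromosomes,loci_per_chromosome Founder-genome
#'   dimensions. The default 200 loci per chromosome is the reduced
#'   desk-scale profile; the full-scale profile uses 1,000.
#' @param window Comparison window of source generations (default 11..20).
#' @param keep_trajectories Also return per-replicate trajectories?
#' @param quiet Suppress progress messages?
#' @return A list with `ygg` (tibble: replicate, strategy, ygg vs the
#'   conventional top-50 reference), `nucleus` (tibble: per-replicate gain
#'   rate and dilution lag), `summary` (aggregated YGG per strategy) and
#'   optionally `trajectories`.
#' @export
#' @examples
#' \donttest{
#' res <- simulate_strategy_comparison(
#'   "small", 0.5,
#'   strategies = list(best_two_stage = strategy_surrogate(112, 125)),
#'   n_replicates = 2, seed = 1, loci_per_chromosome = 50
#' )
#' res$summary
#' }
simulate_strategy_comparison <- function(size = c("small", "big"),
                                         genomic_accuracy = 0.5,
                                         strategies,
                                         n_replicates = 20,
                                         seed = 1,
                                         n_haplotypes = 400,
                                         n_chromosomes = 10,
                                         loci_per_chromosome = 200,
                                         window = 11:20,
                                         keep_trajectories = FALSE,
                                         quiet = TRUE) {
  size <- match.arg(size)
  cohort_size <- if (size == "small") 1000L else 5000L
  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, function(s) s$label, character(1))
  }
  seeds <- derive_seeds(seed, n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (!quiet) message(sprintf("replicate %d/%d", r, n_replicates))
    reps[[r]] <- .evaluate_replicate(
      seeds[r], cohort_size, genomic_accuracy, strategies,
      n_haplotypes, n_chromosomes, loci_per_chromosome,
      window = window, keep_trajectories = keep_trajectories
    )
    reps[[r]]$ygg$replicate <- r
    reps[[r]]$nucleus$replicate <- r
    if (keep_trajectories) reps[[r]]$trajectories$replicate <- r
  }
  ygg_tbl <- dplyr::bind_rows(purrr::map(reps, "ygg"))
  nucleus <- dplyr::bind_rows(purrr::map(reps, "nucleus"))
  out <- list(
    ygg = ygg_tbl,
    nucleus = nucleus,
    summary = aggregate_ygg(dplyr::group_by(ygg_tbl, .data$strategy)),
    size = size, genomic_accuracy = genomic_accuracy, seed = seed
  )
  if (keep_trajectories) {
    out$trajectories <- dplyr::bind_rows(purrr::map(reps, "trajectories"))
  }
  out
}

#' Run a full scenario-grid experiment
#'
#' Expands (or accepts) a scenario grid, runs every (size, accuracy) block
#' with a shared nucleus run per replicate, and — when `out_dir` is given —
#' writes `ygg.csv` (per replicate and scenario), `ygg_summary.csv`
#' (aggregated), `trajectories.csv` and a `manifest.json` recording seeds
#' and configuration. Completed (size, accuracy, replicate) chunks are
#' written as they finish and skipped on resumption, so an interrupted run
#' picks up where it left off and yields identical outputs.
#'
#' @param grid A scenario grid from [scenario_grid()] (defaults to the
#'   reduced preset: small size, accuracy 0.5).
#' @param n_replicates Replicates per block.
#' @param seed Root seed.
#' @param loci_per_chromosome Founder loci per chromosome (reduced profile:
#'   200; full profile: 1,000).
#' @param out_dir Output directory (created if needed); `NULL` for none.
#' @param resume Skip chunks already present in `out_dir`?
#' @param keep_trajectories Store window trajectories?
#' @param quiet Suppress progress messages?
#' @return A list with `ygg`, `summary`, optionally `trajectories`, and
#'   `manifest`.
#' @export
run_experiment <- function(grid = scenario_grid("small", 0.5),
                           n_replicates = 20, seed = 1,
                           loci_per_chromosome = 200,
                           out_dir = NULL, resume = TRUE,
                           keep_trajectories = FALSE, quiet = TRUE) {
  validate_scenario_grid(grid)
  if (nrow(grid) == 0) abort("empty scenario grid")
  blocks <- dplyr::group_split(dplyr::group_by(grid, .data$size, .data$accuracy))
  chunk_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    chunk_dir <- file.path(out_dir, "chunks")
    dir.create(chunk_dir, showWarnings = FALSE)
  }
  block_seeds <- derive_seeds(seed, length(blocks))

  all_ygg <- list()
  all_traj <- list()
  for (b in seq_along(blocks)) {
    block <- blocks[[b]]
    size <- block$size[1]
    accuracy <- block$accuracy[1]
    strategies <- lapply(seq_len(nrow(block)), function(i) .strategy_from_row(block[i, ]))
    names(strategies) <- block$scenario_id
    rep_seeds <- derive_seeds(block_seeds[b], n_replicates)
    cohort_size <- if (size == "small") 1000L else 5000L
    for (r in seq_len(n_replicates)) {
      tag <- sprintf("%s_a%s_rep%03d", size, accuracy, r)
      chunk_file <- if (!is.null(chunk_dir)) file.path(chunk_dir, paste0(tag, ".csv"))
      if (!is.null(chunk_file) && resume && file.exists(chunk_file)) {
        all_ygg[[tag]] <- as_tibble(utils::read.csv(chunk_file))
        next
      }
      if (!quiet) message(tag)
      res <- .evaluate_replicate(
        rep_seeds[r], cohort_size, accuracy, strategies,
        n_haplotypes = 400, n_chromosomes = 10,
        loci_per_chromosome = loci_per_chromosome,
        keep_trajectories = keep_trajectories
      )
      chunk <- dplyr::mutate(res$ygg,
        replicate = r, size = size, accuracy = accuracy,
        gain_rate = res$nucleus$gain_rate,
        dilution_lag = res$nucleus$dilution_lag
      )
      names(chunk)[names(chunk) == "strategy"] <- "scenario_id"
      if (!is.null(chunk_file)) utils::write.csv(chunk, chunk_file, row.names = FALSE)
      all_ygg[[tag]] <- chunk
      if (keep_trajectories) {
        res$trajectories$replicate <- r
        res$trajectories$size <- size
        res$trajectories$accuracy <- accuracy
        all_traj[[tag]] <- res$trajectories
      }
    }
  }

  ygg_tbl <- dplyr::bind_rows(all_ygg)
  summary_tbl <- aggregate_ygg(dplyr::group_by(ygg_tbl, .data$scenario_id, .data$size, .data$accuracy))
  manifest <- list(
    package = "surrosire",
    version = as.character(utils::packageVersion("surrosire")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    n_replicates = n_replicates,
    loci_per_chromosome = loci_per_chromosome,
    profile = if (loci_per_chromosome < 1000) "reduced" else "full",
    blocks = lapply(seq_along(blocks), function(b) {
      list(
        size = blocks[[b]]$size[1], accuracy = blocks[[b]]$accuracy[1],
        block_seed = block_seeds[b],
        replicate_seeds = derive_seeds(block_seeds[b], n_replicates),
        scenarios = blocks[[b]]$scenario_id
      )
    })
  )
  out <- list(ygg = ygg_tbl, summary = summary_tbl, manifest = manifest)
  if (keep_trajectories) out$trajectories <- dplyr::bind_rows(all_traj)

  if (!is.null(out_dir)) {
    utils::write.csv(ygg_tbl, file.path(out_dir, "ygg.csv"), row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "ygg_summary.csv"), row.names = FALSE)
    if (keep_trajectories) {
      utils::write.csv(out$trajectories, file.path(out_dir, "trajectories.csv"),
        row.names = FALSE
      )
    }
    manifest$files <- list.files(out_dir, recursive = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    out$manifest <- manifest
  }
  out
}
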