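#' Define a dissemination strategy
#'
#' A strategy converts nucleus males into commercial sires. The
#' *conventional* strategy multiplies the top `n_males` (by genomic test)
#' through a multiplier layer: its commercial sires appear `lag_years` (3.5)
#' later and their merit is diluted by the lagged, unselected multiplier
#' females (see [dilute()]). The *surrogate-sire* strategy identifies one or
#' a few elite donors per cohort by multi-stage testing — a genomic screen
#' (S0) followed by one (two-stage, lag 3.5 years) or two (three-stage,
#' lag 4.5 years) progeny tests — and disseminates the donors' germline
#' through surrogate sires, with no multiplier dilution.
#'
#' @param n_males Conventional only: number of top males used in
#'   multiplication (50, 200 or 500 in the standard grid).
#' @param lag_years Years from nucleus cohort to commercial use. Defaults:
#'   3.5 (conventional and two-stage), 4.5 (three-stage).
#' @param dilution Apply multiplier dilution? (conventional only,
#'   default `TRUE`).
#' @return An object of class `strategy_spec`.
#' @export
#' @examples
#' strategy_conventional(50)
#' strategy_surrogate(112, 125) # best two-stage design
#' strategy_surrogate(100, 60, 20, 400) # best three-stage design
strategy_conventional <- function(n_males = 50L, lag_years = 3.5,
                                  dilution = TRUE) {
  n_males <- .check_count(n_males, "n_males")
  structure(
    list(
      kind = "conventional", n_males = n_males,
      s1_candidates = NA_integer_, s1_progeny = NA_integer_,
      s2_candidates = NA_integer_, s2_progeny = NA_integer_,
      n_donors = NA_integer_, h2 = NA_real_,
      lag_years = lag_years, dilution = isTRUE(dilution),
      label = sprintf("conv-%d", n_males)
    ),
    class = "strategy_spec"
  )
}

#' @rdname strategy_conventional
#' @param s1_candidates,s1_progeny First progeny-test stage: number of donor
#'   candidates advanced from the genomic screen and progeny per candidate.
#' @param s2_candidates,s2_progeny Second progeny-test stage (three-stage
#'   testing only); `NULL` for two-stage testing.
#' @param n_donors Number of elite donors finally used (1 or 5 in the
#'   standard grid).
#' @param h2 Heritability used to map progeny counts to test accuracies.
#' @export
strategy_surrogate <- function(s1_candidates, s1_progeny,
                               s2_candidates = NULL, s2_progeny = NULL,
                               n_donors = 1L, h2 = 0.25, lag_years = NULL) {
  s1_candidates <- .check_count(s1_candidates, "s1_candidates")
  s1_progeny <- .check_count(s1_progeny, "s1_progeny")
  n_donors <- .check_count(n_donors, "n_donors")
  h2 <- .check_prob(h2, "h2")
  three_stage <- !is.null(s2_candidates)
  if (three_stage) {
    s2_candidates <- .check_count(s2_candidates, "s2_candidates")
    if (is.null(s2_progeny)) abort("three-stage testing requires `s2_progeny`")
    s2_progeny <- .check_count(s2_progeny, "s2_progeny")
    if (s2_candidates > s1_candidates) {
      abort("stage sizes must be non-increasing: `s2_candidates` > `s1_candidates`")
    }
    if (n_donors > s2_candidates) {
      abort("stage sizes must be non-increasing: `n_donors` > `s2_candidates`")
    }
  } else {
    if (!is.null(s2_progeny)) abort("`s2_progeny` given without `s2_candidates`")
    if (n_donors > s1_candidates) {
      abort("stage sizes must be non-increasing: `n_donors` > `s1_candidates`")
    }
    s2_candidates <- NA_integer_
    s2_progeny <- NA_integer_
  }
  lag_years <- lag_years %||% if (three_stage) 4.5 else 3.5
  structure(
    list(
      kind = if (three_stage) "ss_three_stage" else "ss_two_stage",
      n_males = NA_integer_,
      s1_candidates = s1_candidates, s1_progeny = s1_progeny,
      s2_candidates = s2_candidates, s2_progeny = s2_progeny,
      n_donors = n_donors, h2 = h2,
      lag_years = lag_years, dilution = FALSE,
      label = if (three_stage) {
        sprintf(
          "ss3-%dx%d-%dx%d-d%d", s1_candidates, s1_progeny,
          s2_candidates, s2_progeny, n_donors
        )
      } else {
        sprintf("ss2-%dx%d-d%d", s1_candidates, s1_progeny, n_donors)
      }
    ),
    class = "strategy_spec"
  )
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf(
    "<strategy_spec> %s (%s), lag %.1f y%s\n",
    x$label, x$kind, x$lag_years,
    if (x$dilution) ", multiplier dilution" else ""
  ))
  invisible(x)
}

#' Total progeny-test budget of a strategy
#'
#' @param strategy A `strategy_spec`.
#' @return Total progeny across progeny-test stages (0 for conventional).
#' @export
progeny_budget <- function(strategy) {
  if (strategy$kind == "conventional") {
    return(0L)
  }
  b <- strategy$s1_candidates * strategy$s1_progeny
  if (strategy$kind == "ss_three_stage") {
    b <- b + strategy$s2_candidates * strategy$s2_progeny
  }
  as.integer(b)
}

#' Maternal-ancestor dilution weights
#'
#' Relationship coefficients between a commercial sire and his maternal male
#' ancestors, `0.5, 0.25, ..., 0.015625` for generations `t-1` to `t-6`.
#' Applied exactly as stated, without renormalisation, even though
#' `0.5 + 0.5 * sum(w)` is 0.9921875 rather than 1.
#'
#' @return Numeric vector of 6 weights.
#' @export
dilution_weights <- function() 0.5^(1:6)

#' Dilute a merit series by lagged multiplier females
#'
#' Under conventional multiplication the commercial sire inherits half his
#' genome from a current nucleus male and half from a multiplier female whose
#' male ancestors are nucleus males of earlier generations (no selection on
#' multiplier females). The diluted series is
#' `d[t] = 0.5 x[t] + 0.5 * sum_i w[i] x[t - i]` over the 6 preceding
#' generations. The first `length(weights)` entries lack sufficient history
#' and are returned as `NA`.
#'
#' @param x Numeric merit series, one value per consecutive generation.
#' @param weights Ancestor weights; default [dilution_weights()].
#' @return Numeric vector, same length as `x`, with leading `NA`s.
#' @export
#' @examples
#' dilute(rep(1, 10)) # 0.9921875 where defined
dilute <- function(x, weights = dilution_weights()) {
  k <- length(weights)
  if (length(x) <= k) {
    abort(sprintf("series of length %d has insufficient history (need > %d)", length(x), k))
  }
  d <- rep(NA_real_, length(x))
  for (t in seq.int(k + 1, length(x))) {
    d[t] <- 0.5 * x[t] + 0.5 * sum(weights * x[t - seq_len(k)])
  }
  d
}

#' Per-generation merit of the conventional strategy's top males
#'
#' For each generation of a nucleus run, all males are re-tested with a
#' fresh genomic pseudo-test at `accuracy` and the mean true breeding value
#' of the top `n_males` is recorded. This draw is independent of the one
#' used for parent selection within the run.
#'
#' @param run A `nucleus_run`.
#' @param n_males Number of top males used in multiplication.
#' @param accuracy Genomic-test accuracy; default the run's.
#' @return A tibble with `generation` and `merit` (raw TBV units).
#' @export
conventional_merit_series <- function(run, n_males, accuracy = NULL) {
  accuracy <- accuracy %||% run$params$genomic_accuracy
  n_males <- .check_count(n_males, "n_males")
  gens <- as.integer(names(run$male_tbvs))
  merit <- vapply(run$male_tbvs, function(tbv) {
    if (n_males > length(tbv)) {
      abort(sprintf("n_males = %d exceeds the %d males in a cohort", n_males, length(tbv)))
    }
    test <- pseudo_ebv(tbv, accuracy, stage = "S0")
    mean(test$tbv[.top_idx(test$ebv, test$id, n_males)])
  }, numeric(1))
  tibble(generation = gens, merit = unname(merit))
}

#' Identify elite donors by multi-stage testing
#'
#' The surrogate-sire testing funnel applied to one cohort of nucleus males:
#' a genomic screen (S0) at `genomic_accuracy` keeps the top
#' `s1_candidates`; a first progeny test (S1) at
#' `progeny_test_accuracy(s1_progeny, h2)` keeps the top `s2_candidates`
#' (three-stage only); the final stage keeps the top `n_donors`, ranked on
#' that stage's test alone. Every stage draws fresh, independent test noise
#' calibrated to the current candidate group's TBV variance.
#'
#' @param males Named numeric vector of male TBVs (names = ids), or a
#'   `cohort` (its males are used).
#' @param strategy A surrogate `strategy_spec`.
#' @param genomic_accuracy Accuracy of the S0 genomic screen.
#' @return A list with `id`, `tbv` and `mean_tbv` of the donors, and
#'   `stages`, a tibble of per-stage audit records (stage, accuracy used,
#'   candidates in, candidates kept).
#' @export
identify_donors <- function(males, strategy, genomic_accuracy = 0.5) {
  if (inherits(males, "cohort")) {
    m <- males$sex == "male"
    if (is.null(males$tbv)) abort("cohort has no TBVs; call add_tbv() first")
    males <- setNames(males$tbv[m], males$id[m])
  }
  if (!strategy$kind %in% c("ss_two_stage", "ss_three_stage")) {
    abort("`strategy` must be a surrogate-sire strategy")
  }
  if (length(males) < strategy$s1_candidates) {
    abort(sprintf(
      "cohort has %d males but S1 requires %d candidates",
      length(males), strategy$s1_candidates
    ))
  }
  stages <- list()
  keep <- function(tbv, accuracy, k, stage) {
    test <- pseudo_ebv(tbv, accuracy, stage = stage)
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, accuracy = accuracy,
      n_in = length(tbv), n_kept = as.integer(k)
    )
    idx <- .top_idx(test$ebv, test$id, k)
    setNames(test$tbv[idx], test$id[idx])
  }

  s0 <- keep(males, genomic_accuracy, strategy$s1_candidates, "S0")
  if (strategy$kind == "ss_three_stage") {
    s1 <- keep(
      s0, progeny_test_accuracy(strategy$s1_progeny, strategy$h2),
      strategy$s2_candidates, "S1"
    )
    donors <- keep(
      s1, progeny_test_accuracy(strategy$s2_progeny, strategy$h2),
      strategy$n_donors, "S2"
    )
  } else {
    donors <- keep(
      s0, progeny_test_accuracy(strategy$s1_progeny, strategy$h2),
      strategy$n_donors, "S1"
    )
  }
  list(
    id = names(donors), tbv = unname(donors), mean_tbv = mean(donors),
    stages = dplyr::bind_rows(stages)
  )
}

#' Commercial-sire merit trajectory of a strategy
#'
#' Converts a nucleus run into the genetic merit of the commercial sires a
#' strategy delivers, per calendar year. For each source generation `t`, the
#' strategy's selected males (top `n_males`, or the elite donors of that
#' cohort's testing funnel) determine the merit reported at year
#' `t + lag_years`. Merit is standardized by the run's base scale;
#' conventional trajectories are additionally passed through [dilute()]
#' before the lag shift. Surrogate funnels are launched from every future
#' generation (1 onwards); conventional series extend back through the
#' historical phase so the dilution history and the reference comparison
#' window are fully covered.
#'
#' @param run A `nucleus_run`.
#' @param strategy A `strategy_spec`.
#' @param accuracy Genomic-test accuracy for S0 / top-male selection;
#'   default the run's.
#' @param window Source generations forming the comparison window
#'   (default 11..20, merit emerging from generation 11 onward).
#' @return A tibble of class `commercial_trajectory` with columns
#'   `source_generation`, `year`, `merit` (standardized) and `in_window`;
#'   the strategy is attached as an attribute.
#' @export
commercial_trajectory <- function(run, strategy, accuracy = NULL,
                                  window = 11:20) {
  accuracy <- accuracy %||% run$params$genomic_accuracy
  last <- run$params$last_generation
  if (length(window) == 0 || min(window) > last) {
    abort("comparison window is empty: no simulated generation reaches it")
  }
  if (strategy$kind == "conventional") {
    series <- conventional_merit_series(run, strategy$n_males, accuracy)
    std <- (series$merit - run$base$mean) / run$base$sd
    if (strategy$dilution) std <- dilute(std)
    out <- tibble(
      source_generation = series$generation,
      year = series$generation + strategy$lag_years,
      merit = std
    )
    out <- out[!is.na(out$merit), ]
  } else {
    gens <- seq.int(1L, last)
    merit <- vapply(gens, function(g) {
      identify_donors(
        run$male_tbvs[[as.character(g)]], strategy, accuracy
      )$mean_tbv
    }, numeric(1))
    out <- tibble(
      source_generation = gens,
      year = gens + strategy$lag_years,
      merit = (merit - run$base$mean) / run$base$sd
    )
  }
  out$in_window <- out$source_generation %in% window
  attr(out, "strategy") <- strategy
  attr(out, "window") <- window
  class(out) <- c("commercial_trajectory", class(out))
  out
}
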