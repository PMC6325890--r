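#' Standardize a merit series
#'
#' Affine transform `(x - mean) / sd` with a frozen [base_scale()].
#'
#' @param x Numeric vector of merit values (trait units).
#' @param scale A `base_scale`.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x, scale) {
  stopifnot(inherits(scale, "base_scale"))
  (x - scale$mean) / scale$sd
}

#' Years' worth of genetic gain of a trajectory over a reference
#'
#' Expresses the merit of a test trajectory on the time axis of a reference
#' trajectory (canonically: the conventional strategy using the top 50
#' males). For every test point in the comparison window, the year `t*` at
#' which the reference attains the test's merit is found by inverse linear
#' interpolation on the reference points; where the test merit falls outside
#' the reference's observed range, `t*` is obtained from the reference's
#' linear trend fitted over its comparison window. The years'-worth-of-
#' genetic-gain (YGG) of the trajectory is the mean of `t* - t` over the
#' window; a trajectory below the reference yields a negative YGG.
#'
#' The reference must be strictly increasing in merit over its points.
#'
#' @param test,reference `commercial_trajectory` tibbles (or any data frames
#'   with `source_generation`, `year` and `merit` columns).
#' @param window Source generations of `test` to average over
#'   (default 11..20).
#' @return A single number (years), with the per-year detail in the
#'   `per_year` attribute.
#' @export
#' @examples
#' ref <- tibble::tibble(
#'   source_generation = 1:20, year = 1:20 + 3.5,
#'   merit = 0.4 * (1:20)
#' )
#' test <- transform(ref, merit = merit + 0.8) # 0.8 merit = 2 years ahead
#' ygg(test, ref)
ygg <- function(test, reference, window = 11:20) {
  tw <- test[test$source_generation %in% window, , drop = FALSE]
  if (nrow(tw) == 0) abort("no test points fall in the comparison window")
  ref <- reference[order(reference$year), , drop = FALSE]
  if (any(diff(ref$merit) <= 0)) {
    abort("reference trajectory must be strictly increasing in merit")
  }
  fit_rows <- ref$source_generation %in% window
  if (sum(fit_rows) < 2) fit_rows <- rep(TRUE, nrow(ref))
  fit <- lm(year ~ merit, data = ref[fit_rows, , drop = FALSE])

  tstar <- approx(ref$merit, ref$year, xout = tw$merit, rule = 1)$y
  out_of_range <- is.na(tstar)
  if (any(out_of_range)) {
    tstar[out_of_range] <- predict(
      fit,
      newdata = data.frame(merit = tw$merit[out_of_range])
    )
  }
  per_year <- tibble(
    source_generation = tw$source_generation,
    year = tw$year,
    merit = tw$merit,
    reference_year = tstar,
    ygg = tstar - tw$year
  )
  structure(mean(per_year$ygg), per_year = per_year)
}

#' YGG advantage of one strategy over another
#'
#' Both trajectories are expressed in years on the reference's time axis and
#' the difference of their mean YGG over the window is returned; positive
#' values mean `test` delivers higher commercial-sire merit than
#' `competitor`.
#'
#' @param test,competitor `commercial_trajectory` tibbles.
#' @param reference Reference trajectory (conventional top-50); when
#'   `competitor` *is* the reference its YGG is zero by construction.
#' @inheritParams ygg
#' @return A single number (years).
#' @export
ygg_advantage <- function(test, competitor, reference, window = 11:20) {
  as.numeric(ygg(test, reference, window)) -
    as.numeric(ygg(competitor, reference, window))
}

#' Aggregate per-replicate YGG values
#'
#' @param x Numeric vector of per-replicate YGG values, or a data frame with
#'   a `ygg` column (grouping columns, if any, are respected).
#' @return For a vector: a `ygg_result` tibble with `mean_ygg`, `se`
#'   (standard error over replicates) and `n_replicates`. For a grouped data
#'   frame: one row per group.
#' @export
aggregate_ygg <- function(x) {
  if (is.data.frame(x)) {
    out <- dplyr::summarise(
      x,
      mean_ygg = mean(.data$ygg),
      se = sd(.data$ygg) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  } else {
    x <- as.numeric(x)
    if (length(x) < 2) abort("need at least 2 replicates to aggregate")
    out <- tibble(
      mean_ygg = mean(x),
      se = sd(x) / sqrt(length(x)),
      n_replicates = length(x)
    )
  }
  class(out) <- c("ygg_result", class(out))
  out
}
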