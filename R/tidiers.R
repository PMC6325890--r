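#' Tidy a nucleus run
#'
#' One row per generation: cohort and male-cohort TBV summaries, genic
#' variance at causal loci, selected-sire mean and standardized merit.
#'
#' @param x A `nucleus_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nucleus_run
#' @export
tidy.nucleus_run <- function(x, ...) {
  as_tibble(x$generations)
}

#' @rdname tidy.nucleus_run
#' @method glance nucleus_run
#' @export
glance.nucleus_run <- function(x, ...) {
  p <- x$params
  tibble(
    cohort_size = p$cohort_size,
    n_sires = p$n_sires,
    genomic_accuracy = p$genomic_accuracy,
    n_generations = p$last_generation - p$first_generation + 1L,
    base_mean = x$base$mean,
    base_sd = x$base$sd,
    gain_rate = gain_rate(x),
    final_merit = x$generations$merit_std[nrow(x$generations)]
  )
}

#' Tidy aggregated YGG results
#'
#' @param x A `ygg_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-group means and standard errors as a plain
#'   tibble. `glance()`: a one-row overview.
#' @method tidy ygg_result
#' @export
tidy.ygg_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ygg_result")
  out
}

#' @rdname tidy.ygg_result
#' @method glance ygg_result
#' @export
glance.ygg_result <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x),
    n_replicates = max(x$n_replicates),
    max_mean_ygg = max(x$mean_ygg),
    max_se = max(x$se)
  )
}
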