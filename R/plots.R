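#' Plot a nucleus run
#'
#' Standardized male-cohort mean merit against generation, with the selected
#' sires' mean overlaid.
#'
#' @param object A `nucleus_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nucleus_run
#' @export
autoplot.nucleus_run <- function(object, ...) {
  d <- object$generations
  d$sire_std <- (d$sire_mean_tbv - object$base$mean) / object$base$sd
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$merit_std, colour = "male cohort")) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$sire_std, colour = "selected sires"),
      size = 0.8, na.rm = TRUE
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "generation (years)",
      y = expression("merit (" * sigma[b] * " units)"),
      colour = NULL,
      title = "Nucleus genetic trend"
    ) +
    ggplot2::theme_minimal()
}

#' Plot one or several commercial-sire trajectories
#'
#' @param object A `commercial_trajectory`.
#' @param ... Further `commercial_trajectory` objects to overlay; unnamed
#'   arguments are labelled by their strategy.
#' @return A ggplot of standardized merit against calendar year.
#' @method autoplot commercial_trajectory
#' @export
autoplot.commercial_trajectory <- function(object, ...) {
  trajs <- c(list(object), list(...))
  labels <- vapply(trajs, function(t) attr(t, "strategy")$label, character(1))
  d <- dplyr::bind_rows(lapply(seq_along(trajs), function(i) {
    dplyr::mutate(as_tibble(trajs[[i]]), strategy = labels[i])
  }))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$year, y = .data$merit, colour = .data$strategy
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$in_window, ], size = 0.9) +
    ggplot2::labs(
      x = "calendar year",
      y = expression("commercial-sire merit (" * sigma[b] * " units)"),
      colour = NULL,
      title = "Commercial-sire genetic merit by strategy"
    ) +
    ggplot2::theme_minimal()
}

#' Plot aggregated YGG results
#'
#' Mean years'-worth-of-genetic-gain per scenario with +-2 standard-error
#' bars.
#'
#' @param object A `ygg_result` (from [aggregate_ygg()], possibly grouped by
#'   scenario columns).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ygg_result
#' @export
autoplot.ygg_result <- function(object, ...) {
  d <- as_tibble(object)
  label_col <- intersect(c("scenario_id", "strategy"), names(d))[1]
  if (is.na(label_col)) {
    d$scenario <- "result"
  } else {
    d$scenario <- d[[label_col]]
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$scenario, .data$mean_ygg),
    y = .data$mean_ygg
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_ygg - 2 * .data$se,
      ymax = .data$mean_ygg + 2 * .data$se
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = "years' worth of genetic gain vs conventional top-50",
      title = "Strategy comparison"
    ) +
    ggplot2::theme_minimal()
}
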