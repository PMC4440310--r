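#' Plot a Monte-Carlo ensemble
#'
#' Median trajectories with 95% percentile ribbons, one facet per reported
#' quantity.
#'
#' @param object A [run_monte_carlo()] result.
#' @param quantities Which summary quantities to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ens <- run_monte_carlo(n_replicates = 20, master_seed = 1)
#' autoplot(ens)
#' @export
autoplot.quota_ensemble <- function(object,
                                    quantities = c("n_training", "n_transition",
                                                   "n_fixed", "n_retired_this_year"),
                                    ...) {
  dat <- dplyr::filter(object$summary, .data$quantity %in% quantities)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "year", y = "anaesthetists",
                  title = "Projected workforce (median, 95% band)") +
    ggplot2::theme_minimal()
}

#' Plot the FTE gap trajectory
#'
#' @param object A [fte_gap_series()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quota_fte_gap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "year", y = "unfilled FTE transition positions (%)",
                  title = "Full-time-equivalent gap in transition positions") +
    ggplot2::theme_minimal()
}
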