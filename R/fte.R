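#' Full-time-equivalent parameters
#'
#' Parameters converting transition-position headcounts into full-time
#' equivalents (FTE): the hours fraction `w` worked by a part-timer, the FTE
#' demand for transition positions, and the baseline-year anchor gap used to
#' calibrate `w`. The survey records who works part-time (24%) but not their
#' hours fraction, so by default `w` is solved from the published baseline
#' condition that 10% of full-time-equivalent transition positions were
#' already unfilled at the end of the first projected year, assuming baseline
#' headcount equals demand: `1 - (1 - p + p w) = anchor/100`, giving
#' `w = 1 - (anchor/100)/p` (about 0.575 at the surveyed part-time share).
#'
#' @param part_time_weight Fraction of full time worked by a part-timer, in
#'   (0, 1); `NULL` calibrates it from `anchor_gap` and the surveyed
#'   part-time share.
#' @param transition_demand_fte FTE demand for transition positions; `NULL`
#'   defers to the analysis step, which uses the ensemble's median
#'   end-of-baseline-year transition headcount (treated as all-full-time
#'   demand). Set it explicitly to probe alternative readings (e.g. the
#'   99-person start-of-year pool).
#' @param anchor_gap Baseline-year printed gap, percent.
#' @param marginals [survey_marginals()] supplying the part-time share.
#' @return An object of class `fte_parameters`.
#' @examples
#' fte_parameters()
#' @export
fte_parameters <- function(part_time_weight = NULL,
                           transition_demand_fte = NULL,
                           anchor_gap = 10,
                           marginals = survey_marginals()) {
  p <- marginal_probs(marginals$parttime_counts, "parttime_counts")[["part_time"]]
  if (is.null(part_time_weight)) {
    part_time_weight <- calibrate_part_time_weight(
      part_time_share = p, headcount = 1, demand = 1, anchor_gap = anchor_gap
    )
  }
  if (part_time_weight <= 0 || part_time_weight >= 1) {
    abort_validation("part_time_weight must lie strictly between 0 and 1")
  }
  if (!is.null(transition_demand_fte) && transition_demand_fte <= 0) {
    abort_validation("transition_demand_fte must be positive")
  }
  structure(
    list(
      part_time_weight = part_time_weight,
      transition_demand_fte = transition_demand_fte,
      anchor_gap = anchor_gap,
      part_time_share = p
    ),
    class = "fte_parameters"
  )
}

#' @export
print.fte_parameters <- function(x, ...) {
  cat("<fte_parameters>\n")
  cat("  part-time weight :", format(x$part_time_weight, digits = 4), "\n")
  cat("  demand (FTE)     :",
      if (is.null(x$transition_demand_fte)) "baseline-year headcount"
      else x$transition_demand_fte, "\n")
  cat("  anchor gap       :", x$anchor_gap, "%\n")
  invisible(x)
}

#' Calibrate the part-time FTE weight from the baseline gap
#'
#' Solves the baseline-year gap identity
#' `anchor/100 = 1 - (1 - p + p w) * headcount / demand` for the part-time
#' hours fraction `w`, where `p` is the part-time share of the baseline
#' transition census. A solution outside (0, 1) is a calibration error (e.g.
#' a zero anchor with any part-time staff would require `w = 1`).
#'
#' @param baseline_census Optional roster tibble; its TRANSITION rows supply
#'   `part_time_share` and `headcount`.
#' @param demand FTE demand for transition positions.
#' @param anchor_gap Printed baseline gap, percent.
#' @param part_time_share,headcount Supply these directly instead of a
#'   census.
#' @return The calibrated weight `w`.
#' @examples
#' calibrate_part_time_weight(part_time_share = 0.24, headcount = 93,
#'                            demand = 93, anchor_gap = 10)
#' @export
calibrate_part_time_weight <- function(baseline_census = NULL, demand,
                                       anchor_gap,
                                       part_time_share = NULL,
                                       headcount = NULL) {
  if (!is.null(baseline_census)) {
    rows <- baseline_census
    if ("state" %in% names(rows)) {
      rows <- dplyr::filter(rows, .data$state == "TRANSITION")
    }
    if (nrow(rows) == 0) abort_validation("baseline census has no transition occupants")
    part_time_share <- mean(rows$part_time)
    headcount <- nrow(rows)
  }
  if (is.null(part_time_share) || is.null(headcount)) {
    abort_validation("supply either a baseline census or part_time_share and headcount")
  }
  if (part_time_share <= 0) {
    abort_validation("calibration requires a positive part-time share")
  }
  if (demand <= 0) abort_validation("demand must be positive")
  w <- ((1 - anchor_gap / 100) * demand / headcount - (1 - part_time_share)) /
    part_time_share
  if (w <= 0 || w >= 1) {
    abort(
      paste0(
        "part-time weight calibration has no solution in (0, 1): solved w = ",
        format(w, digits = 4), " from part_time_share = ",
        format(part_time_share, digits = 4), ", headcount/demand = ",
        format(headcount / demand, digits = 4), ", anchor = ", anchor_gap, "%"
      ),
      class = "quotasim_calibration_error"
    )
  }
  w
}

#' Full-time equivalents filled in transition positions
#'
#' Sum of FTE weights over the transition occupants of a census.
#'
#' @param census A roster tibble; rows with `state == "TRANSITION"` are used
#'   (all rows if no `state` column).
#' @param part_time_weight Optional weight overriding the stored
#'   `fte_weight` (recomputed from `part_time`).
#' @return FTE filled, in positions.
#' @examples
#' r <- sample_cohort(seed = 1)
#' fte_filled(r)
#' @export
fte_filled <- function(census, part_time_weight = NULL) {
  rows <- census
  if ("state" %in% names(rows)) {
    rows <- dplyr::filter(rows, .data$state == "TRANSITION")
  }
  if (is.null(part_time_weight)) {
    sum(rows$fte_weight)
  } else {
    sum(ifelse(rows$part_time, part_time_weight, 1))
  }
}

#' FTE gap trajectory of transition positions
#'
#' For each replicate and year, the percentage of full-time-equivalent
#' transition demand left unfilled,
#' `gap = 100 * (1 - fte_filled / transition_demand_fte)`, summarized across
#' replicates by the median and the 2.5/97.5 empirical percentiles. When
#' `params$transition_demand_fte` is `NULL`, demand defaults to the
#' ensemble's median end-of-baseline-year transition headcount, read as
#' all-full-time positions.
#'
#' @param ensemble A [run_monte_carlo()] result.
#' @param params [fte_parameters()].
#' @return A tibble of class `quota_fte_gap` with columns `year`, `median`,
#'   `lo95`, `hi95` (percent), and attributes `demand_fte` and
#'   `part_time_weight`.
#' @export
fte_gap_series <- function(ensemble, params = fte_parameters()) {
  reps <- ensemble$replicates
  if (is.null(reps) || !"fte_transition_filled" %in% names(reps)) {
    abort_validation("ensemble does not carry per-replicate FTE fills")
  }
  demand <- params$transition_demand_fte
  if (is.null(demand)) {
    base_year <- ensemble$scenario$start_year
    demand <- median(reps$n_transition[reps$year == base_year])
  }
  if (demand <= 0) abort_validation("transition FTE demand must be positive")
  out <- reps |>
    dplyr::mutate(gap = 100 * (1 - .data$fte_transition_filled / demand)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      median = median(.data$gap),
      lo95 = quantile(.data$gap, 0.025, names = FALSE),
      hi95 = quantile(.data$gap, 0.975, names = FALSE),
      .groups = "drop"
    )
  attr(out, "demand_fte") <- demand
  attr(out, "part_time_weight") <- params$part_time_weight
  class(out) <- c("quota_fte_gap", class(out))
  out
}
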