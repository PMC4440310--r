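#' Format an ensemble as the decade projection table
#'
#' One row per year with `median (lo to hi)` cells for the four reported
#' quantities: training, transition and fixed positions and retirees per
#' year. Medians and bounds are rounded half away from zero for display;
#' use `tidy()` on the ensemble for full precision.
#'
#' @param summary A [run_monte_carlo()] result (or its `summary` tibble).
#' @return A tibble with columns `year`, `training`, `transition`, `fixed`,
#'   `retirees`.
#' @examples
#' ens <- run_monte_carlo(n_replicates = 20, master_seed = 1)
#' make_table2(ens)
#' @export
make_table2 <- function(summary) {
  tab <- if (inherits(summary, "quota_ensemble")) summary$summary else summary
  if (is.null(tab) || nrow(tab) == 0) {
    abort_validation("ensemble summary is empty")
  }
  wanted <- c(
    training = "n_training", transition = "n_transition",
    fixed = "n_fixed", retirees = "n_retired_this_year"
  )
  missing <- setdiff(wanted, unique(tab$quantity))
  if (length(missing)) {
    abort_validation(paste0("summary is missing quantity: ",
                            paste(missing, collapse = ", ")))
  }
  cells <- tab |>
    dplyr::filter(.data$quantity %in% wanted) |>
    dplyr::mutate(
      cell = sprintf(
        "%d (%d to %d)",
        as.integer(round_half_up(.data$median)),
        as.integer(round_half_up(.data$lo95)),
        as.integer(round_half_up(.data$hi95))
      ),
      quantity = names(wanted)[match(.data$quantity, wanted)]
    ) |>
    dplyr::select(dplyr::all_of(c("year", "quantity", "cell"))) |>
    tidyr::pivot_wider(names_from = "quantity", values_from = "cell")
  dplyr::select(cells, dplyr::all_of(c("year", names(wanted))))
}

#' Percent decline of a projected quantity between two years
#'
#' `100 * (median_a - median_b) / median_a`, rounded half away from zero --
#' e.g. the headline decline of transition positions over the projection
#' decade.
#'
#' @param summary A [run_monte_carlo()] result (or its `summary` tibble).
#' @param quantity Summary quantity name (default transition positions).
#' @param year_a,year_b Comparison years (baseline first).
#' @return Integer percent (positive when the quantity declines).
#' @export
decline_percent <- function(summary, quantity = "n_transition",
                            year_a = 2014, year_b = 2024) {
  tab <- if (inherits(summary, "quota_ensemble")) summary$summary else summary
  med <- function(y) {
    v <- tab$median[tab$quantity == quantity & tab$year == y]
    if (length(v) != 1) {
      abort_validation(paste0("summary has no '", quantity, "' median for year ", y))
    }
    v
  }
  a <- med(year_a)
  b <- med(year_b)
  if (a == 0) abort_validation("undefined decline: baseline median is zero")
  as.integer(round_half_up(100 * (a - b) / a))
}

#' Write a simulation run to disk
#'
#' Writes `trajectory_summary.csv` (year, quantity, median, lo95, hi95),
#' optionally `replicates.csv` (per-replicate censuses) and `fte_gap.csv`,
#' and `run_meta.json` -- the run manifest echoing the scenario, seeds,
#' replicate count, a hash of the marginals, and the package version. The
#' manifest and CSVs are byte-stable: re-running with the same configuration
#' and seed reproduces them exactly (the wall-clock timestamp goes to
#' `run.log` only).
#'
#' @param ensemble A [run_monte_carlo()] result.
#' @param dir Output directory (created if needed).
#' @param marginals The marginals the run used (hashed into the manifest).
#' @param fte_gap Optional [fte_gap_series()] result.
#' @param replicates Also write per-replicate censuses.
#' @return `dir`, invisibly.
#' @export
write_run <- function(ensemble, dir, marginals = survey_marginals(),
                      fte_gap = NULL, replicates = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ensemble$summary, file.path(dir, "trajectory_summary.csv"))
  if (replicates) {
    readr::write_csv(ensemble$replicates, file.path(dir, "replicates.csv"))
  }
  if (!is.null(fte_gap)) {
    readr::write_csv(as.data.frame(fte_gap), file.path(dir, "fte_gap.csv"))
  }
  meta <- run_manifest(ensemble, marginals)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(
    sprintf("[%s] wrote run: %d replicates, seed %d",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
            ensemble$n_replicates, ensemble$master_seed),
    file.path(dir, "run.log")
  )
  invisible(dir)
}

#' Run manifest
#'
#' Scenario echo, marginals hash, master seed, replicate count and software
#' version identifying a run; every file written by [write_run()] belongs to
#' exactly one manifest.
#'
#' @param ensemble A [run_monte_carlo()] result.
#' @param marginals The marginals the run used.
#' @return A named list (serializable to JSON).
#' @export
run_manifest <- function(ensemble, marginals = survey_marginals()) {
  sc <- ensemble$scenario
  list(
    package = "quotasim",
    version = as.character(utils::packageVersion("quotasim")),
    master_seed = ensemble$master_seed,
    n_replicates = ensemble$n_replicates,
    marginals_hash = rlang::hash(marginals),
    scenario = list(
      start_year = sc$start_year,
      horizon_year = sc$horizon_year,
      quota = sc$quota,
      fixed_capacity = sc$fixed_capacity,
      training_state_years = sc$training_state_years,
      return_policy = sc$return_policy,
      foreign_departure_hazard = sc$foreign_departure_hazard,
      legal_retirement_age = as.list(sc$legal_retirement_age)
    )
  )
}
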