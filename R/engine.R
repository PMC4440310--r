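# Default residual departure hazard for foreign transition occupants,
# calibrated with calibrate_hazard() against the published projection
# endpoints (see the methods vignette).
default_foreign_departure_hazard <- function() 0.39

#' Policy scenario for the quota simulation
#'
#' Bundles the policy levers and institutional constants of the projection:
#' the annual training quota (the number of training posts, held constant and
#' always refillable), the number of permanent ("fixed") positions, the
#' training residence time before certification, the strict return policy
#' (certified foreign trainees leave the workforce instead of taking a
#' transition post), the residual annual departure hazard for foreign
#' transition occupants, and the legal retirement ages used to truncate
#' desired retirement.
#'
#' @param start_year,horizon_year Calendar years of the projection
#'   (`start_year <= horizon_year`); censuses are end-of-year.
#' @param quota Training positions per year.
#' @param fixed_capacity Permanent positions maintained by the system. The
#'   default 244 is the constant fixed-position count of the published
#'   projection; the 4-position difference from the surveyed 248 is treated
#'   as positions not refilled.
#' @param transition_demand Optional senior-registrar demand (persons) for
#'   FTE analyses; `NULL` defers to the baseline-year headcount.
#' @param training_state_years Years spent in TRAINING before certification
#'   (the official specialty-training length, 5).
#' @param return_policy If `TRUE`, certified foreign trainees depart.
#' @param foreign_departure_hazard Annual probability that a foreign
#'   transition occupant leaves; default calibrated via [calibrate_hazard()].
#' @param legal_retirement_age Named vector, years, by gender.
#' @return An object of class `policy_scenario`.
#' @examples
#' policy_scenario()
#' @export
policy_scenario <- function(start_year = 2014,
                            horizon_year = 2024,
                            quota = 66,
                            fixed_capacity = 244,
                            transition_demand = NULL,
                            training_state_years = 5,
                            return_policy = TRUE,
                            foreign_departure_hazard = default_foreign_departure_hazard(),
                            legal_retirement_age = c(male = 65, female = 64)) {
  if (quota < 0) abort_validation("quota must be non-negative")
  if (fixed_capacity < 0) abort_validation("fixed_capacity must be non-negative")
  if (start_year > horizon_year) {
    abort_validation("start_year must not exceed horizon_year")
  }
  if (foreign_departure_hazard < 0 || foreign_departure_hazard > 1) {
    abort_validation("foreign_departure_hazard must be a probability")
  }
  if (training_state_years <= 0) {
    abort_validation("training_state_years must be positive")
  }
  structure(
    list(
      start_year = start_year,
      horizon_year = horizon_year,
      quota = quota,
      fixed_capacity = fixed_capacity,
      transition_demand = transition_demand,
      training_state_years = training_state_years,
      return_policy = isTRUE(return_policy),
      foreign_departure_hazard = foreign_departure_hazard,
      legal_retirement_age = legal_retirement_age
    ),
    class = "policy_scenario"
  )
}

#' @export
print.policy_scenario <- function(x, ...) {
  cat("<policy_scenario>", x$start_year, "-", x$horizon_year, "\n")
  cat("  quota", x$quota, "| fixed capacity", x$fixed_capacity,
      "| training years", x$training_state_years, "\n")
  cat("  return policy", if (x$return_policy) "on" else "off",
      "| foreign departure hazard", x$foreign_departure_hazard, "\n")
  invisible(x)
}

#' Load a policy scenario from a configuration file
#'
#' Reads the `scenario` section of a `quotasim-params-v1` configuration
#' document (see [quotasim_config()]); missing keys fall back to the
#' [policy_scenario()] defaults.
#'
#' @param source Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `policy_scenario`.
#' @export
load_scenario <- function(source = quotasim_config()) {
  doc <- read_config(source)
  sc <- doc$scenario %||% list()
  args <- sc[intersect(names(sc), names(formals(policy_scenario)))]
  if (!is.null(args$legal_retirement_age)) {
    args$legal_retirement_age <- unlist(args$legal_retirement_age)
  }
  do.call(policy_scenario, args)
}

# One simulated year on a column-list roster. Order of events:
#   1. ageing (+1 year of age and of state residence for actives)
#   2. retirement at desired retirement age
#   3. certification after training_state_years; foreign certifiers depart
#      under the return policy, others enter TRANSITION
#   4. residual departure hazard on foreign TRANSITION occupants
#   5. promotion TRANSITION -> FIXED up to capacity, by state seniority,
#      then age, then lower person id
#   6. quota refill of TRAINING with new entrants
# Returns the updated columns and the end-of-year record.
step_impl <- function(cols, scenario, marginals, part_time_weight, year) {
  active <- cols$state == "TRAINING" | cols$state == "TRANSITION" |
    cols$state == "FIXED"
  cols$age[active] <- cols$age[active] + 1
  cols$years_in_state[active] <- cols$years_in_state[active] + 1

  retire <- active & cols$age >= cols$desired_retirement_age
  n_retired <- sum(retire)
  cols$state[retire] <- "RETIRED"

  n_departed <- 0L
  cert <- cols$state == "TRAINING" &
    cols$years_in_state >= scenario$training_state_years
  if (any(cert)) {
    if (scenario$return_policy) {
      leaving <- cert & cols$nationality == "foreign"
      cols$state[leaving] <- "DEPARTED"
      n_departed <- n_departed + sum(leaving)
      cert <- cert & !leaving
    }
    cols$state[cert] <- "TRANSITION"
    cols$years_in_state[cert] <- 0
  }

  h <- scenario$foreign_departure_hazard
  if (h > 0) {
    ft <- which(cols$state == "TRANSITION" & cols$nationality == "foreign")
    if (length(ft)) {
      gone <- ft[runif(length(ft)) < h]
      cols$state[gone] <- "DEPARTED"
      n_departed <- n_departed + length(gone)
    }
  }

  vacancies <- scenario$fixed_capacity - sum(cols$state == "FIXED")
  if (vacancies > 0) {
    pool <- which(cols$state == "TRANSITION")
    if (length(pool)) {
      ord <- pool[order(-cols$years_in_state[pool], -cols$age[pool],
                        cols$person_id[pool])]
      promoted <- ord[seq_len(min(vacancies, length(ord)))]
      cols$state[promoted] <- "FIXED"
      cols$years_in_state[promoted] <- 0
    }
  }

  n_entrants <- scenario$quota - sum(cols$state == "TRAINING")
  if (n_entrants > 0) {
    ent <- sample_entrants(n_entrants, marginals, part_time_weight,
                           scenario$legal_retirement_age)
    next_id <- if (length(cols$person_id)) max(cols$person_id) + 1L else 1L
    ent$person_id <- seq.int(next_id, length.out = n_entrants)
    for (nm in names(cols)) cols[[nm]] <- c(cols[[nm]], ent[[nm]])
  } else {
    n_entrants <- 0L
  }

  in_transition <- cols$state == "TRANSITION"
  rec <- tibble::tibble(
    year = year,
    n_training = sum(cols$state == "TRAINING"),
    n_transition = sum(in_transition),
    n_fixed = sum(cols$state == "FIXED"),
    n_retired_this_year = n_retired,
    n_departed_this_year = n_departed,
    n_entrants = as.integer(n_entrants),
    fte_transition_filled = sum(cols$fte_weight[in_transition])
  )
  list(cols = cols, record = rec)
}

#' Advance the workforce by one simulated year
#'
#' Applies, in order: ageing, retirement at desired retirement age,
#' certification of trainees who have completed the training residence
#' (foreign certifiers depart under the return policy), the residual
#' departure hazard on foreign transition occupants, promotion into fixed
#' positions up to capacity (by state seniority, then age, then lower person
#' id), and quota refill of the training pool with new entrants. Randomness
#' is drawn from the current RNG stream.
#'
#' @param roster A roster tibble (see [sample_cohort()]); retired and
#'   departed rows are retained for bookkeeping.
#' @param scenario A [policy_scenario()].
#' @param marginals [survey_marginals()] used for entrant attributes.
#' @param fte [fte_parameters()] for entrant FTE weights.
#' @param year Calendar year to stamp on the census record.
#' @return A list with `roster` (updated tibble) and `record` (one-row
#'   end-of-year census tibble).
#' @examples
#' r <- sample_cohort(seed = 1)
#' set.seed(2)
#' step <- annual_step(r, policy_scenario())
#' step$record
#' @export
annual_step <- function(roster, scenario, marginals = survey_marginals(),
                        fte = fte_parameters(marginals = marginals),
                        year = scenario$start_year) {
  cols <- as.list(roster[roster_columns])
  out <- step_impl(cols, scenario, marginals, fte$part_time_weight, year)
  list(roster = tibble::as_tibble(out$cols), record = out$record)
}

#' Simulate one replicate trajectory
#'
#' Runs [annual_step()] for every year from `start_year` to `horizon_year`
#' and collects the end-of-year censuses.
#'
#' @inheritParams annual_step
#' @param initial_roster Roster of actives at the start of `start_year`.
#' @return A tibble with one row per year: state headcounts, retirements and
#'   departures during the year, entrants, and the FTE filled in transition
#'   positions.
#' @examples
#' r <- sample_cohort(seed = 1)
#' set.seed(2)
#' simulate_replicate(r, policy_scenario())
#' @export
simulate_replicate <- function(initial_roster, scenario,
                               marginals = survey_marginals(),
                               fte = fte_parameters(marginals = marginals)) {
  cols <- as.list(initial_roster[roster_columns])
  years <- seq(scenario$start_year, scenario$horizon_year)
  records <- vector("list", length(years))
  for (i in seq_along(years)) {
    out <- step_impl(cols, scenario, marginals, fte$part_time_weight, years[i])
    cols <- out$cols
    records[[i]] <- out$record
  }
  dplyr::bind_rows(records)
}

#' Monte-Carlo ensemble of workforce trajectories
#'
#' Draws `n_replicates` independent realizations -- each with a freshly
#' sampled cohort and trajectory -- and summarizes every reported quantity by
#' its median and empirical 2.5/97.5 percentiles (linear interpolation,
#' [stats::quantile()] type 7) per year. Replicate substreams are derived
#' from `master_seed` by seeding the generator with it and drawing one
#' integer sub-seed per replicate, so results are fully reproducible.
#'
#' @inheritParams sample_cohort
#' @param scenario A [policy_scenario()].
#' @param n_replicates Number of replicates (at least 2, or percentiles are
#'   undefined).
#' @param master_seed Integer master seed.
#' @return An object of class `quota_ensemble`: a list with `summary`
#'   (year x quantity x median/lo95/hi95 tibble), `replicates` (per-replicate
#'   censuses), `scenario`, `n_replicates`, `master_seed`.
#' @examples
#' ens <- run_monte_carlo(n_replicates = 20, master_seed = 1)
#' tidy(ens)
#' @export
run_monte_carlo <- function(marginals = survey_marginals(),
                            state_counts = default_state_counts(),
                            scenario = policy_scenario(),
                            n_replicates = 1000,
                            master_seed = 20140522,
                            fte = fte_parameters(marginals = marginals)) {
  if (n_replicates < 2) {
    abort_validation("n_replicates must be at least 2 to form percentile bands")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(master_seed %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    roster <- sample_cohort(marginals, state_counts, fte,
                            legal_retirement_age = scenario$legal_retirement_age)
    traj <- simulate_replicate(roster, scenario, marginals, fte)
    traj$replicate <- i
    reps[[i]] <- traj
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- replicates |>
    tidyr::pivot_longer(
      cols = -dplyr::all_of(c("year", "replicate")),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::group_by(.data$year, .data$quantity) |>
    dplyr::summarise(
      median = median(.data$value),
      lo95 = quantile(.data$value, 0.025, names = FALSE),
      hi95 = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(
      summary = summary,
      replicates = replicates,
      scenario = scenario,
      n_replicates = n_replicates,
      master_seed = master_seed
    ),
    class = "quota_ensemble"
  )
}

#' @export
print.quota_ensemble <- function(x, ...) {
  cat("<quota_ensemble>", x$n_replicates, "replicates, seed", x$master_seed,
      "\n")
  final <- dplyr::filter(x$summary, .data$year == x$scenario$horizon_year)
  cat("  end-", x$scenario$horizon_year, " medians:\n", sep = "")
  for (i in seq_len(nrow(final))) {
    cat(sprintf("    %-22s %g (%g to %g)\n", final$quantity[i],
                final$median[i], final$lo95[i], final$hi95[i]))
  }
  invisible(x)
}

#' @export
tidy.quota_ensemble <- function(x, ...) {
  x$summary
}

#' @export
glance.quota_ensemble <- function(x, ...) {
  final <- dplyr::filter(x$summary, .data$year == x$scenario$horizon_year)
  med <- function(q) final$median[final$quantity == q]
  tibble::tibble(
    n_replicates = x$n_replicates,
    master_seed = x$master_seed,
    start_year = x$scenario$start_year,
    horizon_year = x$scenario$horizon_year,
    quota = x$scenario$quota,
    foreign_departure_hazard = x$scenario$foreign_departure_hazard,
    final_training = med("n_training"),
    final_transition = med("n_transition"),
    final_fixed = med("n_fixed")
  )
}

#' Calibrate the foreign-departure hazard against projection anchors
#'
#' The source projection does not publish its transition probabilities, so
#' the residual annual departure hazard of foreign transition occupants is
#' the model's explicit stand-in, fitted by grid search: for each hazard
#' value, a common-random-number Monte-Carlo ensemble is run and the sum of
#' squared errors between the simulated transition medians and the anchor
#' values is evaluated; the minimizing hazard is returned. An optimum on the
#' edge of the grid sets `boundary = TRUE`.
#'
#' @inheritParams run_monte_carlo
#' @param anchors Named numeric vector of transition-position medians keyed
#'   by year (default: the published first/last projection years,
#'   [endpoint_anchors()]).
#' @param hazard_grid Candidate hazards.
#' @param n_replicates Replicates per grid point.
#' @return An object of class `quota_calibration`: list with `hazard`,
#'   `sse`, `grid` (tibble of hazard vs. error), `boundary`, `anchors`.
#' @examples
#' \donttest{
#' cal <- calibrate_hazard(n_replicates = 50, master_seed = 1,
#'                         hazard_grid = seq(0, 0.5, 0.1))
#' cal$hazard
#' }
#' @export
calibrate_hazard <- function(marginals = survey_marginals(),
                             state_counts = default_state_counts(),
                             scenario = policy_scenario(),
                             anchors = endpoint_anchors(),
                             n_replicates = 200,
                             hazard_grid = seq(0, 0.5, by = 0.01),
                             master_seed = 20140522,
                             fte = fte_parameters(marginals = marginals)) {
  if (length(anchors) == 0) {
    abort_validation("calibration requires at least one (year, median) anchor")
  }
  anchor_years <- as.integer(names(anchors))
  if (any(is.na(anchor_years))) {
    abort_validation("anchors must be named by calendar year")
  }
  if (any(anchor_years < scenario$start_year |
            anchor_years > scenario$horizon_year)) {
    abort_validation("anchor years must lie within the scenario horizon")
  }
  sse <- purrr::map_dbl(hazard_grid, function(h) {
    sc <- scenario
    sc$foreign_departure_hazard <- h
    ens <- run_monte_carlo(marginals, state_counts, sc, n_replicates,
                           master_seed, fte)
    sim <- dplyr::filter(ens$summary, .data$quantity == "n_transition",
                         .data$year %in% anchor_years)
    sim <- sim$median[match(anchor_years, sim$year)]
    sum((sim - anchors)^2)
  })
  best <- which.min(sse)
  boundary <- best %in% c(1L, length(hazard_grid))
  if (boundary) {
    warn("calibrated hazard lies on the grid boundary; the grid may not bracket the optimum")
  }
  structure(
    list(
      hazard = hazard_grid[best],
      sse = sse[best],
      grid = tibble::tibble(hazard = hazard_grid, sse = sse),
      boundary = boundary,
      anchors = anchors
    ),
    class = "quota_calibration"
  )
}

#' @export
print.quota_calibration <- function(x, ...) {
  cat("<quota_calibration> hazard =", x$hazard, "(sse =",
      format(x$sse, digits = 4), ")\n")
  if (x$boundary) cat("  note: optimum on grid boundary\n")
  invisible(x)
}

#' @export
tidy.quota_calibration <- function(x, ...) {
  x$grid
}

#' @export
glance.quota_calibration <- function(x, ...) {
  tibble::tibble(hazard = x$hazard, sse = x$sse, boundary = x$boundary,
                 n_anchors = length(x$anchors))
}
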