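roster_columns <- c(
  "person_id", "age", "gender", "nationality", "state", "hospital",
  "part_time", "fte_weight", "desired_retirement_age", "years_in_state",
  "total_training_duration"
)

# sampling probabilities derived from a marginal (normalized within its own
# observed total; item non-response is thereby ignored)
marginal_probs <- function(counts, field) {
  total <- sum(counts)
  if (total <= 0) {
    abort_validation(paste0("cannot sample: marginal '", field, "' is empty"))
  }
  counts / total
}

draw_categorical <- function(n, counts, field) {
  if (n == 0) return(character(0))
  p <- marginal_probs(counts, field)
  sample(names(counts), n, replace = TRUE, prob = p)
}

#' Draw desired retirement ages
#'
#' Desired retirement age is modelled as a normal distribution with the
#' surveyed gender-specific mean and SD (62/3.1 years for men, 60/2.8 for
#' women), truncated to the interval from 55 to the legal retirement age
#' (65 for men, 64 for women). Draws use inverse-CDF sampling, so a zero SD
#' degenerates to the mean.
#'
#' @param n Number of draws (used when `gender` has length 1).
#' @param gender Character vector of `"male"`/`"female"`; recycled via `n`.
#' @param marginals A [survey_marginals()] object supplying the moments.
#' @param legal_retirement_age Named upper truncation bounds by gender.
#' @param lower Lower truncation bound in years.
#' @return Numeric vector of ages in years.
#' @examples
#' set.seed(1)
#' summary(draw_retirement_age(1000, "male"))
#' @export
draw_retirement_age <- function(n = length(gender), gender,
                                marginals = survey_marginals(),
                                legal_retirement_age = c(male = 65, female = 64),
                                lower = 55) {
  if (length(gender) == 1) gender <- rep(gender, n)
  stopifnot(length(gender) == n)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (g in unique(gender)) {
    idx <- which(gender == g)
    mom <- marginals$retirement_age[[g]]
    if (is.null(mom)) abort_validation(paste0("no retirement-age moments for gender '", g, "'"))
    m <- mom[["mean"]]
    s <- mom[["sd"]]
    upper <- legal_retirement_age[[g]]
    if (s <= 0) {
      out[idx] <- pmin(pmax(m, lower), upper)
    } else {
      u <- runif(length(idx), pnorm(lower, m, s), pnorm(upper, m, s))
      out[idx] <- qnorm(u, m, s)
    }
  }
  out
}

#' Draw graduation-to-certification intervals
#'
#' Integer draws from the empirical distribution of the interval between
#' medical graduation and specialty certification (surveyed range 5 to 15+
#' years; the open category is drawn as 15).
#'
#' @param n Number of draws.
#' @param marginals A [survey_marginals()] object.
#' @return Integer vector of durations in years (all at least 5 under the
#'   default marginals, the official training length).
#' @examples
#' set.seed(1)
#' median(draw_training_duration(1e4))
#' @export
draw_training_duration <- function(n, marginals = survey_marginals()) {
  counts <- marginals$training_duration_counts
  lab <- draw_categorical(n, counts, "training_duration_counts")
  as.integer(sub("\\+$", "", lab))
}

# residual age-band probabilities for the FIXED state: overall band marginal
# minus the expected contributions of the TRAINING and TRANSITION age schemes,
# so the whole cohort reproduces the surveyed age-band marginal.
fixed_band_probs <- function(marginals, state_counts) {
  bands <- marginals$age_band_counts
  p_band <- marginal_probs(bands, "age_band_counts")
  n_total <- sum(state_counts)
  target <- p_band * n_total
  n_train <- state_counts[["TRAINING"]]
  n_trans <- state_counts[["TRANSITION"]]
  # TRAINING ~ U[26,35]: all below 36; TRANSITION ~ U[31,45]: P(<36) = 5/14
  contrib <- c(
    n_train + n_trans * 5 / 14,
    n_trans * 9 / 14,
    0
  )
  resid <- pmax(0, target - contrib)
  if (sum(resid) <= 0) return(p_band)
  resid / sum(resid)
}

# age for FIXED members given band index (1..3): bands 1-2 piecewise-uniform;
# band 3 (56+) from the stationary-population density, proportional to the
# survival function of the gendered desired-retirement distribution, so that
# the standing stock above 56 is consistent with a steady retirement outflow
# (a uniform band-3 age would over-represent people within months of
# retirement and front-load the retirement flow). Desired retirement age is
# drawn afterwards, conditioned on exceeding current age.
fixed_age_from_band <- function(band, gender, marginals, legal_retirement_age) {
  n <- length(band)
  age <- numeric(n)
  b12 <- band < 3
  if (any(b12)) {
    lo <- c(33, 36)[band[b12]]
    hi <- c(36, 56)[band[b12]]
    age[b12] <- runif(sum(b12), lo, hi)
  }
  for (g in unique(gender[band == 3])) {
    idx <- which(band == 3 & gender == g)
    mom <- marginals$retirement_age[[g]]
    m <- mom[["mean"]]
    s <- mom[["sd"]]
    legal <- legal_retirement_age[[g]]
    if (s <= 0) {
      age[idx] <- runif(length(idx), 56, max(m, 56.5))
    } else {
      # rejection sampling with density ratio S(a)/S(56)
      pending <- idx
      p_hi <- pnorm(legal, m, s)
      s56 <- p_hi - pnorm(56, m, s)
      while (length(pending)) {
        a <- runif(length(pending), 56, legal - 0.01)
        accept <- runif(length(pending)) < (p_hi - pnorm(a, m, s)) / s56
        age[pending[accept]] <- a[accept]
        pending <- pending[!accept]
      }
    }
  }
  age
}

# survivorship draw: desired retirement age conditional on exceeding the
# person's current age (an active anaesthetist aged a has R > a)
draw_retirement_age_conditional <- function(gender, age, marginals,
                                            legal_retirement_age, lower = 55) {
  n <- length(gender)
  out <- numeric(n)
  for (g in unique(gender)) {
    idx <- which(gender == g)
    mom <- marginals$retirement_age[[g]]
    m <- mom[["mean"]]
    s <- mom[["sd"]]
    upper <- legal_retirement_age[[g]]
    lo <- pmax(lower, age[idx])
    if (s <= 0) {
      out[idx] <- pmin(pmax(m, lo), upper)
    } else {
      u <- runif(length(idx), pnorm(lo, m, s), pnorm(upper, m, s))
      out[idx] <- qnorm(u, m, s)
    }
  }
  out
}

sample_people <- function(n, state, marginals, part_time_weight,
                          legal_retirement_age, state_counts) {
  gender <- draw_categorical(n, marginals$gender_counts, "gender_counts")
  key <- c(TRAINING = "training", TRANSITION = "transition", FIXED = "fixed")[[state]]
  w_swiss <- marginals$position_by_nationality$swiss[key] %||% 0
  w_foreign <- marginals$position_by_nationality$foreign[key] %||% 0
  nationality <- draw_categorical(
    n, c(swiss = unname(w_swiss), foreign = unname(w_foreign)),
    paste0("position_by_nationality[", key, "]")
  )
  hospital <- character(n)
  for (nat in unique(nationality)) {
    idx <- which(nationality == nat)
    hospital[idx] <- draw_categorical(
      length(idx), marginals$hospital_by_nationality[[nat]],
      paste0("hospital_by_nationality$", nat)
    )
  }
  if (state == "TRAINING") {
    age <- runif(n, 26, 35)
    yis <- runif(n, 0, 5)
  } else if (state == "TRANSITION") {
    age <- runif(n, 31, 45)
    yis <- runif(n, 0, 4)
  } else {
    probs <- fixed_band_probs(marginals, state_counts)
    band <- sample.int(3, n, replace = TRUE, prob = probs)
    age <- fixed_age_from_band(band, gender, marginals, legal_retirement_age)
    yis <- runif(n, 0, pmax(age - 33, 0))
  }
  retire_age <- draw_retirement_age_conditional(gender, age, marginals,
                                                legal_retirement_age)
  part_time <- runif(n) < marginal_probs(marginals$parttime_counts,
                                         "parttime_counts")[["part_time"]]
  data.frame(
    person_id = NA_integer_,
    age = age,
    gender = gender,
    nationality = nationality,
    state = state,
    hospital = hospital,
    part_time = part_time,
    fte_weight = ifelse(part_time, part_time_weight, 1),
    desired_retirement_age = retire_age,
    years_in_state = yis,
    total_training_duration = draw_training_duration(n, marginals),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic roster of active anaesthetists
#'
#' Builds an individual-level stand-in for the (undeposited) person-level
#' survey data: one row per active anaesthetist, with attributes drawn from
#' the surveyed marginals. Nationality is drawn conditional on state from the
#' position-by-nationality cross-tab and hospital type conditional on
#' nationality; ages are drawn conditional on career stage (training
#' uniform 26-35, transition uniform 31-45, fixed from the residual age-band
#' distribution so the cohort reproduces the surveyed age-band marginal);
#' remaining attributes are sampled independently from their marginals.
#' Desired retirement age is drawn from the gendered truncated normal
#' conditioned on exceeding the person's current age (survivorship: an
#' anaesthetist still active at 58 has not yet reached their desired
#' retirement age), so it is always strictly above current age for active
#' records.
#'
#' @param marginals A [survey_marginals()] object.
#' @param state_counts Named counts of actives per state
#'   (default `c(TRAINING = 66, TRANSITION = 99, FIXED = 248)`).
#' @param fte [fte_parameters()] supplying the part-time FTE weight.
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   RNG state is restored afterwards.
#' @param legal_retirement_age Named truncation bounds by gender.
#' @return A tibble with one row per person and columns `person_id`, `age`,
#'   `gender`, `nationality`, `state`, `hospital`, `part_time`, `fte_weight`,
#'   `desired_retirement_age`, `years_in_state`, `total_training_duration`.
#' @examples
#' roster <- sample_cohort(seed = 1)
#' dplyr::count(roster, state)
#' @export
sample_cohort <- function(marginals = survey_marginals(),
                          state_counts = default_state_counts(),
                          fte = fte_parameters(marginals = marginals),
                          seed = NULL,
                          legal_retirement_age = c(male = 65, female = 64)) {
  if (!all(c("TRAINING", "TRANSITION", "FIXED") %in% names(state_counts))) {
    abort_validation("state_counts must name TRAINING, TRANSITION and FIXED")
  }
  if (any(state_counts < 0)) abort_validation("state_counts must be non-negative")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  blocks <- purrr::map(
    c("TRAINING", "TRANSITION", "FIXED"),
    function(s) {
      n <- state_counts[[s]]
      if (n == 0) return(NULL)
      sample_people(n, s, marginals, fte$part_time_weight,
                    legal_retirement_age, state_counts)
    }
  )
  roster <- dplyr::bind_rows(blocks)
  if (nrow(roster) == 0) {
    roster <- empty_roster()
  } else {
    roster$person_id <- seq_len(nrow(roster))
  }
  tibble::as_tibble(roster)
}

empty_roster <- function() {
  tibble::tibble(
    person_id = integer(0), age = numeric(0), gender = character(0),
    nationality = character(0), state = character(0), hospital = character(0),
    part_time = logical(0), fte_weight = numeric(0),
    desired_retirement_age = numeric(0), years_in_state = numeric(0),
    total_training_duration = numeric(0)
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Draw new training entrants under the quota-refill rule
#'
#' Entrants are young trainees: age uniform 26-30, gender from the surveyed
#' gender marginal, part-time status from the part/full-time marginal, and
#' nationality from the surveyed trainee mix (24 foreign of 66 under the
#' default marginals). Hospital follows nationality; desired retirement age
#' and certification latency are drawn as for the initial cohort;
#' `years_in_state` starts at 0.
#'
#' @inheritParams sample_cohort
#' @param n Number of entrants.
#' @param part_time_weight FTE weight assigned to part-time entrants.
#' @return A tibble of entrant rows (person_id unset; assigned by the caller).
#' @export
sample_entrants <- function(n, marginals = survey_marginals(),
                            part_time_weight = fte_parameters(marginals = marginals)$part_time_weight,
                            legal_retirement_age = c(male = 65, female = 64)) {
  if (n == 0) return(empty_roster())
  out <- sample_people(n, "TRAINING", marginals, part_time_weight,
                       legal_retirement_age,
                       c(TRAINING = n, TRANSITION = 0, FIXED = 0))
  out$age <- runif(n, 26, 30)
  out$years_in_state <- rep(0, n)
  tibble::as_tibble(out)
}

#' Goodness-of-fit of a roster against the survey marginals
#'
#' Chi-square tests of the roster's realized category counts against the
#' expected counts implied by the sampling design: gender, part/full-time,
#' age bands, state occupancy, nationality given state, and hospital type
#' given nationality. Marginals whose expected counts fall below 5 in any
#' category are flagged `insufficient_counts` rather than tested.
#'
#' @param roster A roster tibble from [sample_cohort()] (active rows are
#'   used).
#' @param marginals The [survey_marginals()] the roster was drawn from.
#' @param alpha Significance level for the pass flag.
#' @return A tibble with columns `marginal`, `statistic`, `df`, `p_value`,
#'   `pass`, `note`.
#' @examples
#' r <- sample_cohort(seed = 1)
#' validate_cohort(r)
#' @export
validate_cohort <- function(roster, marginals = survey_marginals(), alpha = 0.01) {
  if (nrow(roster) == 0) abort_validation("roster is empty")
  active <- dplyr::filter(roster, .data$state %in% c("TRAINING", "TRANSITION", "FIXED"))
  n <- nrow(active)
  state_counts <- c(
    TRAINING = sum(active$state == "TRAINING"),
    TRANSITION = sum(active$state == "TRANSITION"),
    FIXED = sum(active$state == "FIXED")
  )

  checks <- list()
  obs_over <- function(values, categories) {
    tab <- table(factor(values, levels = categories))
    as.numeric(tab)
  }

  checks$gender <- list(
    obs = obs_over(active$gender, names(marginals$gender_counts)),
    p = marginal_probs(marginals$gender_counts, "gender_counts")
  )
  checks$part_time <- list(
    obs = c(sum(active$part_time), sum(!active$part_time)),
    p = marginal_probs(marginals$parttime_counts, "parttime_counts")
  )
  band <- cut(active$age, c(-Inf, 36, 56, Inf), right = FALSE,
              labels = names(marginals$age_band_counts))
  checks$age_bands <- list(
    obs = as.numeric(table(band)),
    p = marginal_probs(marginals$age_band_counts, "age_band_counts")
  )
  for (s in c("TRAINING", "TRANSITION", "FIXED")) {
    if (state_counts[[s]] == 0) next
    key <- c(TRAINING = "training", TRANSITION = "transition", FIXED = "fixed")[[s]]
    w <- c(
      swiss = unname(marginals$position_by_nationality$swiss[key] %||% 0),
      foreign = unname(marginals$position_by_nationality$foreign[key] %||% 0)
    )
    rows <- active[active$state == s, ]
    checks[[paste0("nationality_", tolower(s))]] <- list(
      obs = obs_over(rows$nationality, c("swiss", "foreign")),
      p = marginal_probs(w, "position_by_nationality")
    )
  }
  for (nat in c("swiss", "foreign")) {
    rows <- active[active$nationality == nat, ]
    if (nrow(rows) == 0) next
    checks[[paste0("hospital_", nat)]] <- list(
      obs = obs_over(rows$hospital, names(marginals$hospital_by_nationality[[nat]])),
      p = marginal_probs(marginals$hospital_by_nationality[[nat]],
                         paste0("hospital_by_nationality$", nat))
    )
  }

  purrr::map_dfr(names(checks), function(nm) {
    obs <- checks[[nm]]$obs
    p <- as.numeric(checks[[nm]]$p)
    expected <- sum(obs) * p
    keep <- p > 0
    if (any(expected[keep] < 5) || sum(obs) == 0) {
      return(tibble::tibble(
        marginal = nm, statistic = NA_real_, df = NA_integer_,
        p_value = NA_real_, pass = NA, note = "insufficient_counts"
      ))
    }
    if (any(!keep) && any(obs[!keep] > 0)) {
      return(tibble::tibble(
        marginal = nm, statistic = Inf, df = sum(keep) - 1L,
        p_value = 0, pass = FALSE, note = "mass_in_zero_probability_category"
      ))
    }
    if (sum(keep) < 2) {
      return(tibble::tibble(
        marginal = nm, statistic = 0, df = 0L, p_value = 1,
        pass = TRUE, note = "single_category"
      ))
    }
    ct <- stats::chisq.test(obs[keep], p = p[keep] / sum(p[keep]))
    tibble::tibble(
      marginal = nm, statistic = unname(ct$statistic),
      df = as.integer(unname(ct$parameter)), p_value = unname(ct$p.value),
      pass = unname(ct$p.value) > alpha, note = ""
    )
  })
}
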