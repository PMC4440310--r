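# Hand-built rosters and degenerate marginals used across test files.

# one roster row with explicit career attributes; everything else benign
make_person <- function(id, state, age, yis = 0, retire_age = 80,
                        nationality = "swiss", gender = "male",
                        part_time = FALSE, fte_weight = 1) {
  tibble::tibble(
    person_id = as.integer(id),
    age = age,
    gender = gender,
    nationality = nationality,
    state = state,
    hospital = "district",
    part_time = part_time,
    fte_weight = fte_weight,
    desired_retirement_age = retire_age,
    years_in_state = yis,
    total_training_duration = 9
  )
}

make_roster <- function(...) dplyr::bind_rows(...)

# marginals with all randomness that could affect state counts removed:
# no part-time staff and a degenerate trainee nationality mix, so entrant
# attribute draws never alter the census arithmetic
degenerate_marginals <- function(entrant_nationality = c("swiss", "foreign")) {
  entrant_nationality <- match.arg(entrant_nationality)
  training <- if (entrant_nationality == "swiss") {
    list(swiss = 66, foreign = 0)
  } else {
    list(swiss = 0, foreign = 66)
  }
  survey_marginals(
    parttime_counts = c(part_time = 0, full_time = 412),
    position_by_nationality = list(
      swiss = c(fixed = 218, transition = 80, training = training$swiss),
      foreign = c(fixed = 31, transition = 20, training = training$foreign)
    )
  )
}

degenerate_fte <- function() fte_parameters(part_time_weight = 0.5)
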