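#' Survey marginals parameterizing the workforce model
#'
#' Container for the published survey's marginal distributions and parametric
#' summaries that drive cohort generation: age bands, gender, part/full-time
#' counts, nationality, position and hospital-type cross-tabulated by
#' nationality, desired-retirement-age moments by gender, and the empirical
#' distribution of the interval between graduation and specialty certification.
#' Defaults are the counts observed in the 2014 cross-sectional survey of all
#' anaesthetists practising in the French- and Italian-speaking cantons of
#' Switzerland (506 listed, 416 usable responses).
#'
#' Category totals differ across variables (407 for age, 410 for gender, 412
#' for part/full-time, 413 for positions) because of item non-response; each
#' marginal is normalized within its own observed total when converted to
#' sampling probabilities. "Foreign" merges the European and extra-European
#' categories, which the survey analyses jointly. The printed nationality-by-
#' position cross-tab sums to 249/100/66 by state while the all-anaesthetists
#' column prints 248/99/66; validation therefore tolerates a discrepancy of up
#' to 2 between cross-tab totals and state headcounts, and the cross-tab is
#' only ever used as conditional nationality-given-state weights.
#'
#' @param age_band_counts Named counts for bands `<=35`, `36-55`, `>=56`.
#' @param gender_counts Named counts for `female`, `male`.
#' @param parttime_counts Named counts for `part_time`, `full_time`.
#' @param nationality_counts Named counts for `swiss`, `european`, `other`.
#' @param position_by_nationality List with elements `swiss` and `foreign`,
#'   each a named count vector over `fixed`, `transition`, `training`.
#' @param hospital_by_nationality List with elements `swiss` and `foreign`,
#'   each a named count vector over `university`, `district`, `private`,
#'   `office`.
#' @param retirement_age List with elements `male` and `female`, each
#'   `c(mean = , sd = )` in years (desired, not legal, retirement age).
#' @param training_duration_counts Named counts over whole years `"5"` ...
#'   `"14"` and `"15+"` for the graduation-to-certification interval.
#' @param listed_n,responded_n Survey frame size and usable responses.
#' @return An object of class `survey_marginals`.
#' @seealso [load_marginals()], [describe_survey()], [sample_cohort()]
#' @examples
#' m <- survey_marginals()
#' m$gender_counts
#' tidy(m)
#' @export
survey_marginals <- function(
    age_band_counts = c("<=35" = 97, "36-55" = 254, ">=56" = 56),
    gender_counts = c(female = 171, male = 239),
    parttime_counts = c(part_time = 97, full_time = 315),
    nationality_counts = c(swiss = 338, european = 69, other = 6),
    position_by_nationality = list(
      swiss   = c(fixed = 218, transition = 80, training = 42),
      foreign = c(fixed = 31, transition = 20, training = 24)
    ),
    hospital_by_nationality = list(
      swiss   = c(university = 133, district = 119, private = 82, office = 2),
      foreign = c(university = 28, district = 36, private = 10, office = 0)
    ),
    retirement_age = list(
      male   = c(mean = 62, sd = 3.1),
      female = c(mean = 60, sd = 2.8)
    ),
    training_duration_counts = c(
      "5" = 10, "6" = 32, "7" = 42, "8" = 36, "9" = 31, "10" = 36,
      "11" = 24, "12" = 15, "13" = 10, "14" = 7, "15+" = 25
    ),
    listed_n = 506,
    responded_n = 416) {
  num <- function(x) setNames(as.numeric(x), names(x))
  x <- list(
    age_band_counts = num(age_band_counts),
    gender_counts = num(gender_counts),
    parttime_counts = num(parttime_counts),
    nationality_counts = num(nationality_counts),
    position_by_nationality = lapply(position_by_nationality, num),
    hospital_by_nationality = lapply(hospital_by_nationality, num),
    retirement_age = lapply(retirement_age, num),
    training_duration_counts = num(training_duration_counts),
    listed_n = as.numeric(listed_n),
    responded_n = as.numeric(responded_n)
  )
  validate_marginals(structure(x, class = "survey_marginals"))
}

#' Validate a `survey_marginals` object
#'
#' Checks non-negativity of every count, that each marginal's total does not
#' exceed the number of respondents (item non-response is allowed), that the
#' desired retirement means lie below the legal retirement ages, and that the
#' nationality-by-position cross-tab totals agree with the initialization
#' headcounts to within the printing discrepancy of the source table.
#'
#' @param x A `survey_marginals` object.
#' @param state_counts Optional initialization headcounts (`TRAINING`,
#'   `TRANSITION`, `FIXED`) to check the cross-tab against; `NULL` skips the
#'   check (used for deliberately reduced marginals in sensitivity work).
#' @param legal_retirement_age Named vector of legal ages by gender.
#' @return `x` if valid; otherwise a validation error naming the offending
#'   field.
#' @export
validate_marginals <- function(x,
                               state_counts = NULL,
                               legal_retirement_age = c(male = 65, female = 64)) {
  required <- c(
    "age_band_counts", "gender_counts", "parttime_counts",
    "nationality_counts", "position_by_nationality",
    "hospital_by_nationality", "retirement_age",
    "training_duration_counts", "listed_n", "responded_n"
  )
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_validation(paste0("marginals are missing field(s): ",
                            paste(missing, collapse = ", ")))
  }
  counts <- list(
    age_band_counts = x$age_band_counts,
    gender_counts = x$gender_counts,
    parttime_counts = x$parttime_counts,
    nationality_counts = x$nationality_counts,
    training_duration_counts = x$training_duration_counts
  )
  counts <- c(counts,
              setNames(x$position_by_nationality,
                       paste0("position_by_nationality$", names(x$position_by_nationality))),
              setNames(x$hospital_by_nationality,
                       paste0("hospital_by_nationality$", names(x$hospital_by_nationality))))
  for (nm in names(counts)) {
    if (!is_count_vector(counts[[nm]])) {
      abort_validation(paste0("field '", nm, "' must contain non-negative finite counts"))
    }
  }
  if (x$responded_n <= 0 || x$listed_n <= 0 || x$responded_n > x$listed_n) {
    abort_validation("survey frame requires 0 < responded_n <= listed_n")
  }
  per_marginal <- c(
    age_band_counts = sum(x$age_band_counts),
    gender_counts = sum(x$gender_counts),
    parttime_counts = sum(x$parttime_counts),
    nationality_counts = sum(x$nationality_counts)
  )
  over <- per_marginal[per_marginal > x$responded_n]
  if (length(over)) {
    abort_validation(paste0("field '", names(over)[1],
                            "' totals more than responded_n"))
  }
  for (g in c("male", "female")) {
    ra <- x$retirement_age[[g]]
    if (is.null(ra) || !all(c("mean", "sd") %in% names(ra)) || ra[["sd"]] < 0) {
      abort_validation(paste0("retirement_age$", g, " needs a mean and a non-negative sd"))
    }
    if (ra[["mean"]] >= legal_retirement_age[[g]]) {
      abort_validation(paste0("retirement_age$", g,
                              " mean must lie below the legal retirement age"))
    }
  }
  if (!is.null(state_counts)) {
    # cross-tab state totals vs initialization headcounts (printing tolerance 2)
    xt <- crosstab_state_totals(x)
    tgt <- c(
      TRAINING = unname(state_counts[["TRAINING"]]),
      TRANSITION = unname(state_counts[["TRANSITION"]]),
      FIXED = unname(state_counts[["FIXED"]])
    )
    if (any(abs(xt[names(tgt)] - tgt) > 2)) {
      warn(paste0(
        "position_by_nationality state totals (",
        paste(xt[names(tgt)], collapse = "/"),
        ") differ from initialization headcounts (",
        paste(tgt, collapse = "/"),
        ") by more than the printing tolerance"
      ))
    }
  }
  x
}

crosstab_state_totals <- function(m) {
  pos <- function(nat, p) {
    v <- m$position_by_nationality[[nat]]
    if (p %in% names(v)) v[[p]] else 0
  }
  c(
    TRAINING = pos("swiss", "training") + pos("foreign", "training"),
    TRANSITION = pos("swiss", "transition") + pos("foreign", "transition"),
    FIXED = pos("swiss", "fixed") + pos("foreign", "fixed")
  )
}

#' Initialization headcounts of the active workforce
#'
#' The surveyed active workforce used to seed the simulation: 66 in training,
#' 99 in transition (senior-registrar) and 248 in fixed positions, 413 in all.
#'
#' @return Named numeric vector over `TRAINING`, `TRANSITION`, `FIXED`.
#' @export
default_state_counts <- function() {
  c(TRAINING = 66, TRANSITION = 99, FIXED = 248)
}

#' @export
print.survey_marginals <- function(x, ...) {
  cat("<survey_marginals>\n")
  cat("  respondents:", x$responded_n, "of", x$listed_n, "listed\n")
  cat("  gender     :", paste(names(x$gender_counts), x$gender_counts,
                              collapse = ", "), "\n")
  cat("  positions  :", paste(names(crosstab_state_totals(x)),
                              crosstab_state_totals(x), collapse = ", "), "\n")
  cat("  part-time  :", x$parttime_counts[["part_time"]], "of",
      sum(x$parttime_counts), "\n")
  invisible(x)
}

#' @export
tidy.survey_marginals <- function(x, ...) {
  simple <- c("age_band_counts", "gender_counts", "parttime_counts",
              "nationality_counts", "training_duration_counts")
  rows <- purrr::map_dfr(simple, function(nm) {
    tibble::tibble(variable = nm, group = NA_character_,
                   category = names(x[[nm]]), count = unname(x[[nm]]))
  })
  nested <- purrr::map_dfr(
    c("position_by_nationality", "hospital_by_nationality"),
    function(nm) {
      purrr::map_dfr(names(x[[nm]]), function(g) {
        tibble::tibble(variable = nm, group = g,
                       category = names(x[[nm]][[g]]),
                       count = unname(x[[nm]][[g]]))
      })
    }
  )
  dplyr::bind_rows(rows, nested)
}

#' Load survey marginals from a configuration file
#'
#' Reads a YAML or JSON configuration document (schema `quotasim-params-v1`,
#' as shipped in `system.file("extdata", "quotasim-params.yaml", package =
#' "quotasim")`), validates it and returns a [survey_marginals()] object.
#'
#' @param source Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `survey_marginals` object.
#' @examples
#' m <- load_marginals(quotasim_config())
#' m$position_by_nationality$foreign
#' @export
load_marginals <- function(source = quotasim_config()) {
  doc <- read_config(source)
  sv <- doc$survey
  if (is.null(sv)) abort_validation("config is missing the 'survey' section")
  need <- c("age_bands", "gender", "employment", "nationality",
            "position_by_nationality", "hospital_by_nationality",
            "retirement_age", "training_duration", "listed_n", "responded_n")
  missing <- setdiff(need, names(sv))
  if (length(missing)) {
    abort_validation(paste0("config survey section is missing field(s): ",
                            paste(missing, collapse = ", ")))
  }
  as_counts <- function(x, field) {
    v <- unlist(x)
    if (!is_count_vector(v)) {
      abort_validation(paste0("config field '", field,
                              "' must contain non-negative counts"))
    }
    v
  }
  survey_marginals(
    age_band_counts = as_counts(sv$age_bands, "age_bands"),
    gender_counts = as_counts(sv$gender, "gender"),
    parttime_counts = as_counts(sv$employment, "employment"),
    nationality_counts = as_counts(sv$nationality, "nationality"),
    position_by_nationality = lapply(sv$position_by_nationality, unlist),
    hospital_by_nationality = lapply(sv$hospital_by_nationality, unlist),
    retirement_age = lapply(sv$retirement_age, unlist),
    training_duration_counts = as_counts(sv$training_duration, "training_duration"),
    listed_n = sv$listed_n,
    responded_n = sv$responded_n
  )
}

read_config <- function(source) {
  if (!file.exists(source)) {
    abort_validation(paste0("config file not found: ", source))
  }
  ext <- tolower(tools::file_ext(source))
  doc <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(source),
    json = jsonlite::read_json(source, simplifyVector = TRUE),
    abort_validation("config must be a .yaml, .yml or .json document")
  )
  schema <- doc$schema %||% ""
  if (!identical(schema, "quotasim-params-v1")) {
    abort_validation("config schema must be 'quotasim-params-v1'")
  }
  doc
}

#' Path to the packaged default configuration
#'
#' @return Path to the YAML configuration holding the published survey
#'   marginals and the default policy scenario.
#' @export
quotasim_config <- function() {
  system.file("extdata", "quotasim-params.yaml", package = "quotasim")
}

#' Write survey marginals back to a YAML configuration file
#'
#' Serializes with the same schema read by [load_marginals()]; a write/load
#' round trip reproduces the object exactly.
#'
#' @param marginals A `survey_marginals` object.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_marginals <- function(marginals, path) {
  doc <- list(
    schema = "quotasim-params-v1",
    survey = list(
      listed_n = marginals$listed_n,
      responded_n = marginals$responded_n,
      age_bands = as.list(marginals$age_band_counts),
      gender = as.list(marginals$gender_counts),
      employment = as.list(marginals$parttime_counts),
      nationality = as.list(marginals$nationality_counts),
      position_by_nationality = lapply(marginals$position_by_nationality, as.list),
      hospital_by_nationality = lapply(marginals$hospital_by_nationality, as.list),
      retirement_age = lapply(marginals$retirement_age, as.list),
      training_duration = as.list(marginals$training_duration_counts)
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Percentage of a total, rounded to the nearest integer
#'
#' `100 * numerator / sum(category_counts)`, rounded half away from zero --
#' the convention of the source tables.
#'
#' @param numerator A count (one of the categories or a stated subtotal).
#' @param category_counts Counts over the categories forming the total.
#' @return Integer percent.
#' @examples
#' proportion(24, c(31, 20, 24)) # trainee share among foreign anaesthetists
#' proportion(36, c(28, 36, 10, 0)) # district-hospital share, foreign
#' @export
proportion <- function(numerator, category_counts) {
  total <- sum(category_counts)
  if (total <= 0) abort_validation("undefined proportion: category counts sum to zero")
  if (numerator < 0 || numerator > total) {
    abort_validation("numerator must lie between 0 and the category total")
  }
  as.integer(round_half_up(100 * numerator / total))
}

#' Percent change between two counts, rounded to the nearest integer
#'
#' @param before,after Counts; `before` must be positive.
#' @return Integer percent change `100 * (after - before) / before`.
#' @examples
#' percent_change(756, 813) # growth in annual medical graduates, 2000-2010
#' @export
percent_change <- function(before, after) {
  if (before <= 0) abort_validation("undefined percent change: 'before' must be positive")
  as.integer(round_half_up(100 * (after - before) / before))
}

#' Survey response rate, rounded to the nearest integer percent
#'
#' @param responded,listed Counts with `0 <= responded <= listed`.
#' @return Integer percent.
#' @examples
#' response_rate(416, 506)
#' @export
response_rate <- function(responded, listed) {
  if (listed <= 0) abort_validation("'listed' must be positive")
  if (responded < 0 || responded > listed) {
    abort_validation("'responded' must lie between 0 and 'listed'")
  }
  as.integer(round_half_up(100 * responded / listed))
}

#' Descriptive statistics of the survey
#'
#' Recomputes, from the raw marginal counts, the headline descriptive
#' percentages of the surveyed workforce: response rate, gender and part-time
#' shares, trainee shares by nationality, hospital-type shares, and the growth
#' in annual Swiss medical graduates.
#'
#' @param marginals A [survey_marginals()] object.
#' @param graduates Named counts `c(before = , after = )` of annual medical
#'   graduates at the ends of the observation window (2000 and 2010).
#' @return A tibble with columns `statistic`, `value` (integer percent) and
#'   `description`.
#' @examples
#' describe_survey()
#' @export
describe_survey <- function(marginals = survey_marginals(),
                            graduates = c(before = 756, after = 813)) {
  m <- marginals
  pos_s <- m$position_by_nationality$swiss
  pos_f <- m$position_by_nationality$foreign
  hos_s <- m$hospital_by_nationality$swiss
  hos_f <- m$hospital_by_nationality$foreign
  tibble::tibble(
    statistic = c(
      "response_rate_pct", "male_pct", "female_pct", "part_time_pct",
      "foreign_trainee_pct", "swiss_trainee_pct", "foreign_district_pct",
      "swiss_university_pct", "swiss_private_pct", "graduate_change_pct"
    ),
    value = c(
      response_rate(m$responded_n, m$listed_n),
      proportion(m$gender_counts[["male"]], m$gender_counts),
      proportion(m$gender_counts[["female"]], m$gender_counts),
      proportion(m$parttime_counts[["part_time"]], m$parttime_counts),
      proportion(pos_f[["training"]], pos_f),
      proportion(pos_s[["training"]], pos_s),
      proportion(hos_f[["district"]], hos_f),
      proportion(hos_s[["university"]], hos_s),
      proportion(hos_s[["private"]], hos_s),
      percent_change(graduates[["before"]], graduates[["after"]])
    ),
    description = c(
      "usable responses among listed anaesthetists",
      "male share of respondents",
      "female share of respondents",
      "part-time share of respondents",
      "trainee share among foreign anaesthetists",
      "trainee share among Swiss anaesthetists",
      "district-hospital share among foreign anaesthetists",
      "university-hospital share among Swiss anaesthetists",
      "private-hospital share among Swiss anaesthetists",
      "change in annual Swiss medical graduates over the window"
    )
  )
}

#' Published decade projection used for anchoring and benchmarking
#'
#' The published 2014-2024 projection of the four reported quantities (median
#' and 95% interval) for the default quota scenario. Used (a) to supply the
#' endpoint anchors for [calibrate_hazard()] and (b) as the benchmark the
#' simulated trajectory is compared against.
#'
#' @return A tibble with columns `year`, `quantity` (`n_training`,
#'   `n_transition`, `n_fixed`, `n_retired_this_year`), `median`, `lo95`,
#'   `hi95`.
#' @export
reference_projection <- function() {
  years <- 2014:2024
  tr <- function(m, lo, hi, q) {
    tibble::tibble(year = years, quantity = q, median = m, lo95 = lo, hi95 = hi)
  }
  dplyr::bind_rows(
    tr(rep(66, 11), rep(66, 11), rep(66, 11), "n_training"),
    tr(c(93, 92, 89, 90, 88, 81, 78, 70, 66, 60, 58),
       c(86, 85, 82, 83, 80, 74, 70, 61, 57, 51, 49),
       c(98, 98, 95, 98, 96, 89, 85, 77, 73, 68, 66), "n_transition"),
    tr(c(244, 244, 244, 244, 244, 244, 244, 245, 244, 244, 244),
       c(241, 241, 241, 241, 240, 240, 240, 241, 240, 240, 239),
       c(247, 247, 248, 248, 247, 248, 248, 249, 249, 249, 249), "n_fixed"),
    tr(c(12, 8, 9, 6, 10, 13, 11, 14, 11, 13, 9),
       c(8, 4, 5, 2, 6, 9, 7, 9, 7, 8, 5),
       c(16, 12, 14, 10, 14, 18, 16, 20, 16, 17, 14), "n_retired_this_year")
  )
}

#' Endpoint anchors for hazard calibration
#'
#' First and last projected transition-position medians of the published
#' projection, as `c("2014" = 93, "2024" = 58)`.
#'
#' @return Named numeric vector of transition medians keyed by year.
#' @export
endpoint_anchors <- function() {
  ref <- dplyr::filter(reference_projection(),
                       .data$quantity == "n_transition",
                       .data$year %in% c(2014, 2024))
  setNames(ref$median, ref$year)
}
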