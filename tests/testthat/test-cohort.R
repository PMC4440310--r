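test_that("sample_cohort draws the requested headcounts with valid attributes", {
  r <- sample_cohort(seed = 1)
  expect_equal(nrow(r), 413)
  expect_equal(sum(r$state == "TRAINING"), 66)
  expect_equal(sum(r$state == "TRANSITION"), 99)
  expect_equal(sum(r$state == "FIXED"), 248)
  expect_true(all(r$age >= 20))
  expect_true(all(r$age < r$desired_retirement_age))
  expect_true(all(r$total_training_duration >= 5))
  expect_true(all(r$fte_weight %in% c(1, fte_parameters()$part_time_weight)))
  expect_true(all(r$years_in_state >= 0))
  expect_true(all(r$years_in_state[r$state == "TRAINING"] <= 5))
  expect_true(all(r$years_in_state[r$state == "TRANSITION"] <= 4))
})

test_that("cohort draws are deterministic in the seed and differ across seeds", {
  a <- sample_cohort(seed = 99)
  b <- sample_cohort(seed = 99)
  expect_identical(a, b)
  c <- sample_cohort(seed = 100)
  expect_false(isTRUE(all.equal(a, c)))
  # empty request yields an empty roster
  empty <- sample_cohort(state_counts = c(TRAINING = 0, TRANSITION = 0, FIXED = 0),
                         seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("retirement-age draws match the truncated-normal law", {
  # closed-form moments of N(62, 3.1) truncated to [55, 65], computed
  # independently of the inversion sampler
  m <- 62; s <- 3.1; lo <- 55; hi <- 65
  a <- (lo - m) / s; b <- (hi - m) / s
  Z <- pnorm(b) - pnorm(a)
  mean_trunc <- m + s * (dnorm(a) - dnorm(b)) / Z
  set.seed(5)
  x <- draw_retirement_age(1e5, "male")
  expect_lt(abs(mean(x) - mean_trunc), 0.05)
  expect_lt(sd(x), 3.1) # truncation shrinks the SD below the survey value
  expect_true(all(x <= 65) && all(x >= 55))
  y <- draw_retirement_age(1e4, "female")
  expect_true(all(y <= 64))
  # degenerate SD pins the draw at the mean
  m0 <- survey_marginals(retirement_age = list(male = c(mean = 62, sd = 3.1),
                                               female = c(mean = 60, sd = 0)))
  expect_true(all(draw_retirement_age(100, "female", m0) == 60))
})

test_that("training-duration draws follow the empirical certification-latency table", {
  set.seed(6)
  d <- draw_training_duration(1e5)
  expect_equal(median(d), 9) # published median graduation-to-certification interval
  expect_true(all(d >= 5) && all(d <= 15))
  single <- survey_marginals(training_duration_counts = c("5" = 12))
  expect_true(all(draw_training_duration(50, single) == 5))
})

test_that("category frequencies converge to their marginals in a large cohort", {
  n <- c(TRAINING = 16000, TRANSITION = 24000, FIXED = 60000)
  r <- sample_cohort(state_counts = n, seed = 3)
  m <- survey_marginals()
  tol <- 0.01
  expect_lt(abs(mean(r$gender == "female") - 171 / 410), tol)
  expect_lt(abs(mean(r$part_time) - 97 / 412), tol)
  # nationality conditional on state, from the printed cross-tab
  tr <- r[r$state == "TRAINING", ]
  expect_lt(abs(mean(tr$nationality == "foreign") - 24 / 66), tol)
  fx <- r[r$state == "FIXED", ]
  expect_lt(abs(mean(fx$nationality == "foreign") - 31 / 249), tol)
  # hospital conditional on nationality
  fo <- r[r$nationality == "foreign", ]
  expect_lt(abs(mean(fo$hospital == "district") - 36 / 74), tol)
  # age bands: reproduced within the design tolerance at cohort scale
  bands <- table(cut(r$age, c(-Inf, 36, 56, Inf), right = FALSE)) / nrow(r)
  target <- c(97, 254, 56) / 407
  expect_true(all(abs(as.numeric(bands) - target) < tol))
})

test_that("validate_cohort passes a faithful roster and flags a biased one", {
  r <- sample_cohort(seed = 1)
  rep <- validate_cohort(r)
  testable <- rep[!is.na(rep$pass), ]
  expect_gt(nrow(testable), 4)
  expect_true(all(testable$pass))
  # all-male roster against the surveyed gender split must fail
  r_male <- dplyr::mutate(r, gender = "male")
  rep_male <- validate_cohort(r_male)
  expect_false(rep_male$pass[rep_male$marginal == "gender"])
  # a single person cannot support the test
  rep_one <- validate_cohort(r[1, ])
  expect_true(all(rep_one$note == "insufficient_counts"))
  expect_error(validate_cohort(r[0, ]), class = "quotasim_validation_error")
})

test_that("sampling errors name the empty marginal", {
  bad <- survey_marginals(position_by_nationality = list(
    swiss = c(fixed = 218, transition = 80, training = 0),
    foreign = c(fixed = 31, transition = 20, training = 0)
  ))
  expect_error(sample_cohort(bad, seed = 1), "position_by_nationality")
})

test_that("entrants are young trainees drawn from the surveyed mixes", {
  set.seed(8)
  e <- sample_entrants(5000)
  expect_true(all(e$age >= 26 & e$age <= 30))
  expect_true(all(e$state == "TRAINING"))
  expect_true(all(e$years_in_state == 0))
  expect_lt(abs(mean(e$nationality == "foreign") - 24 / 66), 0.02)
  expect_lt(abs(mean(e$gender == "female") - 171 / 410), 0.02)
})
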