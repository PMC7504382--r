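# survey conversions, risk-perception congruence, and the Level of Satisfaction

test_that("personal conversion follows the performance curve, peaking at 'focused'", {
  expect_identical(convert_personal(1:6), c(1L, 3L, 5L, 25L, 15L, 9L))
  v <- convert_personal(1:6)
  expect_identical(which.max(v), 4L) # unimodal with maximum at answer 4
  expect_true(all(diff(v[1:4]) > 0) && all(diff(v[4:6]) < 0))
  expect_error(convert_personal(0), class = "lpac_error_range")
  expect_error(convert_personal(7), class = "lpac_error_range")
})

test_that("environment conversion is the strictly monotone scale map", {
  expect_identical(convert_environment(1:6), c(1L, 3L, 5L, 9L, 15L, 25L))
  expect_true(all(diff(convert_environment(1:6)) > 0))
  expect_error(convert_environment(2.5), class = "lpac_error_range")
})

test_that("congruence ratio is the mean of worker/assessor ratios on the 0.2 grid", {
  expect_equal(congruence_ratio(c(4, 4), c(4, 4)),
               tibble::tibble(ratio = 1, grid = 1))
  got <- congruence_ratio(c(3, 3, 3, 3), c(5, 5, 5, 5))
  expect_equal(got$ratio, 0.6)
  expect_equal(got$grid, 0.6)
  # facade environment block: ratios 1.0 and 1.2 average 1.1, and the grid
  # midpoint snaps away from 1.0 (to 1.2)
  got <- congruence_ratio(c(5, 6), c(5, 5))
  expect_equal(got$ratio, 1.1)
  expect_equal(got$grid, 1.2)
  # below 1 the midpoint snaps down: ratios (0.8, 1.0) -> 0.9 -> 0.8
  expect_equal(congruence_ratio(c(4, 5), c(5, 5))$grid, 0.8)
  # extreme over-confidence clamps to the end of the grid
  expect_equal(congruence_ratio(c(6, 6), c(1, 1))$ratio, 2)
  expect_error(congruence_ratio(c(1, 2), c(1, 2, 3)),
               class = "lpac_error_validation")
  expect_error(congruence_ratio(integer(0), integer(0)),
               class = "lpac_error_range")
})

test_that("the congruence tent map is symmetric about perfect congruence", {
  grid <- seq(0, 2, by = 0.2)
  expect_identical(congruence_cv(grid),
                   c(1L, 3L, 5L, 9L, 15L, 25L, 15L, 9L, 5L, 3L, 1L))
  expect_identical(congruence_cv(1.0), 25L)
  for (d in seq(0.2, 1, by = 0.2)) {
    expect_identical(congruence_cv(1 - d), congruence_cv(1 + d))
  }
  expect_error(congruence_cv(0.5), class = "lpac_error_validation")
  expect_error(congruence_cv(2.2), class = "lpac_error_validation")
})

test_that("the level of satisfaction averages its three components and rounds to the scale", {
  got <- level_of_satisfaction(13, 9, 15)
  expect_equal(got$ls_raw, 37 / 3, tolerance = 1e-12) # 12.33
  expect_identical(got$ls_cv, 15L)
  expect_identical(level_of_satisfaction(25, 25, 25)$ls_cv, 25L)
  got <- level_of_satisfaction(1, 3, 5)
  expect_equal(got$ls_raw, 3)
  expect_identical(got$ls_cv, 3L)
  expect_error(level_of_satisfaction(0, 9, 15), class = "lpac_error_range")
})

make_survey <- function(workers, assessor) {
  qs <- c(paste0("personal_", 1:4), paste0("environment_", 1:2),
          paste0("safety_", 1:4))
  rows <- purrr::imap(workers, function(ans, id) {
    tibble::tibble(respondent = "worker", id = id, question = qs, answer = ans)
  })
  dplyr::bind_rows(c(unname(rows), list(
    tibble::tibble(respondent = "assessor", id = "a",
                   question = qs[5:10], answer = assessor)
  )))
}

test_that("full congruence between worker and assessor yields the maximal perception values", {
  ans <- c(4L, 4L, 4L, 4L, 3L, 5L, 2L, 6L, 4L, 1L)
  sat <- satisfaction_from_survey(make_survey(list(w1 = ans), ans[5:10]))
  expect_equal(sat$workers$safety_cv, 25)
  expect_equal(sat$workers$environment_cv, 25)
  expect_equal(sat$workers$personal_cv, 25) # all personal answers at the peak
  expect_identical(sat$ls_cv, 25L)
})

test_that("site satisfaction averages per-worker raw means before rounding", {
  a <- c(3L, 3L, 3L, 3L, 3L, 3L)
  w1 <- c(4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L) # congruent, personal 25
  w2 <- c(1L, 1L, 1L, 1L, 6L, 6L, 6L, 6L, 6L, 6L) # incongruent, personal 1
  sat <- satisfaction_from_survey(make_survey(list(w1 = w1, w2 = w2), a))
  expect_equal(sat$ls_raw, mean(sat$workers$ls_raw))
  # order of survey rows is irrelevant
  shuffled <- make_survey(list(w1 = w1, w2 = w2), a)
  shuffled <- shuffled[rev(seq_len(nrow(shuffled))), ]
  expect_equal(satisfaction_from_survey(shuffled)$ls_raw, sat$ls_raw)
})

test_that("an externally supplied personal value reproduces the facade satisfaction chain", {
  w <- c(4L, 4L, 2L, 3L, 5L, 6L, 3L, 3L, 3L, 3L)
  a <- c(5L, 5L, 5L, 5L, 5L, 5L)
  sat <- satisfaction_from_survey(make_survey(list(w1 = w), a), personal_cv = 13)
  expect_equal(sat$workers$personal_cv, 13)
  expect_equal(sat$workers$safety_cv, 9)       # congruence 0.6
  expect_equal(sat$workers$environment_cv, 15) # congruence 1.1 -> 1.2
  expect_equal(sat$ls_raw, 37 / 3, tolerance = 1e-12)
  expect_identical(sat$ls_cv, 15L)
})

test_that("survey schema violations are rejected with field context", {
  w <- c(4L, 4L, 2L, 3L, 5L, 6L, 3L, 3L, 3L, 3L)
  a <- c(5L, 5L, 5L, 5L, 5L, 5L)
  s <- make_survey(list(w1 = w), a)
  expect_error(
    satisfaction_from_survey(s[s$question != "safety_2", ]),
    regexp = "safety", class = "lpac_error_schema"
  )
  expect_error(
    satisfaction_from_survey(s[s$respondent == "worker", ]),
    regexp = "assessor", class = "lpac_error_schema"
  )
  bad <- s
  bad$question[1] <- "wellbeing_1"
  expect_error(satisfaction_from_survey(bad), class = "lpac_error_schema")
  bad <- s
  bad$answer[2] <- 7L
  expect_error(satisfaction_from_survey(bad), class = "lpac_error_range")
})
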