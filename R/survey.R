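# Level of Satisfaction ----------------------------------------------------
#
# The on-site psychosocial survey has ten questions on a 1..6 scale:
# four on personal perception (emotional state, energy, personal and job
# satisfaction), two on the perception of the environment (difficulty,
# danger) and four on the perception of safety (participation and
# protection).  Workers answer all ten; the assessor answers the
# environment and safety blocks.  Personal answers convert through the
# performance curve (peak at "focused"); environment/safety answers enter
# through the congruence of the worker's and the assessor's risk
# perception: perfect congruence (ratio 1) earns the maximal value 25,
# over- or under-confidence decays symmetrically to 1.

.personal_conversion <- c(1L, 3L, 5L, 25L, 15L, 9L)
.environment_conversion <- c(1L, 3L, 5L, 9L, 15L, 25L)
# tent map over the congruence grid 0, 0.2, ..., 2.0
.congruence_values <- c(1L, 3L, 5L, 9L, 15L, 25L, 15L, 9L, 5L, 3L, 1L)

.survey_questions <- c(
  paste0("personal_", 1:4),
  paste0("environment_", 1:2),
  paste0("safety_", 1:4)
)

check_answers <- function(answer, what = "answer") {
  if (length(answer) == 0 || anyNA(answer) ||
      !all(answer %in% 1:6)) {
    stop_range(sprintf("`%s` values must be integers in 1..6", what))
  }
  as.integer(answer)
}

#' Convert a personal-perception answer to the characteristic scale
#'
#' The six states of mind (apathetic, bored, motivated, focused, upbeat,
#' excited) follow the performance curve: the maximum 25 sits at answer 4
#' ("focused"), with conversions 1, 3, 5, 25, 15, 9.
#'
#' @param answer Integer 1..6 (vectorised).
#' @return Integer characteristic values.
#' @export
#' @examples
#' convert_personal(4) # 25, the performance peak
convert_personal <- function(answer) {
  .personal_conversion[check_answers(answer)]
}

#' Convert an environment/safety perception answer to the characteristic scale
#'
#' Monotone conversion 1, 3, 5, 9, 15, 25 of the 1..6 answer scale.
#'
#' @inheritParams convert_personal
#' @return Integer characteristic values.
#' @export
convert_environment <- function(answer) {
  .environment_conversion[check_answers(answer)]
}

#' Congruence of worker and assessor risk perception
#'
#' The worker's answers are compared with the assessor's over the same
#' questions; the congruence ratio is the mean of the per-question
#' worker/assessor ratios, clamped to \[0, 2\] and snapped to the 0.2 grid
#' (a ratio exactly midway between two grid points snaps away from 1.0,
#' the conservative direction: less congruence, more required action).
#'
#' @param worker,assessor Equal-length integer vectors of answers 1..6.
#' @return One-row tibble with `ratio` and `grid` (the snapped grid point).
#' @export
#' @examples
#' congruence_ratio(c(3, 3, 3, 3), c(5, 5, 5, 5)) # ratio 0.6
congruence_ratio <- function(worker, assessor) {
  worker <- check_answers(worker, "worker")
  assessor <- check_answers(assessor, "assessor")
  if (length(worker) != length(assessor)) {
    stop_validation("`worker` and `assessor` must have the same length")
  }
  ratio <- min(max(mean(worker / assessor), 0), 2)
  g <- ratio / 0.2
  frac <- g - floor(g)
  k <- if (abs(frac - 0.5) < 1e-8) {
    if (ratio < 1) floor(g) else ceiling(g) # midpoint: away from 1.0
  } else {
    round(g)
  }
  tibble(ratio = ratio, grid = k * 0.2)
}

#' Perception value of a congruence grid point
#'
#' Tent map over the congruence grid: 0 -> 1 rising to 1.0 -> 25 and
#' falling symmetrically back to 2.0 -> 1 (values 1, 3, 5, 9, 15, 25, 15,
#' 9, 5, 3, 1).
#'
#' @param grid_point Multiple of 0.2 in \[0, 2\] (vectorised).
#' @return Integer characteristic values.
#' @export
#' @examples
#' congruence_cv(1.0) # perfect congruence: 25
#' congruence_cv(0.6) # 9
congruence_cv <- function(grid_point) {
  idx <- grid_point / 0.2
  if (anyNA(idx) || any(abs(idx - round(idx)) > 1e-8) ||
      any(idx < -1e-8) || any(idx > 10 + 1e-8)) {
    stop_validation("`grid_point` must be a multiple of 0.2 in [0, 2]")
  }
  .congruence_values[as.integer(round(idx)) + 1L]
}

#' Level of Satisfaction (L_s) from its three components
#'
#' Averages the personal-perception value, the safety-perception value and
#' the environment-perception value, and rounds the mean to the
#' characteristic scale.
#'
#' @param personal_cv,safety_cv,environment_cv Component values in 1..25.
#' @return One-row tibble with the three components, `ls_raw` (mean) and
#'   `ls_cv`.
#' @export
#' @examples
#' level_of_satisfaction(13, 9, 15) # ls_raw 12.33 -> ls_cv 15
level_of_satisfaction <- function(personal_cv, safety_cv, environment_cv) {
  comp <- c(personal_cv, safety_cv, environment_cv)
  if (anyNA(comp) || any(comp < 1) || any(comp > 25)) {
    stop_range("satisfaction components must lie in [1, 25]")
  }
  ls_raw <- mean(comp)
  tibble(
    personal_cv = personal_cv, safety_cv = safety_cv,
    environment_cv = environment_cv,
    ls_raw = ls_raw, ls_cv = round_cv(ls_raw)
  )
}

#' Level of Satisfaction from a survey table
#'
#' Processes the long survey table (one row per respondent-question-answer)
#' into per-worker satisfaction components and the site-level L_s.  Each
#' worker's personal value is the integer-rounded mean of their four
#' converted personal answers (overridable via `personal_cv` when, e.g.,
#' the value was established externally); safety and environment values
#' come from the congruence of the worker's answers with the assessor's.
#' The site aggregate averages the per-worker raw means before rounding.
#'
#' @param survey Data frame with columns `respondent` (`"worker"` or
#'   `"assessor"`), `id` (worker identifier; ignored for the assessor),
#'   `question` (`personal_1..4`, `environment_1..2`, `safety_1..4`) and
#'   `answer` (1..6).
#' @param personal_cv Optional externally supplied personal-perception
#'   value (applied to every worker).
#' @return A list with `workers` (per-worker component tibble), `ls_raw`
#'   (site mean before rounding) and `ls_cv`.
#' @export
satisfaction_from_survey <- function(survey, personal_cv = NULL) {
  survey <- as_tibble(survey)
  needed <- c("respondent", "id", "question", "answer")
  if (!all(needed %in% names(survey))) {
    stop_schema(sprintf(
      "survey: columns %s are required",
      paste(setdiff(needed, names(survey)), collapse = ", ")
    ))
  }
  if (!all(survey$question %in% .survey_questions)) {
    stop_schema(sprintf(
      "survey: unknown question id(s): %s",
      paste(unique(setdiff(survey$question, .survey_questions)), collapse = ", ")
    ))
  }
  survey$answer <- check_answers(survey$answer, "survey$answer")

  assessor <- filter(survey, .data$respondent == "assessor")
  workers <- filter(survey, .data$respondent == "worker")
  if (nrow(workers) == 0) {
    stop_schema("survey: at least one worker respondent is required")
  }
  assessor_block <- function(prefix) {
    rows <- assessor[startsWith(assessor$question, prefix), ]
    arrange(rows, .data$question)$answer
  }
  a_env <- assessor_block("environment_")
  a_saf <- assessor_block("safety_")
  if (length(a_env) != 2 || length(a_saf) != 4) {
    stop_schema("survey: the assessor must answer environment_1..2 and safety_1..4")
  }

  per_worker <- workers %>%
    group_by(.data$id) %>%
    dplyr::group_modify(function(df, key) {
      block <- function(prefix, n) {
        rows <- df[startsWith(df$question, prefix), ]
        if (nrow(rows) != n || anyDuplicated(rows$question)) {
          stop_schema(sprintf(
            "survey: worker '%s' must answer %s1..%d exactly once",
            key$id, prefix, n
          ))
        }
        arrange(rows, .data$question)$answer
      }
      personal <- block("personal_", 4)
      w_env <- block("environment_", 2)
      w_saf <- block("safety_", 4)
      p_cv <- personal_cv %||%
        round_half_up(mean(convert_personal(personal)))
      saf <- congruence_ratio(w_saf, a_saf)
      env <- congruence_ratio(w_env, a_env)
      ls <- level_of_satisfaction(p_cv, congruence_cv(saf$grid), congruence_cv(env$grid))
      mutate(ls,
        safety_ratio = saf$ratio, safety_grid = saf$grid,
        environment_ratio = env$ratio, environment_grid = env$grid
      )
    }) %>%
    ungroup()

  ls_raw <- mean(per_worker$ls_raw)
  list(workers = per_worker, ls_raw = ls_raw, ls_cv = round_cv(ls_raw))
}
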