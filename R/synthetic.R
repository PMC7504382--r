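# Synthetic fixtures ---------------------------------------------------------
#
# Two sources of test inputs: the canonical worked example (a bare brick
# facade on the first floor, fully specified in the method's reference
# tables) and a seeded generator of arbitrary inspection campaigns.  The
# generator parameterises each observation parameter by a weight vector
# over six *risk levels*, where level 1 is always the safest end: for the
# increasing parameters (relative risk, borderline, exposure) level 1 maps
# to characteristic value 1, while for the decreasing parameters (economic
# capacity, participative interest) level 1 maps to 25 (best organisation
# and participation).  "All mass on level 1" therefore produces the
# closed-form minimum of the scoring chain.

#' The canonical worked inspection: a bare brick facade
#'
#' Builds the inspection record of the method's worked example — the
#' construction of a bare brick facade on the first floor: the eight
#' relative-risk selections averaging 8.25, the scaffold platform below
#' 5 m with workers at the edge (borderline value 6), exposure criteria 9
#' and 15, economic capacity 5.40, participative interest 3.50, a survey
#' with safety congruence 0.6 and environment congruence 1.1 (personal
#' perception value 13 supplied externally), the ten assessed risks with
#' their plan ratings and per-risk impact adjustments.
#'
#' @return An `lpac_inspection` whose [assess()] output reproduces the
#'   reference results (e.g. risk 010: A_pac 4.38, L_pac 18%, more
#'   control; technique aggregates 32/34/51/20%).
#' @export
#' @examples
#' fit <- assess(make_worked_example())
#' glance(fit)
make_worked_example <- function() {
  risks <- tibble(
    code = c("010", "020", "040", "110", "350", "380", "420", "440", "560", "570"),
    probability = c(
      "high", "medium", "high", "medium", "medium",
      "high", "medium", "high", "high", "medium"
    ),
    consequence = c(
      "extremely_damaging", "damaging", "damaging", "slightly_damaging",
      "damaging", "slightly_damaging", "damaging", "slightly_damaging",
      "slightly_damaging", "slightly_damaging"
    )
  )
  survey <- bind_rows(
    tibble(
      respondent = "worker", id = "w1",
      question = paste0("personal_", 1:4), answer = c(4L, 4L, 2L, 3L)
    ),
    # environment: ratios 5/5 = 1.0 and 6/5 = 1.2, mean 1.1
    tibble(
      respondent = "worker", id = "w1",
      question = paste0("environment_", 1:2), answer = c(5L, 6L)
    ),
    tibble(
      respondent = "assessor", id = "a",
      question = paste0("environment_", 1:2), answer = c(5L, 5L)
    ),
    # safety: every ratio 3/5 = 0.6
    tibble(
      respondent = "worker", id = "w1",
      question = paste0("safety_", 1:4), answer = rep(3L, 4)
    ),
    tibble(
      respondent = "assessor", id = "a",
      question = paste0("safety_", 1:4), answer = rep(5L, 4)
    )
  )
  overrides <- list(
    "010" = list(r_r = 8, b_r = 7, e = 15, e_c = 4, p_i = 4, l_s = 12),
    "020" = list(r_r = 10, b_r = 5, e = 12, e_c = 4, p_i = 4, l_s = 12),
    "040" = list(r_r = 9, b_r = 5, e = 12, e_c = 6, p_i = 4, l_s = 14),
    "110" = list(r_r = 10, b_r = 5, e = 12, e_c = 5, p_i = 4, l_s = 15),
    "350" = list(r_r = 7, b_r = 5, e = 12, e_c = 4, p_i = 4, l_s = 16),
    "380" = list(r_r = 8, b_r = 5, e = 13, e_c = 4, p_i = 4, l_s = 13),
    "420" = list(r_r = 10, b_r = 5, e = 16, e_c = 6, p_i = 4, l_s = 12),
    "440" = list(r_r = 9, b_r = 5, e = 15, e_c = 4, p_i = 4, l_s = 12),
    "560" = list(r_r = 8, b_r = 2, e = 12, e_c = 4, p_i = 4, l_s = 15),
    "570" = list(r_r = 10, b_r = 2, e = 14, e_c = 6, p_i = 4, l_s = 16)
  )
  new_inspection(
    site = list(
      name = "Semi-detached single-family homes",
      date = "2016-08-19",
      construction_system = "Facade",
      inspection_number = 10L
    ),
    risks = risks,
    rubrics = list(
      relative_risk = list(
        graphics = 9, setting_out = 5, workers = 9, qualification = 5,
        auxiliary_systems_level = 15, tools_machinery = 15,
        material_weight = 3, manageability = 5
      ),
      borderline = list(height_m = 4, distance_cm = 0),
      exposure = list(execution_intensity = 9, environment_intensity = 15),
      economic_capacity = list(
        individual_organization = 9, team_organization = 5,
        work_organization = 5, individual_protection = 3,
        collective_safeguards = 5
      ),
      participative_interest = list(
        worker_information = 5, individual_participation = 5,
        group_participation = 3, external_appearance = 1
      )
    ),
    survey = survey,
    survey_personal_cv = 13,
    overrides = overrides
  )
}

# weight-vector presets over the six risk levels (1 = safest)
.scenario_presets <- list(
  minimal = list(
    rubric = c(1, 0, 0, 0, 0, 0),
    pc = c(1, 0, 0, 0, 0, 0)[1:3],
    worker = c(0, 0, 1, 0, 0, 0),
    personal = c(0, 0, 0, 1, 0, 0),
    shift = 0L, noise = c(0, 1, 0)
  ),
  low = list(
    rubric = c(0.45, 0.30, 0.15, 0.07, 0.03, 0),
    pc = c(0.6, 0.3, 0.1),
    worker = c(0.10, 0.20, 0.30, 0.20, 0.15, 0.05),
    personal = c(0.05, 0.10, 0.25, 0.35, 0.15, 0.10),
    shift = 0L, noise = c(0.25, 0.5, 0.25)
  ),
  baseline = list(
    rubric = c(0.10, 0.20, 0.25, 0.20, 0.15, 0.10),
    pc = c(0.4, 0.4, 0.2),
    worker = c(0.05, 0.10, 0.15, 0.25, 0.25, 0.20),
    personal = c(0.05, 0.15, 0.25, 0.25, 0.20, 0.10),
    shift = -1L, noise = c(0.25, 0.5, 0.25)
  ),
  high = list(
    rubric = c(0, 0.03, 0.07, 0.15, 0.30, 0.45),
    pc = c(0.1, 0.3, 0.6),
    worker = c(0, 0, 0.10, 0.20, 0.30, 0.40),
    personal = c(0.20, 0.25, 0.25, 0.10, 0.10, 0.10),
    shift = -2L, noise = c(0.25, 0.5, 0.25)
  )
)

normalise_weights <- function(w, n, what) {
  if (length(w) != n || anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop_validation(sprintf(
      "%s: weights must be %d non-negative numbers with positive sum", what, n
    ))
  }
  w / sum(w)
}

#' Define a synthetic campaign scenario
#'
#' Describes the stochastic conditions of a simulated inspection campaign.
#' Rubric selections are drawn over six risk levels (1 = safest end of each
#' rubric, see the module notes above); the plan's probability and
#' consequence ratings over three levels; worker survey answers over the
#' 1..6 scale; and the assessor's answers are drawn conditionally on the
#' workers' with a configurable shift (a negative shift emulates workers
#' perceiving more risk than the assessor, driving the congruence ratio
#' above 1) plus -1/0/+1 noise.  The default campaign emulates the
#' qualitative structure of a 34-week residential construction campaign.
#'
#' @param n_inspections Number of inspections.
#' @param risk_profile Preset: `"baseline"`, `"low"`, `"high"` or
#'   `"minimal"` (all mass on the safest level, perfect congruence).
#' @param rubric_weights Length-6 weights over risk levels (all rubric
#'   parameters), overriding the preset.
#' @param pc_weights Length-3 weights over probability/consequence levels.
#' @param worker_weights Length-6 weights over worker environment/safety
#'   answers.
#' @param personal_weights Length-6 weights over worker personal answers.
#' @param assessor_shift Integer shift of the assessor's answers relative
#'   to the rounded worker mean.
#' @param noise_weights Length-3 weights over -1/0/+1 assessor noise.
#' @param n_workers Integer range (min, max) of surveyed workers.
#' @param n_risks Integer range (min, max) of assessed risks per inspection.
#' @param systems Pool of construction-system names.
#' @param seed Integer seed; the same scenario yields the same campaign.
#' @return A list of class `lpac_scenario`.
#' @export
campaign_scenario <- function(n_inspections = 34,
                              risk_profile = c("baseline", "low", "high", "minimal"),
                              rubric_weights = NULL, pc_weights = NULL,
                              worker_weights = NULL, personal_weights = NULL,
                              assessor_shift = NULL, noise_weights = NULL,
                              n_workers = c(4, 12), n_risks = c(4, 10),
                              systems = c(
                                "Foundations", "Slab", "Facade", "Partitions",
                                "Roof", "Coating", "Flooring", "Urbanization",
                                "Stairs", "Plumbing inst."
                              ),
                              seed = 1L) {
  risk_profile <- match.arg(risk_profile)
  preset <- .scenario_presets[[risk_profile]]
  structure(
    list(
      n_inspections = as.integer(n_inspections),
      risk_profile = risk_profile,
      rubric_weights = normalise_weights(
        rubric_weights %||% preset$rubric, 6, "rubric_weights"
      ),
      pc_weights = normalise_weights(pc_weights %||% preset$pc, 3, "pc_weights"),
      worker_weights = normalise_weights(
        worker_weights %||% preset$worker, 6, "worker_weights"
      ),
      personal_weights = normalise_weights(
        personal_weights %||% preset$personal, 6, "personal_weights"
      ),
      assessor_shift = as.integer(assessor_shift %||% preset$shift),
      noise_weights = normalise_weights(
        noise_weights %||% preset$noise, 3, "noise_weights"
      ),
      n_workers = as.integer(n_workers), n_risks = as.integer(n_risks),
      systems = systems, seed = as.integer(seed)
    ),
    class = "lpac_scenario"
  )
}

# map a risk level 1..6 to a characteristic value in the parameter's
# direction: increasing parameters score S[level], decreasing ones S[7-level]
level_to_value <- function(level, direction) {
  if (direction == "increasing") .scale_values[level] else .scale_values[7L - level]
}

# map a risk level to a borderline geometry (height band = level; the
# distance places the worker deeper in the risk area as the level rises)
level_to_borderline <- function(level) {
  heights <- c(0.8, 2.5, 4, 7, 12, 18)
  b <- .border_distance_cm[level]
  zone_idx <- c(1L, 2L, 3L, 4L, 5L, 5L)[level]
  dist <- c(b + 50, b + 10, b - 10, b - 35, max(0, b - 60), max(0, b - 60))[zone_idx]
  list(height_m = heights[level], distance_cm = dist)
}

sample_levels <- function(n, weights) {
  sample.int(length(weights), n, replace = TRUE, prob = weights)
}

generate_inspection <- function(scenario, index, date, registry) {
  sc <- scenario
  draw_rubric <- function(factors, direction) {
    lv <- sample_levels(length(factors), sc$rubric_weights)
    setNames(as.list(level_to_value(lv, direction)), factors)
  }
  rubrics <- list(
    relative_risk = draw_rubric(
      c(
        "graphics", "setting_out", "workers", "qualification",
        "auxiliary_systems_level", "tools_machinery", "material_weight",
        "manageability"
      ),
      "increasing"
    ),
    borderline = level_to_borderline(sample_levels(1, sc$rubric_weights)),
    exposure = draw_rubric(
      c("execution_intensity", "environment_intensity"), "increasing"
    ),
    economic_capacity = draw_rubric(
      c(
        "individual_organization", "team_organization", "work_organization",
        "individual_protection", "collective_safeguards"
      ),
      "decreasing"
    ),
    participative_interest = draw_rubric(
      c(
        "worker_information", "individual_participation",
        "group_participation", "external_appearance"
      ),
      "decreasing"
    )
  )

  n_risk <- sample(sc$n_risks[1]:sc$n_risks[2], 1)
  codes <- sort(sample(registry$code, n_risk))
  risks <- tibble(
    code = codes,
    probability = .probability_levels[sample_levels(n_risk, sc$pc_weights)],
    consequence = .consequence_levels[sample_levels(n_risk, sc$pc_weights)]
  )

  n_w <- sample(sc$n_workers[1]:sc$n_workers[2], 1)
  worker_rows <- map(seq_len(n_w), function(w) {
    id <- sprintf("w%02d", w)
    bind_rows(
      tibble(
        respondent = "worker", id = id, question = paste0("personal_", 1:4),
        answer = sample_levels(4, sc$personal_weights)
      ),
      tibble(
        respondent = "worker", id = id, question = paste0("environment_", 1:2),
        answer = sample_levels(2, sc$worker_weights)
      ),
      tibble(
        respondent = "worker", id = id, question = paste0("safety_", 1:4),
        answer = sample_levels(4, sc$worker_weights)
      )
    )
  }) %>% bind_rows()
  # assessor answers conditional on the workers': rounded worker mean per
  # question, shifted and jittered, clamped to the 1..6 scale
  assessor_rows <- worker_rows %>%
    filter(!startsWith(.data$question, "personal_")) %>%
    group_by(.data$question) %>%
    summarise(base = round_half_up(mean(.data$answer)), .groups = "drop") %>%
    mutate(
      answer = pmin(6L, pmax(1L, as.integer(
        .data$base + sc$assessor_shift +
          (sample_levels(dplyr::n(), sc$noise_weights) - 2L)
      ))),
      respondent = "assessor", id = "assessor"
    ) %>%
    select("respondent", "id", "question", "answer")

  new_inspection(
    site = list(
      name = "Synthetic campaign",
      date = as.character(date),
      construction_system = sample(sc$systems, 1),
      inspection_number = as.integer(index)
    ),
    risks = risks,
    rubrics = rubrics,
    survey = bind_rows(worker_rows, assessor_rows)
  )
}

#' Generate a synthetic inspection campaign
#'
#' Draws `n_inspections` inspection records under the scenario's
#' distributions, dated weekly.  Reproducible: the same scenario (same
#' seed) yields an identical campaign.  Riskier scenarios stochastically
#' dominate safer ones in global L_pac by the monotonicity of the scoring
#' chain.
#'
#' @param scenario A [campaign_scenario()].
#' @param dir Optional directory; when given, one YAML file per inspection
#'   is written (`inspection_001.yaml`, ...).
#' @param registry Risk registry.
#' @return List of `lpac_inspection` records (invisibly returns the same
#'   list when writing files).
#' @export
#' @examples
#' camp <- generate_campaign(campaign_scenario(n_inspections = 3, seed = 7))
#' length(camp)
generate_campaign <- function(scenario, dir = NULL, registry = risk_registry()) {
  if (!inherits(scenario, "lpac_scenario")) {
    stop_validation("`scenario` must come from campaign_scenario()")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(scenario$seed)
  dates <- as.Date("2016-06-17") + 7 * (seq_len(scenario$n_inspections) - 1)
  records <- map(seq_len(scenario$n_inspections), function(i) {
    generate_inspection(scenario, i, dates[i], registry)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    walk(seq_along(records), function(i) {
      write_inspection(
        records[[i]],
        file.path(dir, sprintf("inspection_%03d.yaml", i))
      )
    })
  }
  records
}
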