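# Inspection records --------------------------------------------------------
#
# One inspection = one YAML file: site metadata, the plan's per-risk
# probability/consequence ratings, the rubric selections for the five
# observation parameters, the survey table, optional per-risk overrides
# and an optional explicit scale factor.  A campaign is a directory of
# such files.

#' Construct an inspection record
#'
#' @param site Named list with `name`, `date` (ISO string), `construction_system`,
#'   `inspection_number`.
#' @param risks Data frame with columns `code`, `probability`, `consequence`
#'   (level labels or 0..2 ordinals).
#' @param rubrics Named list with elements `relative_risk`,
#'   `borderline` (with `height_m` and `distance_cm` and/or `zone`),
#'   `exposure` (`execution_intensity`, `environment_intensity`),
#'   `economic_capacity`, `participative_interest` — see the `cv_*`
#'   functions for the factor names.  Any block may be omitted when the
#'   corresponding base value is supplied via `parameters`.
#' @param survey Data frame with columns `respondent`, `id`, `question`,
#'   `answer` (see [satisfaction_from_survey()]), or `NULL` when
#'   `parameters$l_s` is given.
#' @param survey_personal_cv Optional externally supplied personal-perception
#'   value for [satisfaction_from_survey()].
#' @param parameters Optional named list of explicit base parameter values
#'   (`r_r`, `b_r`, `e`, `e_c`, `p_i`, `l_s`) that take precedence over
#'   the rubric-derived values.
#' @param overrides Named list: risk code -> named list of per-parameter
#'   impact adjustments (see [adjust_for_risk()]).
#' @param epsilon Optional explicit scale factor.
#' @return An object of class `lpac_inspection`.
#' @export
new_inspection <- function(site = list(), risks, rubrics = list(),
                           survey = NULL, survey_personal_cv = NULL,
                           parameters = list(), overrides = list(),
                           epsilon = NULL) {
  risks <- as_tibble(as.data.frame(risks, stringsAsFactors = FALSE))
  if (!is.null(survey)) survey <- as_tibble(as.data.frame(survey))
  structure(
    list(
      site = site, risks = risks, rubrics = rubrics, survey = survey,
      survey_personal_cv = survey_personal_cv, parameters = parameters,
      overrides = overrides, epsilon = epsilon
    ),
    class = "lpac_inspection"
  )
}

#' Validate an inspection record
#'
#' Checks the schema: at least one risk with valid level labels, unique
#' codes, overrides referencing declared risks, rubric/parameter coverage
#' for all six parameters, and survey availability for L_s.  Errors carry
#' the offending field path.
#'
#' @param record An `lpac_inspection`.
#' @param registry Risk registry ([risk_registry()]).
#' @return The record, invisibly, when valid.
#' @export
validate_inspection <- function(record, registry = risk_registry()) {
  if (!inherits(record, "lpac_inspection")) {
    stop_schema("not an inspection record (see `new_inspection()`)")
  }
  risks <- record$risks
  if (is.null(risks) || nrow(risks) == 0) {
    stop_schema("risks: at least one risk must be declared")
  }
  if (!all(c("code", "probability", "consequence") %in% names(risks))) {
    stop_schema("risks: columns code, probability, consequence are required")
  }
  if (anyDuplicated(risks$code)) {
    stop_schema(sprintf(
      "risks: duplicated code(s): %s",
      paste(unique(risks$code[duplicated(risks$code)]), collapse = ", ")
    ))
  }
  unknown <- setdiff(risks$code, registry$code)
  if (length(unknown)) {
    stop_lpac(
      sprintf(
        "risks: code(s) not in the registry: %s",
        paste(unknown, collapse = ", ")
      ),
      c("lpac_error_unknown_risk", "lpac_error_schema")
    )
  }
  # level labels/ordinals must quantify
  quantify_level("probability", risks$probability)
  quantify_level("consequence", risks$consequence)

  stray <- setdiff(names(record$overrides), risks$code)
  if (length(stray)) {
    stop_schema(sprintf(
      "overrides: risk(s) not declared in this inspection: %s",
      paste(stray, collapse = ", ")
    ))
  }
  if (!is.null(record$epsilon)) {
    if (!is.numeric(record$epsilon) || record$epsilon <= 0) {
      stop_schema("epsilon: must be a positive number")
    }
  }
  explicit <- names(record$parameters)
  need_block <- function(param, block) {
    if (!param %in% explicit && is.null(record$rubrics[[block]])) {
      stop_schema(sprintf(
        "rubrics.%s: missing, and no explicit parameters.%s was given",
        block, param
      ))
    }
  }
  need_block("r_r", "relative_risk")
  need_block("b_r", "borderline")
  need_block("e", "exposure")
  need_block("e_c", "economic_capacity")
  need_block("p_i", "participative_interest")
  if (!"l_s" %in% explicit && is.null(record[["survey"]])) {
    stop_schema(paste(
      "survey: missing - the Level of Satisfaction (l_s) requires survey",
      "responses or an explicit `parameters$l_s` value"
    ))
  }
  invisible(record)
}

#' Read an inspection record from a YAML file
#'
#' @param path Path to a YAML inspection file.
#' @inheritParams validate_inspection
#' @return A validated `lpac_inspection`.
#' @export
read_inspection <- function(path, registry = risk_registry()) {
  if (!file.exists(path)) {
    stop_schema(sprintf("inspection file '%s' does not exist", path))
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_lpac(
      sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
      c("lpac_error_parse", "lpac_error_schema")
    )
  )
  survey <- doc$survey$responses
  record <- new_inspection(
    site = doc$site %||% list(),
    risks = bind_rows(map(doc$risks, as_tibble)),
    rubrics = doc$rubrics %||% list(),
    survey = if (!is.null(survey)) bind_rows(map(survey, tidy_survey_row)),
    survey_personal_cv = doc$survey$personal_cv,
    parameters = doc$parameters %||% list(),
    overrides = doc$overrides %||% list(),
    epsilon = doc$epsilon
  )
  validate_inspection(record, registry)
}

tidy_survey_row <- function(row) {
  as_tibble(list(
    respondent = row$respondent %||% NA_character_,
    id = as.character(row$id %||% NA_character_),
    question = row$question %||% NA_character_,
    answer = row$answer %||% NA_integer_
  ))
}

#' Write an inspection record to a YAML file
#'
#' The round trip `read_inspection(write_inspection(x))` is the identity at
#' the data-model level.
#'
#' @param record An `lpac_inspection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inspection <- function(record, path) {
  doc <- list(
    site = record$site,
    risks = unname(apply(record$risks, 1, as.list)),
    rubrics = record$rubrics,
    parameters = record$parameters,
    overrides = record$overrides,
    epsilon = record$epsilon
  )
  if (!is.null(record[["survey"]])) {
    doc$survey <- list(
      personal_cv = record$survey_personal_cv,
      responses = unname(
        apply(record[["survey"]], 1, function(r) {
          list(
            respondent = unname(r[["respondent"]]), id = unname(r[["id"]]),
            question = unname(r[["question"]]),
            answer = as.integer(r[["answer"]])
          )
        })
    ))
  }
  doc <- drop_nulls(doc)
  yaml::write_yaml(doc, path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!map_lgl(x, is.null)]
  map(x, drop_nulls)
}

# compute the six base characteristic values from the rubric blocks,
# the survey, and any explicit parameter overrides
base_parameters <- function(record, tables = load_rubric_tables()) {
  rb <- record$rubrics
  expl <- record$parameters
  rows <- list()
  get_cv <- function(param, compute) {
    if (!is.null(expl[[param]])) {
      v <- expl[[param]]
      if (!is.numeric(v) || v < 1 || v > 25) {
        stop_schema(sprintf("parameters.%s: must lie in [1, 25]", param))
      }
      tibble(parameter = param, raw = as.numeric(v), cv = as.integer(v))
    } else {
      compute()
    }
  }
  rr <- get_cv("r_r", function() cv_relative_risk(rb$relative_risk, tables))
  br <- get_cv("b_r", function() {
    b <- rb$borderline
    cv_borderline(b$height_m, b$distance_cm, b$zone)[c("parameter", "raw", "cv")]
  })
  ex <- get_cv("e", function() {
    cv_exposure(rb$exposure$execution_intensity,
                rb$exposure$environment_intensity, tables)
  })
  ec <- get_cv("e_c", function() cv_economic_capacity(rb$economic_capacity, tables))
  pi_ <- get_cv("p_i", function() {
    cv_participative_interest(rb$participative_interest, tables)
  })
  ls <- get_cv("l_s", function() {
    sat <- satisfaction_from_survey(record[["survey"]], record$survey_personal_cv)
    tibble(parameter = "level_of_satisfaction", raw = sat$ls_raw, cv = sat$ls_cv)
  })
  detail <- bind_rows(rr, br, ex, ec, pi_, ls)
  detail$parameter <- .param_names
  detail
}

#' Assess an inspection record
#'
#' Runs the full Level of Preventive Action pipeline: quantifies each
#' risk's absolute risk from the plan's probability/consequence ratings,
#' derives the six base characteristic values from the rubric selections
#' and the survey, applies the per-risk impact overrides, computes
#' `A_pac` and the L_pac percentage per risk, selects (or accepts) the
#' exigency scale factor, classifies each risk into a control level and
#' aggregates by technique and globally.  Deterministic: identical inputs
#' yield identical results.
#'
#' @param record An `lpac_inspection` (see [new_inspection()],
#'   [read_inspection()], [make_worked_example()]).
#' @param epsilon Optional explicit scale factor (overrides the record's).
#' @param registry Risk registry.
#' @param tables Rubric tables.
#' @return An object of class `lpac_assessment`: a list with `site`,
#'   `base` (parameter detail tibble), `risks` (per-risk result tibble),
#'   `techniques`, `global`, and `policy`.  Use [tidy()], [glance()],
#'   [autoplot()] and [write_report()] on it.
#' @export
#' @examples
#' fit <- assess(make_worked_example())
#' tidy(fit)
assess <- function(record, epsilon = NULL, registry = risk_registry(),
                   tables = load_rubric_tables()) {
  validate_inspection(record, registry)
  base <- base_parameters(record, tables)
  base_vec <- setNames(base$cv, base$parameter)

  risks <- record$risks %>%
    left_join(registry, by = "code") %>%
    bind_cols(absolute_risk(record$risks$probability, record$risks$consequence))

  adjusted <- map(risks$code, function(code) {
    adjust_for_risk(base_vec, record$overrides[[code]] %||% list(), code)
  })
  adj_tbl <- as_tibble(do.call(rbind, adjusted))
  risks <- bind_cols(risks, adj_tbl) %>%
    mutate(
      a_pac = a_pac(.data$r_r, .data$b_r, .data$e, .data$e_c, .data$p_i, .data$l_s),
      a_pac_display = round_half_up(.data$a_pac, 2),
      lpac_pct = lpac_pct(.data$ab_r, .data$a_pac),
      lpac_pct_display = round_half_up(.data$lpac_pct),
      lpac_score = lpac_score(.data$ab_r, .data$a_pac)
    )

  policy <- if (!is.null(epsilon %||% record$epsilon)) {
    control_policy(epsilon %||% record$epsilon)
  } else {
    select_scale_factor(risks$lpac_pct)
  }
  risks$control <- classify_control(risks$lpac_pct, policy)

  agg <- aggregate_lpac(risks)
  agg$techniques$control <- classify_control(agg$techniques$lpac_pct, policy)
  agg$global$control <- classify_control(agg$global$lpac_pct, policy)

  structure(
    list(
      site = record$site, base = base, risks = risks,
      techniques = agg$techniques, global = agg$global, policy = policy
    ),
    class = "lpac_assessment"
  )
}

#' Assess a directory of inspection files (campaign mode)
#'
#' Reads every YAML inspection file in a directory, assesses each, and
#' binds the per-risk results into a campaign table plus a per-inspection
#' series (one global L_pac value per inspection) for trend plots.
#' Malformed files are skipped with a logged warning and counted.  Rows
#' are ordered by inspection date, then inspection number.
#'
#' @param dir Directory containing `*.yaml`/`*.yml` inspection files.
#' @inheritParams assess
#' @return An object of class `lpac_campaign`: list with `results`
#'   (inspection x risk rows), `series` (one row per inspection),
#'   `skipped` (tibble of skipped files and reasons).
#' @export
assess_batch <- function(dir, epsilon = NULL, registry = risk_registry(),
                         tables = load_rubric_tables()) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(files) == 0) {
    stop_schema(sprintf("no inspection files (*.yaml) found in '%s'", dir))
  }
  skipped <- list()
  rows <- list()
  series <- list()
  for (f in files) {
    res <- tryCatch(
      {
        rec <- read_inspection(f, registry)
        fit <- assess(rec, epsilon = epsilon, registry = registry, tables = tables)
        list(rec = rec, fit = fit)
      },
      lpac_error = function(e) e,
      error = function(e) e
    )
    if (inherits(res, "condition")) {
      warn(
        sprintf("skipping '%s': %s", basename(f), conditionMessage(res)),
        class = "lpac_warn_skipped_file"
      )
      skipped[[f]] <- tibble(file = basename(f), reason = conditionMessage(res))
      next
    }
    site <- res$rec$site
    meta <- tibble(
      file = basename(f),
      date = as.character(site$date %||% NA_character_),
      inspection_number = as.integer(site$inspection_number %||% NA_integer_),
      construction_system = as.character(site$construction_system %||% NA_character_)
    )
    rows[[f]] <- bind_cols(meta[rep(1, nrow(res$fit$risks)), ], res$fit$risks)
    series[[f]] <- bind_cols(
      meta,
      res$fit$global %>% select(
        global_lpac_pct = "lpac_pct",
        global_lpac_pct_display = "lpac_pct_display",
        n_risks = "n", "control"
      ),
      tibble(epsilon = res$fit$policy$epsilon)
    )
  }
  if (length(rows) == 0) {
    stop_schema(sprintf("no valid inspection files in '%s'", dir))
  }
  results <- bind_rows(rows) %>% arrange(.data$date, .data$inspection_number)
  series <- bind_rows(series) %>% arrange(.data$date, .data$inspection_number)
  structure(
    list(
      results = results, series = series,
      skipped = if (length(skipped)) bind_rows(skipped) else
        tibble(file = character(), reason = character())
    ),
    class = "lpac_campaign"
  )
}

#' Write an assessment report
#'
#' `csv` mirrors the per-risk results table column order (code, risk,
#' tolerance, A_pac, L_pac, control, technique, technique L_pac) at the
#' display precisions, followed by full-precision columns for chaining
#' and a final global row.  `json` serialises the tidy pieces; `text`
#' writes the printed report.
#'
#' @param x An `lpac_assessment`.
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "lpac_assessment"))
  if (format == "csv") {
    tech <- x$techniques
    out <- x$risks %>%
      left_join(
        tech %>% select("technique", technique_lpac_pct = "lpac_pct_display"),
        by = "technique"
      ) %>%
      mutate(
        # the technique aggregate prints once per technique, as in the
        # merged cells of the results table
        technique_lpac = ifelse(
          !duplicated(.data$technique),
          sprintf("%d%%", as.integer(.data$technique_lpac_pct)), ""
        )
      )
    out <- tibble(
      code = out$code,
      risk = out$description,
      tolerance = out$tolerance,
      a_pac = sprintf("%.2f", out$a_pac_display),
      lpac = sprintf("%d%%", as.integer(out$lpac_pct_display)),
      control = paste(out$control, "control"),
      technique = out$technique,
      technique_lpac = out$technique_lpac,
      ab_r = out$ab_r,
      a_pac_exact = out$a_pac,
      lpac_pct_exact = out$lpac_pct,
      lpac_score = out$lpac_score
    )
    global <- tibble(
      code = "GLOBAL", risk = "All risks", tolerance = "",
      a_pac = "", lpac = sprintf("%d%%", as.integer(x$global$lpac_pct_display)),
      control = paste(x$global$control, "control"), technique = "",
      technique_lpac = "", ab_r = NA_integer_, a_pac_exact = NA_real_,
      lpac_pct_exact = x$global$lpac_pct, lpac_score = NA_real_
    )
    utils::write.csv(bind_rows(out, global), path,
      row.names = FALSE, fileEncoding = "UTF-8", na = ""
    )
  } else if (format == "json") {
    jsonlite::write_json(
      list(
        site = x$site,
        epsilon = x$policy$epsilon,
        thresholds = as.list(x$policy$thresholds),
        base = x$base, risks = tidy(x),
        techniques = x$techniques, global = x$global
      ),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    writeLines(utils::capture.output(print(x)), path)
  }
  invisible(path)
}
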