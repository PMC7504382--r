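# Rubric parameters --------------------------------------------------------
#
# Five observation parameters are scored on site.  Four (relative risk,
# degree of exposure, economic capacity, participative interest) come from
# factor rubrics: the assessor picks one of six options per factor, each
# option carrying a characteristic value, and the arithmetic mean of the
# selections is rounded back to the scale.  The fifth (borderline risk) is
# a geometric lookup on the work-platform safety grid.

#' Load the observation rubric tables
#'
#' The factor rubrics ship as a packaged YAML document and can be replaced
#' by a custom file (e.g. a localisation) with identical structure: every
#' factor must offer exactly six options, valued 1, 3, 5, 9, 15, 25 in
#' order.  The file is validated on load.
#'
#' @param path Optional path to a rubric YAML file; default is the packaged
#'   table set.
#' @return A named list with one element per parameter, each a tibble with
#'   columns `factor`, `option` (1..6), `label`, `value`, plus a
#'   `direction` attribute.
#' @export
load_rubric_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rubrics.yaml", package = "lpac")
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_lpac(
      sprintf("cannot parse rubric file '%s': %s", path, conditionMessage(e)),
      "lpac_error_parse"
    )
  )
  if (!identical(as.integer(doc$values), .scale_values)) {
    stop_schema("rubric file: `values` must be 1, 3, 5, 9, 15, 25")
  }
  imap(doc$tables, function(tab, id) {
    tbl <- imap(tab$factors, function(labels, fct) {
      if (length(labels) != 6) {
        stop_schema(sprintf(
          "rubric file: tables.%s.factors.%s must have exactly 6 options (has %d)",
          id, fct, length(labels)
        ))
      }
      tibble(
        factor = fct, option = 1:6,
        label = as.character(labels), value = .scale_values
      )
    }) %>% bind_rows()
    attr(tbl, "direction") <- match.arg(tab$direction, c("increasing", "decreasing"))
    tbl
  })
}

# validate a set of factor selections against a rubric table and average them
rubric_mean <- function(parameter, selections, table) {
  if (is.data.frame(selections)) {
    selections <- setNames(selections$value, selections$factor)
  }
  selections <- unlist(selections)
  expected <- unique(table$factor)
  missing <- setdiff(expected, names(selections))
  extra <- setdiff(names(selections), expected)
  if (length(missing) || length(extra) || anyDuplicated(names(selections))) {
    stop_validation(sprintf(
      "%s: selections must name each factor exactly once%s%s%s",
      parameter,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else "",
      if (anyDuplicated(names(selections))) "; duplicated names present" else ""
    ))
  }
  bad <- !selections %in% .scale_values
  if (any(bad)) {
    stop_validation(sprintf(
      "%s: values must be on the characteristic scale {1,3,5,9,15,25}; offending: %s",
      parameter,
      paste0(names(selections)[bad], "=", selections[bad], collapse = ", ")
    ))
  }
  mean(selections)
}

rubric_cv_tbl <- function(parameter, raw) {
  tibble(parameter = parameter, raw = raw, cv = round_cv(raw))
}

#' Characteristic value of Relative Risk (R_r)
#'
#' Interprets the complexity of the construction safety of the unit of work
#' from the eight-factor rubric (graphics, setting-out, workers,
#' qualification, auxiliary systems level, tools/machinery, material
#' weight, manageability).  The mean of the eight selections is rounded to
#' the characteristic scale.
#'
#' @param selections Named list/vector (factor name -> chosen characteristic
#'   value) or a data frame with columns `factor` and `value`.
#' @param tables Rubric tables from [load_rubric_tables()].
#' @return One-row tibble with `parameter`, `raw` (mean), `cv`.
#' @export
#' @examples
#' cv_relative_risk(list(
#'   graphics = 9, setting_out = 5, workers = 9, qualification = 5,
#'   auxiliary_systems_level = 15, tools_machinery = 15,
#'   material_weight = 3, manageability = 5
#' )) # raw 8.25 -> cv 9
cv_relative_risk <- function(selections, tables = load_rubric_tables()) {
  rubric_cv_tbl(
    "relative_risk",
    rubric_mean("relative_risk", selections, tables$relative_risk)
  )
}

#' Characteristic value of the Degree of Exposure (E)
#'
#' Two exposure criteria are observed — intensity during the execution of
#' the unit of work and intensity in the work environment and its accesses —
#' each on the never/rare/unusual/occasional/frequent/continual ladder
#' valued 1/3/5/9/15/25.  Their mean is rounded to the scale (midpoints up).
#'
#' @param execution_intensity,environment_intensity Characteristic values
#'   from the exposure rubric.
#' @inheritParams cv_relative_risk
#' @return One-row tibble with `parameter`, `raw`, `cv`.
#' @export
#' @examples
#' cv_exposure(9, 15) # raw 12 (midpoint) -> cv 15
cv_exposure <- function(execution_intensity, environment_intensity,
                        tables = load_rubric_tables()) {
  raw <- rubric_mean(
    "exposure",
    list(
      execution_intensity = execution_intensity,
      environment_intensity = environment_intensity
    ),
    tables$exposure
  )
  rubric_cv_tbl("exposure", raw)
}

#' Characteristic value of Economic Capacity (E_c)
#'
#' Organizational procedure and prevention-system investment, from the
#' five-factor rubric (individual/team/work organization, individual
#' protection, collective safeguards).  Decreases the absolute risk.
#'
#' @inheritParams cv_relative_risk
#' @return One-row tibble with `parameter`, `raw`, `cv`.
#' @export
cv_economic_capacity <- function(selections, tables = load_rubric_tables()) {
  rubric_cv_tbl(
    "economic_capacity",
    rubric_mean("economic_capacity", selections, tables$economic_capacity)
  )
}

#' Characteristic value of Participative Interest (P_i)
#'
#' Interest and participation in risk prevention, from the four-factor
#' rubric (worker information, individual participation, group
#' participation, external appearance of the site).  Decreases the
#' absolute risk.
#'
#' @inheritParams cv_relative_risk
#' @return One-row tibble with `parameter`, `raw`, `cv`.
#' @export
cv_participative_interest <- function(selections, tables = load_rubric_tables()) {
  rubric_cv_tbl(
    "participative_interest",
    rubric_mean("participative_interest", selections, tables$participative_interest)
  )
}

# Borderline risk -----------------------------------------------------------

# six working-plane height bands (upper-inclusive, metres; depth in
# absolute magnitude) and the border distance (cm) of each band
.height_band_upper <- c(1, 3, 5, 9, 15, Inf)
.border_distance_cm <- c(100, 100, 125, 150, 175, 200)
.borderline_zones <- c(
  "within_safe", "close_to_borderline", "borderline",
  "close_to_risk", "within_risk"
)
# value grid, zones (safe -> risk) x height bands; whole numbers 1..25,
# monotone along both axes
.borderline_grid <- rbind(
  within_safe         = c(1, 2, 4, 7, 12, 19),
  close_to_borderline = c(1, 2, 4, 8, 14, 21),
  borderline          = c(1, 3, 5, 9, 15, 22),
  close_to_risk       = c(2, 4, 6, 10, 16, 23),
  within_risk         = c(2, 4, 6, 11, 18, 25)
)
stopifnot(
  all(apply(.borderline_grid, 1, diff) >= 0),
  all(apply(.borderline_grid, 2, diff) >= 0),
  all(.borderline_grid >= 1), all(.borderline_grid <= 25)
)

#' Height band of a working plane
#'
#' @param height_m Height (or depth, taken in absolute magnitude) of the
#'   working plane over the ground, metres; must be positive.
#' @return Integer band 1..6 for the bands up to 1, 3, 5, 9, 15 m and
#'   above 15 m (upper-inclusive).
#' @export
height_band <- function(height_m) {
  height_m <- abs(as.numeric(height_m))
  if (anyNA(height_m) || any(height_m <= 0)) {
    stop_range("`height_m` must be a positive height/depth in metres")
  }
  findInterval(height_m, .height_band_upper, left.open = TRUE) + 1L
}

#' Borderline zone of a worker relative to the fall hazard
#'
#' Work platforms are divided into a safe area, an unsafe (risk) area and a
#' transition strip — the borderline area — whose distance from the hazard
#' grows with the height of the working plane (100, 100, 125, 150, 175,
#' 200 cm for the six height bands).  From the border there are 25 cm to
#' the safe side and 25 cm to the unsafe side.
#'
#' @inheritParams height_band
#' @param distance_cm Distance from the worker to the hazard, cm (>= 0).
#' @return Character vector of zones: `within_safe`, `close_to_borderline`,
#'   `borderline`, `close_to_risk`, `within_risk`.  Boundaries are
#'   upper-inclusive toward the safer side (d = border is `borderline`).
#' @export
#' @examples
#' borderline_zone(4, 125) # borderline (band <=5 m, border at 125 cm)
borderline_zone <- function(height_m, distance_cm) {
  if (any(is.na(distance_cm)) || any(distance_cm < 0)) {
    stop_range("`distance_cm` must be non-negative")
  }
  b <- .border_distance_cm[height_band(height_m)]
  d <- as.numeric(distance_cm)
  dplyr::case_when(
    d > b + 25 ~ "within_safe",
    d > b      ~ "close_to_borderline",
    d > b - 25 ~ "borderline",
    d > b - 50 ~ "close_to_risk",
    TRUE       ~ "within_risk"
  )
}

#' Characteristic value of Borderline Risk (B_r)
#'
#' Looks up the borderline-risk grid from the working-plane height band and
#' the worker's zone.  The zone is derived from the distance to the hazard
#' when geometry is given; an explicit zone may be supplied instead.  When
#' both are given, geometry takes precedence and a mismatch is logged as a
#' warning.  Unlike the rubric parameters, B_r ranges over the whole
#' numbers 1..25, not just the characteristic scale.
#'
#' @inheritParams borderline_zone
#' @param zone Optional explicit zone (see [borderline_zone()]).
#' @return One-row tibble with `parameter`, `band`, `zone`, `raw`, `cv`.
#' @export
#' @examples
#' cv_borderline(4, distance_cm = 0) # within area of risk at <=5 m: cv 6
cv_borderline <- function(height_m, distance_cm = NULL, zone = NULL) {
  if (is.null(distance_cm) && is.null(zone)) {
    stop_validation("borderline_risk: provide `distance_cm` or an explicit `zone`")
  }
  band <- height_band(height_m)
  if (!is.null(distance_cm)) {
    gzone <- borderline_zone(height_m, distance_cm)
    if (!is.null(zone) && !identical(unname(gzone), unname(zone))) {
      warn(
        sprintf(
          "borderline_risk: explicit zone '%s' disagrees with geometry ('%s'); using geometry",
          zone, gzone
        ),
        class = "lpac_warn_zone_mismatch"
      )
    }
    zone <- gzone
  }
  if (!all(zone %in% .borderline_zones)) {
    stop_validation(sprintf(
      "borderline_risk: unknown zone '%s'", setdiff(zone, .borderline_zones)[1]
    ))
  }
  cv <- .borderline_grid[cbind(match(zone, .borderline_zones), band)]
  tibble(
    parameter = "borderline_risk", band = band, zone = zone,
    raw = as.numeric(cv), cv = as.integer(cv)
  )
}

# exposed for tests and documentation
borderline_grid <- function() .borderline_grid
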