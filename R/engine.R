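# L_pac engine --------------------------------------------------------------
#
# Per-risk adjustment of the six parameters, the preventive-action
# assessment A_pac = (Rr * Br * E) / (Ec * Pi * Ls), the Level of
# Preventive Action expressed as a percentage of the absolute risk, and
# the six-band control classification under the exigency scale factor.

.techniques <- c("safety", "hygiene", "ergonomics", "psychosociology")
.control_levels <- c(
  "optimal", "adequate", "more", "greater", "intensive", "exhaustive"
)
.epsilon_menu <- c(0.4, 1, 2, 4, 5.4, 10, 20)
.param_names <- c("r_r", "b_r", "e", "e_c", "p_i", "l_s")

#' Default risk registry
#'
#' The ten characteristic construction risks of the method, keyed by their
#' INSST-style three-digit code and grouped by technique for combating
#' risk.  Extend by binding additional rows.
#'
#' @return Tibble with columns `code`, `description`, `technique`.
#' @export
risk_registry <- function() {
  tibble(
    code = c("010", "020", "040", "110", "350", "380", "420", "440", "560", "570"),
    description = c(
      "Risk of people falling from a different height",
      "Risk of people falling from the same height",
      "Risk of objects falling during handling",
      "Risk of entrapment by or between objects",
      "Risk due to thermal stress",
      "Risk due to inadequate lighting",
      "Risk due to movement",
      "Risk due to incorrect load handling",
      "Risk due to personal relationships",
      "Risk due to incorrect work organization"
    ),
    technique = rep(.techniques, c(4, 2, 2, 2))
  )
}

check_params <- function(p, what = "parameters") {
  p <- unlist(p)[.param_names]
  if (anyNA(p) || any(p < 1) || any(p > 25)) {
    stop_range(sprintf(
      "%s: all six values (r_r, b_r, e, e_c, p_i, l_s) must lie in [1, 25]", what
    ))
  }
  p
}

# one-step window on the characteristic scale around a base value: for a
# base between two scale values the window is that bracket; for a base on
# the scale it is the neighbouring scale values
scale_step_window <- function(base) {
  s <- as.numeric(.scale_values)
  lo <- vapply(base, function(b) {
    below <- s[s < b]
    if (length(below)) max(below) else s[1]
  }, numeric(1))
  hi <- vapply(base, function(b) {
    above <- s[s > b]
    if (length(above)) min(above) else s[length(s)]
  }, numeric(1))
  cbind(lo, hi)
}

#' Adjust the base parameters for the impact on one risk
#'
#' The site-level characteristic values serve as the basis; for each
#' assessed risk the evaluator may push each parameter up or down
#' depending on the parameter's impact on that risk.  Absent overrides
#' keep the base value.  Overrides are bounded by \[1, 25\]; a deviation
#' beyond one step of the characteristic scale from the base is accepted
#' but logged (class `lpac_log_deviation`), building the audit trail.
#'
#' @param base Named list/vector with the six base values `r_r`, `b_r`,
#'   `e`, `e_c`, `p_i`, `l_s`.
#' @param overrides Named list of per-parameter replacement values (a
#'   subset of the six names).
#' @param risk_code Code used in log messages.
#' @return Named numeric vector of the six adjusted values.
#' @export
adjust_for_risk <- function(base, overrides = list(), risk_code = NULL) {
  base <- check_params(base, "base")
  overrides <- unlist(overrides)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), .param_names)
    if (length(unknown)) {
      stop_validation(sprintf(
        "overrides: unknown parameter(s) %s", paste(unknown, collapse = ", ")
      ))
    }
    if (anyNA(overrides) || any(overrides < 1) || any(overrides > 25)) {
      stop_range("overrides: values must lie in [1, 25]")
    }
    win <- scale_step_window(base[names(overrides)])
    big <- overrides < win[, "lo"] | overrides > win[, "hi"]
    if (any(big)) {
      inform(
        sprintf(
          "risk %s: override%s beyond one scale step from the base: %s",
          risk_code %||% "?", if (sum(big) > 1) "s" else "",
          paste0(
            names(overrides)[big], " ", base[names(overrides)][big],
            " -> ", overrides[big],
            collapse = "; "
          )
        ),
        class = "lpac_log_deviation"
      )
    }
    base[names(overrides)] <- overrides
  }
  base
}

#' Preventive action assessment (A_pac)
#'
#' The multiplicative correction factor combining the documentary
#' environment (relative risk, borderline risk), the construction
#' environment (exposure over economic capacity) and the social
#' environment (participative interest, level of satisfaction):
#' `A_pac = (r_r * b_r * e) / (e_c * p_i * l_s)`.  Strictly increasing in
#' each numerator parameter and strictly decreasing in each denominator
#' parameter.  Vectorised.
#'
#' @param r_r,b_r,e,e_c,p_i,l_s Parameter values in \[1, 25\].
#' @return Numeric A_pac (exact ratio; display rounds to 2 decimals).
#' @export
#' @examples
#' a_pac(8, 7, 15, 4, 4, 12) # 4.375
a_pac <- function(r_r, b_r, e, e_c, p_i, l_s) {
  vals <- cbind(r_r, b_r, e, e_c, p_i, l_s)
  if (anyNA(vals) || any(vals < 1) || any(vals > 25)) {
    stop_range("a_pac: all six parameters must lie in [1, 25]")
  }
  (r_r * b_r * e) / (e_c * p_i * l_s)
}

#' Level of Preventive Action as a percentage of the absolute risk
#'
#' The operative L_pac output relates the preventive-action assessment to
#' the absolute risk as the deviation from the plan's baseline:
#' `100 * a_pac / ab_r` (percent).  The companion absolute score
#' `ab_r * a_pac` is available from [lpac_score()].
#'
#' @param ab_r Absolute risk in \{1, 3, 5, 9, 15, 25\}.
#' @param a_pac Preventive action assessment (unrounded).
#' @return Numeric percentage (unrounded; display rounds half-up to
#'   integer).
#' @export
#' @examples
#' lpac_pct(25, 4.375) # 17.5, printed as 18%
lpac_pct <- function(ab_r, a_pac) {
  if (!all(ab_r %in% .scale_values)) {
    stop_range("`ab_r` must be one of 1, 3, 5, 9, 15, 25")
  }
  100 * a_pac / ab_r
}

#' Absolute Level of Preventive Action score
#'
#' The product `ab_r * a_pac` — the absolute form of the level of
#' preventive action, retained alongside the percentage output.
#'
#' @inheritParams lpac_pct
#' @return Numeric score.
#' @export
lpac_score <- function(ab_r, a_pac) {
  if (!all(ab_r %in% .scale_values)) {
    stop_range("`ab_r` must be one of 1, 3, 5, 9, 15, 25")
  }
  ab_r * a_pac
}

#' Control policy from an exigency scale factor
#'
#' The six control-level thresholds are the characteristic scale values
#' multiplied by the scale factor epsilon: `epsilon * c(1, 3, 5, 9, 15, 25)`.
#' For epsilon = 4 they are 4, 12, 20, 36, 60, 100 — the bands optimal
#' (<= 4), adequate (<= 12), more (<= 20), greater (<= 36), intensive
#' (<= 60) and exhaustive (> 60).
#'
#' @param epsilon Positive scale factor; the standard menu is
#'   0.4, 1, 2, 4, 5.4, 10, 20.
#' @return List of class `lpac_policy` with `epsilon`, `thresholds`
#'   (named by control level) and `levels`.
#' @export
control_policy <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
      epsilon <= 0) {
    stop_validation("`epsilon` must be a single positive number")
  }
  structure(
    list(
      epsilon = epsilon,
      thresholds = setNames(epsilon * as.numeric(.scale_values), .control_levels),
      levels = .control_levels
    ),
    class = "lpac_policy"
  )
}

#' The standard scale-factor menu
#' @return Numeric vector 0.4, 1, 2, 4, 5.4, 10, 20.
#' @export
epsilon_menu <- function() .epsilon_menu

#' Classify a Level of Preventive Action percentage into a control level
#'
#' Bands are defined by strict lower bounds at epsilon * (1, 3, 5, 9, 15):
#' a value exactly on an anchor falls into the less demanding level
#' (e.g. 4% with epsilon = 4 is still optimal control).
#'
#' @param pct Numeric L_pac percentages.
#' @param policy A [control_policy()] (or a bare epsilon).
#' @return Character vector of control levels.
#' @export
#' @examples
#' classify_control(c(18, 67), control_policy(4)) # more, exhaustive
classify_control <- function(pct, policy = control_policy(4)) {
  if (is.numeric(policy)) policy <- control_policy(policy)
  anchors <- policy$thresholds[1:5]
  .control_levels[findInterval(pct - 1e-9, anchors) + 1L]
}

#' Select the exigency scale factor for a set of results
#'
#' The scale factor is adjusted to the highest L_pac result: the smallest
#' menu value epsilon with `25 * epsilon >= max(pct)` is chosen, so the
#' worst risk still falls inside the exhaustive band's reach.  If even the
#' largest menu value cannot cover the maximum, it is used with a warning.
#'
#' @param pct Numeric vector of per-risk L_pac percentages (nonempty).
#' @param menu Candidate scale factors, default [epsilon_menu()].
#' @return A [control_policy()].
#' @export
#' @examples
#' select_scale_factor(c(17.5, 70.3))$epsilon # 4
select_scale_factor <- function(pct, menu = epsilon_menu()) {
  if (length(pct) == 0 || anyNA(pct)) {
    stop_validation("`pct` must be a nonempty numeric vector without NA")
  }
  ok <- menu[25 * menu >= max(pct) - 1e-9]
  if (length(ok) == 0) {
    warn(
      sprintf(
        "maximum L_pac %.1f%% exceeds the reach of the largest scale factor (%g); using %g",
        max(pct), max(menu), max(menu)
      ),
      class = "lpac_warn_menu_exhausted"
    )
    ok <- max(menu)
  }
  control_policy(min(ok))
}

#' Aggregate per-risk percentages by technique and globally
#'
#' Technique and global aggregates are means of the *unrounded* per-risk
#' percentages (averaging the rounded figures is not equivalent and is
#' deliberately avoided); display rounds half-up to integer.
#'
#' @param results Tibble with at least `technique` and `lpac_pct` columns.
#' @return List with `techniques` (tibble: `technique`, `lpac_pct`,
#'   `lpac_pct_display`, `n`) and `global` (same, one row).
#' @export
aggregate_lpac <- function(results) {
  if (nrow(results) == 0) {
    stop_validation("`results` must contain at least one risk")
  }
  techniques <- results %>%
    group_by(.data$technique) %>%
    summarise(lpac_pct = mean(.data$lpac_pct), n = dplyr::n(), .groups = "drop") %>%
    mutate(
      technique = factor(.data$technique, levels = .techniques),
      lpac_pct_display = round_half_up(.data$lpac_pct)
    ) %>%
    arrange(.data$technique) %>%
    mutate(technique = as.character(.data$technique)) %>%
    select("technique", "lpac_pct", "lpac_pct_display", "n")
  global <- tibble(
    lpac_pct = mean(results$lpac_pct),
    lpac_pct_display = round_half_up(mean(results$lpac_pct)),
    n = nrow(results)
  )
  list(techniques = techniques, global = global)
}
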