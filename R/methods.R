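# tidy / glance / plot / print methods --------------------------------------

#' Tidy the per-risk results of an assessment
#'
#' @param x An `lpac_assessment`.
#' @param ... Unused.
#' @return Tibble, one row per assessed risk: code, description,
#'   technique, quantified probability/consequence, `ab_r`, `tolerance`,
#'   the six adjusted parameters, `a_pac`, `lpac_pct`, `lpac_score`,
#'   `control` (plus display-rounded companions).
#' @export
tidy.lpac_assessment <- function(x, ...) {
  x$risks %>%
    select(
      "code", "description", "technique", "p", "c", "ab_r", "tolerance",
      "r_r", "b_r", "e", "e_c", "p_i", "l_s",
      "a_pac", "a_pac_display", "lpac_pct", "lpac_pct_display",
      "lpac_score", "control"
    )
}

#' One-row summary of an assessment
#'
#' @param x An `lpac_assessment`.
#' @param ... Unused.
#' @return One-row tibble: number of risks, chosen epsilon, global L_pac
#'   percentage (exact and display), worst risk and its percentage, global
#'   control level.
#' @export
glance.lpac_assessment <- function(x, ...) {
  worst <- x$risks[which.max(x$risks$lpac_pct), ]
  tibble(
    n_risks = nrow(x$risks),
    epsilon = x$policy$epsilon,
    global_lpac_pct = x$global$lpac_pct,
    global_lpac_pct_display = x$global$lpac_pct_display,
    max_lpac_pct = worst$lpac_pct,
    max_risk_code = worst$code,
    control = x$global$control
  )
}

#' Plot an assessment
#'
#' Bar chart of the L_pac percentage of each risk, coloured by control
#' level, with the control-band thresholds of the chosen scale factor as
#' horizontal reference lines.
#'
#' @param object An `lpac_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpac_assessment <- function(object, ...) {
  d <- object$risks %>%
    mutate(control = factor(.data$control, levels = .control_levels))
  thr <- tibble(
    level = factor(names(object$policy$thresholds), levels = .control_levels),
    value = unname(object$policy$thresholds)
  )[1:5, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$code, y = .data$lpac_pct,
                                  fill = .data$control)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      data = thr, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_fill_manual(
      values = c(
        optimal = "#1a9850", adequate = "#91cf60", more = "#d9ef8b",
        greater = "#fee08b", intensive = "#fc8d59", exhaustive = "#d73027"
      ),
      drop = FALSE, name = "Control level"
    ) +
    ggplot2::labs(
      x = "Risk code", y = "Level of Preventive Action (%)",
      title = sprintf("Preventive-action control (scale factor %.1f)",
                      object$policy$epsilon)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a campaign series
#'
#' Line of the global L_pac percentage per inspection over the campaign.
#'
#' @param object An `lpac_campaign` from [assess_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpac_campaign <- function(object, ...) {
  d <- object$series %>% mutate(order = row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$order, y = .data$global_lpac_pct)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$control), size = 2) +
    ggplot2::labs(
      x = "Inspection (chronological)",
      y = "Global Level of Preventive Action (%)",
      colour = "Control level"
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.lpac_assessment <- function(x, ...) {
  site <- x$site
  cat("Level of Preventive Action assessment\n")
  if (length(site)) {
    cat(sprintf(
      "  site: %s | system: %s | date: %s | inspection %s\n",
      site$name %||% "?", site$construction_system %||% "?",
      site$date %||% "?", site$inspection_number %||% "?"
    ))
  }
  cat(sprintf(
    "  scale factor epsilon = %g (thresholds %s)\n",
    x$policy$epsilon,
    paste(format(x$policy$thresholds, trim = TRUE), collapse = "/")
  ))
  cat("\nBase characteristic values:\n")
  print(as.data.frame(x$base), row.names = FALSE)
  cat("\nPer-risk results:\n")
  res <- x$risks %>%
    mutate(
      A_pac = sprintf("%.2f", .data$a_pac_display),
      L_pac = sprintf("%d%%", as.integer(.data$lpac_pct_display))
    ) %>%
    select("code", "description", "tolerance", "A_pac", "L_pac", "control",
           "technique") %>%
    as.data.frame()
  print(res, row.names = FALSE)
  cat("\nTechnique aggregates:\n")
  tech <- x$techniques %>%
    mutate(L_pac = sprintf("%d%%", as.integer(.data$lpac_pct_display))) %>%
    select("technique", "L_pac", "control", "n") %>%
    as.data.frame()
  print(tech, row.names = FALSE)
  cat(sprintf(
    "\nGlobal: %d%% -> %s control (%d risks)\n",
    as.integer(x$global$lpac_pct_display), x$global$control, x$global$n
  ))
  invisible(x)
}

#' @export
print.lpac_inspection <- function(x, ...) {
  cat("Inspection record\n")
  cat(sprintf(
    "  site: %s | system: %s | date: %s\n",
    x$site$name %||% "?", x$site$construction_system %||% "?",
    x$site$date %||% "?"
  ))
  cat(sprintf(
    "  %d risk(s): %s\n", nrow(x$risks), paste(x$risks$code, collapse = ", ")
  ))
  cat(sprintf(
    "  rubric blocks: %s\n",
    paste(names(x$rubrics), collapse = ", ")
  ))
  if (!is.null(x$survey)) {
    cat(sprintf(
      "  survey: %d response rows, %d worker(s)\n", nrow(x$survey),
      length(unique(x$survey$id[x$survey$respondent == "worker"]))
    ))
  }
  invisible(x)
}

#' @export
print.lpac_policy <- function(x, ...) {
  cat(sprintf("Control policy (epsilon = %g)\n", x$epsilon))
  print(x$thresholds)
  invisible(x)
}
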