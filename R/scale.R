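# The characteristic-value scale ------------------------------------------
#
# Every observed parameter of the method is scored on the same six-point
# scale {1, 3, 5, 9, 15, 25}.  The first three points quantify the
# qualitative probability/consequence levels through f(x) = 2x + 1; the
# full ladder is the diagonal of the probability x consequence product,
# f(x) = 4x^2 + 4x + 1 at x = 0, 1, 2 interleaved with the off-diagonal
# products 3, 5, 15.

.scale_values <- c(1L, 3L, 5L, 9L, 15L, 25L)
# midpoints between consecutive scale values; an average landing exactly on
# one is rounded UP to the next scale value
.scale_midpoints <- c(2, 4, 7, 12, 20)

.probability_levels <- c("low", "medium", "high")
.consequence_levels <- c("slightly_damaging", "damaging", "extremely_damaging")
.tolerance_levels <- c(
  "trivial", "tolerable", "moderate_low", "moderate_high",
  "significant", "intolerable"
)
# ab_r in {1,3,5,9,15,25} maps one-to-one onto the tolerance label; both
# off-diagonal cells of the 3x3 matrix with the same product share a label
.tolerance_by_abr <- setNames(.tolerance_levels, as.character(.scale_values))

#' The characteristic-value scale
#'
#' All parameters of the Level of Preventive Action method are scored on the
#' ordered scale 1, 3, 5, 9, 15, 25.
#'
#' @return Integer vector `c(1, 3, 5, 9, 15, 25)`.
#' @export
#' @examples
#' characteristic_scale()
characteristic_scale <- function() .scale_values

#' Quantify a qualitative probability or consequence level
#'
#' Converts the three-level qualitative ratings of the Health & Safety Plan
#' (probability: low/medium/high; consequence: slightly damaging / damaging /
#' extremely damaging) to their numeric values through the linear rule
#' f(x) = 2x + 1, i.e. 1, 3, 5.  A value of zero is never produced, so the
#' multiplicative risk chain cannot collapse.
#'
#' @param kind `"probability"` or `"consequence"`.
#' @param level Level label (e.g. `"low"`, `"damaging"`) or ordinal index
#'   0, 1, 2.  Vectorised.
#' @return Integer vector of quantified values in \{1, 3, 5\}.
#' @export
#' @examples
#' quantify_level("probability", "low")
#' quantify_level("consequence", c(0, 1, 2))
quantify_level <- function(kind = c("probability", "consequence"), level) {
  kind <- match.arg(kind)
  idx <- level_index(kind, level)
  2L * idx + 1L
}

# resolve labels or 0..2 ordinals to the ordinal index, with a named error
level_index <- function(kind, level) {
  labels <- if (kind == "probability") .probability_levels else .consequence_levels
  if (is.character(level)) {
    idx <- match(tolower(gsub("[ -]", "_", level)), labels) - 1L
    if (anyNA(idx)) {
      stop_validation(sprintf(
        "`level` for kind '%s' must be one of %s (got %s)",
        kind, paste0("'", labels, "'", collapse = ", "),
        paste0("'", level[is.na(idx)], "'", collapse = ", ")
      ))
    }
    return(idx)
  }
  level <- as.numeric(level)
  if (any(is.na(level)) || any(level != as.integer(level)) ||
      any(level < 0) || any(level > 2)) {
    stop_range(sprintf("`level` must be an integer in 0..2 or a %s label", kind))
  }
  as.integer(level)
}

#' Absolute risk from quantified probability and consequence
#'
#' The absolute risk Ab_r is the product of the quantified probability and
#' consequence, `Ab_r = P * C`, and carries the qualitative tolerance label
#' of the INSST-style 3 x 3 estimation matrix (trivial, tolerable, moderate
#' low, moderate high, significant, intolerable).  On the diagonal the
#' product follows f(x) = 4x^2 + 4x + 1.
#'
#' @param probability,consequence Level labels or ordinal indexes 0..2
#'   (see [quantify_level()]).  Vectorised and recycled.
#' @return A tibble with columns `p`, `c` (quantified values), `ab_r`
#'   and `tolerance`.
#' @export
#' @examples
#' absolute_risk("medium", "extremely_damaging") # ab_r 15, significant
absolute_risk <- function(probability, consequence) {
  p <- quantify_level("probability", probability)
  c_ <- quantify_level("consequence", consequence)
  ab_r <- p * c_
  tibble(
    p = p, c = c_, ab_r = ab_r,
    tolerance = unname(.tolerance_by_abr[as.character(ab_r)])
  )
}

#' Round a raw average to the characteristic scale
#'
#' Rubric parameters average several characteristic values; the mean is
#' rounded to the nearest member of \{1, 3, 5, 9, 15, 25\}.  An average
#' landing exactly on a midpoint between two scale values (2, 4, 7, 12, 20)
#' is rounded up to the value directly above.
#'
#' @param raw Numeric vector in \[1, 25\].
#' @return Integer vector of characteristic values.
#' @export
#' @examples
#' round_cv(8.25)  # 9
#' round_cv(12)    # midpoint: rounds up to 15
round_cv <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw)) {
    stop_validation("`raw` must be numeric without missing values")
  }
  if (any(raw < 1 - 1e-9) || any(raw > 25 + 1e-9)) {
    stop_range(sprintf(
      "`raw` must lie in [1, 25]; got %s",
      paste(signif(raw[raw < 1 - 1e-9 | raw > 25 + 1e-9], 6), collapse = ", ")
    ))
  }
  # number of midpoints <= raw indexes the upper neighbour at exact midpoints
  .scale_values[findInterval(raw + 1e-9, .scale_midpoints) + 1L]
}

# half-up decimal rounding used only for display-precision figures
# (A_pac to 2 dp, percentages to integers); all chaining stays unrounded
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}
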