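# Logarithmic power-function universal eutrophication index:
#
#   EI_j = 10.77 * (ln x_j)^1.1826,   EI = sum_j W_j * EI_j
#
# x_j >= 1 is a ratio-to-reference normalization of indicator j against its
# "extremely poor" anchor C_j0 (at which x_j reaches the configured ceiling
# x_max); DO is benefit-oriented, so its ratio is inverted before scaling.

#' Normalize an indicator concentration for the eutrophication index
#'
#' Harm-oriented: `x_j = clamp((C_j / C_j0) * x_max, 1, x_max)`.
#' Benefit-oriented (DO): the ratio is inverted (`C_j0 / C_j`) before
#' scaling, so low oxygen maps to high x. Values at or beyond the anchor
#' saturate at `x_max`; values at the clean end clamp to 1 (EI_j = 0).
#'
#' @param c_j Measured concentration(s), > 0.
#' @param c_j0 Reference ("extremely poor") anchor, > 0.
#' @param orientation `"harm"` or `"benefit"`.
#' @param x_max Ceiling of the normalized scale (> 1); the default makes
#'   EI_j span 0-100.
#' @return Normalized value(s) in `[1, x_max]`.
#' @export
normalize_trophic <- function(c_j, c_j0, orientation = c("harm", "benefit"),
                              x_max = 721.9288) {
  orientation <- match.arg(orientation)
  abort_if(any(c_j <= 0) || c_j0 <= 0,
           "Concentrations and reference values must be positive.",
           "aquarisk_bad_input")
  ratio <- if (orientation == "harm") c_j / c_j0 else c_j0 / c_j
  pmin(pmax(ratio * x_max, 1), x_max)
}

#' Single-indicator eutrophication score
#'
#' `EI_j = coef * (ln x_j)^exponent` with the universal-formula constants
#' `coef = 10.77`, `exponent = 1.1826`. Zero at `x_j = 1`, equal to `coef`
#' at `x_j = e`, and strictly increasing.
#'
#' @param x_j Normalized indicator value(s), >= 1.
#' @param coef,exponent Formula constants.
#' @return Score(s) >= 0.
#' @export
#' @examples
#' ei_single(exp(1))  # 10.77
ei_single <- function(x_j, coef = 10.77, exponent = 1.1826) {
  abort_if(any(x_j < 1),
           "`x_j` must be >= 1 (the log must be non-negative).",
           "aquarisk_bad_input")
  coef * log(x_j)^exponent
}

#' Composite eutrophication index
#'
#' Weighted sum `EI = sum_j W_j * EI_j` over the configured indicators;
#' with equal weights this is the arithmetic mean of the single-indicator
#' scores.
#'
#' @param values Named list/vector (or one-row data frame) of indicator
#'   concentrations.
#' @param config A [trophic_config()].
#' @return The composite EI.
#' @export
ei_composite <- function(values, config = trophic_config()) {
  if (is.data.frame(values)) values <- as.list(values[1, , drop = FALSE])
  values <- as.list(values)
  missing <- setdiff(config$indicators, names(values))
  abort_if(length(missing) > 0,
           paste0("Missing indicator(s): ", paste(missing, collapse = ", ")),
           "aquarisk_missing_parameter")
  ei_j <- map_dbl(config$indicators, function(j) {
    ref <- config$reference[[j]]
    x <- normalize_trophic(as.numeric(values[[j]]), ref$c0,
                           ref$orientation %||% "harm", config$x_max)
    ei_single(x, config$coef, config$exponent)
  })
  sum(config$weights[config$indicators] * ei_j)
}

#' Classify an EI value into a trophic grade
#'
#' Grades are ordered lower bounds; an EI exactly on a boundary belongs to
#' the higher (more eutrophic) grade.
#'
#' @param ei EI value(s), >= 0.
#' @param grades Ordered grade scheme (each with `grade`, `label`, `min`);
#'   defaults to the shipped scheme, whose grade-2/3 boundary is 39.42.
#' @return Tibble `ei`, `grade`, `label` (one row per input).
#' @export
#' @examples
#' classify_trophic(c(37.92, 39.42))
classify_trophic <- function(ei, grades = trophic_config()$grades) {
  abort_if(any(ei < 0), "EI must be non-negative.", "aquarisk_bad_input")
  mins <- map_dbl(grades, "min")
  idx <- findInterval(ei, mins)  # boundary -> higher grade
  tibble(ei = ei,
         grade = purrr::map_int(grades, "grade")[idx],
         label = map_chr(grades, "label")[idx])
}

#' Per-site eutrophication assessment
#'
#' Aggregates each site's seasonal records by arithmetic mean of the
#' indicator concentrations, computes the composite EI and assigns the
#' trophic grade.
#'
#' @param measurements Measurement tibble (`site_id`, `season`,
#'   indicators).
#' @param config A [trophic_config()].
#' @return Tibble `site_id`, `ei`, `grade`, `label`.
#' @export
ei_table <- function(measurements, config = trophic_config()) {
  check_columns(measurements, c("site_id", config$indicators),
                "measurements")
  per_site <- measurements %>%
    group_by(.data$site_id) %>%
    summarise(across(all_of(config$indicators), mean), .groups = "drop")
  ei <- map_dbl(seq_len(nrow(per_site)), function(i)
    ei_composite(per_site[i, ], config))
  cls <- classify_trophic(ei, config$grades)
  per_site %>%
    select("site_id") %>%
    mutate(ei = ei, grade = cls$grade, label = cls$label)
}

#' Spearman correlation of water-quality parameters with EI
#'
#' Ranks use average-rank ties. A constant series yields `NA` (undefined
#' correlation).
#'
#' @param ei Per-site EI values.
#' @param parameters Tibble of per-site parameter values (same row order).
#' @return Tibble `parameter`, `rho`, `n`.
#' @export
ei_correlates <- function(ei, parameters) {
  abort_if(length(ei) != nrow(parameters),
           "`ei` and `parameters` must align row-wise.",
           "aquarisk_bad_input")
  abort_if(length(ei) < 3, "Need at least 3 paired observations.",
           "aquarisk_bad_input")
  num <- names(parameters)[map_chr(parameters, function(x)
    class(x)[1]) %in% c("numeric", "integer")]
  rows <- map(num, function(p) {
    x <- parameters[[p]]
    ok <- complete.cases(x, ei)
    rho <- if (sd(x[ok]) == 0 || sd(ei[ok]) == 0) NA_real_
           else cor(x[ok], ei[ok], method = "spearman")
    tibble(parameter = p, rho = rho, n = sum(ok))
  })
  list_rbind(rows)
}
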