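# Weighted water-quality index:
#
#   WQI = k * sum_i(C_i * P_i) / sum_i(P_i)
#
# over eight parameters (pH, DO, COD_Mn, BOD_5, NH3_N, TP, TN, NO3_N).
# C_i is a 0-100 normalized score from a piecewise-linear lookup table,
# P_i an integer weight in 1..4, and k a subjective constant in
# {1.00, 0.75, 0.50, 0.25} reflecting visible pollution (default 1.00).

#' Normalize one parameter value to a 0-100 score
#'
#' Piecewise-linear interpolation between the parameter's breakpoints,
#' clamped to the extreme scores outside the table. Harm-oriented tables
#' are non-increasing in concentration, the DO table non-decreasing, and
#' the pH table peaks at neutral.
#'
#' @param value Raw measurement (concentration in mg/L; pH unitless).
#' @param table A normalization table: list with numeric `conc`, `score`
#'   and an `orientation` flag.
#' @param parameter Parameter name, used for error messages and to reject
#'   negative concentrations.
#' @return Score in `[0, 100]` (vectorized over `value`).
#' @export
#' @examples
#' cfg <- wqi_config()
#' normalize_parameter(5, cfg$normalization$COD_Mn, "COD_Mn")
normalize_parameter <- function(value, table, parameter = "parameter") {
  abort_if(is.null(table$conc) || is.null(table$score) ||
             length(table$conc) != length(table$score),
           paste0("Malformed normalization table for ", parameter),
           "aquarisk_bad_config")
  if (!identical(table$orientation, "two_sided"))
    abort_if(any(value < 0),
             paste0("Negative concentration for ", parameter),
             "aquarisk_bad_input")
  approx(table$conc, table$score, xout = value, rule = 2)$y
}

#' Compute the water-quality index for one record
#'
#' @param record Named list/vector (or one-row data frame) holding all
#'   eight parameters.
#' @param config A [wqi_config()].
#' @return The WQI value in `[0, 100k]`.
#' @export
#' @examples
#' compute_wqi(c(pH = 7.5, DO = 8, COD_Mn = 3, BOD_5 = 2, NH3_N = 0.2,
#'               TP = 0.05, TN = 0.8, NO3_N = 2), wqi_config())
compute_wqi <- function(record, config = wqi_config()) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  record <- as.list(record)
  params <- names(config$weights)
  missing <- setdiff(params, names(record))
  abort_if(length(missing) > 0,
           paste0("Missing WQI parameter(s): ",
                  paste(missing, collapse = ", ")),
           "aquarisk_missing_parameter")
  scores <- map_dbl(params, function(p)
    normalize_parameter(as.numeric(record[[p]]),
                        config$normalization[[p]], p))
  weights <- unlist(config$weights)[params]
  config$k * sum(scores * weights) / sum(weights)
}

#' Classify a WQI value
#'
#' Assigns the label of the first class whose lower bound the value
#' reaches; a WQI exactly on a boundary belongs to the better class.
#'
#' @param wqi WQI value(s) in `[0, 100]`.
#' @param classes Ordered class scheme (best first), each with `label` and
#'   `min`; defaults to the shipped scheme.
#' @return Character class label (vectorized).
#' @export
classify_wqi <- function(wqi, classes = wqi_config()$classes) {
  abort_if(any(wqi < 0 | wqi > 100),
           "WQI must lie in [0, 100].", "aquarisk_bad_input")
  mins <- map_dbl(classes, "min")
  labels <- map_chr(classes, "label")
  map_chr(wqi, function(v) labels[which(v >= mins)[1]])
}

#' WQI for every record of a measurement table
#'
#' @param measurements Tibble with `site_id`, `season` and the eight WQI
#'   parameters.
#' @param config A [wqi_config()].
#' @return Tibble `site_id`, `season`, `wqi`, `class`.
#' @export
wqi_table <- function(measurements, config = wqi_config()) {
  params <- names(config$weights)
  check_columns(measurements, c("site_id", "season", params), "measurements")
  scores <- map(setNames(params, params), function(p)
    normalize_parameter(measurements[[p]], config$normalization[[p]], p))
  weights <- unlist(config$weights)[params]
  wqi <- config$k *
    Reduce(`+`, map(params, function(p) scores[[p]] * weights[[p]])) /
    sum(weights)
  measurements %>%
    select("site_id", "season") %>%
    mutate(wqi = wqi, class = classify_wqi(wqi, config$classes))
}

#' Per-parameter exceedance and variability summary
#'
#' For each parameter with a configured standard limit: the exceedance rate
#' (percent of records beyond the limit, respecting orientation), mean,
#' sample SD and coefficient of variation (SD/mean; reported `NA` when the
#' mean is zero).
#'
#' @param measurements Measurement tibble.
#' @param limits Named list of per-parameter `{limit, orientation}` entries
#'   (`orientation` is `max` for ceilings, `min` for floors); defaults to
#'   the shipped Class III limits.
#' @return Tibble `parameter`, `n`, `exceedance_pct`, `mean`, `sd`, `cv`.
#' @export
exceedance_summary <- function(measurements,
                               limits = wqi_config()$class3_limits) {
  params <- intersect(names(limits), names(measurements))
  abort_if(length(params) == 0,
           "No parameter with a configured limit found in `measurements`.",
           "aquarisk_bad_input")
  rows <- map(params, function(p) {
    x <- measurements[[p]]
    abort_if(length(x) < 1, paste0("No records for ", p),
             "aquarisk_bad_input")
    lim <- limits[[p]]
    beyond <- if (identical(lim$orientation, "min")) x < lim$limit
              else x > lim$limit
    m <- mean(x)
    s <- sd(x)
    tibble(parameter = p, n = length(x),
           exceedance_pct = 100 * mean(beyond),
           mean = m, sd = s,
           cv = if (m == 0) NA_real_ else s / m)
  })
  list_rbind(rows)
}
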