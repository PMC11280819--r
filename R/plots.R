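# ggplot2 displays for the main result types.

#' Cumulative-frequency curves for Monte Carlo risk
#'
#' @param object A `risk_mc` object.
#' @param metric `"cr"` or `"hq"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_mc <- function(object, metric = c("cr", "hq"), ...) {
  metric <- match.arg(metric)
  dat <- object$cumfreq %>% filter(.data$metric == !!metric)
  threshold <- if (metric == "cr") 1e-6 else 1
  ggplot2::ggplot(dat, ggplot2::aes(.data$value, .data$cum_pct,
                                    colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metal, scales = "free_x") +
    ggplot2::labs(x = if (metric == "cr") "carcinogenic risk CR"
                      else "hazard quotient HQ",
                  y = "cumulative frequency (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Loading profile of a rotated principal-component decomposition
#'
#' @param object A `pca_loadings` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_loadings <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$variable, .data$loading,
                                 fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "loading", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Seasonal WQI distributions
#'
#' @param wqi_results Output of [wqi_table()].
#' @return A ggplot (boxplot of WQI by season).
#' @export
plot_wqi_seasons <- function(wqi_results) {
  check_columns(wqi_results, c("season", "wqi"), "wqi_results")
  ggplot2::ggplot(wqi_results,
                  ggplot2::aes(factor(.data$season, levels = SEASONS),
                               .data$wqi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "WQI") +
    ggplot2::theme_minimal()
}

#' Factor-detector q values per response
#'
#' @param q_factors Output of [factor_screen()].
#' @return A ggplot (bar chart of q by factor, faceted by response).
#' @export
plot_q_factors <- function(q_factors) {
  check_columns(q_factors, c("response", "factor", "q"), "q_factors")
  ggplot2::ggplot(q_factors,
                  ggplot2::aes(stats::reorder(.data$factor, .data$q),
                               .data$q)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = NULL, y = "explanatory power q") +
    ggplot2::theme_minimal()
}
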