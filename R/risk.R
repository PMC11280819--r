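# USEPA-style oral-ingestion health-risk assessment:
#
#   ADD = C * IR * EF * ED / (BW * AT)   [mg/(kg d)]
#   CR  = ADD * SF                        (carcinogenic risk)
#   HQ  = ADD / RfD                       (noncarcinogenic hazard quotient)
#
# deterministically or by Monte Carlo over distributions for the metal
# concentration C and the exposure factors, separately for adults and
# children.

#' Average daily dose
#'
#' @param C Concentration (mg/L).
#' @param IR Intake rate (L/d).
#' @param EF Exposure frequency (d/a).
#' @param ED Exposure duration (a).
#' @param BW Body weight (kg), > 0.
#' @param AT Averaging time (d), > 0.
#' @return ADD in mg/(kg d) (vectorized).
#' @export
#' @examples
#' add_dose(0.01, 2, 365, 30, 70, 10950)
add_dose <- function(C, IR, EF, ED, BW, AT) {
  abort_if(any(BW <= 0), "`BW` must be positive.", "aquarisk_bad_input")
  abort_if(any(AT <= 0), "`AT` must be positive.", "aquarisk_bad_input")
  C * IR * EF * ED / (BW * AT)
}

#' Carcinogenic risk and noncarcinogenic hazard quotient
#'
#' @param ADD Average daily dose, mg/(kg d).
#' @param SF Cancer slope factor, (mg/(kg d))^-1, >= 0.
#' @param RfD Reference dose, mg/(kg d), > 0.
#' @return `carcinogenic_risk()`: CR = ADD * SF. `noncarcinogenic_hq()`:
#'   HQ = ADD / RfD.
#' @export
carcinogenic_risk <- function(ADD, SF) {
  abort_if(any(SF < 0), "`SF` must be non-negative.", "aquarisk_bad_input")
  ADD * SF
}

#' @rdname carcinogenic_risk
#' @export
noncarcinogenic_hq <- function(ADD, RfD) {
  abort_if(any(RfD <= 0), "`RfD` must be positive.", "aquarisk_bad_input")
  ADD / RfD
}

#' Risk banding
#'
#' CR below 1e-6 is a low cancer risk, between 1e-6 and 1e-4 a potential
#' risk, above 1e-4 a high risk; HQ at or below 1 is acceptable, above 1
#' high.
#'
#' @param CR,HQ Risk values, >= 0.
#' @return Character band (vectorized).
#' @export
#' @examples
#' classify_cr(c(5e-7, 1e-5, 2e-4))
classify_cr <- function(CR) {
  abort_if(any(CR < 0), "`CR` must be non-negative.", "aquarisk_bad_input")
  ifelse(CR < 1e-6, "low", ifelse(CR <= 1e-4, "potential", "high"))
}

#' @rdname classify_cr
#' @export
classify_hq <- function(HQ) {
  abort_if(any(HQ < 0), "`HQ` must be non-negative.", "aquarisk_bad_input")
  ifelse(HQ <= 1, "acceptable", "high")
}

#' Fit a sampling distribution to a metal's measured concentrations
#'
#' Default: maximum-likelihood lognormal (closed form: log-mean and
#' log-scale SD with the divide-by-n MLE denominator). A constant series
#' collapses to a point mass, as does `family = "point"` (mass at the
#' arithmetic mean).
#'
#' @param x Positive concentrations (>= 3 observations).
#' @param family `"lognormal"` or `"point"`.
#' @return A [dist_spec()].
#' @export
fit_concentration <- function(x, family = c("lognormal", "point")) {
  family <- match.arg(family)
  abort_if(length(x) < 3, "Need at least 3 observations.",
           "aquarisk_bad_input")
  abort_if(any(x <= 0), "Concentrations must be positive.",
           "aquarisk_bad_input")
  if (family == "point" || sd(x) == 0)
    return(dist_spec("point", value = mean(x)))
  lx <- log(x)
  dist_spec("lognormal", meanlog = mean(lx),
            sdlog = sqrt(mean((lx - mean(lx))^2)))
}

# Stable textual key of a population's exposure specs. Monte Carlo cell
# seeds are derived from this (not from the population label), so swapping
# the adult/child spec sets swaps their results exactly.
spec_string <- function(specs) {
  paste(map_chr(sort(names(specs)), function(nm) {
    sp <- specs[[nm]]
    vals <- unlist(sp[setdiff(names(sp), "family")], use.names = TRUE)
    paste0(nm, ":", sp$family, "(",
           paste(names(vals), format(vals, digits = 17), sep = "=",
                 collapse = ","), ")")
  }), collapse = ";")
}

# Averaging-time draws under the configured rule.
at_draws <- function(specs, exposure, ED, n) {
  if (identical(exposure$at_rule, "derived")) {
    list(carc = rep((exposure$lifetime_years %||% 70) * 365, n),
         nonc = ED * 365)
  } else {
    at <- dist_sample(specs$AT, n)
    list(carc = at, nonc = at)
  }
}

#' Monte Carlo health-risk simulation
#'
#' Draws `n_iter` independent realizations of (C, IR, EF, ED, BW, AT) for
#' every metal and population, pushes them through the dose and risk
#' equations, and summarizes: mean, standard error of the mean,
#' percentiles, and the exceedance fractions P(CR > 1e-6), P(CR > 1e-4)
#' and P(HQ > 1). Each metal-population cell uses its own child seed, so
#' results are reproducible and swapping the adult/child exposure specs
#' swaps the results exactly.
#'
#' @param conc_specs Named list (per metal) of concentration
#'   [dist_spec()]s, e.g. from [fit_concentration()].
#' @param exposure An [exposure_model()].
#' @param toxicity A [toxicity_ref()].
#' @param n_iter Number of simulations per metal and population.
#' @param seed Integer seed.
#' @param keep_draws Keep the raw draws (memory: n_iter rows per cell)?
#' @return A `risk_mc` object: `summary` tibble, `cumfreq` tibble of
#'   empirical cumulative frequencies, and optionally `draws`.
#' @export
monte_carlo_risk <- function(conc_specs, exposure = exposure_model(),
                             toxicity = toxicity_ref(), n_iter = 10000,
                             seed = 1, keep_draws = FALSE) {
  abort_if(n_iter < 1, "`n_iter` must be at least 1.", "aquarisk_bad_input")
  conc_specs <- map(conc_specs, as_dist_spec)
  metals <- names(conc_specs)
  abort_if(length(metals) == 0 || is.null(metals),
           "`conc_specs` must be a named list of distribution specs.",
           "aquarisk_bad_input")
  pops <- names(exposure$populations)

  cells <- tidyr::expand_grid(population = pops, metal = metals)
  draws_list <- pmap(cells, function(population, metal) {
    specs <- exposure$populations[[population]]
    tox <- toxicity$metals[[metal]]
    abort_if(is.null(tox), paste0("No toxicity reference for ", metal),
             "aquarisk_bad_config")
    with_seed(child_seed(seed, paste("hra", metal, spec_string(specs))), {
      C <- dist_sample(conc_specs[[metal]], n_iter)
      IR <- dist_sample(specs$IR, n_iter)
      EF <- dist_sample(specs$EF, n_iter)
      ED <- dist_sample(specs$ED, n_iter)
      BW <- dist_sample(specs$BW, n_iter)
      at <- at_draws(specs, exposure, ED, n_iter)
      hq <- noncarcinogenic_hq(add_dose(C, IR, EF, ED, BW, at$nonc),
                               tox$RfD)
      cr <- if (isTRUE(tox$carcinogenic))
        carcinogenic_risk(add_dose(C, IR, EF, ED, BW, at$carc), tox$SF)
      else rep(NA_real_, n_iter)
      tibble(population = population, metal = metal,
             iter = seq_len(n_iter), cr = cr, hq = hq)
    })
  })
  draws <- list_rbind(draws_list)

  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summarise_metric <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(c(mean = NA_real_, se = NA_real_,
               setNames(rep(NA_real_, length(probs)),
                        paste0("p", probs * 100))))
    c(mean = mean(x), se = sd(x) / sqrt(length(x)),
      setNames(quantile(x, probs, names = FALSE), paste0("p", probs * 100)))
  }
  summary <- draws %>%
    group_by(.data$population, .data$metal) %>%
    summarise(
      cr_stats = list(summarise_metric(.data$cr)),
      hq_stats = list(summarise_metric(.data$hq)),
      p_cr_1e6 = mean(.data$cr > 1e-6),
      p_cr_1e4 = mean(.data$cr > 1e-4),
      p_hq_1 = mean(.data$hq > 1),
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("cr_stats", names_sep = "_") %>%
    tidyr::unnest_wider("hq_stats", names_sep = "_") %>%
    rename_with_prefix()

  grid <- seq(0, 1, length.out = min(n_iter, 200) + 1)[-1]
  cumfreq <- draws %>%
    tidyr::pivot_longer(c("cr", "hq"), names_to = "metric",
                        values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$population, .data$metal, .data$metric) %>%
    dplyr::reframe(cum_pct = grid * 100,
                   value = quantile(.data$value, grid, names = FALSE))

  structure(
    list(summary = summary, cumfreq = cumfreq,
         draws = if (keep_draws) draws else NULL,
         n_iter = n_iter, seed = seed),
    class = "risk_mc"
  )
}

# Rename unnest_wider columns cr_stats_mean -> cr_mean etc.
rename_with_prefix <- function(df) {
  names(df) <- gsub("^(cr|hq)_stats_", "\\1_", names(df))
  df
}

#' @export
print.risk_mc <- function(x, ...) {
  cat("<risk_mc> ", x$n_iter, " iterations, seed ", x$seed, "\n", sep = "")
  print(x$summary %>%
          select("population", "metal", "cr_mean", "hq_mean",
                 "p_cr_1e6", "p_hq_1"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.risk_mc <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.risk_mc <- function(x, ...) {
  tibble(n_iter = x$n_iter, seed = x$seed,
         n_metals = length(unique(x$summary$metal)),
         n_populations = length(unique(x$summary$population)),
         max_p_cr_1e4 = max(x$summary$p_cr_1e4, na.rm = TRUE),
         max_p_hq_1 = max(x$summary$p_hq_1))
}

#' Rank metals by mean risk
#'
#' Stable descending sort of the Monte Carlo summary by mean CR and by
#' mean HQ within each population; ties break alphabetically. Metals
#' without a slope factor are omitted from the CR ranking.
#'
#' @param x A `risk_mc` object or its `summary` tibble.
#' @return Tibble `population`, `metric`, `rank`, `metal`, `mean`.
#' @export
risk_ranking <- function(x) {
  summary <- if (inherits(x, "risk_mc")) x$summary else x
  check_columns(summary, c("population", "metal", "cr_mean", "hq_mean"),
                "risk summary")
  long <- bind_rows(
    summary %>%
      filter(!is.na(.data$cr_mean)) %>%
      mutate(metric = "CR", mean = .data$cr_mean),
    summary %>% mutate(metric = "HQ", mean = .data$hq_mean)
  )
  long %>%
    group_by(.data$population, .data$metric) %>%
    arrange(desc(.data$mean), .data$metal, .by_group = TRUE) %>%
    mutate(rank = dplyr::row_number()) %>%
    ungroup() %>%
    select("population", "metric", "rank", "metal", "mean")
}
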