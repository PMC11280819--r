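# Synthetic monitoring-campaign generator.
#
# Emulates a seasonal multi-site surface drinking-water survey: site
# coordinates uniform over a rectangular extent, nine spatially structured
# covariates (five natural, four anthropogenic), and per-season parameter
# concentrations whose variance is stratified by chosen covariates with
# analytically known explanatory power (see expected_q()).

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Generate monitoring-site locations
#'
#' Draws `n_sites` unique sites with coordinates uniform over a rectangular
#' extent (abstract planar decimal degrees; no projection handling).
#'
#' @param n_sites Number of sites (>= 2). The default emulates a 59-point
#'   drinking-water source survey.
#' @param extent Named list/vector with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`.
#' @param seed Integer seed; identical seeds yield identical tables. Each
#'   generator salts the seed with its own stage label (via [child_seed()]),
#'   so passing one global seed to sites, covariates and measurements gives
#'   three independent random streams.
#' @return A tibble with columns `site_id`, `lon`, `lat`.
#' @export
#' @examples
#' generate_sites(10, seed = 1)
generate_sites <- function(n_sites = 59,
                           extent = c(lon_min = 113.3, lon_max = 115.9,
                                      lat_min = 31.4, lat_max = 32.7),
                           seed = 1) {
  abort_if(!is.numeric(n_sites) || n_sites < 2,
           "`n_sites` must be at least 2.", "aquarisk_bad_input")
  extent <- unlist(extent)
  check_columns(as.list(extent),
                c("lon_min", "lon_max", "lat_min", "lat_max"), "extent")
  abort_if(extent["lon_min"] >= extent["lon_max"] ||
             extent["lat_min"] >= extent["lat_max"],
           "`extent` must be a non-degenerate rectangle.",
           "aquarisk_bad_input")
  n_sites <- as.integer(n_sites)
  with_seed(child_seed(seed, "sites"), tibble(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    lon = runif(n_sites, extent["lon_min"], extent["lon_max"]),
    lat = runif(n_sites, extent["lat_min"], extent["lat_max"])
  ))
}

#' Default covariate specifications
#'
#' One spec per geodetector factor. Continuous factors carry a latitude
#' gradient (`gradient` is the change over the south-to-north span; the
#' negative DEM/NDVI/Precipitation/Temperature gradients emulate a terrain
#' that is higher, greener, wetter and warmer in the south, while road
#' density, GDP and population density increase northwards), plus Gaussian
#' noise. Categorical factors are assigned by jittered latitude bands so
#' that strata are spatially coherent.
#'
#' @return Named list of per-factor specs.
#' @export
default_covariate_specs <- function() {
  list(
    DEM = list(type = "continuous", mean = 300, gradient = -250, sd = 60,
               min = 20),
    NDVI = list(type = "continuous", mean = 0.55, gradient = -0.15, sd = 0.05,
                min = 0.05),
    Precipitation = list(type = "continuous", mean = 1000, gradient = -150,
                         sd = 80, min = 300),
    Temperature = list(type = "continuous", mean = 15.5, gradient = -1.5,
                       sd = 0.5),
    Soil_Type = list(type = "categorical",
                     levels = c("paddy", "yellow_brown", "fluvo_aquic",
                                "purple")),
    Land_Use = list(type = "categorical",
                    levels = c("cropland", "forest", "grassland", "urban",
                               "water")),
    Road_Network_Density = list(type = "continuous", mean = 0.8,
                                gradient = 0.4, sd = 0.15, min = 0.01),
    GDP = list(type = "continuous", mean = 50, gradient = 25, sd = 10,
               min = 1),
    Population_Density = list(type = "continuous", mean = 400, gradient = 180,
                              sd = 80, min = 10)
  )
}

#' Generate per-site covariates
#'
#' @param sites Site tibble from [generate_sites()].
#' @param specs Named list of per-factor specs (see
#'   [default_covariate_specs()]); each is `type = "continuous"` (`mean`,
#'   `gradient`, `sd`, optional `min`) or `type = "categorical"` (`levels`).
#' @param seed Integer seed.
#' @return A tibble with one row per site: `site_id` plus one column per
#'   factor.
#' @export
generate_covariates <- function(sites, specs = default_covariate_specs(),
                                seed = 1) {
  check_columns(sites, c("site_id", "lat"), "sites")
  abort_if(length(specs) == 0 || is.null(names(specs)) ||
             any(names(specs) == ""),
           "`specs` must be a named list of factor specs.",
           "aquarisk_bad_input")
  bad <- names(specs)[!map_chr(specs, function(s) s$type %||% "") %in%
                        c("continuous", "categorical")]
  abort_if(length(bad) > 0,
           paste0("Unknown or missing `type` for factor(s): ",
                  paste(bad, collapse = ", ")),
           "aquarisk_bad_input")

  n <- nrow(sites)
  # Latitude scaled to [-1/2, 1/2] over the observed span (south = -1/2).
  lat_s <- (sites$lat - min(sites$lat)) /
    max(max(sites$lat) - min(sites$lat), .Machine$double.eps) - 0.5

  with_seed(child_seed(seed, "covariates"), {
    cols <- imap(specs, function(sp, nm) {
      if (sp$type == "continuous") {
        x <- sp$mean + (sp$gradient %||% 0) * lat_s + rnorm(n, 0, sp$sd)
        if (!is.null(sp$min)) x <- pmax(x, sp$min)
        x
      } else {
        k <- length(sp$levels)
        abort_if(k < 2, paste0("Categorical factor ", nm,
                               " needs at least 2 levels."),
                 "aquarisk_bad_input")
        # Jittered latitude bands give spatially coherent strata while
        # guaranteeing every level appears.
        band <- cut(rank(lat_s + rnorm(n, 0, 0.15), ties.method = "first"),
                    breaks = k, labels = FALSE)
        sp$levels[band]
      }
    })
    bind_cols_sites(sites$site_id, cols)
  })
}

bind_cols_sites <- function(site_id, cols) {
  as_tibble(c(list(site_id = site_id), cols))
}

# Resolve an effect's stratum labels against the covariate table.
effect_strata <- function(effect, covariates) {
  fac <- effect$factor
  abort_if(!fac %in% names(covariates),
           paste0("Effect for '", effect$parameter %||% "?",
                  "' references missing covariate: ", fac),
           "aquarisk_missing_factor")
  x <- covariates[[fac]]
  labels <- names(effect$means)
  if (is.numeric(x)) {
    # Continuous covariates: quantile classes Q1..Qk, one per stratum mean.
    k <- length(labels)
    strat <- discretize(x, method = "quantile", n_classes = k)
    lab <- paste0("Q", strat$stratum)
  } else {
    lab <- as.character(x)
    uncovered <- setdiff(unique(lab), labels)
    abort_if(length(uncovered) > 0,
             paste0("Effect means for factor ", fac,
                    " do not cover stratum label(s): ",
                    paste(uncovered, collapse = ", ")),
             "aquarisk_missing_factor")
  }
  lab
}

#' Generate seasonal measurements with planted stratum effects
#'
#' Emits three rows per site (wet, dry, normal seasons). Each parameter's
#' site-level mean is either its baseline or, when a planted effect names a
#' covariate, the per-stratum mean; seasonal draws are independent around
#' that mean with lognormal (log-scale sd, default) or normal noise.
#' Lognormal draws are `exp(log(mean) + eps)`; normal draws are floored at
#' a tiny positive value so all concentrations stay strictly positive.
#'
#' @param sites Site tibble.
#' @param covariates Covariate tibble from [generate_covariates()].
#' @param effects An [effects_config()] (baselines, planted effects, season
#'   multipliers).
#' @param seed Integer seed.
#' @return A tibble with `site_id`, `season` and one column per parameter.
#' @export
generate_measurements <- function(sites, covariates,
                                  effects = effects_config(), seed = 1) {
  check_columns(sites, "site_id", "sites")
  check_columns(covariates, "site_id", "covariates")
  n <- nrow(sites)
  params <- names(effects$baseline)
  eff_by_param <- setNames(effects$effects,
                           map_chr(effects$effects, "parameter"))
  mult <- unlist(effects$season_multipliers)[SEASONS]

  # Per-site mean for every parameter.
  site_means <- map(setNames(params, params), function(p) {
    eff <- eff_by_param[[p]]
    if (is.null(eff)) rep(effects$baseline[[p]]$mean, n)
    else unname(unlist(eff$means)[effect_strata(eff, covariates)])
  })

  with_seed(child_seed(seed, "measurements"), {
    rows <- map(SEASONS, function(season) {
      vals <- map(setNames(params, params), function(p) {
        eff <- eff_by_param[[p]]
        fam <- if (is.null(eff)) effects$baseline[[p]]$family %||% "lognormal"
               else eff$family %||% "lognormal"
        s <- if (is.null(eff)) effects$baseline[[p]]$sd else eff$noise_sd
        mu <- site_means[[p]]
        mlt <- unname(mult[season])
        if (fam == "lognormal") {
          exp(log(mu * mlt) + rnorm(n, 0, s))
        } else {
          pmax(mu + (mlt - 1) + rnorm(n, 0, s), .Machine$double.eps)
        }
      })
      as_tibble(c(list(site_id = sites$site_id,
                       season = rep(season, n)), vals))
    })
    arrange(bind_rows(rows), .data$site_id, match(.data$season, SEASONS))
  })
}

#' Expected geodetector q of a planted effect
#'
#' Evaluates, exactly from population moments, the stratified-variance share
#' the factor detector should recover on data generated from an effect
#' spec: `q* = B / (B + W)` where `B` is the size-weighted population
#' variance of the stratum means and `W` the size-weighted within-stratum
#' noise variance. For lognormal noise (`exp(log(m_h) + eps)`,
#' `eps ~ N(0, sd^2)`) the stratum moments are `m_h exp(sd^2/2)` and
#' `m_h^2 exp(sd^2)(exp(sd^2) - 1)`; for normal noise they are `m_h` and
#' `sd^2`.
#'
#' @param effect A single effect spec (fields `means`, `noise_sd`,
#'   optional `family`).
#' @param sizes Stratum sizes, in the order of `effect$means` (recycled if
#'   length 1).
#' @return The expected q in `[0, 1]`.
#' @export
#' @examples
#' expected_q(list(means = c(a = 10, b = 12), noise_sd = 2,
#'                 family = "normal"), sizes = c(50, 50))
expected_q <- function(effect, sizes = 1) {
  m <- unlist(effect$means)
  abort_if(length(m) < 2, "An effect needs at least 2 strata.",
           "aquarisk_bad_input")
  s <- effect$noise_sd
  abort_if(is.null(s) || s < 0, "`noise_sd` must be non-negative.",
           "aquarisk_bad_input")
  fam <- effect$family %||% "lognormal"
  sizes <- rep_len(sizes, length(m))
  w <- sizes / sum(sizes)
  if (fam == "lognormal") {
    mu_h <- m * exp(s^2 / 2)
    v_h <- m^2 * exp(s^2) * (exp(s^2) - 1)
  } else {
    mu_h <- m
    v_h <- rep(s^2, length(m))
  }
  between <- sum(w * (mu_h - sum(w * mu_h))^2)
  within <- sum(w * v_h)
  abort_if(between + within <= 0,
           "Total variance is zero; expected q is undefined.",
           "aquarisk_zero_variance")
  between / (between + within)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_sites()], [generate_covariates()]
#' and [generate_measurements()] with per-stage child seeds derived from one
#' global seed.
#'
#' @inheritParams generate_sites
#' @param covariate_specs See [generate_covariates()].
#' @param effects See [generate_measurements()].
#' @return A list with tibbles `sites`, `covariates`, `measurements`.
#' @export
generate_dataset <- function(n_sites = 59,
                             extent = c(lon_min = 113.3, lon_max = 115.9,
                                        lat_min = 31.4, lat_max = 32.7),
                             covariate_specs = default_covariate_specs(),
                             effects = effects_config(), seed = 1) {
  sites <- generate_sites(n_sites, extent, seed = seed)
  covariates <- generate_covariates(sites, covariate_specs, seed = seed)
  measurements <- generate_measurements(sites, covariates, effects,
                                        seed = seed)
  list(sites = sites, covariates = covariates, measurements = measurements)
}
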