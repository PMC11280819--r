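# Configuration loaders. Every analysis stage is driven by an editable YAML
# file; the package ships defaults under inst/extdata which these helpers
# load, optionally overlaid with user overrides (recursive list merge).

default_config_path <- function(name) {
  system.file("extdata", name, package = "aquarisk", mustWork = TRUE)
}

load_yaml_config <- function(path, defaults_name) {
  if (is.null(path)) path <- default_config_path(defaults_name)
  abort_if(!file.exists(path), paste0("Config file not found: ", path),
           "aquarisk_missing_file")
  yaml::read_yaml(path)
}

#' Load a WQI configuration
#'
#' Reads the subjective constant `k`, per-parameter weights \eqn{P_i},
#' piecewise-linear normalization tables for the scores \eqn{C_i}, the
#' ordered class scheme and the Class III standard limits. The shipped
#' default is editable and non-authoritative.
#'
#' @param path Path to a YAML file; `NULL` loads the shipped default.
#' @param overrides Optional named list merged over the file contents.
#' @return A list with class `wqi_config`.
#' @export
wqi_config <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "wqi_config.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  abort_if(!is.numeric(cfg$k) || cfg$k < 0.25 || cfg$k > 1,
           "`k` must lie in [0.25, 1].", "aquarisk_bad_config")
  w <- unlist(cfg$weights)
  abort_if(any(w < 1 | w > 4), "Weights P_i must lie in [1, 4].",
           "aquarisk_bad_config")
  for (p in names(cfg$normalization)) {
    tab <- cfg$normalization[[p]]
    abort_if(is.unsorted(tab$conc, strictly = TRUE),
             paste0("Breakpoints for ", p, " must be strictly increasing."),
             "aquarisk_bad_config")
    abort_if(any(tab$score < 0 | tab$score > 100),
             paste0("Scores for ", p, " must lie in [0, 100]."),
             "aquarisk_bad_config")
  }
  mins <- map_dbl(cfg$classes, "min")
  abort_if(is.unsorted(rev(mins), strictly = TRUE),
           "Class boundaries must be strictly decreasing.",
           "aquarisk_bad_config")
  structure(cfg, class = c("wqi_config", "list"))
}

#' Load a trophic-state (EI) configuration
#'
#' Reads the indicator list, per-indicator "extremely poor" reference
#' anchors \eqn{C_{j0}} with orientation, the normalization ceiling
#' `x_max`, indicator weights and the ordered grade thresholds.
#'
#' @inheritParams wqi_config
#' @return A list with class `trophic_config`.
#' @export
trophic_config <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "trophic_config.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  n <- length(cfg$indicators)
  if (identical(cfg$weights, "equal")) {
    cfg$weights <- setNames(rep(1 / n, n), cfg$indicators)
  } else {
    w <- unlist(cfg$weights)[cfg$indicators]
    abort_if(anyNA(w) || any(w <= 0),
             "Indicator weights must be positive and cover all indicators.",
             "aquarisk_bad_config")
    cfg$weights <- w / sum(w)
  }
  for (j in cfg$indicators)
    abort_if(is.null(cfg$reference[[j]]) || cfg$reference[[j]]$c0 <= 0,
             paste0("Reference C_j0 missing or non-positive for ", j),
             "aquarisk_bad_config")
  gmins <- map_dbl(cfg$grades, "min")
  abort_if(is.unsorted(gmins, strictly = TRUE),
           "Grade thresholds must be strictly increasing.",
           "aquarisk_bad_config")
  abort_if(cfg$x_max <= 1, "`x_max` must exceed 1.", "aquarisk_bad_config")
  structure(cfg, class = c("trophic_config", "list"))
}

#' Load an exposure model
#'
#' Per-population (adult, child) distribution specs for IR (L/d), EF (d/a),
#' ED (a) and BW (kg), plus the averaging-time rule: `at_rule: derived`
#' computes AT as ED*365 d for noncarcinogens and `lifetime_years`*365 d for
#' carcinogens; explicit AT specs override.
#'
#' @inheritParams wqi_config
#' @return A list with class `exposure_model`.
#' @export
exposure_model <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "exposure.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  for (pop in names(cfg$populations)) {
    specs <- cfg$populations[[pop]]
    needed <- c("IR", "EF", "ED", "BW")
    if (!identical(cfg$at_rule, "derived")) needed <- c(needed, "AT")
    missing <- setdiff(needed, names(specs))
    abort_if(length(missing) > 0,
             paste0("Population '", pop, "' is missing spec(s): ",
                    paste(missing, collapse = ", ")),
             "aquarisk_bad_config")
    cfg$populations[[pop]] <- map(specs, as_dist_spec)
    ef <- cfg$populations[[pop]]$EF
    ef_max <- if (ef$family == "point") ef$value else
      ef$trunc_max %||% dist_quantile(ef, 1)
    abort_if(is.finite(ef_max) && ef_max > 366,
             "Exposure frequency EF cannot exceed 366 d/a.",
             "aquarisk_bad_config")
  }
  structure(cfg, class = c("exposure_model", "list"))
}

#' Load toxicity references
#'
#' Oral slope factors SF ((mg/(kg d))^-1) for carcinogenic metals and
#' reference doses RfD (mg/(kg d)) for all metals.
#'
#' @inheritParams wqi_config
#' @return A list with class `toxicity_ref`.
#' @export
toxicity_ref <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "toxicity.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  for (m in names(cfg$metals)) {
    tox <- cfg$metals[[m]]
    abort_if(is.null(tox$RfD) || tox$RfD <= 0,
             paste0("RfD must be positive for ", m), "aquarisk_bad_config")
    if (isTRUE(tox$carcinogenic))
      abort_if(is.null(tox$SF) || tox$SF < 0,
               paste0("Carcinogenic metal ", m, " needs a non-negative SF."),
               "aquarisk_bad_config")
  }
  structure(cfg, class = c("toxicity_ref", "list"))
}

#' Load geodetector settings
#'
#' Discretization method and class count for continuous covariates, the
#' interaction-classification tolerance, and which covariates are treated
#' as categorical.
#'
#' @inheritParams wqi_config
#' @return A list with class `geodetector_config`.
#' @export
geodetector_config <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "geodetector.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg$method <- match.arg(cfg$method,
                          c("natural_breaks", "quantile", "equal_interval",
                            "geometric"))
  abort_if(cfg$n_classes < 2, "`n_classes` must be at least 2.",
           "aquarisk_bad_config")
  abort_if(cfg$tolerance < 0, "`tolerance` must be non-negative.",
           "aquarisk_bad_config")
  structure(cfg, class = c("geodetector_config", "list"))
}

#' Load a synthetic measurement model (baselines, planted effects, seasons)
#'
#' @inheritParams wqi_config
#' @return A list with class `effects_config`.
#' @export
effects_config <- function(path = NULL, overrides = NULL) {
  cfg <- load_yaml_config(path, "effects.yaml")
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  for (e in cfg$effects) {
    abort_if(is.null(e$parameter) || is.null(e$factor) || is.null(e$means),
             "Each effect needs `parameter`, `factor` and `means`.",
             "aquarisk_bad_config")
    abort_if(length(e$means) < 2, "Each effect needs at least 2 strata.",
             "aquarisk_bad_config")
    abort_if(is.null(e$noise_sd) || e$noise_sd <= 0,
             "`noise_sd` must be positive.", "aquarisk_bad_config")
  }
  structure(cfg, class = c("effects_config", "list"))
}
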