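# Pipeline orchestration: validate inputs, run the analysis stages in
# order (simulate -> wqi -> ei -> hra -> geodetect -> associate), write
# every stage's CSV outputs plus a report.json of headline quantities.

#' Build a pipeline run configuration
#'
#' @param outdir Output directory (created if missing).
#' @param seed Non-negative integer global seed; per-stage child seeds are
#'   derived from it with [child_seed()], so toggling one stage never
#'   shifts another stage's random stream.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "wqi", "ei", "hra", "geodetect", "associate")`.
#' @param inputs Named list of input CSV paths (`sites`, `covariates`,
#'   `measurements`); ignored for tables the simulate stage generates.
#' @param n_sites Sites to simulate.
#' @param n_iter Monte Carlo iterations for the hra stage.
#' @param keep_draws Write the raw Monte Carlo draws (`risk_draws.csv`)?
#' @param config_paths Named list of YAML config paths (`wqi`, `trophic`,
#'   `exposure`, `toxicity`, `geodetector`, `effects`); `NULL` entries load
#'   the shipped defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1,
                       stages = c("simulate", "wqi", "ei", "hra",
                                  "geodetect", "associate"),
                       inputs = list(), n_sites = 59, n_iter = 10000,
                       keep_draws = FALSE, config_paths = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  abort_if(!is.numeric(seed) || seed < 0, "`seed` must be non-negative.",
           "aquarisk_bad_config")
  for (nm in names(inputs))
    abort_if(!file.exists(inputs[[nm]]),
             paste0("Input file for `", nm, "` not found: ", inputs[[nm]]),
             "aquarisk_missing_file")
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 inputs = inputs, n_sites = n_sites, n_iter = n_iter,
                 keep_draws = keep_draws, config_paths = config_paths),
            class = c("run_config", "list"))
}

#' Validate pipeline input tables
#'
#' Report-only checks: required columns, strictly positive concentrations,
#' season labels in `wet`/`dry`/`normal`, and site-id consistency across
#' tables.
#'
#' @param measurements Measurement tibble.
#' @param covariates Optional covariate tibble.
#' @param sites Optional site tibble.
#' @return A tibble of issues (`table`, `row`, `column`, `issue`); zero
#'   rows when the inputs are clean.
#' @export
validate_inputs <- function(measurements, covariates = NULL, sites = NULL) {
  issues <- list()
  note <- function(table, row, column, issue)
    issues[[length(issues) + 1]] <<- tibble(
      table = table, row = as.integer(row), column = column, issue = issue)

  required <- c("site_id", "season")
  for (col in setdiff(required, names(measurements)))
    note("measurements", NA, col, "required column missing")
  if ("season" %in% names(measurements)) {
    bad <- which(!measurements$season %in% SEASONS)
    for (i in bad)
      note("measurements", i, "season",
           paste0("invalid season label: ", measurements$season[i]))
  }
  conc_cols <- setdiff(
    names(measurements)[map_chr(measurements, function(x)
      class(x)[1]) %in% c("numeric", "integer")],
    c("pH", "lon", "lat"))
  for (col in conc_cols) {
    bad <- which(!is.na(measurements[[col]]) & measurements[[col]] <= 0)
    for (i in bad) note("measurements", i, col, "non-positive concentration")
    for (i in which(is.na(measurements[[col]])))
      note("measurements", i, col, "missing value")
  }
  if (!is.null(covariates) && "site_id" %in% names(measurements) &&
      "site_id" %in% names(covariates)) {
    for (s in setdiff(covariates$site_id, measurements$site_id))
      note("covariates", which(covariates$site_id == s)[1], "site_id",
           paste0("site absent from measurements: ", s))
    for (s in setdiff(unique(measurements$site_id), covariates$site_id))
      note("measurements", which(measurements$site_id == s)[1], "site_id",
           paste0("site absent from covariates: ", s))
  }
  if (!is.null(sites) && "site_id" %in% names(sites)) {
    if (anyDuplicated(sites$site_id))
      note("sites", anyDuplicated(sites$site_id), "site_id",
           "duplicate site_id")
  }
  if (length(issues) == 0)
    tibble(table = character(), row = integer(), column = character(),
           issue = character())
  else list_rbind(issues)
}

read_stage_csv <- function(path, what) {
  abort_if(is.null(path) || !file.exists(path),
           paste0("Missing input for ", what,
                  if (!is.null(path)) paste0(": ", path) else
                    " (no path configured and simulate stage disabled)"),
           "aquarisk_missing_file")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `config$outdir` and a final `report.json` with headline
#' quantities (WQI class counts, trophic grade shares, risk exceedance
#' fractions, top-3 factors and interactions per response). A stage
#' failure removes that stage's partial outputs and aborts with the stage
#' name.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "run_config"),
           "`config` must come from run_config().", "aquarisk_bad_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  cp <- config$config_paths
  report <- list(seed = config$seed, stages = as.list(config$stages),
                 outputs = list())

  tables <- list()
  run_stage <- function(stage, files, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    tryCatch(fn(), error = function(e) {
      unlink(map_chr(files, out))
      rlang::abort(paste0("Stage '", stage, "' failed: ",
                          conditionMessage(e)),
                   class = "aquarisk_stage_error", parent = e)
    })
    message(sprintf("[aquarisk] stage %-9s %6.2fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report$outputs[[stage]] <<- as.list(unlist(files))  # names, outdir-relative
  }

  run_stage("simulate",
            c("sites.csv", "covariates.csv", "measurements.csv"), function() {
    ds <- generate_dataset(n_sites = config$n_sites,
                           effects = effects_config(cp$effects),
                           seed = config$seed)
    tables <<- ds
    readr::write_csv(ds$sites, out("sites.csv"))
    readr::write_csv(ds$covariates, out("covariates.csv"))
    readr::write_csv(ds$measurements, out("measurements.csv"))
  })

  if (!"simulate" %in% config$stages) {
    tables$measurements <- read_stage_csv(config$inputs$measurements,
                                          "measurements")
    if (!is.null(config$inputs$covariates))
      tables$covariates <- read_stage_csv(config$inputs$covariates,
                                          "covariates")
    if (!is.null(config$inputs$sites))
      tables$sites <- read_stage_csv(config$inputs$sites, "sites")
  }

  needs_meas <- intersect(c("wqi", "ei", "hra", "geodetect", "associate"),
                          config$stages)
  if (length(needs_meas) > 0)
    check_columns(tables$measurements %||% tibble(), c("site_id", "season"),
                  "measurements")

  run_stage("wqi", c("wqi_results.csv", "exceedance.csv"), function() {
    cfg <- wqi_config(cp$wqi)
    wt <- wqi_table(tables$measurements, cfg)
    readr::write_csv(wt, out("wqi_results.csv"))
    readr::write_csv(exceedance_summary(tables$measurements,
                                        cfg$class3_limits),
                     out("exceedance.csv"))
    per_site <- wt %>%
      group_by(.data$site_id) %>%
      summarise(wqi = mean(.data$wqi), .groups = "drop") %>%
      mutate(class = classify_wqi(.data$wqi, cfg$classes))
    report$wqi <<- list(
      mean = mean(wt$wqi),
      record_class_counts = as.list(table(wt$class)),
      site_class_counts = as.list(table(per_site$class)))
  })

  run_stage("ei", c("ei_results.csv", "ei_correlations.csv"), function() {
    cfg <- trophic_config(cp$trophic)
    et <- ei_table(tables$measurements, cfg)
    readr::write_csv(et, out("ei_results.csv"))
    per_site <- tables$measurements %>%
      group_by(.data$site_id) %>%
      summarise(across(all_of(cfg$indicators), mean), .groups = "drop")
    corr <- ei_correlates(et$ei, per_site %>% select(-"site_id"))
    readr::write_csv(corr, out("ei_correlations.csv"))
    report$ei <<- list(
      overall = mean(et$ei),
      grade_shares_pct = as.list(100 * table(et$label) / nrow(et)))
  })

  run_stage("hra",
            c("risk_summary.csv", "cumulative_frequency.csv",
              if (config$keep_draws) "risk_draws.csv"), function() {
    metals <- intersect(HRA_METALS, names(tables$measurements))
    abort_if(length(metals) == 0, "no heavy-metal columns present")
    conc <- map(setNames(metals, metals), function(m)
      fit_concentration(tables$measurements[[m]]))
    mc <- monte_carlo_risk(conc, exposure_model(cp$exposure),
                           toxicity_ref(cp$toxicity),
                           n_iter = config$n_iter,
                           seed = child_seed(config$seed, "hra"),
                           keep_draws = config$keep_draws)
    readr::write_csv(mc$summary, out("risk_summary.csv"))
    readr::write_csv(mc$cumfreq, out("cumulative_frequency.csv"))
    if (config$keep_draws)
      readr::write_csv(mc$draws, out("risk_draws.csv"))
    report$hra <<- list(
      exceedance = mc$summary %>%
        select("population", "metal", "p_cr_1e6", "p_cr_1e4", "p_hq_1") %>%
        purrr::transpose(),
      ranking = risk_ranking(mc) %>% purrr::transpose())
  })

  run_stage("geodetect", c("q_factors.csv", "q_interactions.csv"),
            function() {
    abort_if(is.null(tables$covariates), "no covariate table available")
    cfg <- geodetector_config(cp$geodetector)
    qf <- factor_screen(tables$measurements, tables$covariates,
                        config = cfg)
    qi <- interaction_screen(tables$measurements, tables$covariates,
                             config = cfg)
    readr::write_csv(qf, out("q_factors.csv"))
    readr::write_csv(qi, out("q_interactions.csv"))
    report$geodetector <<- list(
      top_factors = qf %>%
        group_by(.data$response) %>%
        dplyr::slice_head(n = 3) %>%
        ungroup() %>%
        select("response", "factor", "q") %>%
        purrr::transpose(),
      top_interactions = qi %>%
        group_by(.data$response) %>%
        arrange(desc(.data$q12), .by_group = TRUE) %>%
        dplyr::slice_head(n = 3) %>%
        ungroup() %>%
        select("response", "factor_a", "factor_b", "q12", "category") %>%
        purrr::transpose())
  })

  run_stage("associate", c("correlations.csv", "pca_loadings.csv"),
            function() {
    metals <- intersect(HRA_METALS, names(tables$measurements))
    abort_if(length(metals) < 2, "need at least 2 metal columns")
    per_site <- tables$measurements %>%
      group_by(.data$site_id) %>%
      summarise(across(all_of(metals), mean), .groups = "drop")
    cm <- correlation_matrix(per_site %>% select(-"site_id"))
    readr::write_csv(as_tibble(cm, rownames = "variable"),
                     out("correlations.csv"))
    pca <- pca_rotated(per_site %>% select(-"site_id"),
                       n_components = min(2, length(metals)))
    load_tab <- tidy(pca) %>%
      tidyr::pivot_wider(names_from = "component",
                         values_from = "loading")
    readr::write_csv(
      bind_rows(load_tab,
                tibble(variable = "explained_pct",
                       !!!setNames(as.list(pca$explained_pct),
                                   colnames(pca$loadings)))),
      out("pca_loadings.csv"))
    report$association <<- list(
      cumulative_pct = pca$cumulative_pct[length(pca$cumulative_pct)])
  })

  report_path <- out("report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
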