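# Small distribution-spec toolkit for Monte Carlo exposure sampling.
#
# A spec is a named list: family plus its parameters, with optional
# truncation bounds applied by inverse-CDF restriction (no rejection loops,
# so draw counts are exact and reproducible).

#' Build a distribution specification
#'
#' Specifications drive Monte Carlo sampling of exposure factors and metal
#' concentrations. Supported families: `point` (degenerate mass at `value`),
#' `normal` (`mean`, `sd`), `lognormal` (`meanlog`, `sdlog` on the log scale),
#' `triangular` (`min`, `mode`, `max`) and `uniform` (`min`, `max`).
#' Optional `trunc_min`/`trunc_max` restrict the support by inverse-CDF
#' conditioning, so truncated draws are exact (no rejection).
#'
#' @param family One of `"point"`, `"normal"`, `"lognormal"`, `"triangular"`,
#'   `"uniform"`.
#' @param ... Family parameters (see Description).
#' @param trunc_min,trunc_max Optional truncation bounds.
#' @return A `dist_spec` object.
#' @export
#' @examples
#' dist_spec("normal", mean = 2, sd = 0.3, trunc_min = 0.1)
dist_spec <- function(family, ..., trunc_min = NULL, trunc_max = NULL) {
  family <- match.arg(family,
                      c("point", "normal", "lognormal", "triangular", "uniform"))
  params <- list(...)
  needed <- switch(family,
    point      = "value",
    normal     = c("mean", "sd"),
    lognormal  = c("meanlog", "sdlog"),
    triangular = c("min", "mode", "max"),
    uniform    = c("min", "max")
  )
  missing <- setdiff(needed, names(params))
  abort_if(length(missing) > 0,
           paste0("Distribution family '", family, "' needs parameter(s): ",
                  paste(missing, collapse = ", ")),
           class = "aquarisk_bad_spec")
  if (family == "normal")
    abort_if(params$sd < 0, "`sd` must be non-negative.", "aquarisk_bad_spec")
  if (family == "lognormal")
    abort_if(params$sdlog < 0, "`sdlog` must be non-negative.", "aquarisk_bad_spec")
  if (family == "triangular")
    abort_if(!(params$min <= params$mode && params$mode <= params$max &&
                 params$min < params$max),
             "Triangular needs min <= mode <= max and min < max.",
             "aquarisk_bad_spec")
  if (family == "uniform")
    abort_if(params$min >= params$max, "Uniform needs min < max.",
             "aquarisk_bad_spec")
  if (!is.null(trunc_min) && !is.null(trunc_max))
    abort_if(trunc_min >= trunc_max, "trunc_min must be below trunc_max.",
             "aquarisk_bad_spec")
  structure(
    c(list(family = family), params,
      list(trunc_min = trunc_min, trunc_max = trunc_max)),
    class = "dist_spec"
  )
}

# Parse a YAML-style list into a dist_spec.
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  abort_if(is.null(x$family), "Distribution spec needs a `family` field.",
           "aquarisk_bad_spec")
  args <- x[setdiff(names(x), "family")]
  do.call(dist_spec, c(list(family = x$family), args))
}

# CDF of the untruncated family at x.
dist_cdf <- function(spec, x) {
  switch(spec$family,
    point      = as.numeric(x >= spec$value),
    normal     = stats::pnorm(x, spec$mean, spec$sd),
    lognormal  = stats::plnorm(x, spec$meanlog, spec$sdlog),
    uniform    = stats::punif(x, spec$min, spec$max),
    triangular = {
      a <- spec$min; cc <- spec$mode; b <- spec$max
      ifelse(x <= a, 0,
        ifelse(x >= b, 1,
          ifelse(x <= cc,
                 (x - a)^2 / ((b - a) * (cc - a)),
                 1 - (b - x)^2 / ((b - a) * (b - cc)))))
    }
  )
}

# Quantile function of the untruncated family.
dist_quantile <- function(spec, u) {
  switch(spec$family,
    point      = rep(spec$value, length(u)),
    normal     = stats::qnorm(u, spec$mean, spec$sd),
    lognormal  = stats::qlnorm(u, spec$meanlog, spec$sdlog),
    uniform    = stats::qunif(u, spec$min, spec$max),
    triangular = {
      a <- spec$min; cc <- spec$mode; b <- spec$max
      fc <- (cc - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (cc - a)),
             b - sqrt((1 - u) * (b - a) * (b - cc)))
    }
  )
}

#' Sample from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n) {
  spec <- as_dist_spec(spec)
  abort_if(n < 0, "`n` must be non-negative.")
  if (spec$family == "point") return(rep(spec$value, n))
  lo <- if (is.null(spec$trunc_min)) 0 else dist_cdf(spec, spec$trunc_min)
  hi <- if (is.null(spec$trunc_max)) 1 else dist_cdf(spec, spec$trunc_max)
  u <- lo + (hi - lo) * runif(n)
  dist_quantile(spec, u)
}

# Mean of the (untruncated) family; exact for point, used for summaries.
dist_mean <- function(spec) {
  spec <- as_dist_spec(spec)
  switch(spec$family,
    point      = spec$value,
    normal     = spec$mean,
    lognormal  = exp(spec$meanlog + spec$sdlog^2 / 2),
    uniform    = (spec$min + spec$max) / 2,
    triangular = (spec$min + spec$mode + spec$max) / 3
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "trunc_min", "trunc_max"))]
  cat("<dist_spec> ", x$family, "(",
      paste(names(pars), unlist(pars), sep = " = ", collapse = ", "), ")",
      sep = "")
  if (!is.null(x$trunc_min) || !is.null(x$trunc_max))
    cat("  truncated to [", x$trunc_min %||% -Inf, ", ",
        x$trunc_max %||% Inf, "]", sep = "")
  cat("\n")
  invisible(x)
}
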