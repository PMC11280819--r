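# Geodetector: factor detector (q-statistic), continuous-covariate
# discretization, and the five-category two-factor interaction detector.
#
# q = 1 - SSW/SST with population (divide-by-count) variances, so q is
# exactly the between-strata share of the sum of squares and lies in [0, 1]
# whenever the total variance is positive.

#' Discretize a continuous covariate into strata
#'
#' Methods: `quantile` (equal-frequency), `equal_interval`, `geometric`
#' (geometrically spaced edges; requires positive values), and
#' `natural_breaks` (exact Jenks optimization by dynamic programming,
#' minimizing the within-class sum of squared deviations).
#'
#' @param values Numeric vector.
#' @param method Discretization method.
#' @param n_classes Number of classes (>= 2, at most the number of distinct
#'   values).
#' @return A `stratification` object: integer `stratum` per observation,
#'   class `edges`, `method`, `n_classes` and provenance.
#' @export
#' @examples
#' discretize(c(1, 2, 3, 100, 101, 102), "natural_breaks", 2)
discretize <- function(values,
                       method = c("natural_breaks", "quantile",
                                  "equal_interval", "geometric"),
                       n_classes = 5) {
  method <- match.arg(method)
  abort_if(anyNA(values), "`values` must not contain NA.",
           "aquarisk_bad_input")
  abort_if(n_classes < 2, "`n_classes` must be at least 2.",
           "aquarisk_bad_input")
  n_distinct <- length(unique(values))
  abort_if(n_distinct < n_classes,
           paste0("Need at least ", n_classes, " distinct values; got ",
                  n_distinct, "."),
           "aquarisk_too_few_values")

  inner <- switch(method,
    quantile = unique(unname(
      quantile(values, probs = seq_len(n_classes - 1) / n_classes))),
    equal_interval = seq(min(values), max(values),
                         length.out = n_classes + 1)[-c(1, n_classes + 1)],
    geometric = {
      abort_if(min(values) <= 0,
               "Geometric intervals require strictly positive values.",
               "aquarisk_bad_input")
      r <- (max(values) / min(values))^(1 / n_classes)
      min(values) * r^seq_len(n_classes - 1)
    },
    natural_breaks = jenks_breaks(values, n_classes)
  )
  edges <- c(-Inf, sort(unique(inner)), Inf)
  stratum <- findInterval(values, edges, left.open = TRUE)
  new_stratification(stratum, edges = edges, method = method,
                     n_classes = length(edges) - 1,
                     provenance = "discretized")
}

# Exact Jenks natural breaks: dynamic programming minimizing the total
# within-class sum of squared deviations. Returns the n_classes - 1 interior
# break values (upper edge of each class but the last). O(k n^2).
jenks_breaks <- function(values, n_classes) {
  x <- sort(values)
  n <- length(x)
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  # cost(i, j): within-class SSD of x[i..j], via prefix sums.
  cost <- function(i, j) {
    s <- s1[j] - if (i > 1) s1[i - 1] else 0
    ss <- s2[j] - if (i > 1) s2[i - 1] else 0
    ss - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, nrow = n, ncol = n_classes)
  B <- matrix(0L, nrow = n, ncol = n_classes)
  i_all <- seq_len(n)
  D[, 1] <- s2 - s1^2 / i_all
  for (k in 2:n_classes) {
    for (j in k:n) {
      starts <- k:j
      tot <- D[starts - 1L, k - 1L] + cost_vec(s1, s2, starts, j)
      best <- which.min(tot)
      D[j, k] <- tot[best]
      B[j, k] <- starts[best]
    }
  }
  # Recover class boundaries (value of the last member of each class).
  breaks <- numeric(n_classes - 1)
  j <- n
  for (k in n_classes:2) {
    i <- B[j, k]
    breaks[k - 1] <- x[i - 1]
    j <- i - 1
  }
  breaks
}

cost_vec <- function(s1, s2, starts, j) {
  s <- s1[j] - c(0, s1)[starts]
  ss <- s2[j] - c(0, s2)[starts]
  ss - s^2 / (j - starts + 1)
}

new_stratification <- function(stratum, edges = NULL, method = "categorical",
                               n_classes = length(unique(stratum)),
                               provenance = "native", labels = NULL) {
  structure(
    list(stratum = as.integer(stratum), labels = labels, edges = edges,
         method = method, n_classes = n_classes, provenance = provenance),
    class = "stratification"
  )
}

#' Coerce labels to a stratification
#'
#' @param x A `stratification`, or a vector of categorical stratum labels.
#' @return A `stratification` object.
#' @export
as_stratification <- function(x) {
  if (inherits(x, "stratification")) return(x)
  abort_if(anyNA(x), "Stratum labels must not contain NA.",
           "aquarisk_bad_input")
  f <- factor(x)
  new_stratification(as.integer(f), method = "categorical",
                     provenance = "native", labels = levels(f))
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification> ", x$n_classes, " strata (", x$method, ", ",
      x$provenance, "), n = ", length(x$stratum), "\n", sep = "")
  print(table(stratum = x$stratum))
  invisible(x)
}

#' Factor detector q-statistic
#'
#' Measures the share of the spatial variance of `y` explained by a
#' stratification: `q = 1 - sum_h(N_h * sigma_h^2) / (N * sigma^2)` with
#' population variances, equivalently the between-strata over total sum of
#' squares. q = 0 means the strata explain nothing; q = 1 means `y` is
#' constant within every stratum.
#'
#' @param y Numeric response (one value per site).
#' @param strata A `stratification` or a vector of stratum labels of the
#'   same length.
#' @return A `q_result`: `q`, `N`, `sigma2`, `ssw`, `sst`, `n_singleton`,
#'   and the per-stratum table (`stratum`, `n`, `mean`, `var`).
#' @export
#' @examples
#' q_statistic(c(1, 2, 3, 4), c("A", "A", "B", "B"))$q  # 0.8
q_statistic <- function(y, strata) {
  strata <- as_stratification(strata)
  abort_if(length(y) != length(strata$stratum),
           "`y` and `strata` must have the same length.",
           "aquarisk_bad_input")
  abort_if(anyNA(y), "`y` must not contain NA.", "aquarisk_bad_input")
  N <- length(y)
  sigma2 <- pop_var(y)
  abort_if(sigma2 <= 0,
           "Total variance of `y` is zero; q is undefined.",
           "aquarisk_zero_variance")
  g <- split(y, strata$stratum)
  n_h <- lengths(g)
  var_h <- map_dbl(g, pop_var)
  mean_h <- map_dbl(g, mean)
  ssw <- sum(n_h * var_h)
  sst <- N * sigma2
  structure(
    list(q = 1 - ssw / sst, N = N, sigma2 = sigma2, ssw = ssw, sst = sst,
         n_singleton = sum(n_h == 1),
         strata = tibble(stratum = names(g), n = as.integer(n_h),
                         mean = unname(mean_h), var = unname(var_h))),
    class = "q_result"
  )
}

#' @export
print.q_result <- function(x, ...) {
  cat("<q_result> q = ", format(x$q, digits = 4), " over ",
      nrow(x$strata), " strata (N = ", x$N, ")\n", sep = "")
  if (x$n_singleton > 0)
    cat("note: ", x$n_singleton,
        " singleton stratum/strata (zero within-variance)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.q_result <- function(x, ...) x$strata

#' @exportS3Method generics::glance
glance.q_result <- function(x, ...) {
  tibble(q = x$q, N = x$N, L = nrow(x$strata), sigma2 = x$sigma2,
         ssw = x$ssw, sst = x$sst, n_singleton = x$n_singleton)
}

# Five-category interaction classification.
classify_interaction <- function(q1, q2, q12, tolerance = 1e-9) {
  if (abs(q12 - (q1 + q2)) <= tolerance) "independent"
  else if (q12 > q1 + q2) "nonlinear_enhance"
  else if (q12 > max(q1, q2) + tolerance) "bivariable_enhance"
  else if (q12 >= min(q1, q2) - tolerance) "univariable_weaken"
  else "nonlinear_weaken"
}

#' Two-factor interaction detector
#'
#' Computes q for each factor and for their intersection stratification
#' (distinct label pairs), then classifies the interaction: independent
#' (`q12 = q1 + q2` within tolerance), nonlinear enhancement
#' (`q12 > q1 + q2`), bivariable enhancement (`q12 > max(q1, q2)`),
#' univariable weakening (`min <= q12 <= max`) or nonlinear weakening
#' (`q12 < min(q1, q2)`). Under population variances the intersection is a
#' refinement of both factors, so q12 can never fall below
#' `max(q1, q2)` beyond rounding; the weakening labels remain reachable
#' only through the tolerance.
#'
#' @param y Numeric response.
#' @param strata_a,strata_b Stratifications (or label vectors) on the same
#'   sites.
#' @param tolerance Numeric slack for the category comparisons.
#' @return An `interaction_result`: `q1`, `q2`, `q12`, `category`,
#'   `tolerance`.
#' @export
interact <- function(y, strata_a, strata_b, tolerance = 1e-9) {
  strata_a <- as_stratification(strata_a)
  strata_b <- as_stratification(strata_b)
  abort_if(length(strata_a$stratum) != length(strata_b$stratum),
           "Both stratifications must cover the same sites.",
           "aquarisk_bad_input")
  q1 <- q_statistic(y, strata_a)$q
  q2 <- q_statistic(y, strata_b)$q
  inter <- paste(strata_a$stratum, strata_b$stratum, sep = ":")
  q12 <- q_statistic(y, inter)$q
  structure(
    list(q1 = q1, q2 = q2, q12 = q12,
         category = classify_interaction(q1, q2, q12, tolerance),
         tolerance = tolerance),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result> q1 = ", format(x$q1, digits = 4),
      ", q2 = ", format(x$q2, digits = 4),
      ", q12 = ", format(x$q12, digits = 4),
      " -> ", x$category, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.interaction_result <- function(x, ...) {
  tibble(q1 = x$q1, q2 = x$q2, q12 = x$q12, category = x$category,
         tolerance = x$tolerance)
}

# Build the stratification of one covariate column under the config.
covariate_stratification <- function(x, name, config) {
  categorical <- !is.numeric(x) || name %in% (config$categorical %||% character())
  if (categorical) as_stratification(x)
  else discretize(x, method = config$method, n_classes = config$n_classes)
}

# Per-site season-mean responses joined with covariates.
site_response_table <- function(measurements, covariates, responses) {
  check_columns(measurements, c("site_id", responses), "measurements")
  per_site <- measurements %>%
    group_by(.data$site_id) %>%
    summarise(across(all_of(responses), mean), .groups = "drop")
  check_columns(covariates, "site_id", "covariates")
  joined <- dplyr::inner_join(per_site, covariates, by = "site_id")
  abort_if(nrow(joined) == 0,
           "No sites shared between measurements and covariates.",
           "aquarisk_bad_input")
  joined
}

#' Factor screening: q of every covariate for every response
#'
#' Aggregates measurements to per-site season means, stratifies each
#' covariate (native categories, or discretized per the config), and
#' computes the factor-detector q for every (response, factor) pair.
#'
#' @param measurements Measurement tibble (`site_id`, `season`, parameters).
#' @param covariates Covariate tibble (`site_id` + factors).
#' @param responses Response columns; default from the config.
#' @param config A [geodetector_config()].
#' @return A tibble (`response`, `factor`, `q`, `n_classes`, `singletons`)
#'   sorted by descending q within response.
#' @export
factor_screen <- function(measurements, covariates, responses = NULL,
                          config = geodetector_config()) {
  responses <- responses %||% intersect(config$responses, names(measurements))
  tab <- site_response_table(measurements, covariates, responses)
  factors <- setdiff(names(covariates), "site_id")
  strats <- map(setNames(factors, factors), function(f)
    covariate_stratification(tab[[f]], f, config))
  res <- tidyr::expand_grid(response = responses, factor = factors) %>%
    mutate(fit = purrr::map2(.data$response, .data$factor, function(r, f)
      q_statistic(tab[[r]], strats[[f]]))) %>%
    mutate(q = map_dbl(.data$fit, "q"),
           n_classes = purrr::map_int(.data$fit, function(x)
             nrow(x$strata)),
           singletons = purrr::map_int(.data$fit, function(x)
             as.integer(x$n_singleton))) %>%
    select(-"fit") %>%
    arrange(match(.data$response, responses), desc(.data$q))
  res
}

#' Interaction screening: all factor pairs for every response
#'
#' @inheritParams factor_screen
#' @return A tibble (`response`, `factor_a`, `factor_b`, `q1`, `q2`, `q12`,
#'   `category`), one row per unordered factor pair; results are invariant
#'   to factor order.
#' @export
interaction_screen <- function(measurements, covariates, responses = NULL,
                               config = geodetector_config()) {
  responses <- responses %||% intersect(config$responses, names(measurements))
  tab <- site_response_table(measurements, covariates, responses)
  factors <- setdiff(names(covariates), "site_id")
  abort_if(length(factors) < 2,
           "Interaction screening needs at least 2 factors.",
           "aquarisk_bad_input")
  strats <- map(setNames(factors, factors), function(f)
    covariate_stratification(tab[[f]], f, config))
  pairs <- utils::combn(factors, 2)
  grid <- tidyr::expand_grid(
    response = responses,
    pair = seq_len(ncol(pairs))
  )
  rows <- pmap(grid, function(response, pair) {
    fa <- pairs[1, pair]; fb <- pairs[2, pair]
    it <- interact(tab[[response]], strats[[fa]], strats[[fb]],
                   tolerance = config$tolerance)
    tibble(response = response, factor_a = fa, factor_b = fb,
           q1 = it$q1, q2 = it$q2, q12 = it$q12, category = it$category)
  })
  list_rbind(rows)
}
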