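# Independent oracles and small fixture builders used across the suite.

# Brute-force ANOVA-decomposition oracle for the factor detector:
# q = SSB / SST computed from group means, a different route than the
# 1 - SSW/(N sigma^2) formula in the implementation.
q_oracle <- function(y, labels) {
  grand <- mean(y)
  sst <- sum((y - grand)^2)
  ssb <- sum(tapply(y, labels, function(g) length(g) * (mean(g) - grand)^2))
  ssb / sst
}

# Random small q-instance: n values, 2..6 strata, every stratum nonempty.
random_q_instance <- function(n_max = 30) {
  n <- sample(4:n_max, 1)
  L <- sample(2:min(6, n), 1)
  labels <- c(seq_len(L), sample(seq_len(L), n - L, replace = TRUE))
  y <- rnorm(n)
  if (stats::sd(y) == 0) y <- y + seq_len(n)  # ensure SST > 0
  list(y = y, labels = sample(labels))
}

# Hand-sized measurement table covering all pipeline parameters.
tiny_measurements <- function(n_sites = 4) {
  ds <- generate_dataset(n_sites = n_sites, seed = 42)
  ds$measurements
}

# Two-parameter WQI config for hand-arithmetic checks: identity score
# tables (score == concentration on 0-100).
two_param_wqi_config <- function(weights = c(a = 4, b = 1), k = 1) {
  identity_table <- list(orientation = "harm",
                         conc = c(0, 100), score = c(0, 100))
  structure(list(
    k = k,
    weights = as.list(weights),
    normalization = list(a = identity_table, b = identity_table),
    classes = list(list(label = "excellent", min = 90),
                   list(label = "good", min = 70),
                   list(label = "medium", min = 50),
                   list(label = "poor", min = 0))
  ), class = c("wqi_config", "list"))
}

# Minimal synthetic measurement model with a single planted normal effect
# on TN; expected q is analytic (see expected_q()).
planted_effects <- function(means, noise_sd, factor = "Precipitation") {
  list(
    baseline = list(TN = list(mean = 1, sd = noise_sd, family = "normal")),
    effects = list(list(parameter = "TN", factor = factor,
                        means = as.list(means), noise_sd = noise_sd,
                        family = "normal")),
    season_multipliers = list(wet = 1, dry = 1, normal = 1)
  )
}
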