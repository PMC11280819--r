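test_that("generate_sites yields unique sites inside the extent, reproducibly", {
  extent <- c(lon_min = 113.3, lon_max = 115.9, lat_min = 31.4,
              lat_max = 32.7)
  sites <- generate_sites(59, extent, seed = 1)
  expect_equal(nrow(sites), 59)
  expect_equal(anyDuplicated(sites$site_id), 0)
  expect_true(all(sites$lon >= extent["lon_min"] &
                    sites$lon <= extent["lon_max"]))
  expect_true(all(sites$lat >= extent["lat_min"] &
                    sites$lat <= extent["lat_max"]))
  expect_identical(sites, generate_sites(59, extent, seed = 1))
  expect_false(identical(sites, generate_sites(59, extent, seed = 2)))

  two <- generate_sites(2, extent, seed = 3)
  expect_equal(nrow(two), 2)
  expect_false(two$site_id[1] == two$site_id[2])

  expect_error(generate_sites(1), class = "aquarisk_bad_input")
  expect_error(generate_sites(0), class = "aquarisk_bad_input")
})

test_that("covariates have the configured spatial structure", {
  sites <- generate_sites(120, seed = 5)
  cov <- generate_covariates(sites, seed = 5)
  expect_equal(nrow(cov), 120)
  # Configured gradient signs: DEM decreases northwards, GDP increases.
  expect_lt(cor(cov$DEM, sites$lat, method = "spearman"), 0)
  expect_gt(cor(cov$GDP, sites$lat, method = "spearman"), 0)
  expect_setequal(unique(cov$Soil_Type),
                  default_covariate_specs()$Soil_Type$levels)
  expect_identical(cov, generate_covariates(sites, seed = 5))

  specs <- default_covariate_specs()
  specs$DEM$type <- "mystery"
  expect_error(generate_covariates(sites, specs),
               class = "aquarisk_bad_input")
  expect_error(generate_covariates(sites, list(x = list())),
               class = "aquarisk_bad_input")
})

test_that("measurements: 3 seasons per site, strictly positive, deterministic", {
  sites <- generate_sites(59, seed = 2)
  cov <- generate_covariates(sites, seed = 2)
  meas <- generate_measurements(sites, cov, seed = 2)
  expect_equal(nrow(meas), 177)
  expect_equal(unname(table(meas$season))[1:3], rep(59L, 3),
               ignore_attr = TRUE)
  expect_true(all(table(meas$site_id) == 3))
  num <- meas[sapply(meas, is.numeric)]
  expect_true(all(as.matrix(num) > 0))
  expect_identical(meas, generate_measurements(sites, cov, seed = 2))
})

test_that("an effect referencing a missing covariate errors", {
  sites <- generate_sites(10, seed = 1)
  cov <- generate_covariates(sites, seed = 1)
  eff <- planted_effects(c(Q1 = 1, Q2 = 2), 0.1, factor = "NotAFactor")
  expect_error(generate_measurements(sites, cov, eff, seed = 1),
               class = "aquarisk_missing_factor")
})

test_that("within-stratum variance collapses as noise_sd -> 0", {
  sites <- generate_sites(40, seed = 3)
  cov <- generate_covariates(sites, seed = 3)
  eff <- planted_effects(c(Q1 = 10, Q2 = 20), noise_sd = 1e-9)
  meas <- generate_measurements(sites, cov, eff, seed = 3)
  expect_setequal(round(meas$TN), c(10, 20))
  v <- tapply(meas$TN, round(meas$TN), stats::var)
  expect_true(all(v < 1e-12))
})

test_that("expected_q matches population-moment enumeration and simulation", {
  # All stratum means equal -> nothing between strata.
  expect_equal(expected_q(list(means = c(a = 5, b = 5), noise_sd = 1,
                               family = "normal"), c(10, 10)), 0)
  # Vanishing noise with unequal means -> everything between strata.
  expect_equal(expected_q(list(means = c(a = 1, b = 2), noise_sd = 1e-12,
                               family = "normal"), c(10, 10)), 1,
               tolerance = 1e-12)
  # means (0, 10), equal sizes, sd 5: brute-force population moments give
  # between = 25, within = 25, q* = 1/2.
  eff <- list(means = c(a = 0, b = 10), noise_sd = 5, family = "normal")
  expect_equal(expected_q(eff, c(1, 1)), 0.5)
  # Cross-check against a large simulated instance.
  set.seed(99)
  y <- c(rnorm(20000, 0, 5), rnorm(20000, 10, 5))
  lab <- rep(c("a", "b"), each = 20000)
  expect_equal(q_statistic(y, lab)$q, 0.5, tolerance = 0.02)
  # Lognormal moments: weighted enumeration oracle.
  effl <- list(means = c(a = 1, b = 3), noise_sd = 0.4,
               family = "lognormal")
  mu <- c(1, 3) * exp(0.08)
  v <- c(1, 9) * exp(0.16) * (exp(0.16) - 1)
  w <- c(0.25, 0.75)
  between <- sum(w * (mu - sum(w * mu))^2)
  expect_equal(expected_q(effl, c(1, 3)),
               between / (between + sum(w * v)), tolerance = 1e-14)

  expect_error(expected_q(list(means = c(a = 1), noise_sd = 1)),
               class = "aquarisk_bad_input")
  expect_error(expected_q(list(means = c(a = 1, b = 1), noise_sd = 0,
                               family = "normal"), c(1, 1)),
               class = "aquarisk_zero_variance")
})

test_that("one global seed determines the whole dataset", {
  d1 <- generate_dataset(n_sites = 20, seed = 11)
  d2 <- generate_dataset(n_sites = 20, seed = 11)
  expect_identical(d1, d2)
  d3 <- generate_dataset(n_sites = 20, seed = 12)
  expect_false(identical(d1$measurements, d3$measurements))
})
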