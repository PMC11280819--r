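test_that("quantile discretization splits 1..10 at the median", {
  s <- discretize(1:10, "quantile", 2)
  expect_equal(s$stratum, rep(1:2, each = 5))
})

test_that("natural breaks finds the obvious gap and matches enumeration", {
  s <- discretize(c(1, 2, 3, 100, 101, 102), "natural_breaks", 2)
  expect_equal(s$stratum, c(1, 1, 1, 2, 2, 2))

  # Exact DP equals brute-force enumeration of all 3-class partitions.
  ssd <- function(v) sum((v - mean(v))^2)
  set.seed(4)
  for (rep in 1:10) {
    x <- sort(round(stats::rnorm(12, 50, 20), 1))
    best <- Inf
    for (i in 1:10) for (j in (i + 1):11) {
      cost <- ssd(x[1:i]) + ssd(x[(i + 1):j]) + ssd(x[(j + 1):12])
      best <- min(best, cost)
    }
    s3 <- discretize(x, "natural_breaks", 3)
    got <- sum(tapply(x, s3$stratum, ssd))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("discretization rejects degenerate input", {
  expect_error(discretize(rep(1, 10), "quantile", 2),
               class = "aquarisk_too_few_values")
  expect_error(discretize(1:10, "quantile", 1), class = "aquarisk_bad_input")
  expect_error(discretize(c(-1, 1, 2, 3), "geometric", 2),
               class = "aquarisk_bad_input")
})

test_that("q_statistic matches hand values and its definition", {
  expect_equal(q_statistic(c(1, 5, 2, 8), rep("all", 4))$q, 0)
  expect_equal(q_statistic(c(1, 1, 2, 2), c("A", "A", "B", "B"))$q, 1)
  # Hand sum of squares: SSW = 0.5 + 0.5, SST = 5 -> q = 0.8.
  fit <- q_statistic(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(fit$q, 0.8)
  expect_equal(fit$ssw, 1)
  expect_equal(fit$sst, 5)
  expect_equal(glance(fit)$L, 2)
  expect_error(q_statistic(rep(3, 5), c(1, 1, 2, 2, 2)),
               class = "aquarisk_zero_variance")
  expect_error(q_statistic(c(1, 2), c("A", "B", "B")),
               class = "aquarisk_bad_input")
})

test_that("q equals the brute-force ANOVA decomposition on random instances", {
  set.seed(7)
  for (i in 1:200) {
    inst <- random_q_instance()
    expect_lt(abs(q_statistic(inst$y, inst$labels)$q -
                    q_oracle(inst$y, inst$labels)), 1e-12)
  }
})

test_that("q stays in [0, 1] and singleton strata are counted", {
  set.seed(8)
  for (i in 1:50) {
    inst <- random_q_instance()
    expect_true(dplyr::between(q_statistic(inst$y, inst$labels)$q, 0, 1))
  }
  fit <- q_statistic(c(1, 2, 3), c("A", "A", "B"))
  expect_equal(fit$n_singleton, 1)
})

test_that("interaction detector reproduces the hand example and refinement", {
  y <- c(1, 2, 3, 4)
  # A refines nothing new over itself: q12 = q1.
  self <- interact(y, c("A", "A", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(self$q12, self$q1)
  expect_equal(self$category, "univariable_weaken")
  # Crossed design: q1 = 0.8, q2 = 0.2, q12 = 1 = q1 + q2 -> independent.
  it <- interact(y, c("A", "A", "B", "B"), c("A", "B", "A", "B"))
  expect_equal(c(it$q1, it$q2, it$q12), c(0.8, 0.2, 1))
  expect_equal(it$category, "independent")
  # Refinement monotonicity on random pairs.
  set.seed(9)
  for (i in 1:100) {
    inst <- random_q_instance()
    labels_b <- sample(letters[1:3], length(inst$y), replace = TRUE)
    labels_b[1:2] <- c("a", "b")  # at least 2 strata
    it <- interact(inst$y, inst$labels, labels_b)
    expect_gte(it$q12, max(it$q1, it$q2) - 1e-12)
  }
})

test_that("all five interaction categories are assignable", {
  cls <- aquarisk:::classify_interaction
  expect_equal(cls(0.2, 0.3, 0.5), "independent")
  expect_equal(cls(0.2, 0.3, 0.7), "nonlinear_enhance")
  expect_equal(cls(0.2, 0.3, 0.4), "bivariable_enhance")
  expect_equal(cls(0.2, 0.3, 0.25), "univariable_weaken")
  expect_equal(cls(0.2, 0.3, 0.1), "nonlinear_weaken")
})

test_that("factor screening recovers a planted dominant factor", {
  sites <- generate_sites(200, seed = 21)
  cov <- generate_covariates(sites, seed = 21)
  eff <- planted_effects(c(Q1 = 10, Q2 = 14), noise_sd = 1)  # q* = 0.8
  meas <- generate_measurements(sites, cov, eff, seed = 21)
  qf <- factor_screen(meas, cov, responses = "TN")
  expect_equal(qf$factor[1], "Precipitation")
  expect_gt(qf$q[1], 2 * max(qf$q[-1]))
  # Permuting covariate columns leaves q values unchanged.
  cov_perm <- cov[, c("site_id", sample(setdiff(names(cov), "site_id")))]
  qf2 <- factor_screen(meas, cov_perm, responses = "TN")
  expect_equal(dplyr::arrange(qf, factor), dplyr::arrange(qf2, factor))
})

test_that("pure-noise responses score near zero", {
  hits <- 0
  for (s in 1:10) {
    sites <- generate_sites(200, seed = 100 + s)
    cov <- generate_covariates(sites, seed = 100 + s)
    noise <- list(
      baseline = list(TN = list(mean = 1, sd = 0.3, family = "lognormal")),
      effects = list(),
      season_multipliers = list(wet = 1, dry = 1, normal = 1))
    meas <- generate_measurements(sites, cov, noise, seed = 100 + s)
    qf <- factor_screen(meas, cov, responses = "TN")
    if (max(qf$q) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("interaction screening is symmetric and skips the diagonal", {
  ds <- generate_dataset(n_sites = 40, seed = 31)
  qi <- interaction_screen(ds$measurements, ds$covariates,
                           responses = c("TN", "As"))
  expect_equal(nrow(qi), 2 * choose(9, 2))
  expect_false(any(qi$factor_a == qi$factor_b))
  # Reversing covariate column order leaves the set of results unchanged.
  cov_rev <- ds$covariates[, c("site_id",
                               rev(setdiff(names(ds$covariates),
                                           "site_id")))]
  qi2 <- interaction_screen(ds$measurements, cov_rev,
                            responses = c("TN", "As"))
  key <- function(d) {
    d$pair <- paste(pmin(d$factor_a, d$factor_b),
                    pmax(d$factor_a, d$factor_b))
    dplyr::arrange(d[c("response", "pair", "q12", "category")],
                   response, pair)
  }
  expect_equal(key(qi), key(qi2), tolerance = 1e-12)
})

test_that("two planted effects on different factors never weaken", {
  sites <- generate_sites(150, seed = 41)
  cov <- generate_covariates(sites, seed = 41)
  eff <- list(
    baseline = list(TN = list(mean = 10, sd = 0.5, family = "normal")),
    effects = list(list(parameter = "TN", factor = "GDP",
                        means = list(Q1 = 8, Q2 = 12), noise_sd = 2,
                        family = "normal")),
    season_multipliers = list(wet = 1, dry = 1, normal = 1))
  meas <- generate_measurements(sites, cov, eff, seed = 41)
  tab <- dplyr::summarise(dplyr::group_by(meas, site_id),
                          TN = mean(TN), .groups = "drop")
  tab <- dplyr::inner_join(tab, cov, by = "site_id")
  sa <- discretize(tab$GDP, "quantile", 2)
  sb <- discretize(tab$Precipitation, "quantile", 3)
  it <- interact(tab$TN, sa, sb)
  expect_true(it$category %in% c("nonlinear_enhance", "bivariable_enhance",
                                 "independent"))
})
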