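test_that("dose and risk equations match hand arithmetic", {
  expect_equal(add_dose(1, 1, 1, 1, 1, 1), 1)
  expect_equal(add_dose(0, 2, 365, 30, 70, 10950), 0)
  # 0.01 * 2 * 365 * 30 / (70 * 10950) = 219 / 766500.
  expect_equal(add_dose(0.01, 2, 365, 30, 70, 10950), 219 / 766500)
  expect_error(add_dose(1, 1, 1, 1, 0, 1), class = "aquarisk_bad_input")
  expect_error(add_dose(1, 1, 1, 1, 1, -1), class = "aquarisk_bad_input")

  expect_equal(carcinogenic_risk(2e-4, 1.5), 3e-4)
  expect_equal(carcinogenic_risk(0, 1.5), 0)
  expect_equal(noncarcinogenic_hq(3e-4, 3e-4), 1)
  expect_error(noncarcinogenic_hq(1, 0), class = "aquarisk_bad_input")
  expect_error(carcinogenic_risk(1, -1), class = "aquarisk_bad_input")
})

test_that("risk bands follow the regulatory thresholds", {
  expect_equal(classify_cr(c(5e-7, 1e-5, 2e-4)),
               c("low", "potential", "high"))
  expect_equal(classify_cr(1e-6), "potential")   # inclusive band
  expect_equal(classify_cr(1e-4), "potential")
  expect_equal(classify_hq(c(0.5, 1, 1.01)),
               c("acceptable", "acceptable", "high"))
  expect_error(classify_cr(-1), class = "aquarisk_bad_input")
  expect_error(classify_hq(-1), class = "aquarisk_bad_input")
})

test_that("concentration fitting is the closed-form lognormal MLE", {
  expect_equal(fit_concentration(rep(2.5, 5))$family, "point")
  expect_equal(fit_concentration(rep(2.5, 5))$value, 2.5)
  set.seed(11)
  x <- stats::rlnorm(2000, log(0.002), 0.6)
  sp <- fit_concentration(x)
  expect_equal(sp$family, "lognormal")
  # MLE within 3 standard errors of the truth.
  expect_lt(abs(sp$meanlog - log(0.002)), 3 * 0.6 / sqrt(2000))
  expect_lt(abs(sp$sdlog - 0.6), 3 * 0.6 / sqrt(2 * 2000))
  expect_true(all(dist_sample(sp, 1000) > 0))
  expect_error(fit_concentration(c(1, 2)), class = "aquarisk_bad_input")
  expect_error(fit_concentration(c(1, 2, -3)), class = "aquarisk_bad_input")

  # Cross-check against an independent ML fitter.
  fd <- suppressWarnings(fitdistrplus::fitdist(x, "lnorm"))
  expect_equal(sp$meanlog, unname(fd$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(sp$sdlog, unname(fd$estimate["sdlog"]), tolerance = 1e-3)
})

point_exposure <- function() {
  exposure_model(overrides = list(populations = list(
    adult = list(IR = list(family = "point", value = 2),
                 EF = list(family = "point", value = 365),
                 ED = list(family = "point", value = 30),
                 BW = list(family = "point", value = 65)),
    child = list(IR = list(family = "point", value = 1),
                 EF = list(family = "point", value = 365),
                 ED = list(family = "point", value = 6),
                 BW = list(family = "point", value = 20)))))
}

test_that("degenerate Monte Carlo reproduces the deterministic equations", {
  tox <- toxicity_ref()
  conc <- list(As = dist_spec("point", value = 0.002),
               Hg = dist_spec("point", value = 0.00002))
  mc <- monte_carlo_risk(conc, point_exposure(), tox, n_iter = 200,
                         seed = 5)
  adult <- mc$summary[mc$summary$population == "adult" &
                        mc$summary$metal == "As", ]
  add_carc <- add_dose(0.002, 2, 365, 30, 65, 70 * 365)
  add_nonc <- add_dose(0.002, 2, 365, 30, 65, 30 * 365)
  expect_equal(adult$cr_mean, carcinogenic_risk(add_carc, tox$metals$As$SF),
               tolerance = 1e-12)
  expect_equal(adult$hq_mean, noncarcinogenic_hq(add_nonc,
                                                 tox$metals$As$RfD),
               tolerance = 1e-12)
  expect_equal(adult$cr_se, 0)
  expect_equal(adult$hq_se, 0)
  # Hg carries no slope factor: CR undefined, HQ present.
  hg <- mc$summary[mc$summary$metal == "Hg", ]
  expect_true(all(is.na(hg$cr_mean)))
  expect_true(all(hg$hq_mean > 0))
})

test_that("exceedance fractions are monotone and reproducible", {
  conc <- list(As = dist_spec("lognormal", meanlog = log(4e-5), sdlog = 1))
  mc1 <- monte_carlo_risk(conc, point_exposure(), n_iter = 2000, seed = 5)
  mc2 <- monte_carlo_risk(conc, point_exposure(), n_iter = 2000, seed = 5)
  expect_identical(mc1$summary, mc2$summary)
  expect_true(all(mc1$summary$p_cr_1e4 <= mc1$summary$p_cr_1e6))
  # Survival function is non-increasing along the cumulative grid.
  cf <- mc1$cumfreq[mc1$cumfreq$metric == "cr" &
                      mc1$cumfreq$population == "adult", ]
  expect_true(all(diff(cf$value) >= 0))
})

test_that("CR scales linearly in C and SF; HQ inversely in RfD", {
  exposure <- point_exposure()
  conc1 <- list(As = dist_spec("point", value = 0.001))
  conc2 <- list(As = dist_spec("point", value = 0.003))
  tox1 <- toxicity_ref()
  tox2 <- toxicity_ref(overrides = list(metals = list(
    As = list(SF = 3.0, RfD = 0.0006, carcinogenic = TRUE))))
  m11 <- monte_carlo_risk(conc1, exposure, tox1, n_iter = 50, seed = 1)
  m21 <- monte_carlo_risk(conc2, exposure, tox1, n_iter = 50, seed = 1)
  m12 <- monte_carlo_risk(conc1, exposure, tox2, n_iter = 50, seed = 1)
  expect_equal(m21$summary$cr_mean, 3 * m11$summary$cr_mean,
               tolerance = 1e-12)
  expect_equal(m12$summary$cr_mean, 2 * m11$summary$cr_mean,
               tolerance = 1e-12)
  expect_equal(m12$summary$hq_mean, 0.5 * m11$summary$hq_mean,
               tolerance = 1e-12)
})

test_that("population differences come only from the exposure specs", {
  conc <- list(Pb = dist_spec("lognormal", meanlog = log(0.004),
                              sdlog = 0.8))
  ex <- point_exposure()
  swapped <- ex
  swapped$populations <- list(adult = ex$populations$child,
                              child = ex$populations$adult)
  m1 <- monte_carlo_risk(conc, ex, n_iter = 500, seed = 9)
  m2 <- monte_carlo_risk(conc, swapped, n_iter = 500, seed = 9)
  a1 <- m1$summary[m1$summary$population == "adult", -1]
  c2 <- m2$summary[m2$summary$population == "child", -1]
  expect_equal(as.data.frame(a1), as.data.frame(c2), tolerance = 1e-12)
})

test_that("Monte Carlo error halves in variance when n_iter doubles", {
  conc <- list(As = dist_spec("lognormal", meanlog = log(4e-5), sdlog = 1))
  ex <- point_exposure()
  est <- function(n_iter, seed)
    monte_carlo_risk(conc, ex, n_iter = n_iter,
                     seed = seed)$summary$p_cr_1e6[1]
  p_small <- sapply(1:50, function(s) est(250, s))
  p_large <- sapply(1:50, function(s) est(500, s))
  ratio <- stats::var(p_small) / stats::var(p_large)
  expect_gt(ratio, 1.1)  # variance shrinks with n_iter at the MC rate
  expect_lt(ratio, 4)
})

test_that("risk ranking sorts by mean with alphabetical ties", {
  s <- tibble::tibble(
    population = "adult", metal = c("A", "B", "C"),
    cr_mean = c(3, 1, 2), hq_mean = c(1, 1, 2))
  r <- risk_ranking(s)
  expect_equal(r$metal[r$metric == "CR"], c("A", "C", "B"))
  # HQ tie between A and B resolves alphabetically after the leader C.
  expect_equal(r$metal[r$metric == "HQ"], c("C", "A", "B"))
  # Input order does not matter.
  r2 <- risk_ranking(s[c(3, 1, 2), ])
  expect_equal(r, r2)
  one <- risk_ranking(tibble::tibble(population = "adult", metal = "As",
                                     cr_mean = 1, hq_mean = 1))
  expect_equal(nrow(one), 2)
})
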