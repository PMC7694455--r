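test_that("growth curves satisfy their defining anchors and limits", {
  # Weibull passes through d/e at t = e and approaches its asymptotes
  expect_equal(weibull_curve(1000, c = 8, d = 20, e = 1000), 20 * exp(-1))
  expect_equal(weibull_curve(1e9, 8, 20, 1000), 20, tolerance = 1e-6)
  expect_lt(weibull_curve(1e-6, 8, 20, 1000), 1e-12)
  # magnitude convention: either sign of c gives the increasing curve
  expect_equal(weibull_curve(800, -8, 20, 1000), weibull_curve(800, 8, 20, 1000))

  # log-logistic passes through d/2 at TIME50 and is near d late in the season
  expect_equal(loglogistic_curve(1548, c = -10.1, d = 29.3, t50 = 1548), 29.3 / 2)
  expect_gt(loglogistic_curve(3000, -10.1, 29.3, 1548), 0.95 * 29.3)
  # degenerate slope: constant d/2
  expect_equal(loglogistic_curve(c(10, 1e4), 0, 20, 1000), c(10, 10))

  expect_error(weibull_curve(-1, 8, 20, 1000), class = "phenokit_domain")
  expect_error(loglogistic_curve(0, -10, 20, 1000), class = "phenokit_domain")

  # symbolic-evaluation oracle on a grid
  tg <- seq(200, 3000, by = 200)
  expect_equal(weibull_curve(tg, 8.7, 16.4, 1300),
               16.4 * exp(-exp(-8.7 * (log(tg) - log(1300)))), tolerance = 1e-12)
  expect_equal(loglogistic_curve(tg, -9.8, 22, 1319),
               22 / (1 + exp(-9.8 * (log(tg) - log(1319)))), tolerance = 1e-12)
})

test_that("both families stay within [0, d] and increase after sign normalization", {
  tg <- exp(seq(log(50), log(5000), length.out = 400))
  for (vals in list(weibull_curve(tg, 11.4, 14.8, 1250),
                    loglogistic_curve(tg, -10.1, 29.3, 1548))) {
    expect_true(all(vals >= 0 & vals <= 29.3 + 1e-9))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("time50 inverts the curve for both families", {
  # log-logistic: identity
  fll <- growth_fit("loglogistic", c = -10.1, d = 29.3, timing = 1548)
  expect_identical(time50(fll), 1548)
  expect_equal(loglogistic_curve(time50(fll), fll$c, fll$d, fll$timing),
               fll$d / 2, tolerance = 1e-9)

  # Weibull: closed form e (log 2)^(-1/|c|), cross-checked by bisection
  fw <- growth_fit("weibull", c = 11.4, d = 14.8, timing = 1317 * log(2)^(1 / 11.4))
  t50 <- time50(fw)
  expect_equal(t50, 1317, tolerance = 1e-6)
  expect_equal(weibull_curve(t50, fw$c, fw$d, fw$timing), fw$d / 2,
               tolerance = 1e-9)
  root <- uniroot(function(t) weibull_curve(t, fw$c, fw$d, fw$timing) - fw$d / 2,
                  c(1, 1e5), tol = 1e-9)$root
  expect_equal(t50, root, tolerance = 1e-6)

  # step-function limit: TIME50 -> e as |c| -> infinity
  fsteep <- growth_fit("weibull", c = 1e6, d = 10, timing = 1200)
  expect_equal(time50(fsteep), 1200, tolerance = 1e-3)
})

test_that("least-squares fit recovers noise-free curves exactly", {
  times <- c(600, 900, 1200, 1500, 1800, 2100)
  for (family in c("weibull", "loglogistic")) {
    c_true <- if (family == "weibull") 8 else -10
    dat <- simulate_biomass(family, c_true, d = 20, timing = 1400,
                            times = times, n_plots = 3, sd = 0)
    fit <- fit_growth(dat, family)
    expect_equal(abs(fit$c), abs(c_true), tolerance = 1e-4)
    expect_equal(fit$d, 20, tolerance = 1e-5)
    expect_equal(fit$timing, 1400, tolerance = 1e-3)
  }
})

test_that("fit recovers d within 5% median relative error under 10% noise", {
  set.seed(303)
  times <- c(600, 900, 1200, 1500, 1800, 2100)
  errs <- replicate(200, {
    dat <- simulate_biomass("loglogistic", -10, 20, 1400, times, 3, sd = 2)
    abs(fit_growth(dat, "loglogistic")$d - 20) / 20
  })
  expect_lt(median(errs), 0.05)
})

test_that("insufficient data are rejected with classed errors", {
  flat <- data.frame(cum_tt_c = c(600, 900, 1200, 1500, 1800, 2100),
                     dm_per_plant_g = 0)
  expect_error(fit_growth(flat, "weibull"), class = "phenokit_insufficient_data")
  few <- data.frame(cum_tt_c = c(600, 900, 1200), dm_per_plant_g = c(1, 5, 9))
  expect_error(fit_growth(few, "weibull"), class = "phenokit_insufficient_data")
})

test_that("lack-of-fit test is calibrated under the model and detects a step", {
  times <- c(600, 900, 1200, 1500, 1800, 2100)
  set.seed(404)
  # null: data generated from the fitted family -> ~5% rejection
  pnull <- replicate(200, {
    dat <- simulate_biomass("loglogistic", -10, 20, 1400, times, 3, sd = 1)
    fit <- fit_growth(dat, "loglogistic")
    lack_of_fit(fit, dat)$p_value
  })
  expect_gte(mean(pnull < 0.05), 0.005)
  expect_lte(mean(pnull < 0.05), 0.12)

  # power: step-function mean (5 -> 20 g, a level no zero-asymptote sigmoid
  # can track) with sd = 0.05 d is rejected most of the time
  step_mu <- ifelse(times < 1400, 5, 20)
  prej <- replicate(100, {
    dat <- do.call(rbind, lapply(1:3, function(p) data.frame(
      cum_tt_c = times,
      dm_per_plant_g = pmax(0, step_mu + rnorm(length(times), 0, 1)))))
    fit <- fit_growth(dat, "loglogistic")
    lack_of_fit(fit, dat)$p_value < 0.05
  })
  expect_gt(mean(prej), 0.8)

  # no replication -> unavailable
  single <- data.frame(cum_tt_c = times, dm_per_plant_g = c(1, 3, 8, 14, 18, 20))
  fit <- fit_growth(single, "loglogistic")
  expect_error(lack_of_fit(fit, single), class = "phenokit_test_unavailable")
})

test_that("suppression ratio reproduces its arithmetic and trivial anchors", {
  minus <- growth_fit("weibull", 6.0, d = 14.9, timing = 1251, se = c(d = 1.2))
  plus <- growth_fit("weibull", 4.5, d = 6.2, timing = 1235, se = c(d = 2.2))
  r <- suppression_ratio(minus, plus)
  expect_equal(round(r$ratio, 2), 0.42)

  minus2 <- growth_fit("loglogistic", -10.1, d = 29.3, timing = 1548, se = c(d = 2.6))
  plus2 <- growth_fit("loglogistic", -9.5, d = 5.4, timing = 1384, se = c(d = 1.2))
  expect_equal(round(suppression_ratio(minus2, plus2)$ratio, 2), 0.18)

  same <- suppression_ratio(minus, minus)
  expect_equal(same$ratio, 1)
  expect_gt(same$p_value, 0.99)
})

test_that("delta-method ratio SE agrees with a parametric bootstrap", {
  minus <- growth_fit("weibull", 6.0, d = 14.9, timing = 1251, se = c(d = 1.2))
  plus <- growth_fit("weibull", 4.5, d = 6.2, timing = 1235, se = c(d = 2.2))
  r <- suppression_ratio(minus, plus)
  set.seed(505)
  draws <- rnorm(10000, 6.2, 2.2) / rnorm(10000, 14.9, 1.2)
  expect_equal(r$se, sd(draws), tolerance = 0.15)
})
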