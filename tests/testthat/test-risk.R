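# Incidence interpolation, non-hip derivation, stratum calibration, per-person
# risk adjustment.

test_that("exponential interpolation is exact through two anchors and flat anchors", {
  cv <- fit_exponential_curve(data.frame(age = c(50, 60),
                                         probability = c(0.001, 0.002)))
  expect_equal(predict_incidence(cv, 70), 0.004, tolerance = 1e-12)

  flat <- fit_exponential_curve(data.frame(age = c(50, 60, 70),
                                           probability = rep(0.01, 3)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(predict_incidence(flat, 90), 0.01, tolerance = 1e-12)

  expect_error(fit_exponential_curve(data.frame(age = 50, probability = 0.1)),
               "at least 2")
  expect_error(fit_exponential_curve(data.frame(age = c(50, 60),
                                                probability = c(0, 0.1))),
               "positive")
})

test_that("log-scale least squares matches a profiled grid-search oracle on noisy anchors", {
  set.seed(301)
  ages <- c(50, 58, 67, 75, 88)
  p <- exp(-8 + 0.07 * ages) * exp(rnorm(5, 0, 0.15))
  fit <- fit_exponential_curve(data.frame(age = ages, probability = p))
  # oracle: grid search over the slope, intercept profiled out in closed
  # form, refined around the best slope until the step is ~1e-10
  y <- log(p)
  sse <- function(b) {
    a <- mean(y - b * ages)
    sum((y - a - b * ages)^2)
  }
  lo <- -0.5; hi <- 0.5
  for (stage in 1:7) {
    grid <- seq(lo, hi, length.out = 201)
    best <- grid[which.min(vapply(grid, sse, numeric(1)))]
    step <- grid[2] - grid[1]
    lo <- best - step; hi <- best + step
  }
  b_star <- best
  a_star <- mean(y - b_star * ages)
  expect_equal(fit$slope, b_star, tolerance = 1e-6)
  expect_equal(fit$intercept, a_star, tolerance = 1e-6)
})

test_that("non-hip curves equal hip times banded ratios at every age", {
  hip <- fit_exponential_curve(data.frame(age = c(50, 60),
                                          probability = c(0.001, 0.002)))
  ages <- 50:105

  unit <- hip_ratio_table(50, vertebral = 1, wrist = 1, other = 1)
  curves <- expand_to_nonhip(hip, unit, domain = ages)
  expect_equal(predict_incidence(curves$vertebral, ages),
               predict_incidence(hip, ages), tolerance = 1e-12)

  dbl <- hip_ratio_table(50, vertebral = 2, wrist = 1, other = 1)
  curves <- expand_to_nonhip(hip, dbl, domain = ages)
  expect_equal(predict_incidence(curves$vertebral, ages),
               pmin(1, 2 * predict_incidence(hip, ages)), tolerance = 1e-12)

  pw <- hip_ratio_table(c(50, 65), vertebral = c(3, 1.5), wrist = c(3, 1.5),
                        other = c(3, 1.5))
  curves <- expand_to_nonhip(hip, pw, domain = ages)
  # oracle: direct per-age multiplication
  oracle <- predict_incidence(hip, ages) * ifelse(ages < 65, 3, 1.5)
  expect_equal(predict_incidence(curves$wrist, ages), pmin(1, oracle),
               tolerance = 1e-10)
})

test_that("stratum calibration reproduces the population mixture", {
  # pass-through when the whole cohort is general population
  w1 <- c(general = 1, osteoporosis = 0, prevalent_fracture = 0)
  expect_equal(calibrate_stratum_incidence(0.015, w1, 2, 2.5)$general, 0.015)

  # closed form with a 50/50 general/osteoporosis split
  w2 <- c(general = 0.5, osteoporosis = 0.5, prevalent_fracture = 0)
  cal <- calibrate_stratum_incidence(0.015, w2, rr_op = 2, rr_pf = 2.5)
  expect_equal(cal$general, 0.01, tolerance = 1e-12)
  expect_equal(cal$osteoporosis, 0.02, tolerance = 1e-12)

  # published age-70 stratum weights in women: recomposing the mixture with
  # the effective RRs recovers the population probability
  w <- c(general = 0.670, osteoporosis = 0.286, prevalent_fracture = 0.044)
  cal <- calibrate_stratum_incidence(0.02, w, rr_op = 2.0, rr_pf = 2.5)
  recomposed <- w[["general"]] * cal$general +
    w[["osteoporosis"]] * cal$osteoporosis +
    w[["prevalent_fracture"]] * cal$prevalent_fracture
  expect_lt(abs(recomposed - 0.02), 1e-12)

  expect_error(calibrate_stratum_incidence(0.02, c(general = 0, osteoporosis = 0,
                                                   prevalent_fracture = 0), 2, 2),
               "denominator")
})

test_that("effective prevalent-fracture RR folds the starting history into the stratum RR", {
  m <- risk_modifiers()
  eff <- effective_stratum_rr(m)
  expect_equal(unname(eff["prevalent_fracture", "hip"]), 2.0 * (0.5 * 2.3 + 0.5))
  expect_equal(unname(eff["prevalent_fracture", "vertebral"]), 2.0 * (0.5 * 4.4 + 0.5))
  expect_equal(unname(eff["prevalent_fracture", "wrist"]), 2.0)
  expect_equal(unname(eff["osteoporosis", ]), rep(2, 4), ignore_attr = TRUE)
  expect_equal(unname(eff["general", ]), rep(1, 4), ignore_attr = TRUE)
})

test_that("history and efficacy adjust probabilities as published, with capping", {
  m <- risk_modifiers()
  expect_equal(adjusted_fracture_probability(0.01, "hip", c("hip"), "control", m),
               0.023)
  expect_equal(adjusted_fracture_probability(0.01, "hip", character(),
                                             "intervention", m), 0.0082)
  expect_equal(adjusted_fracture_probability(0.6, "vertebral", "vertebral",
                                             "control", m), 1)
  # a prior fracture elsewhere does not elevate the site's risk
  expect_equal(adjusted_fracture_probability(0.01, "hip", "wrist", "control", m),
               0.01)
})

test_that("adjusted probabilities stay in [0,1] and intervention never exceeds control", {
  m <- risk_modifiers()
  set.seed(77)
  histories <- list(character(), "hip", c("hip", "vertebral"), FX_SITES)
  for (i in 1:50) {
    base <- runif(1)
    site <- sample(FX_SITES, 1)
    h <- histories[[sample.int(4, 1)]]
    ctl <- adjusted_fracture_probability(base, site, h, "control", m)
    int <- adjusted_fracture_probability(base, site, h, "intervention", m)
    expect_gte(ctl, 0); expect_lte(ctl, 1)
    expect_gte(int, 0); expect_lte(int, 1)
    expect_lte(int, ctl)
  }
})
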