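# Arm comparison, typed ratios, price sweep, aggregation.

# Minimal fabricated trace pair with controlled fracture and life-year
# differences, for closed-form ratio checks.
fab_trace <- function(arm, fx_total = 0, py = 100) {
  cyc <- data.frame(t = 0, age = 70, alive_start = 100, fx_hip = fx_total,
                    fx_vertebral = 0, fx_wrist = 0, fx_other = 0,
                    fxs_hip = fx_total, fxs_vertebral = 0, fxs_wrist = 0,
                    fxs_other = 0, deaths = 0, alive_end = 100,
                    person_years = py)
  structure(list(cohort = list(sex = "women", age = 70, stratum = "general",
                               size = 100),
                 arm = arm, cycles = cyc, initial_size = 100),
            class = "cohort_trace")
}

test_that("identical arms yield zero increments and undefined ratios", {
  int <- list(trace = fab_trace("intervention", 5, 100), costs = list(total = 1000))
  ctl <- list(trace = fab_trace("control", 5, 100), costs = list(total = 1000))
  res <- compare(int, ctl)
  expect_equal(res$fractures_avoided[["total"]], 0)
  expect_equal(res$lyg$discounted, 0)
  expect_equal(res$incremental_cost, 0)
  expect_equal(res$cost_per_fracture_avoided$status, "undefined")
  expect_equal(res$cost_per_lyg$status, "undefined")
  expect_true(is.na(res$cost_per_lyg$value))
})

test_that("ratios are incremental cost over increments", {
  int <- list(trace = fab_trace("intervention", 0, 102), costs = list(total = 101000))
  ctl <- list(trace = fab_trace("control", 10, 100), costs = list(total = 1000))
  res <- compare(int, ctl)
  expect_equal(res$fractures_avoided[["total"]], 10)
  expect_equal(res$lyg$discounted, 2)
  expect_equal(res$incremental_cost, 100000)
  expect_equal(res$cost_per_fracture_avoided$value, 10000)
  expect_equal(res$cost_per_lyg$value, 50000)
  expect_equal(res$cost_per_lyg$status, "defined")
})

test_that("mismatched cohorts and mislabelled arms are rejected", {
  a <- fab_trace("intervention"); b <- fab_trace("control")
  b2 <- b; b2$cohort$age <- 60
  expect_error(compare(list(trace = a, costs = list(total = 0)),
                       list(trace = b2, costs = list(total = 0))),
               "different cohorts")
  expect_error(compare(list(trace = b, costs = list(total = 0)),
                       list(trace = b, costs = list(total = 0))),
               "mislabelled")
})

test_that("a free effective supplement is reported as cost-saving", {
  m <- risk_modifiers()  # efficacy < 1, so the intervention averts deaths
  sc <- toy_scenario(qx = 0.05, p_site = c(hip = 0.05, vertebral = 0.05,
                                           wrist = 0, other = 0),
                     max_age = 80, cost_flat = 10000, modifiers = m)
  # zero fracture costs saved and zero price: incremental cost exactly 0
  sc$cost <- cost_schedule(data.frame(age = c(50, 70, 100), cost = c(0, 0, 0)),
                           hip_extra_first_year = 0, cost_curve_family = "poly2",
                           supplement_annual_price = 0)
  res <- price_sweep(toy_cohort(), sc, prices = 0)[[1]]
  expect_gt(res$lyg$discounted, 0)
  expect_lte(res$incremental_cost, 1e-9)
  expect_equal(res$cost_per_lyg$status, "cost_saving")
  expect_lte(res$cost_per_lyg$value, 1e-9)
})

test_that("cost-per-LYG is affine in price with the analytic slope", {
  sc <- ref_scenario()
  ch <- list(sex = "women", age = 70, stratum = "general", size = 35345)
  arms <- run_cohort_pair(ch, sc)
  res <- price_sweep(ch, sc, prices = c(150, 250, 350), arms = arms)
  cpl <- vapply(res, function(r) r$cost_per_lyg$value, numeric(1))
  expect_equal(cpl[2] - cpl[1], cpl[3] - cpl[2], tolerance = 1e-9)
  # analytic slope: discounted person-years of the intervention arm per LYG
  disc_py <- sum(arms$intervention$cycles$person_years /
                   (1 + sc$cost$discount_rate_costs)^arms$intervention$cycles$t)
  slope <- (cpl[3] - cpl[1]) / 200
  expect_equal(slope, disc_py / res[[1]]$lyg$headline, tolerance = 1e-9)
  expect_error(price_sweep(ch, sc, prices = numeric(0)), "at least one")
  expect_error(price_sweep(ch, sc, prices = -10), "non-negative")
})

test_that("exported ratios are self-consistent with their components", {
  sc <- ref_scenario()
  d <- compare_all_cohorts(sc, cohorts = data.frame(
    sex = "women", age = 70, stratum = c("general", "osteoporosis"),
    size = c(35345, 15088), stringsAsFactors = FALSE))
  expect_equal(d$cost_per_fx_avoided, d$incremental_cost / d$fx_avoided_total,
               tolerance = 1e-9)
  expect_equal(d$cost_per_lyg, d$incremental_cost / d$lyg_discounted,
               tolerance = 1e-9)
})

test_that("aggregation sums cohorts and rejects duplicates", {
  one <- data.frame(sex = "women", age = 70, stratum = "general",
                    fx_avoided_total = 10, lyg_discounted = 2,
                    lyg_undiscounted = 3)
  agg1 <- aggregate_results(one)
  expect_equal(agg1$fx_avoided_total[agg1$group == "overall"], 10)

  two <- rbind(one, transform(one, age = 80, fx_avoided_total = 20))
  agg2 <- aggregate_results(two)
  expect_equal(agg2$fx_avoided_total[agg2$group == "overall"], 30)
  expect_equal(agg2$fx_avoided_total[agg2$group == "women"], 30)

  expect_error(aggregate_results(rbind(one, one)), "duplicate")
})

test_that("scenario-wide totals equal the sum of the per-cohort export", {
  sc <- ref_scenario()
  d <- compare_all_cohorts(sc)
  agg <- aggregate_results(d)
  for (sx in c("women", "men")) {
    expect_equal(agg$fx_avoided_total[agg$group == sx],
                 sum(d$fx_avoided_total[d$sex == sx]), tolerance = 1e-12)
    expect_equal(agg$lyg_discounted[agg$group == sx],
                 sum(d$lyg_discounted[d$sex == sx]), tolerance = 1e-12)
  }
  expect_equal(agg$fx_avoided_total[agg$group == "overall"],
               sum(d$fx_avoided_total), tolerance = 1e-12)
})

test_that("higher baseline incidence makes the intervention more efficient", {
  # scale the hip anchors (and with them all site curves) by 1, 2, 4
  base_cfg <- list(risk = list(hip_anchors = list(women = list(
    rate_at_50 = 3e-4, doubling_time = 6, anchor_ages = c(50, 60, 70, 80, 90)))))
  vals <- vapply(c(1, 2, 4), function(k) {
    cfg <- base_cfg
    cfg$risk$hip_anchors$women$rate_at_50 <- 3e-4 * k
    sc <- scenario_from_config(cfg)
    ch <- list(sex = "women", age = 70, stratum = "general", size = 35345)
    res <- price_sweep(ch, sc, prices = 250)[[1]]
    c(res$cost_per_fracture_avoided$value, res$cost_per_lyg$value)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("the efficiency gradient runs with age and with baseline risk", {
  sc <- ref_scenario()
  d <- compare_all_cohorts(sc)
  for (sx in c("women", "men")) {
    for (st in STRATA) {
      dd <- d[d$sex == sx & d$stratum == st, ]
      v <- dd$cost_per_fx_avoided[order(dd$age)]
      expect_true(all(diff(v) < 0),
                  label = sprintf("cost/fx avoided decreasing in age (%s, %s)", sx, st))
    }
    for (a in c(50, 60, 70, 80)) {
      dd <- d[d$sex == sx & d$age == a, ]
      v <- dd$cost_per_fx_avoided[match(STRATA, dd$stratum)]
      expect_true(all(diff(v) < 0),
                  label = sprintf("cost/fx avoided decreasing in risk (%s, %d)", sx, a))
    }
  }
})
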