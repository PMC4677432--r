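# Cohort engine: cycle transitions, lifetime projection, life-years.

test_that("a cycle with no risk leaves occupancy unchanged with zero flows", {
  m <- risk_modifiers()
  occ <- c(runif(16, 0, 100), 5)
  step <- cycle_step(occ, c(hip = 0, vertebral = 0, wrist = 0, other = 0),
                     qx = 0, modifiers = m, arm = "control")
  expect_equal(step$occupancy, occ)
  expect_equal(unname(step$fractures), rep(0, 4))
  expect_equal(step$deaths, 0)
})

test_that("single-class cycle matches the hand-enumerated outcome tree", {
  # 1000 persons, hip risk 0.1, qx 0.02, excess multiplier 5.5:
  # dying fraction = 0.1 * min(1, 5.5 * 0.02) + 0.9 * 0.02 = 0.029
  m <- risk_modifiers()
  occ <- c(1000, rep(0, 16))
  step <- cycle_step(occ, c(hip = 0.1, vertebral = 0, wrist = 0, other = 0),
                     qx = 0.02, modifiers = m, arm = "control")
  expect_equal(step$deaths, 1000 * 0.029, tolerance = 1e-12)
  expect_equal(unname(step$fractures[["hip"]]), 100)
  expect_equal(unname(step$fracture_survivors[["hip"]]), 100 * (1 - 0.11))
  expect_equal(step$occupancy[2], 89)            # hip-history class
  expect_equal(step$occupancy[1], 900 * 0.98)    # unfractured survivors
  expect_equal(step$occupancy[17], 29)
  expect_equal(sum(step$occupancy), 1000)
})

test_that("certain death absorbs the whole cohort in one cycle", {
  m <- risk_modifiers()
  occ <- c(runif(16, 0, 10), 0)
  step <- cycle_step(occ, c(hip = 0.2, vertebral = 0.1, wrist = 0, other = 0),
                     qx = 1, modifiers = m, arm = "control")
  expect_equal(step$occupancy[17], sum(occ))
  expect_equal(sum(step$occupancy[1:16]), 0)
})

test_that("invalid occupancy is rejected", {
  m <- risk_modifiers()
  expect_error(cycle_step(c(-1, rep(0, 16)), c(hip = 0, vertebral = 0,
                                               wrist = 0, other = 0),
                          0.1, m), "occupancy")
  expect_error(cycle_step(rep(NA_real_, 17), c(hip = 0, vertebral = 0,
                                               wrist = 0, other = 0),
                          0.1, m), "occupancy")
})

test_that("zero-size cohorts give all-zero traces; no incidence gives geometric decay", {
  sc <- toy_scenario(qx = 0.1, max_age = 60)
  tr0 <- run_cohort(toy_cohort(size = 0), "control", sc)
  expect_true(all(tr0$occupancy == 0))
  expect_true(all(tr0$cycles$deaths == 0))

  tr <- run_cohort(toy_cohort(size = 1000), "control", sc)
  expect_equal(tr$cycles$alive_start[1:3], c(1000, 900, 810), tolerance = 1e-12)
})

test_that("persons are conserved and the intervention arm cannot fracture more", {
  sc <- ref_scenario()
  ch <- list(sex = "women", age = 70, stratum = "general", size = 35345)
  arms <- run_cohort_pair(ch, sc)
  for (tr in arms) {
    err <- max(abs(rowSums(tr$occupancy) - ch$size)) / ch$size
    expect_lt(err, 1e-9)
  }
  fx_cols <- paste0("fx_", FX_SITES)
  expect_lte(sum(arms$intervention$cycles[, fx_cols]),
             sum(arms$control$cycles[, fx_cols]))
})

test_that("with no supplementation effect the two arms coincide", {
  m <- risk_modifiers(efficacy_rr = c(hip = 1, vertebral = 1, wrist = 1, other = 1))
  sc <- toy_scenario(qx = 0.05, p_site = c(hip = 0.02, vertebral = 0.03,
                                           wrist = 0.01, other = 0.02),
                     max_age = 80, modifiers = m)
  ch <- toy_cohort()
  tr_i <- run_cohort(ch, "intervention", sc)
  tr_c <- run_cohort(ch, "control", sc)
  expect_equal(tr_i$cycles, tr_c$cycles, tolerance = 1e-12)
})

test_that("cumulative fractures decrease as efficacy strengthens", {
  ch <- toy_cohort()
  fx_cols <- paste0("fx_", FX_SITES)
  totals <- vapply(c(0.6, 0.8, 1.0), function(rr) {
    m <- risk_modifiers(efficacy_rr = c(hip = rr, vertebral = rr,
                                        wrist = rr, other = rr))
    sc <- toy_scenario(qx = 0.05, p_site = c(hip = 0.02, vertebral = 0.03,
                                             wrist = 0.01, other = 0.02),
                       max_age = 80, modifiers = m)
    sum(run_cohort(ch, "intervention", sc)$cycles[, fx_cols])
  }, numeric(1))
  expect_true(all(diff(totals) > 0))  # weaker efficacy, more fractures
})

test_that("with zero incidence the engine reproduces the life-table closed form", {
  lt <- generate_life_table(0.001, 5e-5, 0.1, max_age = 105, sex = "women")
  sc <- toy_scenario(max_age = 105)
  sc$life_tables$women <- lt
  tr <- run_cohort(toy_cohort(size = 1000), "control", sc, max_age = 105)
  expect_equal(life_years(tr, 0)$undiscounted / 1000,
               life_expectancy(lt, 50), tolerance = 1e-9)
})

test_that("life-years follow the half-cycle death credit and discounting", {
  # everyone dies in the first cycle: half a year each
  sc1 <- toy_scenario(qx = 1, max_age = 51)
  tr1 <- run_cohort(toy_cohort(size = 1), "control", sc1)
  expect_equal(life_years(tr1, 0)$undiscounted, 0.5)

  # two-cycle toy against an explicit hand summation
  sc2 <- toy_scenario(qx = 0.5, max_age = 52)
  tr2 <- run_cohort(toy_cohort(size = 1000), "control", sc2)
  ly <- life_years(tr2, 0.03)
  hand_undisc <- (500 + 250) + (250 + 125) + (0 + 125)
  hand_disc <- 750 + 375 / 1.03 + 125 / 1.03^2
  expect_equal(ly$undiscounted, hand_undisc, tolerance = 1e-12)
  expect_equal(ly$discounted, hand_disc, tolerance = 1e-12)

  # no discounting: both totals agree
  expect_equal(life_years(tr2, 0)$discounted, ly$undiscounted, tolerance = 1e-12)
  expect_error(life_years(tr2, -0.01), "non-negative")
})

test_that("prevalent-fracture cohorts start in the configured history states", {
  sc <- toy_scenario(qx = 0.1, max_age = 60,
                     prevalence_row = data.frame(sex = "women", age = 50,
                                                 general = 0.6, osteoporosis = 0.2,
                                                 prevalent_fracture = 0.2))
  tr <- run_cohort(toy_cohort(size = 1000, stratum = "prevalent_fracture"),
                   "control", sc)
  ss <- state_space()
  hip_only <- ss$index[ss$hip & !ss$vertebral & !ss$wrist & !ss$other]
  vert_only <- ss$index[ss$vertebral & !ss$hip & !ss$wrist & !ss$other]
  expect_equal(tr$occupancy[1, hip_only], 500)
  expect_equal(tr$occupancy[1, vert_only], 500)
  expect_equal(sum(tr$occupancy[1, ]), 1000)
})
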