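# Shared fixtures: a cached reference scenario and small toy scenarios with
# hand-controllable mortality and incidence.

.cache <- new.env(parent = emptyenv())

ref_scenario <- function(seed = 1L) {
  key <- paste0("ref", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- make_reference_scenario(seed)
  .cache[[key]]
}

# A flat (age-constant) incidence curve; p = 0 gives a structurally zero curve.
flat_curve <- function(p, site = "hip") {
  structure(list(intercept = if (p > 0) log(p) else -Inf, slope = 0,
                 domain = c(50, Inf), sex = "women", site = site),
            class = "incidence_curve")
}

# Minimal single-sex scenario: constant background mortality `qx` up to
# max_age (absorbing), flat per-site incidence, one general-population
# cohort row, flat hip cost.
toy_scenario <- function(qx = 0.1, p_site = c(hip = 0, vertebral = 0,
                                              wrist = 0, other = 0),
                         max_age = 60, baseline_age = 50,
                         modifiers = risk_modifiers(),
                         price = 250, cost_flat = 10000, hip_extra = 0,
                         rate_costs = 0.03, rate_effects = 0.03,
                         excess_multiplier = 5.5,
                         prevalence_row = NULL) {
  ages <- 50:max_age
  lt <- new_life_table("women", ages, c(rep(qx, length(ages) - 1L), 1))
  curves <- lapply(stats::setNames(nm = FX_SITES),
                   function(s) flat_curve(p_site[[s]], s))
  prev <- if (is.null(prevalence_row)) {
    data.frame(sex = "women", age = baseline_age, general = 1,
               osteoporosis = 0, prevalent_fracture = 0)
  } else prevalence_row
  cost <- cost_schedule(
    hip_cost_anchors = data.frame(age = c(50, 100), cost = c(cost_flat, cost_flat)),
    hip_extra_first_year = hip_extra,
    supplement_annual_price = price,
    discount_rate_costs = rate_costs, discount_rate_effects = rate_effects)
  list(projection = data.frame(sex = "women", age = baseline_age, total = 1000L),
       prevalence = prev,
       life_tables = list(women = lt),
       incidence = list(women = curves),
       modifiers = modifiers,
       cost = cost,
       run = list(max_age = max_age, prices = c(150, 250, 350),
                  fracture_prob_cap = 0.999,
                  excess_mort_multiplier = excess_multiplier,
                  excess_attributable_fraction = 1,
                  headline_discounted = TRUE, seed = 1L),
       seed = 1L)
}

toy_cohort <- function(size = 1000, age = 50, stratum = "general") {
  list(sex = "women", age = age, stratum = stratum, size = size)
}
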