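---
title: "A Markov cohort model of fortified-dairy supplementation for fracture prevention: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort model of fortified-dairy supplementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Dietary calcium and vitamin D are the recommended first-line measure
against osteoporotic fractures, yet the population-level health and budget
consequences of actually supplying them — for instance through dairy
products fortified with 800 IU of vitamin D and 1 g of calcium per daily
serving — are rarely quantified. `osteocea` implements a population-based
state-transition model that asks: if whole national birth cohorts aged 50,
60, 70 and 80 took such a supplement for the rest of their lives, how many
fractures would be avoided, how many life-years gained, and at what cost
per fracture avoided and per life-year gained (LYG)?

The model is deterministic (expected-value cohort propagation with
fractional persons) and is cross-validated by an independent
individual-level Monte-Carlo simulation of the same transition rules.

## Population and strata

Eight closed cohorts (women and men at baseline ages 50, 60, 70, 80) enter
with the head counts of the published population projection, shipped with
the package as plain-text tables. Each cohort is split into three
baseline-risk strata using published prevalence fractions:

* **general** population,
* **osteoporosis** (BMD T-score ≤ −2.5),
* **prevalent fracture** (a hip or vertebral fracture before entry).

Stratum sizes are `round(total × fraction)` with ties away from zero; this
convention reproduces all 24 published head counts exactly (the suite
checks every cell). The general stratum uses its own printed fraction
rather than the complement of the other two, because the printed
percentages were rounded independently; the three strata therefore
reconcile with the cohort total only to within a couple of persons.

## State space and annual transitions

Each alive person is characterised by the set of fracture sites they have
ever fractured — hip, clinical vertebral, wrist, "other" — giving 16 alive
classes (all subsets, including the empty history) plus one absorbing Dead
state. History only grows; there is no recovery state.

Each annual cycle, within each alive class:

1. **Fracture.** Site-specific annual probabilities are assembled
   (see below) and summed; at most one index fracture per person-year is
   allowed, with total probability capped at 0.999 and site allocation
   proportional to the per-site probabilities. Annual cycles make
   multi-fracture years second-order, and the single-event rule keeps the
   flow accounting exact.
2. **Death.** Mortality acts after the fracture draw so that the
   post-fracture excess acts on the correct subpopulation: persons
   fracturing the hip or a vertebra that cycle die with
   `min(1, 5.5 × qx)`, everyone else with the background `qx`. The 5.5
   multiplier applies only in the fracture cycle; its published source
   does not state a duration, and restricting it to the event year is the
   conservative reading. An attributable-fraction knob (default 1, i.e.
   the whole excess attributed to the fracture) scales the multiplier as
   `1 + f·(5.5 − 1)`.
3. **Bookkeeping.** Surviving fracturers move to the class with the site
   added to their history; incident fractures are recorded as flows
   whether or not the person survives the cycle.

Background mortality comes from a per-sex life table whose terminal age
(default 105) is absorbing, closing the lifetime horizon. Person-years use
the half-cycle death credit: one year for surviving a cycle, half a year
when dying within it. With zero fracture incidence the engine's life
expectancy equals the life-table closed form to numerical precision — a
property the suite asserts at 1e-9.

Person conservation (alive + dead = initial size) holds to a relative
1e-9 at every cycle for all 24 cohorts; in practice the engine conserves
to machine precision because every cycle is a redistribution of the
occupancy vector.

## Fracture risk assembly

* **Hip incidence** is interpolated through age anchors by exponential
  regression: ordinary least squares of log(probability) on age,
  exponentiated and capped at 1 on evaluation.
* **Non-hip incidence** is hip incidence times banded site-to-hip ratios
  (default bands 50–64, 65–74, 75+), refitted log-linearly within each
  band so the derived curves stay exponential-in-age piecewise. Since a
  ratio is constant within a band, the refit passes exactly through the
  derived points.
* **Stratum calibration.** Population curves are split so the
  prevalence-weighted stratum mixture reproduces the population
  probability: `p_gen = p_pop / (w_gen + w_op·RR_op + w_pf·RR_pf)`, with
  the mixture weights frozen at the cohort's baseline age. The effective
  prevalent-fracture RR used in the denominator folds in the stratum's
  starting history (see below), so the recomposed mixture equals the
  population curve exactly.
* **Per-person adjustment.** A prior fracture at the *same* site
  multiplies the annual probability by 2.3 (hip), 4.4 (vertebral),
  3.3 (wrist) or 1.9 (other); cross-site elevation is deliberately not
  modelled. In the intervention arm the supplementation efficacy
  multiplies hip risk by 0.82, vertebral by 0.87 and both non-hip
  non-vertebral sites by 0.80 — the source evidence pools wrist and
  "other" fractures into one non-hip non-vertebral estimate, so applying
  0.80 to both sites is an interpretation, flagged here and configurable.
  Efficacy applies from the first cycle for the remaining lifetime with
  full adherence and no waning.

### The prevalent-fracture stratum

The published stratum definitions place prevalent-fracture individuals
*within* the osteoporotic population. The stratum therefore carries the
osteoporosis baseline elevation (default RR 2.0 per site — a required
configuration input, as no stratum-specific baseline risks are published)
*and* starts with a fracture history: half hip, half vertebral by default
(the published split is not stated). Its extra risk beyond the
osteoporosis stratum comes from the same-site prior-fracture RRs acting on
that history, not from an additional stratum multiplier. This makes the
three strata strictly ordered in risk (general < osteoporosis <
prevalent-fracture), which is also what drives the efficiency gradient in
the results.

## Costs and discounting

Only direct medical costs enter. The acute hospitalization cost of a hip
fracture is interpolated through age anchors by power regression (least
squares of log cost on log age; a quadratic-in-age family is available).
Non-hip acute costs are fixed fractions of the hip cost (defaults:
vertebral 0.25, wrist 0.12, other 0.20). Hip fractures add a first-year
extra cost (default €12,000) applied one cycle after the event to persons
who survived the fracture cycle; non-hip fractures carry no cost beyond
the event year, and no long-term (>1 year) hip cost is modelled by default
(a parameter exists, default 0). The supplement costs its annual price
(default €250/person-year, conventionally swept over €150–€350) times the
person-years lived in the intervention arm. Costs and effects are
discounted at independently configurable annual rates, both defaulting to
3%, with the baseline year undiscounted.

Because only the supplement term depends on the price, the incremental
cost — and hence cost-per-LYG — is affine in the price with slope equal
to the intervention arm's discounted person-years divided by the LYG.
The suite asserts this affinity at 1e-9; it is the structural property
behind the equal increments across the price grid.

## Incremental outcomes

For each cohort the two arms are compared on identical inputs: fractures
avoided (control minus intervention, by site and total), LYG (discounted
and undiscounted; the headline uses discounted by default — whether the
published life-year gains were discounted is not stated, so the choice is
explicit and toggleable), incremental cost, cost-per-fracture-avoided and
cost-per-LYG. Ratios with non-positive denominators are *typed outcomes*
(`cost_saving`, `dominated`, `undefined`), never sentinel numbers, so
±Inf cannot leak into tables.

## What the synthetic demography emulates — and what it does not

The original national analysis drew on data sources that are not publicly
tabulated: official mortality projections, a national hospital-bill
register for hip incidence and costs, and a register-based non-hip/hip
ratio table. The package replaces these with parametric stand-ins:

* **Mortality**: Gompertz–Makeham hazards
  `h(a) = A + B·exp(C·(a − 50))`. Defaults (women A = 3e-4, B = 1.2e-3,
  C = 0.115; men A = 7e-4, B = 2.0e-3, C = 0.110) give remaining life
  expectancy at 50 of 35.4 and 32.0 years and q(80) of about 3.7% and
  5.3% — national-level magnitudes for the population emulated.
* **Hip incidence**: exponential in age, women 3e-4 at 50 doubling every
  6 years, men 2e-4 doubling every 7 years, anchored at ages 50–90. The
  reference scenario perturbs the anchors with lognormal noise (sd 0.05,
  seed-driven) so the exponential fitter works on noisy anchors, as it
  would on register estimates.
* **Ratios**: vertebral 3.0/1.8/1.1, wrist 4.5/1.8/0.6, other
  4.0/2.0/1.2 across the three bands — the characteristic pattern of
  forearm-dominated fracture mixes at younger ages giving way to
  hip-dominated mixes in old age.
* **Hip cost**: €8,000 at 50 growing as a power law (exponent 0.75) to
  about €12,400 at 90, with milder anchor noise.

Consequently the absolute outputs (fractures avoided, LYG, € per LYG) are
*not* estimates for any real country, and the published headline totals
are not expected to be reproduced. What the passing tests do establish is
the model's internal correctness: exact stratification, conservation,
the null equivalence of the arms without efficacy, the life-table limit,
price affinity, agreement with an independent microsimulation, and the
published qualitative gradient — supplementation buys fractures avoided
more cheaply in older and riskier cohorts. Transferring the pipeline to
real inputs is a matter of replacing anchors and tables in the YAML
configuration.

## Validation by independent microsimulation

The cohort engine's expectations are checked against an individual-level
Monte-Carlo implementation that shares the scenario parsing but none of
the transition code. Per person-year it samples one-or-no fracture and
then death with the same probabilities and ordering contract, and accrues
the same cost rules. Uniform draws are pre-generated into matrices indexed
by (individual, cycle), so results are reproducible from the seed and
independent of iteration order. The validation runs 20,000 individuals
(plus a 2,000-individual run to observe the error shrink) and requires
every metric — fractures by site, deaths, life-years, discounted costs —
to agree with the deterministic expectation within 4 Monte-Carlo standard
errors; observed z-scores are typically below 2.5.

## Numerical choices

* Total per-cycle fracture probability capped at 0.999; per-site
  probabilities capped at 1 after each multiplicative adjustment.
* Stratum head counts rounded half-away-from-zero (the convention that
  reproduces the published tables; base R's round-half-even does not).
* No half-cycle correction on state occupancy; the half-cycle convention
  enters only through the death credit on person-years.
* Calibration weights frozen at baseline age (the strata are defined at
  entry; their relative sizes at later ages are an output, not an input).
* Degenerate inputs are rejected with named errors: negative hazards,
  probabilities outside (0,1), non-contiguous life tables, prevalence
  rows summing above 1.005, negative occupancy, unknown configuration
  keys (with their key path).
* Scenario assembly and microsimulation restore the caller's RNG state.

## Known limitations

* The excess-mortality multiplier cannot yet persist beyond the fracture
  cycle; modelling a longer duration would require expanding the state
  space with time-since-fracture.
* Quality-of-life weights (QALYs), adherence decay, protein effects and
  non-skeletal benefits of vitamin D are out of scope, as are societal
  costs.
* Re-fracture within a single year is excluded by the one-event-per-year
  rule.
* The stratum-specific baseline risks and the prevalent-fracture
  composition are configuration inputs with defaults, not published
  values; conclusions that depend on them should be swept.
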