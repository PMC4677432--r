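Package: osteocea
Title: Markov Cohort Cost-Effectiveness Model of Fortified Dairy Supplementation for Osteoporotic Fracture Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A population-based multi-state annual-cycle (Markov cohort) model
    of osteoporotic fractures at four sites (hip, clinical vertebral, wrist,
    other) in sex-by-age birth cohorts stratified by baseline risk (general
    population, osteoporosis, prevalent hip/vertebral fracture). Projects each
    cohort over its remaining lifetime under a vitamin-D/calcium-fortified
    dairy supplementation arm versus no intervention, with post-fracture
    excess mortality, age-specific fracture costs and discounting, and
    computes fractures avoided, life-years gained, cost-per-fracture-avoided
    and cost-per-life-year-gained, including a supplement price sweep. Ships
    a synthetic demography generator (Gompertz-Makeham life tables,
    exponential-in-age hip incidence anchors, smooth cost anchors), a
    deterministic cohort engine, and an independent individual-level
    microsimulation used to cross-validate the cohort engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
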