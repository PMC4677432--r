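# Synthetic demography: life tables, cohort stratification, incidence anchors.

#' Fracture sites modelled
#'
#' The four index fracture sites of the model, in canonical order. Hip and
#' clinical vertebral fractures carry excess mortality and (for hip)
#' follow-on costs; wrist and "other" fractures carry neither.
#'
#' @export
FX_SITES <- c("hip", "vertebral", "wrist", "other")

#' Risk strata
#'
#' Baseline-risk strata into which each sex-by-age cohort is divided:
#' the general population, the osteoporotic population (BMD T-score <= -2.5),
#' and the population with a prevalent hip or vertebral fracture.
#'
#' @export
STRATA <- c("general", "osteoporosis", "prevalent_fracture")

#' Round half away from zero
#'
#' Nearest-integer rounding with ties going away from zero, the convention
#' under which every printed stratum head count equals total times prevalence.
#' (Base \code{round()} rounds half to even, which breaks ties differently.)
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build a Gompertz-Makeham life table
#'
#' Annual death probabilities from age 50 to a terminal age, from the
#' Gompertz-Makeham hazard \eqn{h(a) = A + B e^{C (a - 50)}}: the
#' age-independent (Makeham) component \code{makeham_a} plus a Gompertz
#' senescent component growing exponentially from age 50. The annual
#' probability is \eqn{q(a) = 1 - e^{-h(a)}}; the terminal age is absorbing
#' (\eqn{q = 1}), closing the lifetime horizon.
#'
#' @param makeham_a age-independent hazard component (per year, >= 0).
#' @param gompertz_b senescent hazard at age 50 (per year, >= 0).
#' @param gompertz_c exponential growth rate of the senescent hazard
#'   (per year of age, >= 0).
#' @param max_age terminal (absorbing) age, > 50. Default 105.
#' @param sex label, \code{"women"} or \code{"men"}.
#' @return A \code{life_table} object: data frame with columns \code{age}
#'   (50..max_age) and \code{qx}, with \code{sex} and \code{max_age}
#'   attributes.
#' @examples
#' lt <- generate_life_table(0.001, 5e-5, 0.1, max_age = 100, sex = "women")
#' life_expectancy(lt, 50)
#' @export
generate_life_table <- function(makeham_a, gompertz_b, gompertz_c,
                                max_age = 105, sex = "women") {
  for (nm in c("makeham_a", "gompertz_b", "gompertz_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative number", nm))
    }
  }
  if (max_age <= 50) stop("'max_age' must exceed 50")
  ages <- 50:max_age
  hazard <- makeham_a + gompertz_b * exp(gompertz_c * (ages - 50))
  qx <- 1 - exp(-hazard)
  qx[ages == max_age] <- 1
  new_life_table(sex, ages, qx)
}

#' Construct a life table from explicit probabilities
#'
#' @param sex label.
#' @param ages contiguous integer ages starting at 50.
#' @param qx annual death probabilities, same length as \code{ages}; the last
#'   entry must be 1 (absorbing terminal age).
#' @return A \code{life_table} object.
#' @export
new_life_table <- function(sex, ages, qx) {
  stopifnot(length(ages) == length(qx))
  if (any(diff(ages) != 1L)) stop("life-table ages must be contiguous")
  if (any(qx < 0 | qx > 1)) stop("life-table qx must lie in [0, 1]")
  if (abs(qx[length(qx)] - 1) > 1e-12) {
    stop("terminal-age qx must equal 1 (absorbing terminal age)")
  }
  structure(data.frame(age = as.integer(ages), qx = qx),
            sex = sex, max_age = max(ages),
            class = c("life_table", "data.frame"))
}

#' Look up annual death probabilities
#'
#' @param lt a \code{life_table}.
#' @param age integer age(s) within the table's domain.
#' @return annual death probability vector.
#' @export
life_table_qx <- function(lt, age) {
  idx <- match(as.integer(age), lt$age)
  if (anyNA(idx)) {
    stop(sprintf("age(s) %s outside life-table domain [%d, %d]",
                 paste(age[is.na(idx)], collapse = ", "),
                 min(lt$age), max(lt$age)))
  }
  lt$qx[idx]
}

#' Life expectancy under the half-cycle death credit
#'
#' Closed-form remaining life expectancy at \code{from_age}: persons
#' surviving a whole year are credited one person-year, persons dying within
#' the year half a person-year, so
#' \eqn{e(x) = \sum_t S_t (1 - q_{x+t}/2)} with \eqn{S_t} the probability of
#' being alive at the start of year \eqn{t}. This is the same convention the
#' cohort engine uses, so with zero fracture incidence the engine reproduces
#' this value exactly.
#'
#' @param lt a \code{life_table}.
#' @param from_age starting age within the table's domain.
#' @return remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, from_age) {
  qx <- lt$qx[lt$age >= from_age]
  surv <- cumprod(c(1, 1 - qx))[seq_along(qx)]
  sum(surv * (1 - qx / 2))
}

#' Load the packaged cohort tables
#'
#' Reads the packaged per-sex cohort tables (total head counts and stratum
#' prevalences for baseline ages 50, 60, 70, 80) and returns the population
#' projection together with the stratum prevalence fractions.
#'
#' @param dir directory holding \code{cohort_prevalence_women.tsv} and
#'   \code{cohort_prevalence_men.tsv}; defaults to the copies installed with
#'   the package.
#' @return list with elements \code{projection} (data frame: sex, age, total)
#'   and \code{prevalence} (data frame: sex, age, general, osteoporosis,
#'   prevalent_fracture), plus \code{printed_n} (the published stratum head
#'   counts, for cross-checks).
#' @export
load_population_tables <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "osteocea")
  read_one <- function(sex) {
    path <- file.path(dir, sprintf("cohort_prevalence_%s.tsv", sex))
    if (!file.exists(path)) stop("cohort table not found: ", path)
    d <- utils::read.delim(path, check.names = TRUE)
    cbind(sex = sex, d, stringsAsFactors = FALSE)
  }
  d <- rbind(read_one("women"), read_one("men"))
  projection <- d[, c("sex", "age", "total")]
  prevalence <- data.frame(sex = d$sex, age = d$age,
                           general = d$general_pct,
                           osteoporosis = d$osteoporosis_pct,
                           prevalent_fracture = d$prevalent_fx_pct)
  printed_n <- data.frame(sex = d$sex, age = d$age,
                          general = d$general_n,
                          osteoporosis = d$osteoporosis_n,
                          prevalent_fracture = d$prevalent_fx_n)
  validate_prevalence(prevalence)
  list(projection = projection, prevalence = prevalence, printed_n = printed_n)
}

# Printed percentages are independently rounded, so the three fractions may
# exceed 1 by rounding error only.
validate_prevalence <- function(prevalence, tol = 0.005) {
  s <- prevalence$general + prevalence$osteoporosis + prevalence$prevalent_fracture
  bad <- which(!is.finite(s) | prevalence$general < 0 | prevalence$general > 1 |
                 prevalence$osteoporosis < 0 | prevalence$osteoporosis > 1 |
                 prevalence$prevalent_fracture < 0 | prevalence$prevalent_fracture > 1 |
                 s > 1 + tol)
  if (length(bad)) {
    stop(sprintf(
      "invalid stratum prevalence for %s age %d: fractions must lie in [0,1] and sum to at most %.3f (got sum %.3f)",
      prevalence$sex[bad[1]], prevalence$age[bad[1]], 1 + tol, s[bad[1]]))
  }
  invisible(prevalence)
}

#' Stratify cohorts by baseline fracture risk
#'
#' Splits each sex-by-baseline-age cohort total into the general,
#' osteoporosis and prevalent-fracture strata by nearest-integer rounding of
#' total times prevalence fraction (half away from zero). The general stratum
#' uses its own printed fraction, not the complement of the other two, so the
#' three stratum sizes may differ from the cohort total by a couple of
#' persons of independent rounding.
#'
#' @param projection data frame with columns sex, age, total.
#' @param prevalence data frame with columns sex, age, general, osteoporosis,
#'   prevalent_fracture (fractions of the cohort).
#' @return data frame of cohorts: sex, age, stratum, size.
#' @export
build_cohorts <- function(projection, prevalence) {
  validate_prevalence(prevalence)
  if (any(projection$total < 0) || any(projection$total != round(projection$total))) {
    stop("cohort totals must be non-negative integers")
  }
  key <- paste(projection$sex, projection$age)
  pkey <- paste(prevalence$sex, prevalence$age)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    stop("no prevalence row for cohort(s): ",
         paste(key[is.na(idx)], collapse = ", "))
  }
  out <- do.call(rbind, lapply(STRATA, function(st) {
    data.frame(sex = projection$sex, age = projection$age, stratum = st,
               size = round_half_up(projection$total * prevalence[[st]][idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$sex, c("women", "men")), out$age,
                   match(out$stratum, STRATA)), ]
  rownames(out) <- NULL
  out
}

#' Synthetic age anchors for annual hip-fracture incidence
#'
#' Stand-in for national hospital-register hip-fracture incidence: an
#' exponential-in-age first-event probability that doubles every
#' \code{doubling_time} years from its value at age 50, capped at 1,
#' evaluated at the requested anchor ages.
#'
#' @param rate_at_50 annual hip-fracture probability at age 50, in (0, 1).
#' @param doubling_time years over which the probability doubles, > 0.
#' @param anchor_ages ages at which anchors are emitted (non-empty).
#' @return data frame with columns \code{age}, \code{probability}.
#' @export
generate_hip_incidence_anchors <- function(rate_at_50, doubling_time, anchor_ages) {
  if (!is.numeric(rate_at_50) || rate_at_50 <= 0 || rate_at_50 >= 1) {
    stop("'rate_at_50' must lie strictly between 0 and 1")
  }
  if (!is.numeric(doubling_time) || doubling_time <= 0) {
    stop("'doubling_time' must be positive")
  }
  if (length(anchor_ages) == 0L) stop("'anchor_ages' must be non-empty")
  p <- pmin(1, rate_at_50 * 2^((anchor_ages - 50) / doubling_time))
  data.frame(age = anchor_ages, probability = p)
}
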