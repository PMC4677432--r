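# Deterministic annual-cycle cohort engine over fracture-history states.

# Site bit values for the history bitmask (hip = 1, vertebral = 2, wrist = 4,
# other = 8). Alive states are the 16 subsets of sites ever fractured; state
# 17 is absorbing Dead.
.site_bits <- c(hip = 1L, vertebral = 2L, wrist = 4L, other = 8L)

#' The model's state space
#'
#' Sixteen alive classes (every subset of the four fracture sites ever
#' fractured, including the empty history) plus one absorbing Dead state.
#' History can only grow along any admissible path.
#'
#' @return data frame with one row per state: \code{index}, \code{label},
#'   and logical columns per site flagging membership in the history.
#' @export
state_space <- function() {
  masks <- 0:15
  flags <- sapply(FX_SITES, function(s) bitwAnd(masks, .site_bits[[s]]) > 0L)
  labels <- apply(flags, 1, function(f) {
    if (!any(f)) "no_fx" else paste(FX_SITES[f], collapse = "+")
  })
  out <- data.frame(index = c(masks + 1L, 17L),
                    label = c(labels, "dead"))
  for (s in FX_SITES) out[[s]] <- c(flags[, s], FALSE)
  out
}

# Per-class multiplier matrices reused every cycle (16 x 4).
.history_multipliers <- function(modifiers) {
  masks <- 0:15
  mult <- matrix(1, nrow = 16L, ncol = 4L, dimnames = list(NULL, FX_SITES))
  for (s in FX_SITES) {
    has <- bitwAnd(masks, .site_bits[[s]]) > 0L
    mult[has, s] <- modifiers$prior_fx_rr[[s]]
  }
  mult
}

# Destination alive-state index after a fracture at site s from class row h.
.transition_index <- function() {
  masks <- 0:15
  sapply(FX_SITES, function(s) bitwOr(masks, .site_bits[[s]]) + 1L)
}

#' Advance one annual cycle
#'
#' One cycle of the cohort engine for a single stratum at a single age.
#' Within each alive class: (1) at most one index fracture per person-year —
#' the total fracture probability is \code{min(sum of site probabilities,
#' cap)} with site allocation proportional to the per-site probabilities;
#' (2) mortality acts after the fracture draw: persons fracturing the hip or
#' a vertebra that cycle die with the excess-adjusted probability
#' \code{min(1, (1 + af*(mult - 1)) * qx)} (default multiplier 5.5, fully
#' attributed), everyone else with the background \code{qx}; (3) surviving
#' fracturers move to the class with the site added to their history.
#' Fracture flows count incident fractures whether or not the person
#' survives the cycle.
#'
#' @param occupancy numeric length-17 state occupancy (persons; fractional
#'   allowed), alive classes 1..16 then Dead.
#' @param base_site named length-4 vector of stratum baseline annual
#'   fracture probabilities at this age.
#' @param qx background annual death probability at this age.
#' @param modifiers a \code{risk_modifiers} object.
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param cap upper bound on the total annual fracture probability
#'   (default 0.999).
#' @param excess_multiplier mortality multiplier in the cycle of a hip or
#'   vertebral fracture (default 5.5).
#' @param attributable_fraction share of the excess mortality attributed to
#'   the fracture (default 1).
#' @return list with \code{occupancy} (length 17), \code{fractures} and
#'   \code{fracture_survivors} (per site), and \code{deaths} (persons).
#' @export
cycle_step <- function(occupancy, base_site, qx, modifiers,
                       arm = c("control", "intervention"), cap = 0.999,
                       excess_multiplier = 5.5, attributable_fraction = 1) {
  arm <- match.arg(arm)
  if (length(occupancy) != 17L || any(!is.finite(occupancy)) || any(occupancy < 0)) {
    stop("'occupancy' must be 17 non-negative finite values")
  }
  alive <- occupancy[1:16]
  mult <- .history_multipliers(modifiers)
  eff <- if (arm == "intervention") modifiers$efficacy_rr else rep(1, 4L)
  p_mat <- pmin(sweep(mult, 2L, base_site[FX_SITES] * eff, `*`), 1)
  tot <- rowSums(p_mat)
  P <- pmin(tot, cap)
  scale <- ifelse(tot > 0, P / tot, 0)
  alloc <- p_mat * scale

  q_ex <- min(1, (1 + attributable_fraction * (excess_multiplier - 1)) * qx)
  q_site <- c(hip = q_ex, vertebral = q_ex, wrist = qx, other = qx)

  frac_mat <- alloc * alive                     # incident fractures by (class, site)
  surv_mat <- sweep(frac_mat, 2L, 1 - q_site, `*`)
  deaths <- sum(frac_mat %*% q_site) + sum(alive * (1 - P) * qx)

  new_alive <- alive * (1 - P) * (1 - qx)
  to_idx <- .transition_index()
  for (s in seq_along(FX_SITES)) {
    # several classes share a destination (those already holding site s), so
    # contributions must be summed by destination before adding
    agg <- rowsum(surv_mat[, s], to_idx[, s])
    di <- as.integer(rownames(agg))
    new_alive[di] <- new_alive[di] + agg[, 1L]
  }
  out <- c(new_alive, occupancy[17L] + deaths)
  names(out) <- NULL
  list(occupancy = out,
       fractures = colSums(frac_mat),
       fracture_survivors = colSums(surv_mat),
       deaths = deaths)
}

# Stratum baseline probability matrix (ages x sites) for one cohort:
# population curves scaled by the calibration factor at the baseline age.
.stratum_base_matrix <- function(scenario, sex, baseline_age, stratum, max_age) {
  ages <- baseline_age:max_age
  curves <- scenario$incidence[[sex]]
  p_pop <- sapply(FX_SITES, function(s) predict_incidence(curves[[s]], ages))
  p_pop <- matrix(p_pop, nrow = length(ages), dimnames = list(NULL, FX_SITES))
  prev <- scenario$prevalence
  row <- prev[prev$sex == sex & prev$age == baseline_age, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no stratum prevalence for %s at baseline age %d", sex, baseline_age))
  }
  w <- c(general = row$general, osteoporosis = row$osteoporosis,
         prevalent_fracture = row$prevalent_fracture)
  eff <- effective_stratum_rr(scenario$modifiers)
  base <- sapply(FX_SITES, function(s) {
    calib <- calibrate_stratum_incidence(p_pop[, s], w,
                                         rr_op = eff["osteoporosis", s],
                                         rr_pf = eff["prevalent_fracture", s])
    # the prevalent-fracture baseline excludes the history effect, which the
    # engine applies dynamically through the state space
    calib$general * scenario$modifiers$stratum_rr[stratum, s]
  })
  matrix(base, nrow = length(ages), dimnames = list(NULL, FX_SITES))
}

# Starting occupancy: general/osteoporosis cohorts enter with empty history;
# prevalent-fracture cohorts enter split across the {hip} and {vertebral}
# history classes.
.initial_occupancy <- function(size, stratum, modifiers) {
  occ <- numeric(17L)
  if (stratum == "prevalent_fracture") {
    split <- modifiers$pf_history_split
    occ[.site_bits[["hip"]] + 1L] <- size * split[["hip"]]
    occ[.site_bits[["vertebral"]] + 1L] <- size * split[["vertebral"]]
  } else {
    occ[1L] <- size
  }
  occ
}

#' Project one cohort over its remaining lifetime
#'
#' Iterates \code{\link{cycle_step}} annually from the cohort's baseline age
#' to the terminal age of its life table (by which age \code{qx = 1}, so the
#' cohort is fully absorbed). Cycle \code{t = 0} covers the year starting at
#' the baseline age. Person-years follow the half-cycle death credit: one
#' year for persons alive at the end of a cycle, half a year for persons
#' dying within it.
#'
#' @param cohort list or one-row data frame with \code{sex}, \code{age}
#'   (baseline), \code{stratum}, \code{size}.
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param scenario a scenario bundle, see \code{\link{make_reference_scenario}}.
#' @param max_age terminal age; defaults to the scenario's.
#' @return a \code{cohort_trace}: list with \code{cohort}, \code{arm},
#'   \code{cycles} (one row per cycle: t, age, alive_start, per-site
#'   fractures and surviving fracturers, deaths, alive_end, person_years)
#'   and \code{occupancy} (cycle-start state matrix including Dead).
#' @export
run_cohort <- function(cohort, arm = c("control", "intervention"), scenario,
                       max_age = scenario$run$max_age) {
  arm <- match.arg(arm)
  cohort <- as.list(cohort)
  if (cohort$age >= max_age) stop("cohort baseline age must be below 'max_age'")
  lt <- scenario$life_tables[[cohort$sex]]
  if (is.null(lt)) stop("no life table for sex ", cohort$sex)
  if (max_age > attr(lt, "max_age")) stop("life table does not reach 'max_age'")
  base_mat <- .stratum_base_matrix(scenario, cohort$sex, cohort$age,
                                   cohort$stratum, max_age)
  modifiers <- scenario$modifiers
  run <- scenario$run
  occ <- .initial_occupancy(cohort$size, cohort$stratum, modifiers)
  ages <- cohort$age:max_age
  n_cyc <- length(ages)
  occ_hist <- matrix(0, nrow = n_cyc + 1L, ncol = 17L)
  occ_hist[1L, ] <- occ
  cyc <- data.frame(t = seq_len(n_cyc) - 1L, age = ages, alive_start = NA_real_,
                    fx_hip = 0, fx_vertebral = 0, fx_wrist = 0, fx_other = 0,
                    fxs_hip = 0, fxs_vertebral = 0, fxs_wrist = 0, fxs_other = 0,
                    deaths = 0, alive_end = NA_real_, person_years = NA_real_)
  for (i in seq_len(n_cyc)) {
    cyc$alive_start[i] <- sum(occ[1:16])
    step <- cycle_step(occ, base_mat[i, ], life_table_qx(lt, ages[i]),
                       modifiers, arm, cap = run$fracture_prob_cap,
                       excess_multiplier = run$excess_mort_multiplier,
                       attributable_fraction = run$excess_attributable_fraction)
    occ <- step$occupancy
    occ_hist[i + 1L, ] <- occ
    cyc[i, c("fx_hip", "fx_vertebral", "fx_wrist", "fx_other")] <- step$fractures
    cyc[i, c("fxs_hip", "fxs_vertebral", "fxs_wrist", "fxs_other")] <- step$fracture_survivors
    cyc$deaths[i] <- step$deaths
    cyc$alive_end[i] <- sum(occ[1:16])
    cyc$person_years[i] <- cyc$alive_end[i] + 0.5 * step$deaths
  }
  structure(list(cohort = cohort[c("sex", "age", "stratum", "size")], arm = arm,
                 cycles = cyc, occupancy = occ_hist,
                 initial_size = cohort$size),
            class = "cohort_trace")
}

#' Life-years lived by a projected cohort
#'
#' Sums the per-cycle person-years of a trace (one year per survivor, half a
#' year per within-cycle death), both undiscounted and discounted at
#' \code{rate} with cycle \code{t = 0} (the baseline year) undiscounted.
#'
#' @param trace a \code{cohort_trace}.
#' @param discount_rate annual discount rate, >= 0.
#' @return named list: \code{undiscounted}, \code{discounted} (years).
#' @export
life_years <- function(trace, discount_rate = 0.03) {
  if (discount_rate < 0) stop("'discount_rate' must be non-negative")
  ly <- trace$cycles$person_years
  t <- trace$cycles$t
  list(undiscounted = sum(ly),
       discounted = sum(ly / (1 + discount_rate)^t))
}
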