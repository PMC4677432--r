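# Individual-level Monte-Carlo implementation of the identical model,
# used to cross-validate the deterministic cohort engine. It shares the
# scenario parsing (calibrated baseline probabilities, life tables, cost
# inputs) but none of the cohort engine's transition code: per-person risk
# adjustment, event sampling and cost accrual are written independently here.

#' Individual-level microsimulation of one cohort
#'
#' Simulates \code{n} individuals of a cohort year by year under the same
#' contract as the cohort engine: at most one index fracture per
#' person-year, sampled with probability \code{min(sum of adjusted site
#' probabilities, cap)} and site allocation proportional to the per-site
#' probabilities; death sampled afterwards with the excess-adjusted
#' probability for persons fracturing the hip or a vertebra that year and
#' the background probability otherwise; half a person-year credited in the
#' year of death; identical cost rules (acute per fracture, hip first-year
#' extra for survivors, supplement per person-year in the intervention arm)
#' discounted at the cost rate.
#'
#' All uniform draws are taken from matrices indexed by (individual, cycle)
#' generated up front from the seed, so results do not depend on the order
#' in which individuals are processed.
#'
#' @param cohort list or one-row data frame (sex, age, stratum); the
#'   simulated size is \code{n}, not the cohort's population size.
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param scenario a scenario bundle (identical to the cohort engine's).
#' @param n number of simulated individuals, >= 1.
#' @param seed integer seed.
#' @return a \code{microsim_result}: list with \code{estimates} (data frame:
#'   metric, estimate, se, n — totals over the \code{n} individuals with
#'   their Monte-Carlo standard errors) and \code{arm}, \code{n},
#'   \code{seed}.
#' @export
microsim_run <- function(cohort, arm = c("control", "intervention"), scenario,
                         n = 10000L, seed = 1L) {
  arm <- match.arg(arm)
  cohort <- as.list(cohort)
  if (n < 1L) stop("'n' must be at least 1")
  max_age <- scenario$run$max_age
  lt <- scenario$life_tables[[cohort$sex]]
  ages <- cohort$age:max_age
  n_cyc <- length(ages)
  base_mat <- .stratum_base_matrix(scenario, cohort$sex, cohort$age,
                                   cohort$stratum, max_age)
  mods <- scenario$modifiers
  eff <- if (arm == "intervention") mods$efficacy_rr else
    stats::setNames(rep(1, 4), FX_SITES)
  cap <- scenario$run$fracture_prob_cap
  mult_eff <- 1 + scenario$run$excess_attributable_fraction *
    (scenario$run$excess_mort_multiplier - 1)
  sched <- scenario$cost
  price <- sched$supplement_annual_price
  r_cost <- sched$discount_rate_costs
  r_eff <- sched$discount_rate_effects

  u_fx <- .with_seed(seed, {
    list(fx = matrix(stats::runif(n * n_cyc), n, n_cyc),
         death = matrix(stats::runif(n * n_cyc), n, n_cyc))
  })
  u_death <- u_fx$death
  u_fx <- u_fx$fx

  # starting history: prevalent-fracture cohorts split hip/vertebral
  hist <- integer(n)
  if (cohort$stratum == "prevalent_fracture") {
    n_hip <- round_half_up(n * mods$pf_history_split[["hip"]])
    hist[seq_len(n_hip)] <- .site_bits[["hip"]]
    if (n_hip < n) hist[(n_hip + 1L):n] <- .site_bits[["vertebral"]]
  }
  alive <- rep(TRUE, n)
  fx_count <- matrix(0L, n, 4L, dimnames = list(NULL, FX_SITES))
  ly <- numeric(n); ly_disc <- numeric(n); cost_disc <- numeric(n)
  pending_extra <- logical(n)  # hip fracture survivors owe the extra next cycle

  for (i in seq_len(n_cyc)) {
    if (!any(alive)) break
    a <- ages[i]
    qx <- life_table_qx(lt, a)
    idx <- which(alive)
    h <- hist[idx]
    # per-person adjusted site probabilities (independent re-derivation)
    p <- matrix(0, length(idx), 4L)
    for (s in seq_along(FX_SITES)) {
      site <- FX_SITES[s]
      rr <- ifelse(bitwAnd(h, .site_bits[[site]]) > 0L, mods$prior_fx_rr[[site]], 1)
      p[, s] <- pmin(1, base_mat[i, site] * rr * eff[[site]])
    }
    tot <- rowSums(p)
    P <- pmin(tot, cap)
    cum <- p * ifelse(tot > 0, P / tot, 0)
    cum <- t(apply(cum, 1L, cumsum))
    u1 <- u_fx[idx, i]
    site_hit <- rowSums(u1 >= cbind(0, cum[, 1:3, drop = FALSE])) *
      (u1 < cum[, 4L])
    # site_hit: 0 = no fracture, 1..4 = fractured site
    fractured <- site_hit > 0L

    hip_cost <- predict_cost(sched$hip_curve, a)
    site_cost <- c(hip_cost, hip_cost * sched$nonhip_relative[c("vertebral", "wrist", "other")])
    disc_c <- (1 + r_cost)^(-(i - 1L))
    disc_e <- (1 + r_eff)^(-(i - 1L))

    # hip extra owed from last cycle's surviving hip fracturers
    owe <- which(pending_extra)
    if (length(owe)) {
      cost_disc[owe] <- cost_disc[owe] + sched$hip_extra_first_year * disc_c
      pending_extra[] <- FALSE
    }

    q_i <- ifelse(fractured & site_hit <= 2L, pmin(1, mult_eff * qx), qx)
    dies <- u_death[idx, i] < q_i
    py <- ifelse(dies, 0.5, 1)
    ly[idx] <- ly[idx] + py
    ly_disc[idx] <- ly_disc[idx] + py * disc_e

    if (any(fractured)) {
      fi <- which(fractured)
      fx_count[cbind(idx[fi], site_hit[fi])] <- fx_count[cbind(idx[fi], site_hit[fi])] + 1L
      cost_disc[idx[fi]] <- cost_disc[idx[fi]] + site_cost[site_hit[fi]] * disc_c
      hist[idx[fi]] <- bitwOr(hist[idx[fi]], .site_bits[site_hit[fi]])
      pending_extra[idx[fi][site_hit[fi] == 1L & !dies[fi]]] <- TRUE
    }
    if (arm == "intervention") {
      cost_disc[idx] <- cost_disc[idx] + price * py * disc_c
    }
    alive[idx[dies]] <- FALSE
    pending_extra[idx[dies]] <- FALSE
  }

  per_ind <- cbind(fx_count, fx_total = rowSums(fx_count), dead = 1,
                   ly = ly, ly_disc = ly_disc, cost_disc = cost_disc)
  colnames(per_ind)[1:4] <- paste0("fx_", FX_SITES)
  est <- data.frame(metric = colnames(per_ind),
                    estimate = colSums(per_ind),
                    se = apply(per_ind, 2L, stats::sd) * sqrt(n),
                    n = n, row.names = NULL)
  structure(list(estimates = est, arm = arm, n = n, seed = as.integer(seed),
                 cohort = cohort[c("sex", "age", "stratum")]),
            class = "microsim_result")
}

#' Cross-validate the cohort engine against the microsimulation
#'
#' Runs the deterministic cohort engine and the independent microsimulation
#' on the same cohort (size \code{n}) under the identical scenario bundle
#' and returns, per metric, the deterministic expectation, the Monte-Carlo
#' estimate with its standard error, and the z-score of their difference.
#'
#' @param cohort list or one-row data frame (sex, age, stratum); size is
#'   overridden by \code{n}.
#' @param arm arm to validate.
#' @param scenario a scenario bundle.
#' @param n number of simulated individuals.
#' @param seed integer seed for the microsimulation.
#' @return data frame: metric, cohort_engine, microsim, se, z.
#' @export
oracle_check <- function(cohort, arm = "control", scenario, n = 20000L, seed = 1L) {
  cohort <- as.list(cohort)
  cohort$size <- n
  trace <- run_cohort(cohort, arm, scenario)
  costs <- arm_costs(trace, scenario$cost)
  ly <- life_years(trace, scenario$cost$discount_rate_effects)
  cyc <- trace$cycles
  engine <- c(fx_hip = sum(cyc$fx_hip), fx_vertebral = sum(cyc$fx_vertebral),
              fx_wrist = sum(cyc$fx_wrist), fx_other = sum(cyc$fx_other),
              fx_total = sum(cyc[, paste0("fx_", FX_SITES)]),
              dead = sum(cyc$deaths),
              ly = ly$undiscounted, ly_disc = ly$discounted,
              cost_disc = costs$total)
  ms <- microsim_run(cohort, arm, scenario, n = n, seed = seed)
  est <- ms$estimates
  stopifnot(identical(est$metric, names(engine)))
  data.frame(metric = est$metric, cohort_engine = unname(engine),
             microsim = est$estimate, se = est$se,
             z = ifelse(est$se > 0, (unname(engine) - est$estimate) / est$se,
                        ifelse(abs(unname(engine) - est$estimate) < 1e-6, 0, Inf)))
}
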