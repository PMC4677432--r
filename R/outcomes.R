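# Arm comparison, incremental cost-effectiveness, price sweep, aggregation.

# Typed cost-effectiveness ratio: a ratio with a non-positive denominator is
# an outcome category, never a sentinel number.
.cer <- function(incremental_cost, effect) {
  if (effect > 0) {
    status <- if (incremental_cost <= 0) "cost_saving" else "defined"
    list(status = status, value = incremental_cost / effect)
  } else if (incremental_cost > 0) {
    list(status = "dominated", value = NA_real_)
  } else {
    list(status = "undefined", value = NA_real_)
  }
}

#' Compare the intervention and control arms of one cohort
#'
#' Incremental outcomes of supplementation versus no intervention for a
#' single cohort: fractures avoided (control minus intervention, per site
#' and total), life-years gained (discounted at the effects rate, and
#' undiscounted), incremental discounted cost, and the two ratios
#' cost-per-fracture-avoided and cost-per-life-year-gained. Ratios whose
#' denominator is non-positive are reported as typed outcomes
#' (\code{"cost_saving"}, \code{"dominated"}, \code{"undefined"}) with an
#' \code{NA} value rather than an infinite number; a cost-saving ratio keeps
#' its (non-positive) value for ordering purposes.
#'
#' @param intervention,control lists with elements \code{trace} (a
#'   \code{cohort_trace}) and \code{costs} (the matching
#'   \code{\link{arm_costs}} result), run on the identical cohort and
#'   inputs.
#' @param discount_rate_effects annual discount rate for life-years.
#' @param headline_discounted logical; if \code{TRUE} (default) the headline
#'   LYG denominator is the discounted one.
#' @return a \code{comparison_result}: list with \code{cohort},
#'   \code{fractures_avoided} (per site and \code{total}), \code{lyg}
#'   (\code{discounted}, \code{undiscounted}, \code{headline}),
#'   \code{incremental_cost}, \code{cost_per_fracture_avoided},
#'   \code{cost_per_lyg}, \code{price}.
#' @export
compare <- function(intervention, control, discount_rate_effects = 0.03,
                    headline_discounted = TRUE) {
  if (!identical(intervention$trace$cohort, control$trace$cohort)) {
    stop("intervention and control traces describe different cohorts")
  }
  if (intervention$trace$arm != "intervention" || control$trace$arm != "control") {
    stop("arms are mislabelled: expected an intervention and a control trace")
  }
  fx_cols <- paste0("fx_", FX_SITES)
  fx_int <- colSums(intervention$trace$cycles[, fx_cols])
  fx_ctl <- colSums(control$trace$cycles[, fx_cols])
  avoided <- stats::setNames(as.numeric(fx_ctl - fx_int), FX_SITES)
  ly_int <- life_years(intervention$trace, discount_rate_effects)
  ly_ctl <- life_years(control$trace, discount_rate_effects)
  lyg <- list(discounted = ly_int$discounted - ly_ctl$discounted,
              undiscounted = ly_int$undiscounted - ly_ctl$undiscounted)
  lyg$headline <- if (headline_discounted) lyg$discounted else lyg$undiscounted
  inc_cost <- intervention$costs$total - control$costs$total
  structure(list(cohort = intervention$trace$cohort,
                 fractures_avoided = c(avoided, total = sum(avoided)),
                 lyg = lyg,
                 incremental_cost = inc_cost,
                 cost_per_fracture_avoided = .cer(inc_cost, sum(avoided)),
                 cost_per_lyg = .cer(inc_cost, lyg$headline)),
            class = "comparison_result")
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(sex = x$cohort$sex, age = x$cohort$age, stratum = x$cohort$stratum,
             size = x$cohort$size,
             price = if (is.null(x$price)) NA_real_ else x$price,
             fx_avoided_hip = x$fractures_avoided[["hip"]],
             fx_avoided_vertebral = x$fractures_avoided[["vertebral"]],
             fx_avoided_wrist = x$fractures_avoided[["wrist"]],
             fx_avoided_other = x$fractures_avoided[["other"]],
             fx_avoided_total = x$fractures_avoided[["total"]],
             lyg_discounted = x$lyg$discounted,
             lyg_undiscounted = x$lyg$undiscounted,
             incremental_cost = x$incremental_cost,
             cost_per_fx_avoided = x$cost_per_fracture_avoided$value,
             cost_per_fx_avoided_status = x$cost_per_fracture_avoided$status,
             cost_per_lyg = x$cost_per_lyg$value,
             cost_per_lyg_status = x$cost_per_lyg$status,
             stringsAsFactors = FALSE)
}

#' Run both arms of one cohort
#'
#' @param cohort list or one-row data frame (sex, age, stratum, size).
#' @param scenario a scenario bundle.
#' @return list with \code{intervention} and \code{control} traces.
#' @export
run_cohort_pair <- function(cohort, scenario) {
  list(intervention = run_cohort(cohort, "intervention", scenario),
       control = run_cohort(cohort, "control", scenario))
}

#' Sweep the supplement price for one cohort
#'
#' The traces are computed once per arm; across prices only the supplement
#' cost term changes, so the incremental cost — and with it cost-per-LYG —
#' is affine in the price with slope equal to the intervention arm's
#' discounted person-years divided by the LYG.
#'
#' @param cohort list or one-row data frame (sex, age, stratum, size).
#' @param scenario a scenario bundle.
#' @param prices euros per person-year, at least one, all non-negative;
#'   defaults to the scenario's price grid.
#' @param arms optional precomputed \code{\link{run_cohort_pair}} result.
#' @return list of \code{comparison_result}, one per price, each with its
#'   \code{price} recorded.
#' @export
price_sweep <- function(cohort, scenario, prices = scenario$run$prices,
                        arms = NULL) {
  if (length(prices) < 1L) stop("at least one price is required")
  if (any(prices < 0)) stop("prices must be non-negative")
  if (is.null(arms)) arms <- run_cohort_pair(cohort, scenario)
  sched <- scenario$cost
  ctl <- list(trace = arms$control, costs = arm_costs(arms$control, sched))
  lapply(prices, function(p) {
    int <- list(trace = arms$intervention,
                costs = arm_costs(arms$intervention, sched, supplement_price = p))
    res <- compare(int, ctl,
                   discount_rate_effects = sched$discount_rate_effects,
                   headline_discounted = scenario$run$headline_discounted)
    res$price <- p
    res
  })
}

#' Compare every cohort of a scenario at one price
#'
#' @param scenario a scenario bundle.
#' @param price euros per person-year; defaults to the schedule's.
#' @param cohorts optional cohort data frame subset (defaults to all 24).
#' @return data frame, one row per cohort, with incremental outcomes and
#'   typed ratios (see \code{\link{as.data.frame.comparison_result}}).
#' @export
compare_all_cohorts <- function(scenario,
                                price = scenario$cost$supplement_annual_price,
                                cohorts = scenario_cohorts(scenario)) {
  rows <- lapply(seq_len(nrow(cohorts)), function(i) {
    res <- price_sweep(cohorts[i, ], scenario, prices = price)[[1]]
    as.data.frame(res)
  })
  do.call(rbind, rows)
}

#' Aggregate incremental outcomes across cohorts
#'
#' Sums fractures avoided and life-years gained over cohorts, per sex and
#' overall. Cohort identifiers (sex:age:stratum) must be unique.
#'
#' @param results data frame as returned by \code{\link{compare_all_cohorts}}
#'   (or a list of \code{comparison_result} objects).
#' @return data frame with one row per sex plus an \code{"overall"} row:
#'   fractures avoided (total), LYG discounted and undiscounted.
#' @export
aggregate_results <- function(results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  id <- paste(results$sex, results$age, results$stratum, sep = ":")
  if (anyDuplicated(id)) {
    stop("duplicate cohort id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  one <- function(d, label) {
    data.frame(group = label,
               fx_avoided_total = sum(d$fx_avoided_total),
               lyg_discounted = sum(d$lyg_discounted),
               lyg_undiscounted = sum(d$lyg_undiscounted))
  }
  out <- do.call(rbind, lapply(split(results, results$sex),
                               function(d) one(d, d$sex[1])))
  out <- rbind(out, one(results, "overall"))
  rownames(out) <- NULL
  out
}
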