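# Fracture and supplementation costs, cost-curve interpolation, discounting.

#' Fit an age-to-cost interpolation curve
#'
#' Turns a handful of age-cost anchors into a smooth age-specific cost:
#' either a power law (ordinary least squares of log(cost) on log(age),
#' evaluated as \eqn{e^{a} \cdot age^{b}}) or a degree-2 polynomial in age
#' (least squares, evaluation clamped at zero).
#'
#' @param anchors data frame with columns \code{age} and \code{cost}
#'   (distinct ages; at least 2 for \code{"power"}, 3 for \code{"poly2"};
#'   strictly positive costs for the power family).
#' @param family \code{"power"} or \code{"poly2"}.
#' @return a \code{cost_curve} object.
#' @examples
#' fit_cost_curve(data.frame(age = c(50, 70, 90), cost = 2 * c(50, 70, 90)^1.5))
#' @export
fit_cost_curve <- function(anchors, family = c("power", "poly2")) {
  family <- match.arg(family)
  if (anyDuplicated(anchors$age)) stop("anchor ages must be distinct")
  if (family == "power") {
    if (nrow(anchors) < 2L) stop("power interpolation needs at least 2 anchors")
    if (any(anchors$cost <= 0)) {
      stop("power interpolation requires strictly positive costs")
    }
    fit <- stats::lm(log(cost) ~ log(age), data = anchors)
    coef <- stats::coef(fit)
    structure(list(family = "power", log_scale = unname(coef[1]),
                   exponent = unname(coef[2])), class = "cost_curve")
  } else {
    if (nrow(anchors) < 3L) stop("quadratic interpolation needs at least 3 anchors")
    fit <- stats::lm(cost ~ age + I(age^2), data = anchors)
    structure(list(family = "poly2", coef = unname(stats::coef(fit))),
              class = "cost_curve")
  }
}

#' Evaluate a cost curve
#'
#' @param curve a \code{cost_curve}.
#' @param age age vector.
#' @return non-negative costs.
#' @export
predict_cost <- function(curve, age) {
  if (curve$family == "power") {
    exp(curve$log_scale) * age^curve$exponent
  } else {
    pmax(0, curve$coef[1] + curve$coef[2] * age + curve$coef[3] * age^2)
  }
}

#' Present value of a future amount
#'
#' @param amount amount in euros.
#' @param cycle integer cycle index, >= 0 (0 = baseline year, undiscounted).
#' @param rate annual discount rate, >= 0.
#' @return \code{amount / (1 + rate)^cycle}.
#' @export
discount <- function(amount, cycle, rate) {
  if (rate < 0) stop("'rate' must be non-negative")
  if (any(cycle < 0)) stop("'cycle' must be non-negative")
  amount * (1 + rate)^(-cycle)
}

#' Cost schedule of the evaluation
#'
#' Bundles every cost input: age anchors for the acute hospitalization cost
#' of a hip fracture (interpolated by \code{\link{fit_cost_curve}}), the
#' extra cost in the year following a hip fracture, non-hip acute costs as
#' fractions of the hip acute cost, the annual supplement price, and the
#' discount rates for costs and health effects (both default 3\% per annum).
#' Wrist and "other" fractures carry no cost beyond the event year; hip
#' carries only its first-year extra by default (a long-term annual hip cost
#' parameter exists, default 0).
#'
#' @param hip_cost_anchors data frame (age, cost in euros).
#' @param hip_extra_first_year euros, applied one cycle after the fracture
#'   to hip fracturers who survive the fracture cycle.
#' @param nonhip_relative named fractions of the hip acute cost for
#'   vertebral, wrist, other.
#' @param supplement_annual_price euros per person-year in the intervention
#'   arm (default 250, conventionally swept over 150-350).
#' @param discount_rate_costs,discount_rate_effects annual rates (>= 0).
#' @param cost_curve_family \code{"power"} or \code{"poly2"}.
#' @param hip_longterm_annual euros per year beyond the first post-fracture
#'   year; default 0 (not part of the base case).
#' @return a \code{cost_schedule} with the fitted hip cost curve attached.
#' @export
cost_schedule <- function(hip_cost_anchors,
                          hip_extra_first_year,
                          nonhip_relative = c(vertebral = 0.25, wrist = 0.12,
                                              other = 0.20),
                          supplement_annual_price = 250,
                          discount_rate_costs = 0.03,
                          discount_rate_effects = 0.03,
                          cost_curve_family = c("power", "poly2"),
                          hip_longterm_annual = 0) {
  cost_curve_family <- match.arg(cost_curve_family)
  nonhip_relative <- nonhip_relative[c("vertebral", "wrist", "other")]
  if (anyNA(nonhip_relative) || any(nonhip_relative < 0)) {
    stop("'nonhip_relative' must be non-negative for vertebral, wrist and other")
  }
  if (hip_extra_first_year < 0 || supplement_annual_price < 0 ||
      hip_longterm_annual < 0 || any(hip_cost_anchors$cost < 0)) {
    stop("costs must be non-negative")
  }
  if (discount_rate_costs < 0 || discount_rate_effects < 0) {
    stop("discount rates must be non-negative")
  }
  structure(list(hip_cost_anchors = hip_cost_anchors,
                 hip_curve = fit_cost_curve(hip_cost_anchors, cost_curve_family),
                 hip_extra_first_year = hip_extra_first_year,
                 nonhip_relative = nonhip_relative,
                 supplement_annual_price = supplement_annual_price,
                 discount_rate_costs = discount_rate_costs,
                 discount_rate_effects = discount_rate_effects,
                 cost_curve_family = cost_curve_family,
                 hip_longterm_annual = hip_longterm_annual),
            class = "cost_schedule")
}

#' Direct medical costs of one projected arm
#'
#' Assembles the discounted direct-cost stream of a cohort trace: per cycle,
#' acute fracture costs (per-site flows times the age-specific site cost),
#' the extra hip cost applied one cycle after the fracture to surviving hip
#' fracturers, and — in the intervention arm only — the supplement price
#' times the person-years lived that cycle. Everything is discounted at the
#' cost rate with \code{t = 0} undiscounted.
#'
#' @param trace a \code{cohort_trace}.
#' @param schedule a \code{cost_schedule}.
#' @param arm arm the costs are assembled for; defaults to the trace's own.
#' @param supplement_price optional price override (euros per person-year),
#'   used by the price sweep.
#' @return list with \code{total} (discounted euros), \code{undiscounted},
#'   and \code{by_cycle} (data frame: t, age, acute, hip_extra, supplement,
#'   total, discounted).
#' @export
arm_costs <- function(trace, schedule, arm = trace$arm,
                      supplement_price = schedule$supplement_annual_price) {
  cyc <- trace$cycles
  hip_cost <- predict_cost(schedule$hip_curve, cyc$age)
  site_cost <- cbind(hip = hip_cost,
                     vertebral = hip_cost * schedule$nonhip_relative[["vertebral"]],
                     wrist = hip_cost * schedule$nonhip_relative[["wrist"]],
                     other = hip_cost * schedule$nonhip_relative[["other"]])
  flows <- as.matrix(cyc[, c("fx_hip", "fx_vertebral", "fx_wrist", "fx_other")])
  acute <- rowSums(flows * site_cost)
  # first-year extra lands one cycle after the fracture, on survivors only
  hip_extra <- c(0, cyc$fxs_hip[-nrow(cyc)]) * schedule$hip_extra_first_year
  if (schedule$hip_longterm_annual > 0) {
    # survivors carrying a hip history beyond the first post-fracture year
    hip_state <- rowSums(trace$occupancy[-1, which(state_space()$hip), drop = FALSE])
    hip_extra <- hip_extra + pmax(0, hip_state - c(0, cyc$fxs_hip[-nrow(cyc)])) *
      schedule$hip_longterm_annual
  }
  supplement <- if (identical(arm, "intervention")) {
    supplement_price * cyc$person_years
  } else {
    numeric(nrow(cyc))
  }
  total <- acute + hip_extra + supplement
  disc <- discount(total, cyc$t, schedule$discount_rate_costs)
  list(total = sum(disc), undiscounted = sum(total),
       by_cycle = data.frame(t = cyc$t, age = cyc$age, acute = acute,
                             hip_extra = hip_extra, supplement = supplement,
                             total = total, discounted = disc))
}
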