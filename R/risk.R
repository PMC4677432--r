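# Fracture-risk model: incidence curves, hip->non-hip expansion, stratum
# calibration, and per-person risk adjustment.

#' Relative-risk modifiers of annual fracture probabilities
#'
#' Bundles the three multiplicative layers acting on the population incidence
#' curves:
#' \itemize{
#'   \item \code{prior_fx_rr}: elevation for persons with a prior fracture at
#'     the \emph{same} site (defaults 2.3 hip, 4.4 vertebral, 3.3 wrist,
#'     1.9 other). Cross-site elevation is not modelled.
#'   \item \code{stratum_rr}: per-site baseline elevation of the
#'     osteoporosis and prevalent-fracture strata relative to the general
#'     stratum. The prevalent-fracture stratum lies within the osteoporotic
#'     population, so by default it shares the osteoporosis elevation; its
#'     additional risk comes from its starting fracture history, not from a
#'     further stratum multiplier.
#'   \item \code{efficacy_rr}: supplementation effect, applied in the
#'     intervention arm from the first cycle for the remaining lifetime
#'     (defaults 0.82 hip, 0.87 vertebral, 0.80 wrist and other).
#' }
#' \code{pf_history_split} gives the composition of the prevalent-fracture
#' stratum by prior site (default 50/50 hip/vertebral).
#'
#' @param prior_fx_rr named numeric, one RR per site, all > 0.
#' @param osteoporosis_rr per-site RR of the osteoporosis stratum (recycled
#'   to the four sites).
#' @param prevalent_fracture_rr per-site baseline RR of the
#'   prevalent-fracture stratum, \emph{excluding} the history effect.
#' @param efficacy_rr named numeric, one RR per site, > 0 and <= 1 in the
#'   base case.
#' @param pf_history_split named numeric over \code{c("hip", "vertebral")},
#'   non-negative, summing to 1.
#' @return object of class \code{risk_modifiers}.
#' @export
risk_modifiers <- function(prior_fx_rr = c(hip = 2.3, vertebral = 4.4,
                                           wrist = 3.3, other = 1.9),
                           osteoporosis_rr = 2.0,
                           prevalent_fracture_rr = 2.0,
                           efficacy_rr = c(hip = 0.82, vertebral = 0.87,
                                           wrist = 0.80, other = 0.80),
                           pf_history_split = c(hip = 0.5, vertebral = 0.5)) {
  as_site_vec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, 4L)
    if (is.null(names(x))) names(x) <- FX_SITES
    x <- x[FX_SITES]
    if (anyNA(x) || any(x <= 0)) stop(sprintf("'%s' must be positive for every site", nm))
    x
  }
  prior_fx_rr <- as_site_vec(prior_fx_rr, "prior_fx_rr")
  efficacy_rr <- as_site_vec(efficacy_rr, "efficacy_rr")
  stratum_rr <- rbind(general = rep(1, 4L),
                      osteoporosis = as_site_vec(osteoporosis_rr, "osteoporosis_rr"),
                      prevalent_fracture = as_site_vec(prevalent_fracture_rr,
                                                       "prevalent_fracture_rr"))
  colnames(stratum_rr) <- FX_SITES
  pf_history_split <- pf_history_split[c("hip", "vertebral")]
  if (anyNA(pf_history_split) || any(pf_history_split < 0) ||
      abs(sum(pf_history_split) - 1) > 1e-9) {
    stop("'pf_history_split' must be non-negative over hip/vertebral and sum to 1")
  }
  structure(list(prior_fx_rr = prior_fx_rr, stratum_rr = stratum_rr,
                 efficacy_rr = efficacy_rr, pf_history_split = pf_history_split),
            class = "risk_modifiers")
}

#' Effective per-site stratum relative risks
#'
#' The stratum RR actually borne by an average member of each stratum,
#' including the starting-history effect of the prevalent-fracture stratum:
#' for a site \eqn{s}, a fraction of that stratum carries a prior fracture at
#' \eqn{s} and is further elevated by the prior-fracture RR. These effective
#' RRs are what the stratum-mixture calibration must use for the weighted
#' mixture to reproduce the population curve.
#'
#' @param modifiers a \code{risk_modifiers} object.
#' @return 3 x 4 matrix (stratum x site) of effective RRs.
#' @export
effective_stratum_rr <- function(modifiers) {
  eff <- modifiers$stratum_rr
  split <- modifiers$pf_history_split
  hist_factor <- rep(1, 4L)
  names(hist_factor) <- FX_SITES
  hist_factor["hip"] <- split["hip"] * modifiers$prior_fx_rr["hip"] +
    (1 - split["hip"])
  hist_factor["vertebral"] <- split["vertebral"] * modifiers$prior_fx_rr["vertebral"] +
    (1 - split["vertebral"])
  eff["prevalent_fracture", ] <- eff["prevalent_fracture", ] * hist_factor
  eff
}

#' Fit a log-linear (exponential) incidence curve
#'
#' Ordinary least squares of log(probability) on age, the standard
#' exponential interpolation used to turn a handful of age anchors into an
#' age-specific annual fracture probability. Evaluation exponentiates the
#' linear predictor and caps at 1.
#'
#' @param anchors data frame with columns \code{age} and \code{probability}
#'   (at least two rows, probabilities strictly in (0, 1), ages distinct).
#' @param sex,site labels carried on the result.
#' @return an \code{incidence_curve}: list with \code{intercept},
#'   \code{slope} (per year of age, on the log scale) and \code{domain}.
#' @examples
#' fit_exponential_curve(data.frame(age = c(50, 60), probability = c(0.001, 0.002)))
#' @export
fit_exponential_curve <- function(anchors, sex = NA_character_, site = NA_character_) {
  if (nrow(anchors) < 2L) stop("exponential interpolation needs at least 2 anchors")
  if (anyDuplicated(anchors$age)) stop("anchor ages must be distinct")
  if (any(anchors$probability <= 0)) {
    stop("anchor probabilities must be positive (log undefined at 0)")
  }
  if (any(anchors$probability >= 1)) stop("anchor probabilities must be below 1")
  fit <- stats::lm(log(probability) ~ age, data = anchors)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 domain = c(50, Inf), sex = sex, site = site),
            class = "incidence_curve")
}

#' Evaluate an incidence curve
#'
#' @param curve an \code{incidence_curve} or \code{piecewise_incidence_curve}.
#' @param age vector of ages.
#' @return annual probabilities, capped at 1.
#' @export
predict_incidence <- function(curve, age) {
  UseMethod("predict_incidence")
}

#' @export
predict_incidence.incidence_curve <- function(curve, age) {
  pmin(1, exp(curve$intercept + curve$slope * age))
}

#' @export
predict_incidence.piecewise_incidence_curve <- function(curve, age) {
  band <- findInterval(age, curve$breaks)
  if (any(band == 0L | band > nrow(curve$coef))) {
    stop("age outside the banded domain of the curve")
  }
  pmin(1, exp(curve$coef[band, "intercept"] + curve$coef[band, "slope"] * age))
}

#' Banded site-to-hip incidence ratios
#'
#' Ratios of non-hip site incidence to hip incidence by age band, in the
#' style of register-based ratio tables. Bands are left-closed:
#' \code{band_start[i]} up to (but excluding) \code{band_start[i+1]}; the
#' last band is open-ended.
#'
#' @param band_start increasing vector of band lower edges (first <= 50).
#' @param vertebral,wrist,other non-negative ratio vectors, one per band.
#' @return object of class \code{hip_ratio_table}.
#' @export
hip_ratio_table <- function(band_start, vertebral, wrist, other) {
  if (is.unsorted(band_start, strictly = TRUE)) {
    stop("'band_start' must be strictly increasing")
  }
  if (band_start[1] > 50) stop("first band must start at or below age 50")
  m <- cbind(vertebral = vertebral, wrist = wrist, other = other)
  if (nrow(m) != length(band_start)) stop("one ratio per band per site required")
  if (any(m < 0)) stop("ratios must be non-negative")
  structure(list(band_start = band_start, ratios = m), class = "hip_ratio_table")
}

#' Look up a site-to-hip ratio
#'
#' @param ratios a \code{hip_ratio_table}.
#' @param age age vector.
#' @param site one non-hip site.
#' @return ratio vector.
#' @export
ratio_at <- function(ratios, age, site) {
  site <- match.arg(site, c("vertebral", "wrist", "other"))
  band <- findInterval(age, ratios$band_start)
  if (any(band == 0L)) stop("no ratio band covers age(s) below ", ratios$band_start[1])
  ratios$ratios[band, site]
}

#' Derive non-hip incidence curves from the hip curve
#'
#' Multiplies the hip curve by the banded site-to-hip ratios at every integer
#' age of the domain and refits a log-linear curve within each band, so the
#' derived curves remain exponential-in-age piecewise. Because the hip curve
#' is log-linear and the ratio is constant within a band, the refit passes
#' exactly through the derived points.
#'
#' @param hip_curve an \code{incidence_curve} for hip.
#' @param ratios a \code{hip_ratio_table}.
#' @param domain integer age range covered, default 50:105.
#' @return named list of \code{piecewise_incidence_curve}, one per non-hip site.
#' @export
expand_to_nonhip <- function(hip_curve, ratios, domain = 50:105) {
  breaks <- ratios$band_start
  lapply(stats::setNames(nm = c("vertebral", "wrist", "other")), function(site) {
    coef <- t(vapply(seq_along(breaks), function(b) {
      lo <- breaks[b]
      hi <- if (b < length(breaks)) breaks[b + 1] - 1L else max(domain)
      ages <- domain[domain >= lo & domain <= hi]
      p <- predict_incidence(hip_curve, ages) * ratio_at(ratios, ages, site)
      p <- pmin(1, p)
      if (length(ages) >= 2L && all(p > 0) && all(p < 1)) {
        f <- stats::lm(log(p) ~ ages)
        c(intercept = unname(stats::coef(f)[1]), slope = unname(stats::coef(f)[2]))
      } else if (all(p > 0)) {
        # degenerate band (single age or capped values): flat at the mean log
        c(intercept = mean(log(p)), slope = 0)
      } else {
        c(intercept = -Inf, slope = 0)
      }
    }, numeric(2)))
    structure(list(breaks = breaks, coef = coef, sex = hip_curve$sex, site = site),
              class = "piecewise_incidence_curve")
  })
}

#' Calibrate stratum-specific incidence to the population curve
#'
#' Splits a population annual fracture probability into stratum-specific
#' baselines so that the prevalence-weighted mixture of strata reproduces the
#' population value:
#' \deqn{p_{gen} = p_{pop} / (w_{gen} + w_{op} RR_{op} + w_{pf} RR_{pf})}
#' with the other strata at \eqn{p_{gen}} times their effective RR. The
#' weights are the stratum prevalences at the cohort's baseline age and are
#' held fixed over the projection.
#'
#' @param p_pop population annual probability (scalar or per-site vector).
#' @param weights named numeric over \code{STRATA}, summing to ~1, all >= 0.
#' @param rr_op,rr_pf effective stratum RRs (scalars or per-site vectors
#'   aligned with \code{p_pop}).
#' @return list with one element per stratum of annual probabilities at the
#'   same shape as \code{p_pop}.
#' @export
calibrate_stratum_incidence <- function(p_pop, weights, rr_op, rr_pf) {
  w <- weights[STRATA]
  if (anyNA(w) || any(w < 0)) stop("'weights' must be non-negative over all strata")
  denom <- w[["general"]] + w[["osteoporosis"]] * rr_op + w[["prevalent_fracture"]] * rr_pf
  if (any(denom <= 0)) stop("calibration denominator must be positive")
  p_gen <- p_pop / denom
  list(general = p_gen, osteoporosis = p_gen * rr_op, prevalent_fracture = p_gen * rr_pf)
}

#' Adjust a baseline fracture probability for history and arm
#'
#' Applies the same-site prior-fracture RR when the site is in the person's
#' fracture history, and the supplementation efficacy RR in the intervention
#' arm; the result is capped at 1. The stratum RR is already embedded in the
#' stratum-specific baseline and is not reapplied here.
#'
#' @param base baseline annual probability in [0, 1].
#' @param site one of \code{FX_SITES}.
#' @param history character vector of sites previously fractured.
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param modifiers a \code{risk_modifiers} object.
#' @return adjusted annual probability in [0, 1].
#' @export
adjusted_fracture_probability <- function(base, site, history = character(),
                                          arm = c("control", "intervention"),
                                          modifiers = risk_modifiers()) {
  arm <- match.arg(arm)
  site <- match.arg(site, FX_SITES)
  if (any(base < 0 | base > 1)) stop("'base' must lie in [0, 1]")
  p <- base
  if (site %in% history) p <- p * modifiers$prior_fx_rr[[site]]
  if (arm == "intervention") p <- p * modifiers$efficacy_rr[[site]]
  pmin(1, p)
}
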