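#' Estimate per-arm cumulative incidence curves
#'
#' Converts a fitted discrete-time hazard into cumulative incidence:
#' `R_a(t) = 1 - prod_{k <= t} (1 - h_a(k))`, with the risk difference
#' `RD(t) = R_1(t) - R_0(t)` and risk ratio `RR(t) = R_1(t) / R_0(t)`
#' (reported only at months where `R_0(t) > 0`).
#'
#' With the `"rcs"` time basis the model of [fit_pooled_logistic()] is
#' fitted (or a pre-fitted model supplied); under inverse probability
#' weighting the marginal risks are read directly off the weighted
#' treatment-by-time model. In `covariates_in_model` mode risks are
#' standardized: each individual's covariate profile is pushed through the
#' model under both counterfactual arms and the per-person cumulative
#' incidences are averaged over the cohort. With the `"saturated"` basis
#' the maximum-likelihood cell hazards have the closed form
#' `sum(w Y) / sum(w)` per (arm, month) cell, which is used directly.
#'
#' @param rows Person-month rows (deviation rows `C == 1` are dropped).
#' @param spec An [outcome_model_spec()].
#' @param weights Per-row weights (default 1).
#' @param fit Optional pre-fitted `pooled_logistic`.
#' @return A `risk_curve` data frame: `month`, `h1`, `h0`, `R1`, `R0`,
#'   `RD`, `RR`; the fitted model (if any) is attached as attribute
#'   `"fit"`.
#' @export
estimate_risk_curves <- function(rows, spec = outcome_model_spec(),
                                 weights = NULL, fit = NULL) {
  horizon <- spec$horizon
  if ("C" %in% names(rows)) {
    keep <- rows$C == 0
    if (!is.null(weights)) weights <- weights[keep]
    rows <- rows[keep, , drop = FALSE]
  }
  if (is.null(weights)) weights <- rep(1, nrow(rows))

  if (spec$time_basis == "saturated") {
    h <- matrix(0, horizon, 2)  # columns: untreated, treated
    for (a in 0:1) {
      sel <- rows$treated == a
      ev <- tapply(weights[sel] * rows$Y[sel], rows$month[sel], sum)
      at <- tapply(weights[sel], rows$month[sel], sum)
      m <- as.integer(names(at))
      h[m[m <= horizon], a + 1] <- (ev / at)[m <= horizon]
    }
    return(make_risk_curve(h[, 2], h[, 1]))
  }

  if (is.null(fit)) {
    fit <- fit_pooled_logistic(rows, spec, weights = weights)
  }
  grid <- seq_len(horizon)
  if (spec$adjustment == "covariates_in_model" && length(spec$covariates)) {
    # standardize over the cohort's covariate distribution
    base <- rows[!duplicated(rows$person_id), , drop = FALSE]
    n <- nrow(base)
    risk_arm <- function(a) {
      surv <- rep(1, n)
      risks <- numeric(horizon)
      for (t in grid) {
        h_t <- predict_hazard(fit, rep(t, n), rep(a, n),
                              base[, spec$covariates, drop = FALSE])
        surv <- surv * (1 - h_t)
        risks[t] <- 1 - mean(surv)
      }
      risks
    }
    R1 <- risk_arm(1); R0 <- risk_arm(0)
    h1 <- 1 - (1 - R1) / c(1, 1 - R1[-horizon])
    h0 <- 1 - (1 - R0) / c(1, 1 - R0[-horizon])
    out <- make_risk_curve(h1, h0, R1 = R1, R0 = R0)
  } else {
    h1 <- predict_hazard(fit, grid, rep(1, horizon))
    h0 <- predict_hazard(fit, grid, rep(0, horizon))
    out <- make_risk_curve(h1, h0)
  }
  attr(out, "fit") <- fit
  out
}

make_risk_curve <- function(h1, h0, R1 = NULL, R0 = NULL) {
  horizon <- length(h1)
  if (is.null(R1)) R1 <- 1 - cumprod(1 - h1)
  if (is.null(R0)) R0 <- 1 - cumprod(1 - h0)
  rr <- ifelse(R0 > 0, R1 / R0, NA_real_)
  structure(data.frame(month = seq_len(horizon), h1 = h1, h0 = h0,
                       R1 = R1, R0 = R0, RD = R1 - R0, RR = rr),
            class = c("risk_curve", "data.frame"))
}

#' Discrete-time Kaplan-Meier curve on the monthly grid
#'
#' Product-limit estimator over person-month rows, with optional weights
#' (weighted risk-set and event sums): the monthly hazard in each arm is
#' the weighted share of at-risk rows with an event, and survival is the
#' running product of its complement. Months with an empty risk set carry
#' the curve forward flat.
#'
#' @param rows Person-month rows with `treated`, `month`, `Y` (deviation
#'   rows `C == 1` are dropped first).
#' @param weights Optional per-row weights.
#' @param horizon Months (default: maximum observed month).
#' @return A `risk_curve` data frame as in [estimate_risk_curves()].
#' @export
km_curve <- function(rows, weights = NULL, horizon = max(rows$month)) {
  if ("C" %in% names(rows)) {
    keep <- rows$C == 0
    if (!is.null(weights)) weights <- weights[keep]
    rows <- rows[keep, , drop = FALSE]
  }
  if (is.null(weights)) weights <- rep(1, nrow(rows))
  h <- matrix(0, horizon, 2)
  for (a in 0:1) {
    sel <- rows$treated == a
    if (!any(sel)) stop("no person-months in arm treated = ", a,
                        call. = FALSE)
    ev <- tapply(weights[sel] * rows$Y[sel], rows$month[sel], sum)
    at <- tapply(weights[sel], rows$month[sel], sum)
    m <- as.integer(names(at))
    ok <- m <= horizon & at > 0
    h[m[ok], a + 1] <- ev[ok] / at[ok]
  }
  make_risk_curve(h[, 2], h[, 1])
}
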