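#' Restricted cubic spline basis
#'
#' Standard restricted (natural) cubic spline basis with `K` knots: a linear
#' term plus `K - 2` nonlinear terms that are cubic between the boundary
#' knots and linear beyond them,
#' `term_j(t) = [(t - k_j)+^3 - (t - k_{K-1})+^3 (k_K - k_j)/(k_K - k_{K-1})
#'   + (t - k_K)+^3 (k_{K-1} - k_j)/(k_K - k_{K-1})] / (k_K - k_1)^2`.
#' The squared-range divisor is a normalization convention; any full-rank
#' version of this basis yields identical fitted hazards.
#'
#' @param t Numeric vector of evaluation points (months).
#' @param knots Strictly increasing knot vector, length >= 3; the default
#'   places knots at 6, 12, 24 and 48 months.
#' @return Matrix with `length(t)` rows and `length(knots) - 1` columns
#'   (`t1` the linear term, then the nonlinear terms).
#' @export
rcs_basis <- function(t, knots = c(6, 12, 24, 48)) {
  K <- length(knots)
  if (K < 3 || is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing with at least 3 values",
         call. = FALSE)
  }
  pos3 <- function(x) pmax(x, 0)^3
  kK <- knots[K]; kK1 <- knots[K - 1]
  norm <- (kK - knots[1])^2
  out <- matrix(0, length(t), K - 1)
  out[, 1] <- t
  for (j in seq_len(K - 2)) {
    kj <- knots[j]
    out[, j + 1] <- (pos3(t - kj) -
                       pos3(t - kK1) * (kK - kj) / (kK - kK1) +
                       pos3(t - kK) * (kK1 - kj) / (kK - kK1)) / norm
  }
  colnames(out) <- paste0("t", seq_len(K - 1))
  out
}

#' Outcome model specification
#'
#' Describes the discrete-time pooled logistic hazard model: how follow-up
#' time enters (restricted cubic spline with the given knots, or a
#' saturated month-indicator basis), whether the treatment indicator
#' interacts with the time terms, and how confounding is adjusted.
#'
#' @param knots Spline knots in months (default 6, 12, 24, 48).
#' @param time_basis `"rcs"` or `"saturated"`.
#' @param interaction Include treatment-by-time product terms.
#' @param adjustment `"ipw"` (inverse probability weights; the model itself
#'   carries only treatment and time), `"covariates_in_model"` (covariates
#'   enter the outcome model and risks are standardized over the cohort),
#'   `"age_sex_only"` (weights from an age- and sex-only model) or
#'   `"unadjusted"`.
#' @param outcome Outcome the person-months were expanded for.
#' @param horizon Months; must reach past the last knot.
#' @param covariates Covariate column names (used by the
#'   `covariates_in_model` mode).
#' @return A list of class `outcome_model_spec`.
#' @export
outcome_model_spec <- function(knots = c(6, 12, 24, 48),
                               time_basis = c("rcs", "saturated"),
                               interaction = TRUE,
                               adjustment = c("ipw", "covariates_in_model",
                                              "age_sex_only", "unadjusted"),
                               outcome = c("composite", "death", "mi", "hf"),
                               horizon = 60L, covariates = character(0)) {
  time_basis <- match.arg(time_basis)
  if (time_basis == "rcs") {
    if (length(knots) < 3 || is.unsorted(knots, strictly = TRUE)) {
      stop("knots must be strictly increasing with at least 3 values",
           call. = FALSE)
    }
    if (horizon < knots[length(knots)]) {
      stop("horizon must reach the last knot", call. = FALSE)
    }
  }
  structure(list(knots = knots, time_basis = time_basis,
                 interaction = interaction,
                 adjustment = match.arg(adjustment),
                 outcome = match.arg(outcome), horizon = as.integer(horizon),
                 covariates = covariates),
            class = "outcome_model_spec")
}

# Design matrix for the outcome (or censoring) model. `data` must carry
# `month` and, unless intercept_only, `treated`.
outcome_design <- function(data, spec, include_treatment = TRUE) {
  tb <- rcs_basis(data$month, spec$knots)
  X <- cbind(`(Intercept)` = 1, tb)
  if (include_treatment) {
    X <- cbind(X, treated = data$treated)
    if (spec$interaction) {
      inter <- tb * data$treated
      colnames(inter) <- paste0("treated:", colnames(tb))
      X <- cbind(X, inter)
    }
  }
  if (length(spec$covariates)) {
    fm <- stats::as.formula(paste("~", paste(spec$covariates,
                                             collapse = " + ")))
    mm <- stats::model.matrix(fm, data)
    X <- cbind(X, mm[, -1, drop = FALSE])
  }
  X
}

#' Fit a weighted pooled logistic hazard model
#'
#' Maximizes the weighted Bernoulli log-likelihood over person-month rows
#' (iteratively reweighted least squares with a quasi-binomial family, so
#' non-integer inverse probability weights are legitimate). Columns that
#' are collinear are dropped with a record in the design ledger; perfect
#' separation or non-convergence is flagged, never silently returned.
#'
#' @param rows Person-month data (deviation rows `C == 1` are excluded).
#' @param spec An [outcome_model_spec()].
#' @param weights Per-row weights (default 1).
#' @param include_treatment Include treatment (and interaction) terms.
#' @return A list of class `pooled_logistic` with `coef`, `converged`,
#'   `iter`, `design_columns`, `dropped_columns`, `n_rows`, `n_events` and
#'   the spec.
#' @export
fit_pooled_logistic <- function(rows, spec = outcome_model_spec(),
                                weights = NULL, include_treatment = TRUE) {
  if ("C" %in% names(rows)) {
    keep <- rows$C == 0
    rows <- rows[keep, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (is.null(weights)) weights <- rep(1, nrow(rows))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  y <- rows$Y
  if (sum(y) < 1) stop("no events in the person-month data", call. = FALSE)
  if (include_treatment && spec$time_basis == "saturated") {
    # saturated fit handled in closed form by estimate_risk_curves()
    stop("use estimate_risk_curves() directly for the saturated basis",
         call. = FALSE)
  }
  X <- outcome_design(rows, spec, include_treatment)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep_cols]
    X <- X[, keep_cols, drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = weights,
                   family = stats::quasibinomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  eta <- drop(X %*% fit$coefficients)
  separated <- any(abs(eta) > 30 & (y == (eta > 0)))
  if (!fit$converged || separated) {
    warning("pooled logistic fit did not converge cleanly",
            if (separated) " (possible separation)" else "")
  }
  structure(list(coef = stats::setNames(fit$coefficients, colnames(X)),
                 converged = fit$converged && !separated,
                 iter = fit$iter, design_columns = colnames(X),
                 dropped_columns = dropped, n_rows = nrow(rows),
                 n_events = sum(y),
                 sum_events_weighted = sum(weights * y),
                 spec = spec, include_treatment = include_treatment),
            class = "pooled_logistic")
}

#' @export
print.pooled_logistic <- function(x, ...) {
  cat("<pooled_logistic> ", x$n_rows, "person-months, ", x$n_events,
      "events; converged:", x$converged, "\n")
  print(round(x$coef, 4))
  invisible(x)
}

# Predicted monthly hazard from a pooled_logistic fit for given months/arm
# and optional covariate rows.
predict_hazard <- function(fit, month, treated, covariate_rows = NULL) {
  nd <- data.frame(month = month, treated = treated)
  if (!is.null(covariate_rows)) nd <- cbind(nd, covariate_rows)
  X <- outcome_design(nd, fit$spec, fit$include_treatment)
  X <- X[, fit$design_columns, drop = FALSE]
  stats::plogis(drop(X %*% fit$coef))
}

#' Baseline inverse probability of treatment weights
#'
#' Fits a logistic model of treatment assignment on baseline covariates and
#' returns unstabilized weights: `1 / p` for the treated and `1 / (1 - p)`
#' for the untreated. Optional truncation caps the pooled weight
#' distribution at the given percentile. Estimated probabilities at the
#' numerical boundary are reported as positivity violations.
#'
#' @param cohort Cohort with `arm` and covariate columns.
#' @param covariates Covariate column names (numeric enter linearly,
#'   factors as indicators — categorize first for missing-level handling).
#' @param truncation_percentile `NULL` or a percentile in (50, 100].
#' @return Numeric weight vector aligned with `cohort`; attributes `ps`
#'   (propensity scores), `model` (the glm), `n_truncated`.
#' @export
baseline_ip_weights <- function(cohort, covariates,
                                truncation_percentile = NULL) {
  if (!is.null(truncation_percentile) &&
      (truncation_percentile <= 50 || truncation_percentile > 100)) {
    stop("truncation percentile must be in (50, 100]", call. = FALSE)
  }
  a <- as.integer(cohort$arm == "acei_arb")
  fm <- stats::as.formula(paste("a ~", paste(covariates, collapse = " + ")))
  dat <- cohort[, covariates, drop = FALSE]
  dat$a <- a
  ml <- suppressWarnings(stats::glm(fm, data = dat,
                                    family = stats::binomial()))
  p <- stats::fitted(ml)
  eps <- 1e-10
  if (any(p < eps | p > 1 - eps)) {
    bad <- which(p < eps | p > 1 - eps)[1]
    stop("positivity violation: fitted treatment probability ",
         signif(p[bad], 3), " for covariate pattern in row ", bad,
         call. = FALSE)
  }
  w <- ifelse(a == 1, 1 / p, 1 / (1 - p))
  n_trunc <- 0L
  if (!is.null(truncation_percentile)) {
    cap <- stats::quantile(w, truncation_percentile / 100, type = 7)
    n_trunc <- sum(w > cap)
    w <- pmin(w, cap)
  }
  attr(w, "ps") <- p
  attr(w, "model") <- ml
  attr(w, "n_truncated") <- n_trunc
  w
}

#' Time-varying inverse probability of censoring weights
#'
#' Within each arm, fits a pooled logistic model for *remaining uncensored*
#' (not deviating from protocol) in month `t` given baseline covariates,
#' time-varying covariates and a spline in time, and returns per-row
#' unstabilized weights: the cumulative product over months up to `t` of
#' `1 / P(uncensored)`. Rows where the deviation occurs (`C == 1`) receive
#' weight `NA` — they are excluded from outcome fits. The final analysis
#' weight is the product of the baseline treatment weight and this
#' censoring weight.
#'
#' @param rows Per-protocol person-months (with `C`).
#' @param covariates Covariate column names for the censoring model.
#' @param spec An [outcome_model_spec()] supplying the time spline.
#' @param truncation_percentile `NULL` or percentile in (50, 100] applied to
#'   the pooled final per-row censoring weights.
#' @return Numeric per-row weight vector (NA on deviation rows); attributes
#'   `models` (per-arm glms) and `n_truncated`.
#' @export
censoring_weights <- function(rows, covariates,
                              spec = outcome_model_spec(),
                              truncation_percentile = NULL) {
  if (!"C" %in% names(rows)) {
    stop("per-protocol expansion required (no C column)", call. = FALSE)
  }
  w <- rep(NA_real_, nrow(rows))
  models <- list()
  for (a in unique(rows$treated)) {
    sel <- which(rows$treated == a)
    sub <- rows[sel, , drop = FALSE]
    if (!any(sub$C == 1)) {
      w[sel] <- 1  # nobody deviates in this arm
      next
    }
    for (t in unique(sub$month)) {
      if (all(sub$C[sub$month == t] == 1)) {
        stop("positivity failure: all rows censored in arm ", a,
             ", month ", t, call. = FALSE)
      }
    }
    uncens <- 1 - sub$C
    tb <- rcs_basis(sub$month, spec$knots)
    X <- cbind(`(Intercept)` = 1, tb)
    if (length(covariates)) {
      fm <- stats::as.formula(paste("~", paste(covariates,
                                               collapse = " + ")))
      mm <- stats::model.matrix(fm, sub)
      X <- cbind(X, mm[, -1, drop = FALSE])
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
    ml <- suppressWarnings(
      stats::glm.fit(X, uncens, family = stats::quasibinomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    p_unc <- stats::plogis(drop(X %*% ml$coefficients))
    # cumulative product of 1/p within person (rows are month-ordered)
    ord <- order(sub$person_id, sub$month)
    lp <- log(1 / p_unc[ord])
    cum <- stats::ave(lp, sub$person_id[ord], FUN = cumsum)
    w_sub <- numeric(length(sel))
    w_sub[ord] <- exp(cum)
    w_sub[sub$C == 1] <- NA_real_
    w[sel] <- w_sub
    models[[as.character(a)]] <- ml
  }
  n_trunc <- 0L
  if (!is.null(truncation_percentile)) {
    if (truncation_percentile <= 50 || truncation_percentile > 100) {
      stop("truncation percentile must be in (50, 100]", call. = FALSE)
    }
    cap <- stats::quantile(w, truncation_percentile / 100, na.rm = TRUE,
                           type = 7)
    n_trunc <- sum(w > cap, na.rm = TRUE)
    w <- pmin(w, cap)
  }
  attr(w, "models") <- models
  attr(w, "n_truncated") <- n_trunc
  w
}
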