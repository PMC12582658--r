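# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or closed form, never by calling the code paths
# they check.

# Newton-Raphson for the weighted Bernoulli log-likelihood on a fixed
# design matrix; independent of glm's IRLS.
nr_logistic <- function(X, y, w = rep(1, length(y)), tol = 1e-12,
                        maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    score <- drop(crossprod(X, w * (y - p)))
    H <- crossprod(X * (w * p * (1 - p)), X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  beta
}

# Day-by-day stock simulation of dispensation coverage, then episode
# merging by scanning uncovered runs. Independent of the interval
# arithmetic in build_episodes().
day_grid_episodes <- function(dispense_day, pill_count, grace_days = 90,
                              fixed_90 = FALSE) {
  supply <- if (fixed_90) rep(90, length(pill_count)) else pill_count
  last_day <- max(dispense_day) + sum(supply) + 1
  first_day <- min(dispense_day)
  days <- first_day:last_day
  covered <- logical(length(days))
  stock <- 0
  for (k in seq_along(days)) {
    d <- days[k]
    stock <- stock + sum(supply[dispense_day == d])
    if (stock > 0) {
      covered[k] <- TRUE
      stock <- stock - 1
    }
  }
  cov_days <- days[covered]
  if (!length(cov_days)) return(NULL)
  runs <- split(cov_days, cumsum(c(1, diff(cov_days) > 1)))
  starts <- vapply(runs, min, numeric(1))
  ends <- vapply(runs, max, numeric(1))
  ep_start <- starts[1]; ep_end <- ends[1]
  out <- list()
  if (length(runs) > 1) {
    for (j in 2:length(runs)) {
      gap <- starts[j] - ends[j - 1] - 1
      if (gap >= grace_days) {
        out[[length(out) + 1]] <- c(start = ep_start, end = ep_end)
        ep_start <- starts[j]
      }
      ep_end <- ends[j]
    }
  }
  out[[length(out) + 1]] <- c(start = ep_start, end = ep_end)
  do.call(rbind, out)
}

# Exact g-formula for a configuration with a single binary covariate and no
# adherence dynamics: enumerate covariate values and multiply monthly
# survival factors.
enumerate_risk <- function(p_x, hazard_intercept, hazard_coef_x,
                           treatment_effect, a, time_trend, horizon) {
  risk_given_x <- function(x) {
    surv <- 1
    for (t in seq_len(horizon)) {
      tt <- 0
      if (length(time_trend)) {
        for (j in seq_along(time_trend)) tt <- tt + time_trend[j] * (t / 12)^j
      }
      h <- plogis(hazard_intercept + hazard_coef_x * x +
                    treatment_effect * a + tt)
      surv <- surv * (1 - h)
    }
    1 - surv
  }
  (1 - p_x) * risk_given_x(0) + p_x * risk_given_x(1)
}

# Plain-loop re-simulation of the generator's latent event process from its
# documented per-table uniform streams: covariate draws, treatment
# assignment, stop/start months, and the monthly outcome recursion.
resimulate_truth <- function(cfg) {
  n <- cfg$n_individuals
  h <- cfg$horizon_months
  stream_u <- function(offset, k) {
    set.seed(cfg$seed + offset)
    matrix(runif(n * k), n, k, byrow = TRUE)
  }
  covs <- cfg$covariates
  u_cov <- stream_u(1L, length(covs))
  z <- matrix(0, n, length(covs))
  for (j in seq_along(covs)) {
    cv <- covs[[j]]
    if (cv$kind == "binary") {
      z[, j] <- as.numeric(u_cov[, j] < cv$prob)
    } else if (cv$kind == "continuous") {
      x <- pmin(pmax(cv$mean + cv$sd * qnorm(u_cov[, j]), cv$lower),
                cv$upper)
      z[, j] <- (x - cv$mean) / cv$sd
    } else if (cv$kind == "uniform") {
      x <- cv$min + (cv$max - cv$min) * u_cov[, j]
      z[, j] <- (x - (cv$min + cv$max) / 2) / ((cv$max - cv$min) / 2)
    }
  }
  colnames(z) <- vapply(covs, `[[`, character(1), "name")
  lp_of <- function(intercept, coefs) {
    lp <- rep(intercept, n)
    for (nm in names(coefs)) lp <- lp + coefs[[nm]] * z[, nm]
    lp
  }
  u_trt <- stream_u(3L, 1L)[, 1]
  treated <- u_trt < plogis(lp_of(cfg$treatment_intercept,
                                  cfg$treatment_coefs))
  u_adh <- stream_u(6L, h)
  p_stop <- plogis(lp_of(cfg$adherence_stop_logit, cfg$adherence_stop_coefs))
  p_start <- plogis(lp_of(cfg$crossover_start_logit,
                          cfg$crossover_start_coefs))
  u_out <- stream_u(4L, h)
  lp_base <- lp_of(cfg$hazard_intercept, cfg$hazard_coefs)
  event_month <- rep(NA_integer_, n)
  stop_month <- rep(NA_integer_, n)
  start_month <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- as.numeric(treated[i])
    sm <- NA_integer_
    for (t in seq_len(h)) {
      if (treated[i] && is.na(sm) && u_adh[i, t] < p_stop[i]) sm <- t
      if (!treated[i] && is.na(sm) && u_adh[i, t] < p_start[i]) sm <- t
      a_t <- if (treated[i]) as.numeric(is.na(sm) || t < sm) else
        as.numeric(!is.na(sm) && t >= sm)
      tt <- 0
      if (length(cfg$time_trend)) {
        for (j in seq_along(cfg$time_trend)) {
          tt <- tt + cfg$time_trend[j] * (t / 12)^j
        }
      }
      p_t <- plogis(lp_base[i] + cfg$treatment_effect * a_t + tt)
      if (is.na(event_month[i]) && u_out[i, t] < p_t) event_month[i] <- t
    }
    if (treated[i]) stop_month[i] <- sm else start_month[i] <- sm
  }
  data.frame(treated = treated, event_month = event_month,
             stop_month = stop_month, start_month = start_month)
}

# Minimal hand-built registry bundle for eligibility and assignment tests.
# Every person is eligible unless a field below says otherwise.
make_test_bundle <- function(n = 4,
                             age = rep(60, n),
                             lvef = rep(55, n),
                             egfr = rep(90, n),
                             employment = rep("working", n),
                             admission = as.Date("2016-03-01")) {
  ids <- sprintf("T%03d", seq_len(n))
  adm <- data.frame(
    person_id = ids, age = age, female = 0, nstemi = 1, sbp = 140,
    egfr = egfr, ldl = 3, lvef = lvef, employment = employment,
    admission_date = rep(admission, n),
    discharge_date = rep(admission + 5, n), angiography = TRUE)
  disp <- data.frame(
    person_id = rep(ids, 2),
    atc_code = rep(c("C10AA05", "B01AC06"), each = n),
    dispense_date = rep(adm$admission_date + 2, 2), pill_count = 100)
  list(bundle = structure(list(
         admissions = adm, dispensations = disp,
         diagnoses = data.frame(person_id = character(),
                                code = character(),
                                date = as.Date(character()),
                                setting = character(),
                                position = character()),
         deaths = data.frame(person_id = character(),
                             death_date = as.Date(character())),
         outcomes = data.frame(person_id = character(),
                               event_type = character(),
                               event_date = as.Date(character()))),
         class = "registry_bundle"),
       ids = ids)
}

add_rows <- function(bundle, table, rows) {
  bundle[[table]] <- rbind(bundle[[table]], rows)
  bundle
}

# Shared small synthetic cohort for estimation tests (built once per run).
shared_pipeline_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_individuals = 3000, seed = 42,
                              hazard_intercept = -5.5)
      b <- generate_registry(cfg)
      s <- screen_eligibility(b)
      co <- assign_strategy(s$candidates, b$dispensations,
                            eligibility_spec(), s$flowchart)
      cache <<- list(cfg = cfg, bundle = b, cohort = co,
                     flowchart = attr(co, "flowchart"),
                     data = list(cohort = co,
                                 dispensations = b$dispensations,
                                 diagnoses = b$diagnoses,
                                 deaths = b$deaths,
                                 outcomes = b$outcomes))
    }
    cache
  }
})
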