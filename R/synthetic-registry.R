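#' Synthetic registry configuration
#'
#' Builds the configuration object for [generate_registry()]. The generator
#' emulates a linked set of registry tables (admissions, drug dispensations,
#' diagnoses, deaths, outcome events) for a cohort hospitalized with an index
#' myocardial infarction, with a fully known data-generating process:
#' treatment assignment is confounded by baseline covariates through a
#' logistic model, the outcome follows a discrete-time (monthly) hazard with
#' a configurable treatment effect, and adherence evolves as a monthly
#' stop/start process that is realized as dispensation records.
#'
#' All covariate effects enter linear predictors on a standardized scale:
#' binary covariates as 0/1, continuous covariates as
#' `(x - mean)/sd` with the mean and sd taken from the covariate
#' specification (not estimated from data), and uniform covariates as
#' `(x - midpoint)/(range/2)`. Categorical covariates may be generated but
#' cannot carry coefficients.
#'
#' @param n_individuals Number of eligible individuals to generate.
#' @param seed Integer seed; identical configurations produce identical
#'   bundles.
#' @param covariates List of covariate specifications; see
#'   [default_covariates()]. Each element is a list with `name`, `kind`
#'   (`"binary"`, `"continuous"`, `"uniform"` or `"categorical"`) and
#'   distribution parameters (`prob`; `mean`, `sd`, `lower`, `upper`;
#'   `min`, `max`; `levels`, `probs`).
#' @param treatment_intercept,treatment_coefs Log-odds intercept and named
#'   covariate coefficients of the treatment-assignment model (confounding
#'   strength).
#' @param hazard_intercept Monthly log-odds of the outcome at covariate
#'   means, untreated, at time-trend zero.
#' @param treatment_effect Log-odds ratio of current treatment on the
#'   monthly outcome hazard.
#' @param hazard_coefs Named covariate coefficients on the outcome hazard.
#' @param time_trend Numeric vector `b`; the baseline hazard gains
#'   `sum(b[j] * (t/12)^j)` at month `t` (polynomial in years).
#' @param adherence_stop_logit,adherence_stop_coefs Monthly log-odds (and
#'   covariate coefficients) of stopping treatment in the treated arm. The
#'   default monthly probability of about 1.3% leaves roughly 46% of the
#'   treated still on drug at 60 months.
#' @param crossover_start_logit,crossover_start_coefs Monthly log-odds (and
#'   covariate coefficients) of initiating treatment in the untreated arm.
#'   The default of about 0.4%/month leaves roughly 79% never-users at 60
#'   months.
#' @param indication_rate,contraindication_rate Monthly probabilities of a
#'   first post-baseline indication (hypertension or heart failure) and
#'   contraindication (hypotension or renal artery stenosis) diagnosis.
#' @param comed_rate Monthly probability of a first concomitant-medication
#'   (beta-blocker) dispensation, used as a time-varying covariate.
#' @param tv_diagnosis_rate Monthly probability of a first post-baseline
#'   renal-disease and (separately) diabetes diagnosis.
#' @param event_type_probs Named probabilities splitting a composite event
#'   into `death`, `mi` and `hf`.
#' @param missing_rate Named vector of per-covariate MCAR missingness rates
#'   applied by [inject_missingness()].
#' @param horizon_months Follow-up horizon in 30-day months.
#' @param dispensation_supply_days Pills per dispensation at one pill/day.
#'   The 100-day default exercises the 90-day gap rule on both sides.
#' @param noneligible_fraction Fraction of `n_individuals` to append *per
#'   eligibility rule* as rule violators (for flowchart tests).
#' @param noneligible_counts Optional named integer vector of exact violator
#'   counts per rule, overriding `noneligible_fraction`. Names from
#'   `c("too_old", "low_lvef", "low_egfr", "prior_indication", "prior_use",
#'   "dementia")`.
#' @param recruitment_start,recruitment_end Admission date window.
#' @param end_of_study Administrative end of follow-up.
#' @param assignment_window_days Days after admission within which a
#'   dispensation counts as treatment assignment.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 1000L,
                             seed = 1L,
                             covariates = default_covariates(),
                             treatment_intercept = 0.85,
                             treatment_coefs = c(age = 0.25, female = -0.25,
                                                 nstemi = -0.75, sbp = 0.30),
                             hazard_intercept = -6.6,
                             treatment_effect = 0,
                             hazard_coefs = c(age = 0.45, nstemi = 0.20,
                                              sbp = 0.15),
                             time_trend = c(-0.25),
                             adherence_stop_logit = stats::qlogis(0.013),
                             adherence_stop_coefs = numeric(0),
                             crossover_start_logit = stats::qlogis(0.0039),
                             crossover_start_coefs = numeric(0),
                             indication_rate = 0.002,
                             contraindication_rate = 0.001,
                             comed_rate = 0.01,
                             tv_diagnosis_rate = 0.001,
                             event_type_probs = c(death = 0.40, mi = 0.35,
                                                  hf = 0.25),
                             missing_rate = numeric(0),
                             horizon_months = 60L,
                             dispensation_supply_days = 100L,
                             noneligible_fraction = 0,
                             noneligible_counts = NULL,
                             recruitment_start = as.Date("2015-01-01"),
                             recruitment_end = as.Date("2016-12-31"),
                             end_of_study = as.Date("2022-12-31"),
                             assignment_window_days = 30L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), seed = as.integer(seed),
    covariates = covariates,
    treatment_intercept = treatment_intercept,
    treatment_coefs = treatment_coefs,
    hazard_intercept = hazard_intercept,
    treatment_effect = treatment_effect,
    hazard_coefs = hazard_coefs,
    time_trend = time_trend,
    adherence_stop_logit = adherence_stop_logit,
    adherence_stop_coefs = adherence_stop_coefs,
    crossover_start_logit = crossover_start_logit,
    crossover_start_coefs = crossover_start_coefs,
    indication_rate = indication_rate,
    contraindication_rate = contraindication_rate,
    comed_rate = comed_rate,
    tv_diagnosis_rate = tv_diagnosis_rate,
    event_type_probs = event_type_probs,
    missing_rate = missing_rate,
    horizon_months = as.integer(horizon_months),
    dispensation_supply_days = as.integer(dispensation_supply_days),
    noneligible_fraction = noneligible_fraction,
    noneligible_counts = noneligible_counts,
    recruitment_start = as.Date(recruitment_start),
    recruitment_end = as.Date(recruitment_end),
    end_of_study = as.Date(end_of_study),
    assignment_window_days = as.integer(assignment_window_days)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' Default baseline covariate specification
#'
#' Age, sex, infarction type, systolic blood pressure, eGFR, LDL cholesterol,
#' LVEF and occupational status, with location/scale loosely matched to a
#' post-infarction population with preserved ejection fraction.
#'
#' @return A list of covariate specifications for [synthetic_config()].
#' @export
default_covariates <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 61, sd = 8,
         lower = 18, upper = 74.9),
    list(name = "female", kind = "binary", prob = 0.21),
    list(name = "nstemi", kind = "binary", prob = 0.60),
    list(name = "sbp", kind = "continuous", mean = 148, sd = 26,
         lower = 70, upper = 260),
    list(name = "egfr", kind = "continuous", mean = 88, sd = 15,
         lower = 16, upper = 150),
    list(name = "ldl", kind = "continuous", mean = 3.5, sd = 1,
         lower = 0.5, upper = 8),
    list(name = "lvef", kind = "uniform", min = 50, max = 70),
    list(name = "employment", kind = "categorical",
         levels = c("working", "retired", "student"),
         probs = c(0.62, 0.36, 0.02))
  )
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1L, cfg$horizon_months >= 1L)
  probs <- c(indication_rate = cfg$indication_rate,
             contraindication_rate = cfg$contraindication_rate,
             comed_rate = cfg$comed_rate,
             tv_diagnosis_rate = cfg$tv_diagnosis_rate,
             cfg$event_type_probs, cfg$missing_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (abs(sum(cfg$event_type_probs) - 1) > 1e-8) {
    stop("event_type_probs must sum to 1", call. = FALSE)
  }
  nm <- vapply(cfg$covariates, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names", call. = FALSE)
  for (cv in cfg$covariates) {
    ok <- switch(cv$kind,
      binary = is.numeric(cv$prob) && cv$prob >= 0 && cv$prob <= 1,
      continuous = is.numeric(cv$mean) && is.numeric(cv$sd) && cv$sd > 0,
      uniform = is.numeric(cv$min) && is.numeric(cv$max) && cv$max > cv$min,
      categorical = length(cv$levels) == length(cv$probs) &&
        abs(sum(cv$probs) - 1) < 1e-8,
      FALSE)
    if (!isTRUE(ok)) {
      stop("invalid distribution parameters for covariate '", cv$name, "'",
           call. = FALSE)
    }
  }
  for (fld in c("treatment_coefs", "hazard_coefs", "adherence_stop_coefs",
                "crossover_start_coefs")) {
    cf <- cfg[[fld]]
    if (length(cf) && !all(names(cf) %in% nm)) {
      stop(fld, " names unknown covariates: ",
           paste(setdiff(names(cf), nm), collapse = ", "), call. = FALSE)
    }
  }
  if (!all(names(cfg$missing_rate) %in% nm)) {
    stop("missing_rate names unknown covariates", call. = FALSE)
  }
  invisible(cfg)
}

# Per-table RNG stream offsets added to the config seed. Each stream draws a
# single person-major block, so appending individuals never perturbs the
# draws of existing ones.
.stream <- c(covariates = 1L, dates = 2L, treatment = 3L, outcome = 4L,
             event_type = 5L, adherence = 6L, indication = 7L,
             indication_meta = 8L, contraindication = 9L,
             contraindication_meta = 10L, comed = 11L, tvdx = 12L,
             missing = 13L, noneligible = 14L)

.noneligible_rules <- c("too_old", "low_lvef", "low_egfr",
                        "prior_indication", "prior_use", "dementia")

# Uniform draws for a stream, person-major: person i owns row i.
stream_runif <- function(seed, stream, n, k = 1L) {
  set.seed(seed + .stream[[stream]])
  matrix(stats::runif(n * k), nrow = n, ncol = k, byrow = TRUE)
}

# Draw one covariate column from its spec and a column of uniforms.
draw_covariate <- function(cv, u) {
  switch(cv$kind,
    binary = as.numeric(u < cv$prob),
    continuous = pmin(pmax(cv$mean + cv$sd * stats::qnorm(u), cv$lower),
                      cv$upper),
    uniform = cv$min + (cv$max - cv$min) * u,
    categorical = cv$levels[findInterval(u, cumsum(cv$probs),
                                         left.open = TRUE) + 1L]
  )
}

# Standardized covariate scores used in every linear predictor.
covariate_scores <- function(adm, covariates) {
  out <- list()
  for (cv in covariates) {
    x <- adm[[cv$name]]
    out[[cv$name]] <- switch(cv$kind,
      binary = x,
      continuous = (x - cv$mean) / cv$sd,
      uniform = (x - (cv$min + cv$max) / 2) / ((cv$max - cv$min) / 2),
      categorical = NULL)
  }
  out
}

lin_pred <- function(intercept, coefs, scores, n) {
  lp <- rep(intercept, n)
  for (nm in names(coefs)) {
    if (is.null(scores[[nm]])) {
      stop("coefficient on categorical covariate '", nm, "' not supported",
           call. = FALSE)
    }
    lp <- lp + coefs[[nm]] * scores[[nm]]
  }
  lp
}

time_trend_value <- function(b, t) {
  if (!length(b)) return(rep(0, length(t)))
  s <- t / 12
  val <- 0
  for (j in seq_along(b)) val <- val + b[j] * s^j
  val
}

# First month (1..h) in which u < p, per person; NA if never. `p` is a
# vector (constant over time) or an n x h matrix.
first_hit_month <- function(u, p) {
  h <- ncol(u)
  hit <- u < (if (is.matrix(p)) p else matrix(p, nrow(u), h))
  idx <- max.col(hit, ties.method = "first")
  idx[!hit[cbind(seq_len(nrow(u)), idx)]] <- NA_integer_
  idx
}

#' Generate a synthetic registry bundle
#'
#' Simulates the linked registry tables described in [synthetic_config()].
#' Time is discretized into 30-day months starting at time zero, defined as
#' `admission_date + assignment_window_days` (a fixed landmark common to
#' both arms). Treated individuals receive a qualifying dispensation 1-30
#' days after admission and refills every `dispensation_supply_days` days
#' until their (latent) stop month; untreated individuals dispense nothing
#' unless they cross over. Statin and antithrombotic dispensations and an
#' angiography flag realize "standard care" for eligible persons.
#'
#' The bundle carries a `truth` attribute (one row per person) recording the
#' latent assignment, event month and type, adherence stop/start months and
#' any injected eligibility violation, so downstream stages can be tested
#' against generator bookkeeping.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `registry_bundle` with data frames `admissions`,
#'   `dispensations`, `diagnoses`, `deaths`, `outcomes`, and attribute
#'   `truth`.
#' @export
generate_registry <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  n_elig <- cfg$n_individuals
  h <- cfg$horizon_months
  counts <- noneligible_counts(cfg)
  n <- n_elig + sum(counts)
  ids <- sprintf("P%06d", seq_len(n))
  rule <- rep(c(NA_character_, rep(names(counts), counts)),
              c(n_elig, rep(1L, sum(counts))))

  # --- baseline covariates -------------------------------------------------
  K <- length(cfg$covariates)
  u_cov <- stream_runif(cfg$seed, "covariates", n, K)
  adm <- data.frame(person_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(K)) {
    adm[[cfg$covariates[[j]]$name]] <- draw_covariate(cfg$covariates[[j]],
                                                      u_cov[, j])
  }

  # --- admission/assignment dates -----------------------------------------
  u_dt <- stream_runif(cfg$seed, "dates", n, 3L)
  span <- as.integer(cfg$recruitment_end - cfg$recruitment_start)
  adm$admission_date <- cfg$recruitment_start + floor(u_dt[, 1] * (span + 1))
  adm$discharge_date <- adm$admission_date + 3L + floor(u_dt[, 2] * 8)
  assignment_day <- 1L + floor(u_dt[, 3] * cfg$assignment_window_days)
  adm$angiography <- TRUE

  # --- rule violations (appended persons only) -----------------------------
  u_ne <- if (sum(counts)) stream_runif(cfg$seed, "noneligible", n, 2L)
  lookback_offset <- function(i) 31L + floor(u_ne[i, 2] * 900)
  extra_dx <- list(); extra_disp <- list()
  for (i in which(!is.na(rule))) {
    switch(rule[i],
      too_old = { adm$age[i] <- 75 + 10 * u_ne[i, 1] },
      low_lvef = { adm$lvef[i] <- 30 + 19.9 * u_ne[i, 1] },
      low_egfr = { adm$egfr[i] <- 5 + 9.9 * u_ne[i, 1] },
      prior_indication = {
        extra_dx[[length(extra_dx) + 1L]] <- data.frame(
          person_id = ids[i], code = "I10",
          date = adm$admission_date[i] - lookback_offset(i),
          setting = "outpatient", position = "primary")
      },
      prior_use = {
        extra_disp[[length(extra_disp) + 1L]] <- data.frame(
          person_id = ids[i], atc_code = "C09AA02",
          dispense_date = adm$admission_date[i] - lookback_offset(i),
          pill_count = cfg$dispensation_supply_days)
      },
      dementia = {
        extra_dx[[length(extra_dx) + 1L]] <- data.frame(
          person_id = ids[i], code = "F03",
          date = adm$admission_date[i] - lookback_offset(i),
          setting = "inpatient", position = "secondary")
      })
  }

  scores <- covariate_scores(adm, cfg$covariates)

  # --- treatment assignment ------------------------------------------------
  u_trt <- stream_runif(cfg$seed, "treatment", n, 1L)[, 1]
  p_trt <- stats::plogis(lin_pred(cfg$treatment_intercept,
                                  cfg$treatment_coefs, scores, n))
  treated <- u_trt < p_trt

  # --- adherence (stop in treated, crossover in untreated) -----------------
  u_adh <- stream_runif(cfg$seed, "adherence", n, h)
  p_stop <- stats::plogis(lin_pred(cfg$adherence_stop_logit,
                                   cfg$adherence_stop_coefs, scores, n))
  p_start <- stats::plogis(lin_pred(cfg$crossover_start_logit,
                                    cfg$crossover_start_coefs, scores, n))
  stop_month <- ifelse(treated, first_hit_month(u_adh, p_stop), NA_integer_)
  start_month <- ifelse(!treated, first_hit_month(u_adh, p_start),
                        NA_integer_)

  # On-treatment indicator by month: treated carry drug until the month
  # before their stop month; untreated pick it up at their start month.
  t_grid <- seq_len(h)
  tm <- matrix(t_grid, n, h, byrow = TRUE)
  a_mat <- matrix(0, n, h)
  a_mat[treated, ] <- 1
  sm <- matrix(stop_month, n, h)
  a_mat[!is.na(sm) & tm >= sm] <- 0
  cm <- matrix(start_month, n, h)
  a_mat[!is.na(cm) & tm >= cm] <- 1

  # --- outcome process -----------------------------------------------------
  u_out <- stream_runif(cfg$seed, "outcome", n, h)
  lp_base <- lin_pred(cfg$hazard_intercept, cfg$hazard_coefs, scores, n)
  lp_mat <- outer(lp_base, time_trend_value(cfg$time_trend, t_grid), `+`) +
    cfg$treatment_effect * a_mat
  event_month <- first_hit_month(u_out, stats::plogis(lp_mat))

  u_typ <- stream_runif(cfg$seed, "event_type", n, 1L)[, 1]
  type_cut <- cumsum(cfg$event_type_probs)
  event_type <- names(cfg$event_type_probs)[
    findInterval(u_typ, type_cut, left.open = TRUE) + 1L]
  event_type[is.na(event_month)] <- NA_character_

  time_zero <- adm$admission_date + cfg$assignment_window_days
  # full-length (n) vector of dates for a full-length month vector (NA ok)
  month_day <- function(m, day_in_month = 15L) {
    time_zero + (m - 1L) * 30L + day_in_month
  }

  # --- dispensations -------------------------------------------------------
  supply <- cfg$dispensation_supply_days
  aw <- cfg$assignment_window_days
  disp <- list()
  if (length(extra_disp)) disp <- extra_disp
  # treated: refills from the assignment day until the day before the stop
  # month begins; always at least the qualifying assignment dispensation
  ti <- which(treated)
  if (length(ti)) {
    end_day <- ifelse(is.na(stop_month), aw + h * 30L,
                      aw + (stop_month - 1L) * 30L)
    n_fill <- pmax(1L, floor((end_day - 1L - assignment_day) / supply) + 1L)
    reps <- rep(ti, n_fill[ti])
    offs <- (sequence(n_fill[ti]) - 1L) * supply
    disp[[length(disp) + 1L]] <- data.frame(
      person_id = ids[reps], atc_code = "C09AA02",
      dispense_date = adm$admission_date[reps] + assignment_day[reps] + offs,
      pill_count = supply)
  }
  # untreated crossover: refills from the start month through the horizon
  ci <- which(!is.na(start_month))
  if (length(ci)) {
    # day 1 of the start month, strictly after the assignment window
    cs_day <- aw + (start_month - 1L) * 30L + 1L
    n_fill <- floor((aw + h * 30L - cs_day) / supply) + 1L
    reps <- rep(ci, n_fill[ci])
    offs <- (sequence(n_fill[ci]) - 1L) * supply
    disp[[length(disp) + 1L]] <- data.frame(
      person_id = ids[reps], atc_code = "C09CA01",
      dispense_date = adm$admission_date[reps] + cs_day[reps] + offs,
      pill_count = supply)
  }
  # standard care: one statin and one antithrombotic dispensation in window
  disp[[length(disp) + 1L]] <- data.frame(
    person_id = rep(ids, 2L),
    atc_code = rep(c("C10AA05", "B01AC06"), each = n),
    dispense_date = rep(adm$admission_date + 2L, 2L),
    pill_count = supply)
  # concomitant beta-blocker as a time-varying covariate
  u_cm <- stream_runif(cfg$seed, "comed", n, h)
  comed_month <- first_hit_month(u_cm, rep(cfg$comed_rate, n))
  has_cm <- which(!is.na(comed_month))
  if (length(has_cm)) {
    cm_dates <- month_day(comed_month, 1L)
    disp[[length(disp) + 1L]] <- data.frame(
      person_id = ids[has_cm], atc_code = "C07AB02",
      dispense_date = cm_dates[has_cm],
      pill_count = supply)
  }
  dispensations <- do.call(rbind, disp)

  # --- post-baseline diagnoses --------------------------------------------
  u_ind <- stream_runif(cfg$seed, "indication", n, h)
  ind_month <- first_hit_month(u_ind, rep(cfg$indication_rate, n))
  u_indm <- stream_runif(cfg$seed, "indication_meta", n, 1L)[, 1]
  ind_code <- ifelse(u_indm < 0.7, "I10", "I50")
  u_con <- stream_runif(cfg$seed, "contraindication", n, h)
  con_month <- first_hit_month(u_con, rep(cfg$contraindication_rate, n))
  u_conm <- stream_runif(cfg$seed, "contraindication_meta", n, 1L)[, 1]
  con_code <- ifelse(u_conm < 0.7, "I95", "I70.1")
  u_tv <- stream_runif(cfg$seed, "tvdx", n, 2L * h)
  renal_month <- first_hit_month(u_tv[, seq_len(h), drop = FALSE],
                                 rep(cfg$tv_diagnosis_rate, n))
  diab_month <- first_hit_month(u_tv[, h + seq_len(h), drop = FALSE],
                                rep(cfg$tv_diagnosis_rate, n))

  dx <- extra_dx
  add_dx <- function(month, code, setting) {
    i <- which(!is.na(month))
    if (!length(i)) return(NULL)
    dates <- month_day(month, 7L)
    data.frame(person_id = ids[i],
               code = if (length(code) == 1L) code else code[i],
               date = dates[i],
               setting = setting, position = "secondary")
  }
  dx <- c(dx, list(add_dx(ind_month, ind_code, "outpatient"),
                   add_dx(con_month, con_code, "inpatient"),
                   add_dx(renal_month, "N18", "outpatient"),
                   add_dx(diab_month, "E11", "outpatient")))
  diagnoses <- do.call(rbind, Filter(Negate(is.null), dx))
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(person_id = character(), code = character(),
                            date = as.Date(character()),
                            setting = character(), position = character())
  }

  # --- deaths and outcome events ------------------------------------------
  ev <- which(!is.na(event_month))
  ev_date <- month_day(event_month, 15L)
  deaths <- data.frame(person_id = character(), death_date = as.Date(character()))
  outcomes <- data.frame(person_id = character(), event_type = character(),
                         event_date = as.Date(character()))
  d <- ev[event_type[ev] == "death"]
  if (length(d)) deaths <- data.frame(person_id = ids[d], death_date = ev_date[d])
  o <- ev[event_type[ev] != "death"]
  if (length(o)) {
    outcomes <- data.frame(person_id = ids[o], event_type = event_type[o],
                           event_date = ev_date[o])
  }

  # administrative end of study: unobserved records are dropped
  dispensations <- dispensations[dispensations$dispense_date <= cfg$end_of_study, ]
  diagnoses <- diagnoses[diagnoses$date <= cfg$end_of_study, ]
  deaths <- deaths[deaths$death_date <= cfg$end_of_study, ]
  outcomes <- outcomes[outcomes$event_date <= cfg$end_of_study, ]
  rownames(dispensations) <- rownames(diagnoses) <- NULL
  rownames(deaths) <- rownames(outcomes) <- NULL

  truth <- data.frame(
    person_id = ids, eligible = is.na(rule), noneligible_rule = rule,
    arm = ifelse(treated, "acei_arb", "none"),
    assignment_day = ifelse(treated, assignment_day, NA_integer_),
    time_zero = time_zero,
    event_month = event_month, event_type = event_type,
    stop_month = stop_month, start_month = start_month,
    indication_month = ind_month, contraindication_month = con_month,
    stringsAsFactors = FALSE)

  bundle <- structure(
    list(admissions = adm, dispensations = dispensations,
         diagnoses = diagnoses, deaths = deaths, outcomes = outcomes),
    class = "registry_bundle", truth = truth, config = cfg)
  bundle
}

noneligible_counts <- function(cfg) {
  if (!is.null(cfg$noneligible_counts)) {
    counts <- cfg$noneligible_counts
    if (!all(names(counts) %in% .noneligible_rules)) {
      stop("unknown noneligible rule(s): ",
           paste(setdiff(names(counts), .noneligible_rules), collapse = ", "),
           call. = FALSE)
    }
    out <- stats::setNames(integer(length(.noneligible_rules)),
                           .noneligible_rules)
    out[names(counts)] <- as.integer(counts)
    return(out)
  }
  stats::setNames(rep(as.integer(round(cfg$noneligible_fraction *
                                         cfg$n_individuals)),
                      length(.noneligible_rules)), .noneligible_rules)
}

#' Ground-truth counterfactual risk by Monte Carlo
#'
#' Estimates the counterfactual cumulative incidence at a horizon under
#' sustained assignment to one arm with full adherence, by simulating fresh
#' covariate draws and the monthly hazard process from the configured
#' data-generating model. This is the oracle against which weighted
#' per-protocol estimates are checked.
#'
#' @param config A [synthetic_config()].
#' @param arm `"treated"` or `"untreated"`.
#' @param horizon Months; must not exceed `config$horizon_months`.
#' @param n_mc Monte Carlo sample size.
#' @param oracle_seed Seed for the oracle draws (independent of the bundle).
#' @return A probability; attribute `mc_se` carries its Monte Carlo
#'   standard error.
#' @export
true_marginal_risk <- function(config, arm = c("treated", "untreated"),
                               horizon = config$horizon_months,
                               n_mc = 100000L, oracle_seed = 20201L) {
  arm <- match.arg(arm)
  stopifnot(n_mc >= 1L)
  if (horizon > config$horizon_months) {
    stop("horizon exceeds config$horizon_months", call. = FALSE)
  }
  set.seed(oracle_seed)
  n <- as.integer(n_mc)
  K <- length(config$covariates)
  u_cov <- matrix(stats::runif(n * K), n, K, byrow = TRUE)
  adm <- data.frame(row.names = seq_len(n))
  for (j in seq_len(K)) {
    adm[[config$covariates[[j]]$name]] <-
      draw_covariate(config$covariates[[j]], u_cov[, j])
  }
  scores <- covariate_scores(adm, config$covariates)
  a <- as.numeric(arm == "treated")
  lp_base <- lin_pred(config$hazard_intercept, config$hazard_coefs, scores, n) +
    config$treatment_effect * a
  t_grid <- seq_len(horizon)
  surv <- rep(1, n)
  for (t in t_grid) {
    p_t <- stats::plogis(lp_base + time_trend_value(config$time_trend, t))
    surv <- surv * (1 - p_t)
  }
  risk <- 1 - mean(surv)
  # SE reflects both path randomness and covariate sampling; bounded by the
  # Bernoulli worst case sqrt(0.25/n_mc)
  attr(risk, "mc_se") <- stats::sd(1 - surv) / sqrt(n) + 1e-12
  risk
}

#' Inject MCAR missingness into baseline covariates
#'
#' Sets each listed baseline covariate in the admissions table to `NA`
#' independently with its configured rate (missing completely at random).
#' Every other field and table is untouched. On CSV export the sentinel is
#' an empty field.
#'
#' @param bundle A `registry_bundle`.
#' @param config The [synthetic_config()] carrying `missing_rate`.
#' @return The bundle with missingness applied.
#' @export
inject_missingness <- function(bundle, config) {
  rates <- config$missing_rate
  if (!length(rates)) return(bundle)
  adm <- bundle$admissions
  absent <- setdiff(names(rates), names(adm))
  if (length(absent)) {
    stop("missing_rate covariate(s) not in admissions: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(adm)
  u <- stream_runif(config$seed, "missing", n, length(rates))
  for (j in seq_along(rates)) {
    adm[[names(rates)[j]]][u[, j] < rates[j]] <- NA
  }
  bundle$admissions <- adm
  bundle
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
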