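#' Estimate one treatment-strategy contrast from registry data
#'
#' The single-analysis workhorse behind [run_analysis()] and the unit that
#' the bootstrap re-runs: expands the cohort to person-months for the
#' requested estimand, estimates the adjustment weights (baseline inverse
#' probability of treatment weights; plus time-varying censoring weights in
#' the per-protocol analysis, with weights multiplied), fits the weighted
#' pooled logistic hazard model, and returns risk curves with the
#' 5-year-horizon contrasts. The intention-to-treat path never touches the
#' adherence engine, so its results are invariant to adherence settings.
#'
#' @param data List with `cohort` (from [assign_strategy()]) and the bundle
#'   tables `dispensations`, `diagnoses`, `deaths`, `outcomes`.
#' @param estimand `"itt"` or `"pp"`.
#' @param outcome Outcome to analyse.
#' @param adjustment Adjustment mode; see [outcome_model_spec()].
#' @param weight_covariates Baseline covariate columns for the weight
#'   models (numeric covariates with missing values are automatically
#'   replaced by their categorized-with-missing versions).
#' @param grace_days,adherence_mode,outcome_variant Per-protocol adherence
#'   settings; see [pp_censor_events()].
#' @param truncation_percentile `NULL` or e.g. 99 to truncate weights.
#' @param knots Spline knots in months.
#' @param horizon Months of follow-up.
#' @param end_of_study Administrative end date (optional).
#' @param elig_spec An [eligibility_spec()] (ATC prefixes for the adherence
#'   engine).
#' @param estimator `"pooled_logistic"` (parametric hazard, the default) or
#'   `"km"` (nonparametric product-limit).
#' @return List with `point` (named `c(R1, R0, RD, RR)` at the horizon),
#'   `curve` (a `risk_curve`), `n`, and for per-protocol runs `censor_events`
#'   and `adherence`.
#' @export
estimate_effects <- function(data, estimand = c("itt", "pp"),
                             outcome = c("composite", "death", "mi", "hf"),
                             adjustment = c("ipw", "covariates_in_model",
                                            "age_sex_only", "unadjusted"),
                             weight_covariates = NULL,
                             grace_days = 90,
                             adherence_mode = c("pill_count", "fixed_90"),
                             outcome_variant = NULL,
                             truncation_percentile = NULL,
                             knots = c(6, 12, 24, 48), horizon = 60L,
                             end_of_study = NULL,
                             elig_spec = eligibility_spec(),
                             estimator = c("pooled_logistic", "km")) {
  estimand <- match.arg(estimand)
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  adherence_mode <- match.arg(adherence_mode)
  estimator <- match.arg(estimator)
  cohort <- data$cohort
  if (is.null(weight_covariates)) {
    weight_covariates <- intersect(
      c("age", "female", "nstemi", "sbp", "egfr", "ldl", "lvef",
        "employment"), names(cohort))
  }
  prep <- prepare_covariates(cohort, weight_covariates)
  cohort <- prep$cohort

  censor_events <- NULL
  tv <- NULL
  if (estimand == "pp") {
    if (is.null(outcome_variant)) {
      outcome_variant <- if (outcome %in% c("death", "mi")) "death_or_mi"
        else "composite"
    }
    bundle_like <- list(dispensations = data$dispensations,
                        diagnoses = data$diagnoses)
    censor_events <- pp_censor_events(cohort, bundle_like, elig_spec,
                                      grace_days = grace_days,
                                      mode = adherence_mode,
                                      outcome_variant = outcome_variant,
                                      horizon_months = horizon)
    tv <- tv_first_days(cohort, bundle_like)
  }

  rows <- expand_person_months(cohort, data$outcomes, data$deaths,
                               censor_events = censor_events,
                               horizon = horizon, estimand = estimand,
                               outcome = outcome,
                               end_of_study = end_of_study,
                               carry = prep$covariates, tv = tv)

  w_base <- switch(adjustment,
    ipw = baseline_ip_weights(cohort, prep$covariates,
                              truncation_percentile),
    age_sex_only = baseline_ip_weights(
      cohort, intersect(c("age", "age_cat", "female"), names(cohort)),
      truncation_percentile),
    covariates_in_model = rep(1, nrow(cohort)),
    unadjusted = rep(1, nrow(cohort)))
  w_rows <- as.numeric(w_base)[match(rows$person_id, cohort$person_id)]

  mspec <- outcome_model_spec(
    knots = knots, adjustment = adjustment, outcome = outcome,
    horizon = horizon,
    covariates = if (adjustment == "covariates_in_model") prep$covariates
      else character(0))

  if (estimand == "pp") {
    w_cens <- censoring_weights(rows,
                                c(prep$covariates, names(tv)), mspec,
                                truncation_percentile)
    w_rows <- w_rows * w_cens  # NA on deviation rows; dropped below
  }
  on_protocol <- if ("C" %in% names(rows)) rows$C == 0 else
    rep(TRUE, nrow(rows))
  rows_fit <- rows[on_protocol, , drop = FALSE]
  w_fit <- w_rows[on_protocol]

  curve <- if (estimator == "km") {
    km_curve(rows_fit, weights = w_fit, horizon = horizon)
  } else {
    estimate_risk_curves(rows_fit, mspec, weights = w_fit)
  }
  at_h <- curve[curve$month == horizon, ]
  # effective sample size per arm from the final-month person weights
  # (Kish approximation, used for rough standard errors)
  last <- !duplicated(rows_fit$person_id, fromLast = TRUE)
  ess <- vapply(c(untreated = 0, treated = 1), function(a) {
    wl <- w_fit[last & rows_fit$treated == a]
    sum(wl)^2 / sum(wl^2)
  }, numeric(1))
  out <- list(point = c(R1 = at_h$R1, R0 = at_h$R0, RD = at_h$RD,
                        RR = at_h$RR),
              curve = curve, n = nrow(cohort), ess = ess,
              weights_summary = summary(w_fit))
  if (estimand == "pp") {
    out$censor_events <- censor_events
    out$adherence <- adherence_curve(cohort, censor_events, horizon)
  }
  out
}

# Swap numeric covariates that contain missing values for their
# categorized-with-missing versions; character covariates become factors
# with a missing level.
prepare_covariates <- function(cohort, covariates) {
  scheme <- default_category_scheme()
  final <- character(0)
  for (nm in covariates) {
    x <- cohort[[nm]]
    if (is.numeric(x) && !anyNA(x)) {
      final <- c(final, nm)
    } else {
      cuts <- scheme[[nm]]
      if (is.null(cuts) && is.numeric(x)) {
        cuts <- unique(stats::quantile(x, c(0.25, 0.5, 0.75),
                                       na.rm = TRUE))
      }
      cohort <- categorize_covariates(cohort,
                                      stats::setNames(list(cuts), nm))
      final <- c(final, paste0(nm, "_cat"))
    }
  }
  list(cohort = cohort, covariates = final)
}

#' Run a full target-trial-emulation analysis
#'
#' End-to-end orchestration: obtain a registry bundle (generated from a
#' synthetic configuration or read from disk), screen eligibility, assign
#' strategies at time zero, and produce effect estimates with bootstrap
#' confidence intervals, risk-curve tables, a covariate balance table and
#' the exclusion flowchart, together with a run manifest.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `synthetic` (arguments for [synthetic_config()]) or `bundle_dir`;
#'   optional `eligibility` (arguments for [eligibility_spec()]);
#'   `estimand` (`"itt"`, `"pp"` or both), `outcome`, `adjustment`,
#'   `grace_days`, `adherence_mode`, `truncation_percentile`, `horizon`,
#'   `n_boot` (0 skips the bootstrap), `seed`, and `subgroups` (a named
#'   list of filter expressions on cohort columns, as strings).
#' @param out_dir Optional directory: writes `effects.csv`, `curves.csv`,
#'   `balance.csv`, `flowchart.json` and `manifest.json`.
#' @return A list of class `tte_report` with `effects`, `curves`,
#'   `balance`, `flowchart`, `adherence`, `manifest`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  horizon <- config$horizon %||% 60L
  estimands <- config$estimand %||% c("itt", "pp")
  outcomes <- config$outcome %||% "composite"
  adjustment <- config$adjustment %||% "ipw"
  n_boot <- config$n_boot %||% 0L

  elig_args <- config$eligibility %||% list()
  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- seed
    scfg <- do.call(synthetic_config, syn_args)
    bundle <- inject_missingness(generate_registry(scfg), scfg)
    if (is.null(elig_args$recruitment_start)) {
      elig_args$recruitment_start <- scfg$recruitment_start
      elig_args$recruitment_end <- scfg$recruitment_end
    }
    end_of_study <- scfg$end_of_study
  } else if (!is.null(config$bundle_dir)) {
    bundle <- read_registry(config$bundle_dir,
                            config$bundle_format %||% "csv")
    end_of_study <- if (!is.null(config$end_of_study))
      as.Date(config$end_of_study) else NULL
  } else {
    stop("config needs either 'synthetic' or 'bundle_dir'", call. = FALSE)
  }
  validate_registry(bundle)
  espec <- do.call(eligibility_spec, elig_args)

  screened <- screen_eligibility(bundle, espec)
  cohort <- assign_strategy(screened$candidates, bundle$dispensations,
                            espec, screened$flowchart)
  flowchart <- attr(cohort, "flowchart")

  data <- list(cohort = cohort, dispensations = bundle$dispensations,
               diagnoses = bundle$diagnoses, deaths = bundle$deaths,
               outcomes = bundle$outcomes)

  weight_covariates <- config$weight_covariates %||% NULL
  prep <- prepare_covariates(cohort,
                             weight_covariates %||% intersect(
                               c("age", "female", "nstemi", "sbp", "egfr",
                                 "ldl", "lvef", "employment"),
                               names(cohort)))
  w_bal <- if (adjustment %in% c("ipw", "age_sex_only")) {
    baseline_ip_weights(prep$cohort, prep$covariates,
                        config$truncation_percentile)
  } else rep(1, nrow(cohort))
  balance <- balance_table(prep$cohort, as.numeric(w_bal), prep$covariates)

  subgroups <- c(list(all = NULL), config$subgroups %||% list())
  effects <- list(); curves <- list(); adherence <- list()
  for (sg in names(subgroups)) {
    sel <- if (is.null(subgroups[[sg]])) rep(TRUE, nrow(cohort)) else
      eval(parse(text = subgroups[[sg]]), envir = cohort)
    if (!any(sel)) {
      warning("empty subgroup '", sg, "' skipped")
      next
    }
    d_sg <- data
    d_sg$cohort <- cohort[sel, , drop = FALSE]
    for (est in estimands) for (oc in outcomes) {
      args <- list(estimand = est, outcome = oc, adjustment = adjustment,
                   weight_covariates = weight_covariates,
                   grace_days = config$grace_days %||% 90,
                   adherence_mode = config$adherence_mode %||% "pill_count",
                   truncation_percentile = config$truncation_percentile,
                   horizon = horizon, end_of_study = end_of_study,
                   elig_spec = espec)
      res <- do.call(estimate_effects, c(list(data = d_sg), args))
      row <- data.frame(subgroup = sg, estimand = est, outcome = oc,
                        adjustment = adjustment, n = res$n,
                        t(res$point))
      if (n_boot > 0) {
        pf <- function(d) do.call(estimate_effects,
                                  c(list(data = d), args))$point
        be <- bootstrap_effects(pf, d_sg, n_reps = n_boot, seed = seed)
        for (nm in names(be$point)) {
          row[[paste0(nm, "_lower")]] <- unname(be$lower[nm])
          row[[paste0(nm, "_upper")]] <- unname(be$upper[nm])
        }
        row$n_boot <- n_boot
        row$n_boot_failed <- be$n_failed
      }
      effects[[length(effects) + 1L]] <- row
      cv <- res$curve
      cv$subgroup <- sg; cv$estimand <- est; cv$outcome <- oc
      curves[[length(curves) + 1L]] <- as.data.frame(cv)
      if (!is.null(res$adherence)) {
        ad <- res$adherence; ad$subgroup <- sg; ad$outcome <- oc
        adherence[[length(adherence) + 1L]] <- ad
      }
    }
  }

  manifest <- list(package = "ttemulate",
                   version = as.character(utils::packageVersion("ttemulate")),
                   r_version = R.version.string,
                   seed = seed,
                   config_hash = config_hash(config),
                   timestamp = format(Sys.time(), tz = "UTC"))
  report <- structure(list(effects = do.call(rbind, effects),
                           curves = do.call(rbind, curves),
                           balance = balance, flowchart = flowchart,
                           adherence = if (length(adherence))
                             do.call(rbind, adherence) else NULL,
                           manifest = manifest),
                      class = "tte_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# polynomial rolling hash (mod a Mersenne prime) of the config's JSON form
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a `tte_report` to disk
#'
#' Emits `effects.csv`, `curves.csv`, `balance.csv`, `flowchart.json` and
#' `manifest.json` (plus `adherence.csv` for per-protocol runs).
#'
#' @param report A `tte_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$effects, file.path(out_dir, "effects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$balance, file.path(out_dir, "balance.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$adherence)) {
    utils::write.csv(report$adherence, file.path(out_dir, "adherence.csv"),
                     row.names = FALSE, na = "")
  }
  fc <- report$flowchart
  jsonlite::write_json(list(n_input = fc$n_input,
                            n_eligible = fc$n_eligible,
                            n_by_arm = as.list(fc$n_by_arm),
                            steps = fc$steps),
                       file.path(out_dir, "flowchart.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tte_report <- function(x, ...) {
  cat("<tte_report>\n")
  print(x$flowchart)
  cat("\nEffect estimates at horizon:\n")
  print(x$effects, row.names = FALSE)
  invisible(x)
}
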