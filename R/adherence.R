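#' Build continuous-treatment episodes from dispensations
#'
#' Each dispensation covers `pill_count / pills_per_day` days (or a fixed 90
#' days in `fixed_90` mode) starting at the later of its dispense day and
#' the day after the previous coverage ended (overlapping dispensations
#' stockpile, so no covered day is lost). Successive coverage windows are
#' merged into one episode when the number of uncovered days between one
#' coverage end and the next dispensation is strictly less than
#' `grace_days`; otherwise a new episode starts. An episode's `end_day` is
#' its last *covered* day; bridged gaps shorter than the grace period lie
#' inside the episode but do not extend coverage.
#'
#' Dispensations before `min_day` are ignored: in the pipeline this drops
#' pre-assignment history, which affected eligibility but not adherence.
#'
#' @param dispensations Data frame with `person_id`, `dispense_day` (integer
#'   day offsets) and `pill_count`.
#' @param pills_per_day Fixed daily dose (default 1 tablet/day).
#' @param grace_days Maximum bridgeable gap, exclusive (default `< 90`).
#' @param mode `"pill_count"` (supply from the pill count) or `"fixed_90"`
#'   (every dispensation counts as 90 days of supply).
#' @param min_day Dispensations strictly before this day are dropped.
#' @return Data frame with one row per episode: `person_id`, `episode`,
#'   `start_day`, `end_day`, `covered_days`, `n_dispensations`.
#' @export
build_episodes <- function(dispensations, pills_per_day = 1, grace_days = 90,
                           mode = c("pill_count", "fixed_90"),
                           min_day = -Inf) {
  mode <- match.arg(mode)
  stopifnot(pills_per_day >= 1, grace_days >= 0)
  empty <- data.frame(person_id = character(), episode = integer(),
                      start_day = numeric(), end_day = numeric(),
                      covered_days = numeric(), n_dispensations = integer())
  d <- dispensations[dispensations$dispense_day >= min_day, , drop = FALSE]
  if (!nrow(d)) return(empty)
  if (mode == "pill_count" && any(d$pill_count < 1)) {
    stop("pill_count must be >= 1 in pill_count mode", call. = FALSE)
  }
  d <- d[order(d$person_id, d$dispense_day), ]
  days_supplied <- if (mode == "fixed_90") rep(90, nrow(d)) else
    d$pill_count / pills_per_day
  out <- vector("list", length(unique(d$person_id)))
  k <- 0L
  for (rows in split(seq_len(nrow(d)), d$person_id)) {
    dd <- d$dispense_day[rows]
    supply <- days_supplied[rows]
    ep <- integer(length(rows)); starts <- ends <- numeric(length(rows))
    cur_ep <- 1L
    cov_start <- dd[1]; cov_end <- dd[1] + supply[1] - 1
    ep[1] <- 1L; starts[1] <- cov_start; ends[1] <- cov_end
    if (length(rows) > 1L) {
      for (j in 2:length(rows)) {
        gap <- dd[j] - cov_end - 1
        if (gap >= grace_days) {
          cur_ep <- cur_ep + 1L
          cov_start <- dd[j]
          cov_end <- dd[j] + supply[j] - 1
        } else {
          cov_end <- max(cov_end + 1, dd[j]) + supply[j] - 1
        }
        ep[j] <- cur_ep; starts[j] <- cov_start; ends[j] <- cov_end
      }
    }
    k <- k + 1L
    last <- !duplicated(ep, fromLast = TRUE)
    first <- !duplicated(ep)
    out[[k]] <- data.frame(
      person_id = d$person_id[rows[1]], episode = ep[last],
      start_day = starts[first], end_day = ends[last],
      covered_days = as.numeric(tapply(supply, ep, sum)),
      n_dispensations = as.integer(tabulate(ep)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-protocol deviation time for one individual
#'
#' Under the treated strategy, the protocol is deviated from on the day
#' non-adherence is established: the first coverage end that is not followed
#' by a dispensation within the grace period, plus `grace_days` — unless a
#' contraindication was diagnosed on or before that day, in which case
#' stopping is protocol-consistent and the individual is never censored.
#' Under the untreated strategy, deviation occurs at the first drug
#' dispensation after time zero, unless it was preceded by a qualifying
#' indication (hypertension for the composite and heart-failure outcomes;
#' additionally heart failure for the death and myocardial infarction
#' outcomes).
#'
#' @param arm `"acei_arb"` or `"none"`.
#' @param episodes Episodes for this person from [build_episodes()] (of the
#'   study drug class), day offsets from time zero.
#' @param indication_days,contraindication_days Day offsets of post-baseline
#'   qualifying diagnoses (hypertension/heart failure, and
#'   hypotension/renal-artery-stenosis respectively).
#' @param grace_days Grace period in days.
#' @param horizon_days Follow-up horizon in days; deviations established
#'   after it return `NULL` (strategy followed through horizon).
#' @param outcome_variant `"composite"` (hypertension rescues initiation) or
#'   `"death_or_mi"` (hypertension or heart failure rescues).
#' @return `NULL`, or a list with `censor_day` and `reason`
#'   (`"stopped_treatment"` or `"initiated_treatment"`).
#' @export
pp_censor_time <- function(arm, episodes, indication_days = numeric(0),
                           contraindication_days = numeric(0),
                           grace_days = 90, horizon_days = 1800,
                           outcome_variant = c("composite", "death_or_mi")) {
  outcome_variant <- match.arg(outcome_variant)
  if (arm == "acei_arb") {
    if (is.null(episodes) || !nrow(episodes)) {
      candidate <- grace_days  # never covered: lapsed from time zero
    } else {
      candidate <- episodes$end_day[1] + grace_days
    }
    if (candidate > horizon_days) return(NULL)
    if (length(contraindication_days) &&
        min(contraindication_days) <= candidate) return(NULL)
    return(list(censor_day = candidate, reason = "stopped_treatment"))
  }
  if (is.null(episodes) || !nrow(episodes)) return(NULL)
  first_disp <- min(episodes$start_day)
  if (first_disp > horizon_days) return(NULL)
  if (length(indication_days) && min(indication_days) <= first_disp) {
    return(NULL)
  }
  list(censor_day = first_disp, reason = "initiated_treatment")
}

#' Per-protocol censoring events for a cohort
#'
#' Applies [build_episodes()] and [pp_censor_time()] across a cohort:
#' study-drug dispensations are re-expressed as day offsets from each
#' person's time zero, pre-assignment dispensations are dropped, and
#' post-baseline indication/contraindication diagnoses (any position, any
#' setting) determine protocol-consistent stopping or initiation.
#'
#' @param cohort Cohort from [assign_strategy()].
#' @param bundle The `registry_bundle` the cohort came from.
#' @param spec An [eligibility_spec()] (for the ATC prefixes).
#' @param grace_days,mode,outcome_variant Passed to [build_episodes()] and
#'   [pp_censor_time()].
#' @param horizon_months Follow-up horizon (30-day months).
#' @param hypertension_codes,heart_failure_codes Indication code prefixes
#'   for the untreated strategy's rescue rule.
#' @return Data frame `person_id`, `censor_day`, `reason` (one row per
#'   deviating person).
#' @export
pp_censor_events <- function(cohort, bundle, spec = eligibility_spec(),
                             grace_days = 90,
                             mode = c("pill_count", "fixed_90"),
                             outcome_variant = c("composite", "death_or_mi"),
                             horizon_months = 60L,
                             hypertension_codes = c("I10", "I11", "I12",
                                                    "I13", "I15"),
                             heart_failure_codes = "I50") {
  mode <- match.arg(mode)
  outcome_variant <- match.arg(outcome_variant)
  horizon_days <- horizon_months * 30L
  tz <- stats::setNames(cohort$time_zero, cohort$person_id)
  arm <- stats::setNames(cohort$arm, cohort$person_id)

  disp <- bundle$dispensations
  disp <- disp[matches_prefix(disp$atc_code, spec$acei_arb_atc_prefixes) &
                 disp$person_id %in% cohort$person_id, , drop = FALSE]
  disp$dispense_day <- as.numeric(disp$dispense_date -
                                    tz[disp$person_id])
  # adherence starts at assignment for the treated, at time zero otherwise
  min_day <- stats::setNames(rep(1, nrow(cohort)), cohort$person_id)
  tr <- cohort$arm == "acei_arb"
  min_day[cohort$person_id[tr]] <-
    as.numeric(cohort$assignment_date[tr] - cohort$time_zero[tr])
  disp <- disp[disp$dispense_day >= min_day[disp$person_id], , drop = FALSE]
  episodes <- build_episodes(disp, grace_days = grace_days, mode = mode)
  ep_split <- split(episodes, episodes$person_id)

  dx <- bundle$diagnoses[bundle$diagnoses$person_id %in% cohort$person_id, ,
                         drop = FALSE]
  dx$day <- as.numeric(dx$date - tz[dx$person_id])
  dx <- dx[dx$day > 0, , drop = FALSE]
  ind_codes <- hypertension_codes
  if (outcome_variant == "death_or_mi") {
    ind_codes <- c(ind_codes, heart_failure_codes)
  }
  ind <- dx[matches_prefix(dx$code, ind_codes), c("person_id", "day")]
  con <- dx[matches_prefix(dx$code, spec$contraindication_codes),
            c("person_id", "day")]
  ind_split <- split(ind$day, ind$person_id)
  con_split <- split(con$day, con$person_id)

  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$person_id[i]
    ce <- pp_censor_time(arm[[pid]], ep_split[[pid]],
                         indication_days = ind_split[[pid]] %||% numeric(0),
                         contraindication_days = con_split[[pid]] %||%
                           numeric(0),
                         grace_days = grace_days,
                         horizon_days = horizon_days,
                         outcome_variant = outcome_variant)
    if (!is.null(ce)) {
      out[[i]] <- data.frame(person_id = pid, censor_day = ce$censor_day,
                             reason = ce$reason)
    }
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) {
    res <- data.frame(person_id = character(), censor_day = numeric(),
                      reason = character())
  }
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adherence curve by arm
#'
#' Kaplan-Meier-style proportion still adhering to the assigned strategy at
#' each month, where the "event" is protocol deviation and the end of
#' follow-up (death, outcome, administrative end) is treated as
#' non-informative censoring. Deviations beyond the horizon count as
#' adherent throughout.
#'
#' @param cohort Cohort with `person_id` and `arm`.
#' @param censor_events Output of [pp_censor_events()].
#' @param horizon Months.
#' @param followup_end_month Optional named (by person) vector of last
#'   months under observation; defaults to the full horizon.
#' @return Data frame `arm`, `month`, `prop_adherent`.
#' @export
adherence_curve <- function(cohort, censor_events, horizon = 60L,
                            followup_end_month = NULL) {
  dev_month <- rep(Inf, nrow(cohort))
  i <- match(censor_events$person_id, cohort$person_id)
  dev_month[i] <- pmax(1, ceiling(censor_events$censor_day / 30))
  end_month <- rep(horizon, nrow(cohort))
  if (!is.null(followup_end_month)) {
    j <- match(names(followup_end_month), cohort$person_id)
    end_month[j[!is.na(j)]] <- pmin(horizon,
                                    followup_end_month[!is.na(j)])
  }
  out <- list()
  for (a in unique(cohort$arm)) {
    sel <- cohort$arm == a
    dm <- dev_month[sel]; em <- end_month[sel]
    surv <- numeric(horizon); s <- 1
    for (t in seq_len(horizon)) {
      at_risk <- sum(dm >= t & em >= t)
      events <- sum(dm == t & em >= t)
      if (at_risk > 0) s <- s * (1 - events / at_risk)
      surv[t] <- s
    }
    out[[a]] <- data.frame(arm = a, month = seq_len(horizon),
                           prop_adherent = surv)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
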