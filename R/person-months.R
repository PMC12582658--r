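#' Expand a cohort into person-month rows
#'
#' Discretizes follow-up into 30-day months numbered from 1. A person's
#' series ends at the month of the first qualifying event (`Y = 1` on the
#' final row), at the administrative end of follow-up (end of study or the
#' horizon), or — in per-protocol mode — at the month of protocol deviation
#' (`C = 1`, `Y = 0` on the final row, which is retained so censoring
#' models can be fit but must be excluded from outcome fits). When an event
#' and a deviation fall in the same month the event takes precedence: the
#' outcome occurred while still on protocol at the start of the month. In
#' intention-to-treat mode deviation censoring is ignored entirely.
#'
#' For the nonfatal outcomes (`mi`, `hf`) death ends follow-up without an
#' event; no competing-risk adjustment is attempted.
#'
#' @param cohort Cohort from [assign_strategy()] (needs `person_id`, `arm`,
#'   `time_zero`).
#' @param outcomes,deaths Bundle outcome and death tables.
#' @param censor_events Deviations from [pp_censor_events()] (per-protocol
#'   mode only).
#' @param horizon Months of follow-up.
#' @param estimand `"itt"` or `"pp"`.
#' @param outcome `"composite"`, `"death"`, `"mi"` or `"hf"`.
#' @param end_of_study Optional administrative end date.
#' @param carry Character vector of cohort columns to carry onto every row
#'   (baseline covariates); defaults to all columns except identifiers.
#' @param tv Optional named list of per-person first-event days (named
#'   numeric vectors keyed by `person_id`); each becomes a 0/1 column that
#'   switches on from the month containing the day.
#' @return Data frame of person-months: `person_id`, `month`, `treated`,
#'   `Y`, `C`, carried covariates and time-varying flags.
#' @export
expand_person_months <- function(cohort, outcomes, deaths,
                                 censor_events = NULL, horizon = 60L,
                                 estimand = c("itt", "pp"),
                                 outcome = c("composite", "death", "mi",
                                             "hf"),
                                 end_of_study = NULL, carry = NULL,
                                 tv = NULL) {
  estimand <- match.arg(estimand)
  outcome <- match.arg(outcome)
  n <- nrow(cohort)
  tz <- cohort$time_zero
  pid <- cohort$person_id

  day_of <- function(tab, date_col) {
    d <- rep(Inf, n)
    i <- match(tab$person_id, pid)
    keep <- !is.na(i)
    dd <- as.numeric(tab[[date_col]][keep] - tz[i[keep]])
    dd[dd <= 0] <- Inf  # prevalent records are not follow-up events
    # first occurrence per person
    ord <- order(i[keep], dd)
    ik <- i[keep][ord]; dk <- dd[ord]
    fst <- !duplicated(ik)
    d[ik[fst]] <- dk[fst]
    d
  }
  death_day <- day_of(deaths, "death_date")
  mi_day <- day_of(outcomes[outcomes$event_type == "mi", , drop = FALSE],
                   "event_date")
  hf_day <- day_of(outcomes[outcomes$event_type == "hf", , drop = FALSE],
                   "event_date")
  event_day <- switch(outcome,
    composite = pmin(death_day, mi_day, hf_day),
    death = death_day, mi = mi_day, hf = hf_day)
  # death ends follow-up for nonfatal outcomes
  other_end_day <- if (outcome %in% c("mi", "hf")) death_day else
    rep(Inf, n)

  month_of <- function(day) pmax(1, ceiling(day / 30))
  event_month <- ifelse(is.finite(event_day), month_of(event_day), Inf)
  admin_month <- rep(horizon, n)
  if (!is.null(end_of_study)) {
    admin_month <- pmin(admin_month,
                        pmax(0, floor(as.numeric(as.Date(end_of_study) - tz)
                                      / 30)))
  }
  admin_month <- pmin(admin_month,
                      ifelse(is.finite(other_end_day),
                             month_of(other_end_day) - 1, horizon))
  dev_month <- rep(Inf, n)
  if (estimand == "pp" && !is.null(censor_events) &&
      nrow(censor_events)) {
    i <- match(censor_events$person_id, pid)
    dev_month[i] <- month_of(censor_events$censor_day)
  }

  last_month <- pmin(event_month, admin_month, dev_month, horizon)
  is_event <- is.finite(event_month) & event_month <= last_month &
    event_month <= pmin(admin_month, dev_month, horizon)
  is_dev <- !is_event & is.finite(dev_month) &
    dev_month <= pmin(admin_month, horizon)
  keep <- last_month >= 1
  idx <- which(keep)
  m_i <- as.integer(last_month[idx])

  rows <- data.frame(
    person_id = rep(pid[idx], m_i),
    month = sequence(m_i),
    treated = rep(as.integer(cohort$arm[idx] == "acei_arb"), m_i))
  final <- rows$month == rep(m_i, m_i)
  rows$Y <- as.integer(final & rep(is_event[idx], m_i))
  rows$C <- as.integer(final & rep(is_dev[idx], m_i))

  if (is.null(carry)) {
    carry <- setdiff(names(cohort),
                     c("person_id", "arm", "time_zero", "assignment_date",
                       "admission_date", "discharge_date"))
  }
  for (cl in carry) rows[[cl]] <- rep(cohort[[cl]][idx], m_i)

  if (!is.null(tv)) {
    for (nm in names(tv)) {
      d <- rep(Inf, n)
      j <- match(names(tv[[nm]]), pid)
      d[j[!is.na(j)]] <- tv[[nm]][!is.na(j)]
      first_m <- month_of(d)
      rows[[nm]] <- as.integer(rows$month >= rep(first_m[idx], m_i) &
                                 rep(is.finite(d[idx]), m_i))
    }
  }
  rows
}

#' First post-baseline record days for time-varying covariates
#'
#' Scans the bundle for the first post-baseline diagnosis or dispensation
#' matching each code/ATC prefix set, as day offsets from time zero, in the
#' form [expand_person_months()] expects for its `tv` argument.
#'
#' @param cohort Cohort with `person_id` and `time_zero`.
#' @param bundle The registry bundle.
#' @param diagnosis_sets Named list of diagnosis code prefix vectors.
#' @param dispensation_sets Named list of ATC prefix vectors.
#' @return Named list of named numeric vectors (first day per person).
#' @export
tv_first_days <- function(cohort, bundle,
                          diagnosis_sets = list(tv_renal = "N18",
                                                tv_diabetes = c("E10",
                                                                "E11")),
                          dispensation_sets = list(tv_betablocker = "C07")) {
  tz <- stats::setNames(cohort$time_zero, cohort$person_id)
  first_days <- function(tab, date_col, code_col, prefixes) {
    tab <- tab[tab$person_id %in% cohort$person_id &
                 matches_prefix(tab[[code_col]], prefixes), , drop = FALSE]
    if (!nrow(tab)) return(stats::setNames(numeric(0), character(0)))
    day <- as.numeric(tab[[date_col]] - tz[tab$person_id])
    tab <- tab[day > 0, , drop = FALSE]; day <- day[day > 0]
    if (!nrow(tab)) return(stats::setNames(numeric(0), character(0)))
    ord <- order(tab$person_id, day)
    fst <- !duplicated(tab$person_id[ord])
    stats::setNames(day[ord][fst], tab$person_id[ord][fst])
  }
  out <- list()
  for (nm in names(diagnosis_sets)) {
    out[[nm]] <- first_days(bundle$diagnoses, "date", "code",
                            diagnosis_sets[[nm]])
  }
  for (nm in names(dispensation_sets)) {
    out[[nm]] <- first_days(bundle$dispensations, "dispense_date",
                            "atc_code", dispensation_sets[[nm]])
  }
  out
}
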