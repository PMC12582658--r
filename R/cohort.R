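#' Eligibility specification
#'
#' Encodes the trial eligibility protocol applied to an admission: age
#' window, recruitment period, preserved ejection fraction, standard
#' infarction care (angiography plus statin and antithrombotic dispensations
#' in the assignment window), occupational status, absence of
#' contraindications (low eGFR, hypotension, renal artery stenosis), absence
#' of indications other than secondary prevention (prior ACEi/ARB use,
#' hypertension, chronic kidney disease, diabetes, heart failure), and no
#' dementia or metastatic cancer, each assessed over a lookback window
#' before admission.
#'
#' @param age_min,age_max_exclusive Age at admission must satisfy
#'   `age_min <= age < age_max_exclusive`.
#' @param assignment_window_days Days after admission in which a qualifying
#'   dispensation defines treatment assignment (and in which standard-care
#'   dispensations are sought).
#' @param lvef_min_percent Minimum ejection fraction (inclusive).
#' @param egfr_min Minimum eGFR (mL/min/1.73m2); lower values are a
#'   contraindication.
#' @param lookback_years History window scanned before admission.
#' @param recruitment_start,recruitment_end Admission date window.
#' @param indication_codes,contraindication_codes,dementia_codes,cancer_codes
#'   ICD-10-style code prefixes.
#' @param acei_arb_atc_prefixes,statin_atc_prefixes,antithrombotic_atc_prefixes
#'   ATC code prefixes.
#' @param employment_required If `TRUE`, occupational status must be one of
#'   `employment_eligible`.
#' @param employment_eligible Eligible occupational statuses.
#' @param time_zero_mode `"landmark"` places time zero at
#'   `admission_date + assignment_window_days` for both arms (the default;
#'   a common landmark avoids immortal time between arms). `"assignment"`
#'   uses the qualifying dispensation date for the treated arm instead.
#' @return A list of class `eligibility_spec`.
#' @export
eligibility_spec <- function(age_min = 18, age_max_exclusive = 75,
                             assignment_window_days = 30L,
                             lvef_min_percent = 50, egfr_min = 15,
                             lookback_years = 3,
                             recruitment_start = as.Date("2010-09-01"),
                             recruitment_end = as.Date("2021-06-30"),
                             indication_codes = c("I10", "I11", "I12", "I13",
                                                  "I15", "I50", "E10", "E11",
                                                  "N18"),
                             contraindication_codes = c("I95", "I70.1"),
                             dementia_codes = c("F00", "F01", "F02", "F03",
                                                "G30"),
                             cancer_codes = c("C77", "C78", "C79"),
                             acei_arb_atc_prefixes = c("C09A", "C09B", "C09C",
                                                       "C09D"),
                             statin_atc_prefixes = "C10AA",
                             antithrombotic_atc_prefixes = "B01AC",
                             employment_required = TRUE,
                             employment_eligible = c("working", "retired",
                                                     "student"),
                             time_zero_mode = c("landmark", "assignment")) {
  stopifnot(age_min < age_max_exclusive, assignment_window_days > 0,
            lookback_years > 0)
  spec <- list(age_min = age_min, age_max_exclusive = age_max_exclusive,
               assignment_window_days = as.integer(assignment_window_days),
               lvef_min_percent = lvef_min_percent, egfr_min = egfr_min,
               lookback_years = lookback_years,
               recruitment_start = as.Date(recruitment_start),
               recruitment_end = as.Date(recruitment_end),
               indication_codes = indication_codes,
               contraindication_codes = contraindication_codes,
               dementia_codes = dementia_codes, cancer_codes = cancer_codes,
               acei_arb_atc_prefixes = acei_arb_atc_prefixes,
               statin_atc_prefixes = statin_atc_prefixes,
               antithrombotic_atc_prefixes = antithrombotic_atc_prefixes,
               employment_required = employment_required,
               employment_eligible = employment_eligible,
               time_zero_mode = match.arg(time_zero_mode))
  class(spec) <- "eligibility_spec"
  spec
}

# TRUE where x starts with any of the prefixes
matches_prefix <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(as.character(x), p)
  out
}

# person_ids having a matching record dated in (from, to]
persons_with_record <- function(tab, date_col, code_col, prefixes, from, to) {
  if (!nrow(tab)) return(character(0))
  i <- match(tab$person_id, names(from))
  keep <- !is.na(i) & matches_prefix(tab[[code_col]], prefixes) &
    tab[[date_col]] > from[i] & tab[[date_col]] <= to[i]
  unique(tab$person_id[keep])
}

#' Screen a registry bundle against the eligibility protocol
#'
#' Applies each eligibility criterion in protocol order and tallies
#' exclusions; an individual failing several criteria is counted only under
#' the first failed one, so the flowchart conserves counts
#' (`n_input = n_eligible + sum(excluded)`). Missing values in fields that a
#' criterion needs (age, LVEF, eGFR, occupational status) fail that
#' criterion, since eligibility cannot be confirmed. Lookback windows are
#' `(admission - lookback, admission]` for diagnoses and
#' `(admission - lookback, admission)` for prior dispensations (a
#' dispensation on the admission day itself can be the treatment
#' assignment, not history).
#'
#' If a person has several admission rows, the earliest is used with a
#' warning.
#'
#' @param bundle A `registry_bundle`.
#' @param spec An [eligibility_spec()].
#' @return A list with `candidates` (eligible admission rows) and
#'   `flowchart` (a `flowchart_tally`).
#' @export
screen_eligibility <- function(bundle, spec = eligibility_spec()) {
  adm <- bundle$admissions
  if (anyDuplicated(adm$person_id)) {
    warning("overlapping admissions; keeping the earliest per person")
    adm <- adm[order(adm$admission_date), ]
    adm <- adm[!duplicated(adm$person_id), ]
  }
  n_input <- nrow(adm)
  lb_days <- round(spec$lookback_years * 365.25)
  from <- stats::setNames(adm$admission_date - lb_days, adm$person_id)
  to <- stats::setNames(adm$admission_date, adm$person_id)
  to_excl <- stats::setNames(adm$admission_date - 1L, adm$person_id)
  win_end <- stats::setNames(adm$admission_date + spec$assignment_window_days,
                             adm$person_id)

  dx <- bundle$diagnoses
  disp <- bundle$dispensations
  fail <- list()
  fail$age <- is.na(adm$age) | adm$age < spec$age_min |
    adm$age >= spec$age_max_exclusive
  fail$recruitment_period <- adm$admission_date < spec$recruitment_start |
    adm$admission_date > spec$recruitment_end
  fail$lvef <- is.na(adm$lvef) | adm$lvef < spec$lvef_min_percent
  care_statin <- persons_with_record(disp, "dispense_date", "atc_code",
                                     spec$statin_atc_prefixes,
                                     to_excl, win_end)
  care_at <- persons_with_record(disp, "dispense_date", "atc_code",
                                 spec$antithrombotic_atc_prefixes,
                                 to_excl, win_end)
  angio <- if ("angiography" %in% names(adm)) adm$angiography else TRUE
  fail$standard_care <- !(angio %in% TRUE) |
    !(adm$person_id %in% care_statin) | !(adm$person_id %in% care_at)
  fail$employment <- if (spec$employment_required) {
    is.na(adm$employment) | !(adm$employment %in% spec$employment_eligible)
  } else rep(FALSE, n_input)
  contra_hist <- persons_with_record(dx, "date", "code",
                                     spec$contraindication_codes, from, to)
  fail$contraindication <- is.na(adm$egfr) | adm$egfr < spec$egfr_min |
    adm$person_id %in% contra_hist
  prior_use <- persons_with_record(disp, "dispense_date", "atc_code",
                                   spec$acei_arb_atc_prefixes, from, to_excl)
  fail$prior_acei_arb_use <- adm$person_id %in% prior_use
  ind_hist <- persons_with_record(dx, "date", "code", spec$indication_codes,
                                  from, to)
  fail$prior_indication <- adm$person_id %in% ind_hist
  dem_hist <- persons_with_record(dx, "date", "code", spec$dementia_codes,
                                  from, to)
  fail$dementia <- adm$person_id %in% dem_hist
  ca_hist <- persons_with_record(dx, "date", "code", spec$cancer_codes,
                                 from, to)
  fail$metastatic_cancer <- adm$person_id %in% ca_hist

  remaining <- rep(TRUE, n_input)
  steps <- data.frame(criterion = names(fail),
                      n_excluded = NA_integer_)
  for (k in seq_along(fail)) {
    hit <- remaining & fail[[k]]
    steps$n_excluded[k] <- sum(hit)
    remaining <- remaining & !hit
  }
  candidates <- adm[remaining, , drop = FALSE]
  rownames(candidates) <- NULL
  flowchart <- structure(list(steps = steps, n_input = n_input,
                              n_eligible = nrow(candidates),
                              n_by_arm = NULL),
                         class = "flowchart_tally")
  list(candidates = candidates, flowchart = flowchart)
}

#' @export
print.flowchart_tally <- function(x, ...) {
  cat("<flowchart_tally>  input:", x$n_input, " eligible:", x$n_eligible,
      "\n")
  print(x$steps, row.names = FALSE)
  if (!is.null(x$n_by_arm)) {
    cat("by arm:", paste(names(x$n_by_arm), x$n_by_arm, sep = "=",
                         collapse = "  "), "\n")
  }
  invisible(x)
}

#' Assign treatment strategy at baseline
#'
#' An individual is assigned to the `acei_arb` arm if and only if a
#' dispensation matching one of the configured ATC prefixes is dated within
#' `[admission_date, admission_date + assignment_window_days]`; otherwise to
#' the `none` arm. Time zero follows `spec$time_zero_mode` (see
#' [eligibility_spec()]). Dispensations with unmatched ATC codes are
#' ignored.
#'
#' @param candidates Eligible admission rows from [screen_eligibility()].
#' @param dispensations The bundle dispensations table.
#' @param spec An [eligibility_spec()].
#' @param flowchart Optional `flowchart_tally` to annotate with per-arm
#'   counts.
#' @return A cohort data frame (one row per person) with `arm`,
#'   `assignment_date` (NA in the `none` arm) and `time_zero`; if
#'   `flowchart` was supplied it is attached as attribute `"flowchart"`.
#' @export
assign_strategy <- function(candidates, dispensations,
                            spec = eligibility_spec(), flowchart = NULL) {
  cohort <- candidates
  n <- nrow(cohort)
  disp <- dispensations[matches_prefix(dispensations$atc_code,
                                       spec$acei_arb_atc_prefixes), ]
  i <- match(disp$person_id, cohort$person_id)
  keep <- !is.na(i)
  disp <- disp[keep, ]; i <- i[keep]
  in_window <- disp$dispense_date >= cohort$admission_date[i] &
    disp$dispense_date <= cohort$admission_date[i] + spec$assignment_window_days
  disp <- disp[in_window, ]; i <- i[in_window]
  assignment_date <- as.Date(rep(NA, n))
  if (nrow(disp)) {
    ord <- order(i, disp$dispense_date)
    first <- ord[!duplicated(i[ord])]
    assignment_date[i[first]] <- disp$dispense_date[first]
  }
  cohort$arm <- ifelse(is.na(assignment_date), "none", "acei_arb")
  cohort$assignment_date <- assignment_date
  landmark <- cohort$admission_date + spec$assignment_window_days
  cohort$time_zero <- if (spec$time_zero_mode == "assignment") {
    as.Date(ifelse(is.na(assignment_date), landmark, assignment_date),
            origin = "1970-01-01")
  } else landmark
  if (!is.null(flowchart)) {
    flowchart$n_by_arm <- c(acei_arb = sum(cohort$arm == "acei_arb"),
                            none = sum(cohort$arm == "none"))
    attr(cohort, "flowchart") <- flowchart
  }
  rownames(cohort) <- NULL
  cohort
}

#' Categorize covariates with explicit missing levels
#'
#' Converts continuous covariates to categories at the supplied cut points
#' (open boundary categories absorb out-of-range values) and adds an
#' explicit `"missing"` level wherever a value is `NA`; character/factor
#' covariates gain the `"missing"` level directly. Raw values are preserved:
#' the categorized version is stored as `<name>_cat`.
#'
#' @param rows A cohort data frame.
#' @param scheme Named list: covariate name to numeric cut points (for
#'   continuous covariates) or `NULL` (for categorical ones).
#' @return `rows` with `<name>_cat` factor columns appended.
#' @export
categorize_covariates <- function(rows, scheme = default_category_scheme()) {
  for (nm in names(scheme)) {
    if (!nm %in% names(rows)) {
      stop("covariate '", nm, "' not found in cohort", call. = FALSE)
    }
    x <- rows[[nm]]
    cuts <- scheme[[nm]]
    if (is.null(cuts) || is.character(x) || is.factor(x)) {
      f <- factor(as.character(x))
    } else {
      f <- cut(as.numeric(x), breaks = c(-Inf, cuts, Inf), right = TRUE)
    }
    lv <- c(levels(f), "missing")
    f <- factor(ifelse(is.na(x), "missing", as.character(f)), levels = lv)
    f <- droplevels(f, exclude = NULL)
    rows[[paste0(nm, "_cat")]] <- f
  }
  rows
}

#' Default categorization scheme for the synthetic covariates
#' @return Named list of cut points for [categorize_covariates()].
#' @export
default_category_scheme <- function() {
  list(age = c(55, 65), sbp = c(130, 150, 170), egfr = c(60, 90),
       ldl = c(2.5, 3.5), lvef = c(55, 60), employment = NULL)
}
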