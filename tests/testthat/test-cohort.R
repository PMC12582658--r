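test_that("age and LVEF boundaries follow the protocol inequalities", {
  tb <- make_test_bundle(n = 5, age = c(74.5, 75, 17, 60, 60),
                         lvef = c(55, 55, 55, 49, 50))
  s <- screen_eligibility(tb$bundle)
  expect_setequal(s$candidates$person_id, tb$ids[c(1, 5)])
  steps <- s$flowchart$steps
  expect_equal(steps$n_excluded[steps$criterion == "age"], 2)
  expect_equal(steps$n_excluded[steps$criterion == "lvef"], 1)
})

test_that("history-based exclusions scan the lookback window only", {
  tb <- make_test_bundle(n = 4)
  adm_date <- as.Date("2016-03-01")
  dx <- data.frame(
    person_id = tb$ids[c(1, 2, 3)],
    code = c("I10", "I10", "F03"),
    date = c(adm_date - 100, adm_date - 4 * 365, adm_date - 30),
    setting = "outpatient", position = "secondary")
  b <- add_rows(tb$bundle, "diagnoses", dx)
  # prior drug use strictly before admission; admission-day dispensation is
  # assignment, not history
  disp <- data.frame(person_id = tb$ids[c(4, 2)], atc_code = "C09AA02",
                     dispense_date = c(adm_date - 50, adm_date),
                     pill_count = 100)
  b <- add_rows(b, "dispensations", disp)
  s <- screen_eligibility(b)
  steps <- s$flowchart$steps
  expect_equal(steps$n_excluded[steps$criterion == "prior_indication"], 1)
  expect_equal(steps$n_excluded[steps$criterion == "dementia"], 1)
  expect_equal(steps$n_excluded[steps$criterion == "prior_acei_arb_use"], 1)
  expect_setequal(s$candidates$person_id, tb$ids[2])
})

test_that("flowchart conserves counts and matches injected violations", {
  cfg <- synthetic_config(
    n_individuals = 500, seed = 31,
    noneligible_counts = c(prior_indication = 20, too_old = 5,
                           low_egfr = 8, dementia = 3, prior_use = 6,
                           low_lvef = 4))
  b <- generate_registry(cfg)
  s <- screen_eligibility(b)
  fc <- s$flowchart
  expect_equal(fc$n_input, fc$n_eligible + sum(fc$steps$n_excluded))
  got <- setNames(fc$steps$n_excluded, fc$steps$criterion)
  expect_equal(unname(got["age"]), 5)
  expect_equal(unname(got["lvef"]), 4)
  expect_equal(unname(got["contraindication"]), 8)
  expect_equal(unname(got["prior_acei_arb_use"]), 6)
  expect_equal(unname(got["prior_indication"]), 20)
  expect_equal(unname(got["dementia"]), 3)
  expect_equal(fc$n_eligible, 500)
})

test_that("screening is idempotent and the eligible set is order-free", {
  cfg <- synthetic_config(n_individuals = 300, seed = 17,
                          noneligible_fraction = 0.05)
  b <- generate_registry(cfg)
  s <- screen_eligibility(b)
  # re-screening the eligible set excludes nobody
  b2 <- b
  b2$admissions <- s$candidates
  s2 <- screen_eligibility(b2)
  expect_equal(sum(s2$flowchart$steps$n_excluded), 0)
  expect_equal(s2$flowchart$n_eligible, s$flowchart$n_eligible)
  # first-failure attribution never changes membership: eligible persons
  # are exactly those failing no criterion (generator bookkeeping)
  truth <- attr(b, "truth")
  expect_setequal(s$candidates$person_id,
                  truth$person_id[truth$eligible])
})

test_that("duplicate admissions keep the earliest with a warning", {
  tb <- make_test_bundle(n = 3)
  dup <- tb$bundle$admissions[1, ]
  dup$admission_date <- dup$admission_date + 40
  b <- add_rows(tb$bundle, "admissions", dup)
  expect_warning(s <- screen_eligibility(b), "earliest")
  expect_equal(sum(s$candidates$person_id == tb$ids[1]), 1)
  expect_equal(s$candidates$admission_date[
    s$candidates$person_id == tb$ids[1]], as.Date("2016-03-01"))
})

test_that("assignment follows the 30-day dispensation window strictly", {
  tb <- make_test_bundle(n = 3)
  adm_date <- as.Date("2016-03-01")
  disp <- data.frame(
    person_id = tb$ids[c(1, 2)], atc_code = c("C09AA02", "C09AA02"),
    dispense_date = c(adm_date + 10, adm_date + 31), pill_count = 100)
  b <- add_rows(tb$bundle, "dispensations", disp)
  s <- screen_eligibility(b)
  co <- assign_strategy(s$candidates, b$dispensations, eligibility_spec(),
                        s$flowchart)
  expect_equal(co$arm[match(tb$ids, co$person_id)],
               c("acei_arb", "none", "none"))
  expect_equal(co$assignment_date[co$person_id == tb$ids[1]],
               adm_date + 10)
  # landmark time zero is common to both arms
  expect_true(all(co$time_zero == adm_date + 30))
  fc <- attr(co, "flowchart")
  expect_equal(sum(fc$n_by_arm), fc$n_eligible)
})

test_that("assignment-date time zero applies to the treated arm only", {
  tb <- make_test_bundle(n = 2)
  adm_date <- as.Date("2016-03-01")
  b <- add_rows(tb$bundle, "dispensations",
                data.frame(person_id = tb$ids[1], atc_code = "C09CA01",
                           dispense_date = adm_date + 12, pill_count = 100))
  spec <- eligibility_spec(time_zero_mode = "assignment")
  s <- screen_eligibility(b, spec)
  co <- assign_strategy(s$candidates, b$dispensations, spec)
  expect_equal(co$time_zero[co$person_id == tb$ids[1]], adm_date + 12)
  expect_equal(co$time_zero[co$person_id == tb$ids[2]], adm_date + 30)
})

test_that("cohort arms reproduce the generator's assignment labels", {
  sp <- shared_pipeline_data()
  truth <- attr(sp$bundle, "truth")
  expect_identical(sp$cohort$arm,
                   truth$arm[match(sp$cohort$person_id, truth$person_id)])
  expect_true(all(sp$cohort$time_zero ==
                    truth$time_zero[match(sp$cohort$person_id,
                                          truth$person_id)]))
})

test_that("categorization keeps raw values and adds missing levels", {
  rows <- data.frame(egfr = c(75, NA, 50, 95), employment = c(
    "working", NA, "retired", "working"))
  out <- categorize_covariates(rows, list(egfr = c(60, 90),
                                          employment = NULL))
  expect_equal(as.character(out$egfr_cat),
               c("(60,90]", "missing", "(-Inf,60]", "(90, Inf]"))
  expect_equal(as.character(out$employment_cat)[2], "missing")
  expect_equal(out$egfr, rows$egfr)  # raw preserved
  expect_error(categorize_covariates(rows, list(nope = c(1))), "nope")
})

test_that("category frequencies match a direct cross-tabulation", {
  sp <- shared_pipeline_data()
  co <- categorize_covariates(sp$cohort, list(sbp = c(130, 150, 170)))
  direct <- table(cut(sp$cohort$sbp, c(-Inf, 130, 150, 170, Inf)))
  expect_equal(as.vector(table(co$sbp_cat)[names(direct)]),
               as.vector(direct))
})
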