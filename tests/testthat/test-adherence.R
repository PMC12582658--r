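test_that("gap rule is strict at the grace boundary", {
  d1 <- data.frame(person_id = "a", dispense_day = c(0, 150),
                   pill_count = c(100, 100))
  ep1 <- build_episodes(d1)
  expect_equal(nrow(ep1), 1)
  expect_equal(ep1$start_day, 0)
  expect_equal(ep1$end_day, 249)  # gap 150 - 100 = 50 < 90: bridged

  d2 <- data.frame(person_id = "a", dispense_day = c(0, 190),
                   pill_count = c(100, 100))
  ep2 <- build_episodes(d2)
  expect_equal(nrow(ep2), 2)     # gap exactly 90 is not < 90
  expect_equal(ep2$start_day, c(0, 190))
  expect_equal(ep2$end_day, c(99, 289))
})

test_that("overlapping dispensations stockpile without losing coverage", {
  d <- data.frame(person_id = "a", dispense_day = c(0, 10, 400),
                  pill_count = c(30, 30, 50))
  ep <- build_episodes(d)
  expect_equal(sum(ep$covered_days), 110)  # conservation of pills
  expect_equal(ep$end_day[1], 59)          # 0..29 then 30..59
  expect_equal(nrow(ep), 2)
})

test_that("episodes match a day-grid brute-force simulation", {
  set.seed(404)
  for (s in 1:50) {
    k <- sample(1:8, 1)
    dd <- sort(sample(0:600, k))
    pc <- sample(10:120, k, replace = TRUE)
    d <- data.frame(person_id = "p", dispense_day = dd, pill_count = pc)
    for (grace in c(90, 180)) {
      ep <- build_episodes(d, grace_days = grace)
      oracle <- day_grid_episodes(dd, pc, grace_days = grace)
      expect_equal(cbind(start = ep$start_day, end = ep$end_day), oracle,
                   ignore_attr = TRUE)
      expect_equal(sum(ep$covered_days), sum(pc))
    }
    ep90 <- build_episodes(d, mode = "fixed_90")
    oracle90 <- day_grid_episodes(dd, pc, fixed_90 = TRUE)
    expect_equal(cbind(start = ep90$start_day, end = ep90$end_day),
                 oracle90, ignore_attr = TRUE)
  }
})

test_that("fixed_90 mode equals pill-count mode for 90-pill dispensations", {
  d <- data.frame(person_id = rep(c("a", "b"), c(3, 2)),
                  dispense_day = c(0, 100, 250, 5, 300),
                  pill_count = 90)
  expect_identical(build_episodes(d, mode = "fixed_90"),
                   build_episodes(d, mode = "pill_count"))
})

test_that("dispensations before the origin are ignored", {
  d <- data.frame(person_id = "a", dispense_day = c(-200, 0, 150),
                  pill_count = 100)
  ep <- build_episodes(d, min_day = -30)
  expect_equal(ep$start_day, 0)
  expect_equal(sum(ep$covered_days), 200)
})

test_that("per-protocol deviation follows the strategy-specific rules", {
  # untreated: initiation rescued by a preceding indication
  ep <- data.frame(person_id = "a", episode = 1, start_day = 240,
                   end_day = 339, covered_days = 100, n_dispensations = 1)
  expect_null(pp_censor_time("none", ep, indication_days = 210))
  ce <- pp_censor_time("none", ep, indication_days = 250)
  expect_equal(ce$censor_day, 240)
  expect_equal(ce$reason, "initiated_treatment")

  # treated: lapse established at coverage end + grace
  ep_t <- data.frame(person_id = "a", episode = 1, start_day = 0,
                     end_day = 300, covered_days = 300,
                     n_dispensations = 3)
  ce_t <- pp_censor_time("acei_arb", ep_t)
  expect_equal(ce_t$censor_day, 390)
  expect_equal(ce_t$reason, "stopped_treatment")
  # contraindication on or before the lapse day rescues stopping
  expect_null(pp_censor_time("acei_arb", ep_t, contraindication_days = 390))
  late_con <- pp_censor_time("acei_arb", ep_t, contraindication_days = 391)
  expect_equal(late_con$censor_day, 390)
  # adherent through the horizon: no deviation
  ep_full <- data.frame(person_id = "a", episode = 1, start_day = 0,
                        end_day = 1750, covered_days = 1750,
                        n_dispensations = 18)
  expect_null(pp_censor_time("acei_arb", ep_full, horizon_days = 1800))
  expect_error(pp_censor_time("none", ep, outcome_variant = "bogus"))
})

test_that("heart failure rescues initiation only for death/MI outcomes", {
  sp <- shared_pipeline_data()
  co <- sp$cohort
  b <- sp$bundle
  tr <- attr(b, "truth")
  never <- tr$person_id[tr$arm == "none" & is.na(tr$start_month) &
                          is.na(tr$indication_month)]
  pid <- co$person_id[co$person_id %in% never][1]
  tz <- co$time_zero[co$person_id == pid]
  b$diagnoses <- rbind(
    b$diagnoses[b$diagnoses$person_id != pid, ],
    data.frame(person_id = pid, code = "I50", date = tz + 100,
               setting = "inpatient", position = "primary"))
  b$dispensations <- rbind(
    b$dispensations,
    data.frame(person_id = pid, atc_code = "C09CA01",
               dispense_date = tz + 200, pill_count = 100))
  one <- co[co$person_id == pid, , drop = FALSE]
  ce_comp <- pp_censor_events(one, b, outcome_variant = "composite")
  ce_dm <- pp_censor_events(one, b, outcome_variant = "death_or_mi")
  expect_true(pid %in% ce_comp$person_id)
  expect_false(pid %in% ce_dm$person_id)
})

test_that("cohort censor times are consistent with generator bookkeeping", {
  sp <- shared_pipeline_data()
  truth <- attr(sp$bundle, "truth")
  ce <- pp_censor_events(sp$cohort, sp$bundle)
  tr <- truth[match(sp$cohort$person_id, truth$person_id), ]

  # untreated initiators: deviation on day 1 of the start month unless an
  # indication came first
  none <- which(sp$cohort$arm == "none")
  for (i in none[seq_len(min(200, length(none)))]) {
    pid <- sp$cohort$person_id[i]
    cd <- ce$censor_day[ce$person_id == pid]
    sm <- tr$start_month[i]
    expected_day <- (sm - 1) * 30 + 1
    rescued <- !is.na(tr$indication_month[i]) &&
      tr$indication_month[i] * 30 - 23 <= expected_day
    if (is.na(sm) || sm > 60 || rescued) {
      expect_equal(length(cd), 0)
    } else {
      expect_equal(cd, expected_day)
    }
  }

  # treated stoppers deviate after their latent stop month, never before
  trt <- which(sp$cohort$arm == "acei_arb")
  cd_all <- setNames(ce$censor_day, ce$person_id)[sp$cohort$person_id]
  stopped <- trt[!is.na(tr$stop_month[trt]) & !is.na(cd_all[trt])]
  expect_true(all(cd_all[stopped] >= (tr$stop_month[stopped] - 1) * 30))
  reasons <- setNames(ce$reason, ce$person_id)[sp$cohort$person_id]
  expect_true(all(reasons[trt][!is.na(reasons[trt])] ==
                    "stopped_treatment"))
})

test_that("censor times are monotone in the grace period", {
  sp <- shared_pipeline_data()
  ce90 <- pp_censor_events(sp$cohort, sp$bundle, grace_days = 90)
  ce180 <- pp_censor_events(sp$cohort, sp$bundle, grace_days = 180)
  d90 <- setNames(ce90$censor_day, ce90$person_id)
  d180 <- setNames(ce180$censor_day, ce180$person_id)
  # anyone censored under 180 is censored under 90, no later
  expect_true(all(names(d180) %in% names(d90)))
  expect_true(all(d180 >= d90[names(d180)]))
})

test_that("adherence curves follow the product-limit form", {
  co <- data.frame(person_id = sprintf("p%02d", 1:10),
                   arm = rep(c("acei_arb", "none"), 5))
  none_ce <- data.frame(person_id = character(), censor_day = numeric(),
                        reason = character())
  ad <- adherence_curve(co, none_ce, horizon = 12)
  expect_true(all(ad$prop_adherent == 1))

  all_ce <- data.frame(person_id = co$person_id, censor_day = 10,
                       reason = "stopped_treatment")
  ad2 <- adherence_curve(co, all_ce, horizon = 12)
  expect_true(all(ad2$prop_adherent == 0))

  # geometric stopping at 2%/month: 60-month adherence near 0.98^60
  set.seed(99)
  n <- 5000
  g <- rgeom(n, 0.02) + 1  # month of deviation
  co3 <- data.frame(person_id = sprintf("q%04d", 1:n), arm = "acei_arb")
  ce3 <- data.frame(person_id = co3$person_id[g <= 60],
                    censor_day = g[g <= 60] * 30 - 15,
                    reason = "stopped_treatment")
  ad3 <- adherence_curve(co3, ce3, horizon = 60)
  final <- ad3$prop_adherent[ad3$month == 60]
  expect_lt(abs(final - 0.98^60), 3 * sqrt(0.297 * 0.703 / n))
})
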