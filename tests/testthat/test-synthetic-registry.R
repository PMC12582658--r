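test_that("identical configurations give byte-identical bundles", {
  cfg <- synthetic_config(n_individuals = 300, seed = 5,
                          missing_rate = c(ldl = 0.1))
  b1 <- inject_missingness(generate_registry(cfg), cfg)
  b2 <- inject_missingness(generate_registry(cfg), cfg)
  expect_identical(b1, b2)
})

test_that("generated bundles satisfy referential and date integrity", {
  cfg <- synthetic_config(n_individuals = 400, seed = 9,
                          noneligible_fraction = 0.02)
  expect_silent(validate_registry(generate_registry(cfg)))
})

test_that("appending individuals never perturbs existing individuals", {
  cfg_small <- synthetic_config(n_individuals = 100, seed = 21)
  cfg_large <- synthetic_config(n_individuals = 160, seed = 21)
  t_small <- attr(generate_registry(cfg_small), "truth")
  t_large <- attr(generate_registry(cfg_large), "truth")
  expect_identical(t_small, t_large[seq_len(100), ])
  a_small <- generate_registry(cfg_small)$admissions
  a_large <- generate_registry(cfg_large)$admissions
  expect_identical(a_small, a_large[seq_len(100), ])
})

test_that("null-confounding assignment is a fair coin flip", {
  cfg <- synthetic_config(n_individuals = 10000, seed = 2,
                          treatment_intercept = 0,
                          treatment_coefs = numeric(0))
  tr <- attr(generate_registry(cfg), "truth")
  frac <- mean(tr$arm == "acei_arb")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a numerically zero hazard produces no deaths or outcomes", {
  cfg <- synthetic_config(n_individuals = 500, seed = 3,
                          hazard_intercept = -50)
  b <- generate_registry(cfg)
  expect_equal(nrow(b$outcomes), 0)
  expect_equal(nrow(b$deaths), 0)
})

test_that("latent process matches an independent step-by-step re-simulation", {
  cfg <- synthetic_config(n_individuals = 2000, seed = 13,
                          treatment_effect = -0.3,
                          hazard_intercept = -5.8,
                          adherence_stop_coefs = c(nstemi = 0.5))
  truth <- attr(generate_registry(cfg), "truth")
  oracle <- resimulate_truth(cfg)
  expect_identical(truth$arm == "acei_arb", oracle$treated)
  expect_identical(truth$event_month, oracle$event_month)
  expect_identical(truth$stop_month, oracle$stop_month)
  expect_identical(truth$start_month, oracle$start_month)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(indication_rate = 1.5), "indication_rate")
  expect_error(synthetic_config(covariates = list(
    list(name = "x", kind = "continuous", mean = 0, sd = -1))), "'x'")
  expect_error(synthetic_config(treatment_coefs = c(nope = 1)), "nope")
})

test_that("counterfactual risks are symmetric under a null effect", {
  cfg <- synthetic_config(n_individuals = 100, seed = 1,
                          treatment_effect = 0)
  r1 <- true_marginal_risk(cfg, "treated", 60, n_mc = 20000)
  r0 <- true_marginal_risk(cfg, "untreated", 60, n_mc = 20000)
  se <- sqrt(attr(r1, "mc_se")^2 + attr(r0, "mc_se")^2)
  expect_lt(abs(r1 - r0), 3 * se)
})

test_that("constant-hazard risk matches the geometric closed form", {
  h <- plogis(-5)
  cfg <- synthetic_config(n_individuals = 100, seed = 1,
                          hazard_intercept = -5,
                          hazard_coefs = numeric(0), time_trend = numeric(0))
  r <- true_marginal_risk(cfg, "untreated", 60, n_mc = 50000)
  expect_lt(abs(r - (1 - (1 - h)^60)), 3 * attr(r, "mc_se"))
})

test_that("marginal risk agrees with exact path enumeration", {
  cfg <- synthetic_config(
    n_individuals = 100, seed = 1, horizon_months = 3,
    covariates = list(list(name = "x", kind = "binary", prob = 0.35)),
    treatment_coefs = c(x = 0.5), hazard_coefs = c(x = 0.9),
    hazard_intercept = -3, treatment_effect = -0.6,
    time_trend = c(0.4))
  exact <- enumerate_risk(0.35, -3, 0.9, -0.6, a = 1,
                          time_trend = 0.4, horizon = 3)
  mc <- true_marginal_risk(cfg, "treated", 3, n_mc = 200000)
  expect_lt(abs(mc - exact), 3 * attr(mc, "mc_se"))
  expect_error(true_marginal_risk(cfg, "treated", 4), "horizon")
})

test_that("missingness injection is MCAR at the configured rate", {
  cfg0 <- synthetic_config(n_individuals = 200, seed = 8)
  b0 <- generate_registry(cfg0)
  expect_identical(inject_missingness(b0, cfg0), b0)

  cfg1 <- synthetic_config(n_individuals = 200, seed = 8,
                           missing_rate = c(egfr = 1))
  b1 <- inject_missingness(generate_registry(cfg1), cfg1)
  expect_true(all(is.na(b1$admissions$egfr)))
  expect_identical(b1$admissions$sbp, b0$admissions$sbp)
  expect_identical(b1$dispensations, b0$dispensations)

  cfg2 <- synthetic_config(n_individuals = 10000, seed = 8,
                           missing_rate = c(ldl = 0.11))
  b2 <- inject_missingness(generate_registry(cfg2), cfg2)
  frac <- mean(is.na(b2$admissions$ldl))
  expect_lt(abs(frac - 0.11), 3 * sqrt(0.11 * 0.89 / 10000))

  cfg_bad <- synthetic_config(n_individuals = 10, seed = 1)
  cfg_bad$missing_rate <- c(unknown_cov = 0.5)
  b <- generate_registry(synthetic_config(n_individuals = 10, seed = 1))
  expect_error(inject_missingness(b, cfg_bad), "unknown_cov")
})

test_that("bundles round-trip through CSV with ISO dates and empty sentinels", {
  cfg <- synthetic_config(n_individuals = 50, seed = 4,
                          missing_rate = c(ldl = 0.3))
  b <- inject_missingness(generate_registry(cfg), cfg)
  dir <- withr::local_tempdir()
  write_registry(b, dir, "csv")
  txt <- readLines(file.path(dir, "admissions.csv"), n = 2)
  expect_false(grepl("NA", txt[2]))
  b2 <- read_registry(dir, "csv")
  expect_equal(b2$admissions$ldl, b$admissions$ldl)
  expect_equal(b2$diagnoses$date, b$diagnoses$date)
  expect_s3_class(b2$admissions$admission_date, "Date")
})
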