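test_that("spline basis is zero below the first knot and exact at hand values", {
  b <- rcs_basis(3, c(6, 12, 24, 48))
  expect_equal(as.vector(b), c(3, 0, 0))
  b24 <- rcs_basis(24, c(6, 12, 24, 48))
  expect_equal(unname(b24[1, "t2"]), 5832 / 1764)  # ((24-6)^3) / (48-6)^2
  expect_equal(unname(b24[1, "t1"]), 24)
  expect_error(rcs_basis(1, c(6, 6, 24)), "strictly increasing")
  expect_error(rcs_basis(1, c(6, 12)), "at least 3")
})

test_that("spline basis has linear tails beyond the boundary knots", {
  kn <- c(6, 12, 24, 48)
  b50 <- rcs_basis(50, kn); b55 <- rcs_basis(55, kn); b60 <- rcs_basis(60, kn)
  expect_equal(b55, (b50 + b60) / 2, tolerance = 1e-12)
})

test_that("intercept-only closed form: logit of event share", {
  rows <- data.frame(person_id = rep("p", 50), month = 1,
                     treated = 0, Y = c(rep(1, 7), rep(0, 43)))
  fit <- fit_pooled_logistic(rows, outcome_model_spec(horizon = 60),
                             include_treatment = FALSE)
  expect_equal(unname(fit$coef["(Intercept)"]), qlogis(7 / 50),
               tolerance = 1e-8)
})

test_that("weighted likelihood is invariant to row duplication", {
  set.seed(1)
  rows <- data.frame(person_id = rep(sprintf("p%03d", 1:100), each = 2),
                     month = rep(sample(1:60, 100, TRUE), each = 2),
                     treated = rep(rbinom(100, 1, 0.5), each = 2),
                     Y = rep(rbinom(100, 1, 0.3), each = 2))
  one <- rows[seq(1, 200, 2), ]
  f_dup <- fit_pooled_logistic(rows, outcome_model_spec())
  f_w <- fit_pooled_logistic(one, outcome_model_spec(),
                             weights = rep(2, 100))
  f_1 <- fit_pooled_logistic(one, outcome_model_spec())
  expect_equal(f_dup$coef, f_w$coef, tolerance = 1e-8)
  expect_equal(f_dup$coef, f_1$coef, tolerance = 1e-8)
})

test_that("coefficients match an independent Newton-Raphson to 1e-6", {
  set.seed(7)
  n <- 200
  rows <- data.frame(person_id = sprintf("p%03d", 1:n),
                     month = sample(1:60, n, TRUE),
                     treated = rbinom(n, 1, 0.5))
  lp <- -1 + 0.5 * rows$treated + 0.02 * rows$month
  rows$Y <- rbinom(n, 1, plogis(lp))
  w <- runif(n, 0.5, 3)
  spec <- outcome_model_spec()
  fit <- fit_pooled_logistic(rows, spec, weights = w)
  X <- ttemulate:::outcome_design(rows, spec, TRUE)
  X <- X[, fit$design_columns, drop = FALSE]
  oracle <- nr_logistic(X, rows$Y, w)
  expect_lt(max(abs(fit$coef - oracle)), 1e-6)
})

test_that("degenerate fits are flagged, not silently returned", {
  rows <- data.frame(person_id = sprintf("p%02d", 1:40),
                     month = rep(1:2, 20), treated = rep(0:1, each = 20),
                     Y = rep(0:1, each = 20))  # perfect separation by arm
  expect_warning(fit <- fit_pooled_logistic(rows, outcome_model_spec()),
                 "converge|separation")
  expect_false(fit$converged)
  expect_error(fit_pooled_logistic(rows[rows$Y == 0, ],
                                   outcome_model_spec()), "no events")
})

test_that("saturated treatment-weight model satisfies the HT identity", {
  set.seed(11)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  arm <- ifelse(rbinom(n, 1, plogis(-0.5 + 1.2 * x)) == 1, "acei_arb",
                "none")
  co <- data.frame(person_id = sprintf("p%03d", 1:n), arm = arm,
                   xf = factor(x))
  w <- baseline_ip_weights(co, "xf")
  expect_equal(sum(w[co$arm == "acei_arb"]), n, tolerance = 1e-6)
  expect_equal(sum(w[co$arm == "none"]), n, tolerance = 1e-6)
  expect_true(all(w > 0))
})

test_that("randomized assignment gives weights near two", {
  cfg <- synthetic_config(n_individuals = 4000, seed = 15,
                          treatment_intercept = 0,
                          treatment_coefs = numeric(0))
  b <- generate_registry(cfg)
  s <- screen_eligibility(b)
  co <- assign_strategy(s$candidates, b$dispensations)
  w <- baseline_ip_weights(co, c("age", "female", "nstemi"))
  expect_lt(abs(mean(w) - 2), 0.1)
})

test_that("weight truncation caps at most the top percent", {
  cfg <- synthetic_config(n_individuals = 3000, seed = 23,
                          treatment_coefs = c(age = 0.8, nstemi = -1.2,
                                              sbp = 0.8))
  b <- generate_registry(cfg)
  co <- assign_strategy(screen_eligibility(b)$candidates, b$dispensations)
  w99 <- baseline_ip_weights(co, c("age", "nstemi", "sbp"),
                             truncation_percentile = 99)
  expect_lte(attr(w99, "n_truncated"), ceiling(0.01 * nrow(co)))
  expect_error(baseline_ip_weights(co, "age", truncation_percentile = 30),
               "percentile")
})

test_that("censoring weights are one when nobody deviates", {
  rows <- data.frame(person_id = rep(c("a", "b"), each = 5),
                     month = rep(1:5, 2), treated = rep(0:1, each = 5),
                     Y = 0, C = 0)
  w <- censoring_weights(rows, character(0),
                         outcome_model_spec(knots = c(1, 3, 5),
                                            horizon = 5))
  expect_true(all(w == 1))
})

test_that("constant censoring hazard gives the geometric weight form", {
  set.seed(31)
  n <- 3000; horizon <- 12
  dev_m <- rgeom(n, 0.10) + 1
  last <- pmin(dev_m, horizon)
  rows <- data.frame(person_id = rep(sprintf("p%04d", 1:n), last),
                     month = sequence(last), treated = 1, Y = 0)
  rows$C <- as.integer(rows$month == rep(last, last) &
                         rep(dev_m <= horizon, last))
  w <- censoring_weights(rows, character(0),
                         outcome_model_spec(knots = c(3, 6, 9),
                                            horizon = horizon))
  wbar <- as.vector(tapply(w[rows$C == 0], rows$month[rows$C == 0], mean))
  expect_lt(max(abs(wbar / (1 / 0.9)^(1:horizon) - 1)), 0.06)
})

test_that("all-censored months are reported as positivity failures", {
  rows <- data.frame(person_id = c("a", "b", "b"), month = c(1, 1, 2),
                     treated = 1, Y = 0, C = c(1, 0, 1))
  expect_error(censoring_weights(rows, character(0),
                                 outcome_model_spec(knots = c(1, 2, 3),
                                                    horizon = 3)),
               "positivity")
})
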