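test_that("prediction and inversion reproduce the criterion derivation", {
  m <- er_model_combined()
  expect_equal(predict_sai(m, 466), 36, tolerance = 0.05 / 36)
  expect_equal(predict_sai(m, 100), -27.31 + 23.73 * 2, tolerance = 1e-12)
  expect_equal(predict_sai(m, 10^(27.31 / 23.73)), 0, tolerance = 1e-9)
  cr <- invert_criterion(m, 36)
  expect_equal(round(cr$log10_cce, 3), 2.668)
  expect_equal(cr$cce_display, 466)
  # round trip at a grid point: target = model value at CCE 10
  expect_equal(invert_criterion(m, m$intercept + m$slope)$cce, 10,
               tolerance = 1e-12)
})

test_that("inversion is the exact inverse of prediction", {
  m <- er_model_combined()
  set.seed(12)
  sai <- runif(50, -20, 80)
  cce <- invert_criterion(m, sai)$cce
  expect_equal(predict_sai(m, cce), sai, tolerance = 1e-9)
  # steeper slope -> stricter (smaller) criterion when target exceeds intercept
  b_grid <- c(10, 23.73, 40, 80)
  cces <- vapply(b_grid, function(b) invert_criterion(er_model(-27.31, b), 36)$cce,
                 numeric(1))
  expect_true(all(diff(cces) < 0))
})

test_that("model validation rejects unusable inputs", {
  expect_error(predict_sai(er_model_combined(), -5), "positive")
  expect_error(predict_sai(er_model_combined(), 0), "positive")
  expect_error(invert_criterion(er_model(-27.31, 0), 36), "positive slope")
  expect_error(invert_criterion(er_model(-27.31, -2), 36), "positive slope")
  expect_warning(invert_criterion(er_model_combined(), -10, detection_floor = 10),
                 "detection floor")
  expect_error(er_model(-27.31, 23.73, se_slope = -1), "non-negative")
})

test_that("the identity-link fit recovers the generating coefficients", {
  sw <- sim_swimmer_study(swimmer_sim_config(200, 500, seed = 4))
  fit <- fit_identity_binomial(sw)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept + 27.31), 2 * fit$se_intercept)
  expect_lt(abs(fit$slope - 23.73), 2 * fit$se_slope)
  expect_lt(abs(fit$baseline_p0 - 0.063), 0.01)
  # the fit is itself an exposure-response model usable downstream
  expect_s3_class(fit, "er_model")
  cr <- invert_criterion(fit, 36)
  expect_gt(cr$cce, 100)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope", "baseline_p0"))
})

test_that("a single-day design leaves the slope unidentifiable", {
  one_day <- tibble::tibble(
    day = c(1L, 1L), group = c("swimmer", "nonswimmer"),
    log10_cce = 2.5, n_subjects = 500L, n_ill = c(40L, 30L)
  )
  expect_error(fit_identity_binomial(one_day), "unidentifiable")
  expect_error(fit_identity_binomial(one_day[1, ]), "Both swimmers")
})

test_that("slope comparison follows the normal theory for independent fits", {
  m <- er_model(-27, 24, se_intercept = 5, se_slope = 2)
  same <- compare_slopes(m, m)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  m2 <- er_model(-27, 24 - 1.96 * sqrt(8), se_intercept = 5, se_slope = 2)
  expect_equal(compare_slopes(m, m2)$p.value, 0.05, tolerance = 0.001)
  expect_error(compare_slopes(m, er_model(-27, 24)), "standard errors")
})

test_that("the pooling LRT is null-calibrated and detects unequal slopes", {
  fit_pair <- function(seed1, seed2, model2, days = 100, swimmers = 300) {
    s1 <- sim_swimmer_study(swimmer_sim_config(days, swimmers, seed = seed1))
    s2 <- sim_swimmer_study(swimmer_sim_config(days, swimmers, model = model2,
                                               seed = seed2))
    s2$day <- s2$day + days
    combined <- fit_identity_binomial(rbind(s1, s2))
    lrt_pooling(combined,
                list(fit_identity_binomial(s1), fit_identity_binomial(s2)))
  }
  # common truth: statistic ~ chi-square(3)
  null_stats <- vapply(1:40, function(r) {
    fit_pair(40000 + 2 * r, 40001 + 2 * r, er_model_combined())$statistic
  }, numeric(1))
  expect_lt(abs(mean(null_stats) - 3), 3 * sqrt(6 / 40))
  # genuinely different slopes are usually detected
  steep <- er_model(-27.31, 23.73 + 15)
  rejects <- vapply(1:30, function(r) {
    fit_pair(60000 + 2 * r, 60001 + 2 * r, steep, days = 200)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.8)
})

test_that("pooling LRT degenerate and error cases", {
  sw <- sim_swimmer_study(swimmer_sim_config(50, 200, seed = 2))
  fit <- fit_identity_binomial(sw)
  same <- lrt_pooling(fit, list(fit), df = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  worse <- fit
  worse$log_likelihood <- fit$log_likelihood - 5
  expect_error(lrt_pooling(fit, list(worse), df = 3), "optimisation failed")
})
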