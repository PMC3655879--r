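test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_sim_config(25, 800, 1.4, 98.6, definition_label = "HCGI", seed = 11)
  a <- sim_nonswimmer_cohorts(cfg)
  b <- sim_nonswimmer_cohorts(cohort_sim_config(25, 800, 1.4, 98.6,
                                                definition_label = "HCGI", seed = 11))
  expect_identical(a$n_ill, b$n_ill)
  expect_identical(a$p_true, b$p_true)
  expect_identical(attr(a, "rng_kind"), "Mersenne-Twister")
  c2 <- sim_nonswimmer_cohorts(cohort_sim_config(25, 800, 1.4, 98.6, seed = 12))
  expect_false(identical(a$n_ill, c2$n_ill))
})

test_that("simulated incidence is calibrated to the configured beta mean", {
  # overall empirical rate near 14 per 1000 within 3 sigma of the
  # beta-plus-binomial sampling error of the 30-beach mean
  co <- sim_nonswimmer_cohorts(cohort_sim_config(30, 1000, 1.4, 98.6, seed = 5))
  rate <- sum(co$n_ill) / sum(co$n_subjects)
  mu <- 0.014
  v_beach <- mu * (1 - mu) / (1.4 + 98.6 + 1)
  v_rate <- (v_beach + mu * (1 - mu) / 1000) / 30
  expect_lt(abs(rate - mu), 3 * sqrt(v_rate))
  # law of large numbers on the generator's own latent sidecar
  big <- sim_nonswimmer_cohorts(cohort_sim_config(10000, 1, 6.3, 93.7, seed = 6))
  mc_se <- sqrt(0.063 * 0.937 / (6.3 + 93.7 + 1)) / sqrt(10000)
  expect_lt(abs(mean(big$p_true) - 0.063), 3 * mc_se)
  # single-subject beaches yield Bernoulli counts
  expect_true(all(big$n_ill %in% 0:1))
})

test_that("beach counts are overdispersed relative to a single binomial", {
  for (par in list(c(1.4, 98.6), c(6.3, 93.7), c(5, 495))) {
    co <- sim_nonswimmer_cohorts(cohort_sim_config(
      2000, 500, par[1], par[2], seed = round(par[1] * 10)
    ))
    p_hat <- co$n_ill / co$n_subjects
    mu <- mean(p_hat)
    expect_gt(var(p_hat), mu * (1 - mu) / 500)
  }
})

test_that("presets hit the published means and a two-to-one beach-rate spread", {
  for (lbl in c("HCGI", "NGI")) {
    cfg <- preset_cohort_config(lbl)
    p <- bb_params(cfg$alpha, cfg$beta)
    expect_equal(mean_incidence(p), switch(lbl, HCGI = 0.014, NGI = 0.063),
                 tolerance = 1e-9)
    ci <- beach_rate_interval(p, 0.90)
    expect_equal(ci$upper / ci$lower, 2, tolerance = 1e-6)
  }
  expect_error(preset_cohort_config("GI"), "arg")
})

test_that("wader pooling enlarges the baseline cohort without changing its risk", {
  cfg <- cohort_sim_config(200, 1000, 6.3, 93.7, wader_fraction = 0.2, seed = 3)
  co <- sim_nonswimmer_cohorts(cfg)
  expect_true(all(co$n_subjects == 1250L))
  rate <- sum(co$n_ill) / sum(co$n_subjects)
  expect_lt(abs(rate - 0.063), 0.006)
})

test_that("swimmer simulation applies the identity-link excess day by day", {
  # a day at the criterion concentration carries ~36/1000 excess risk
  cfg <- swimmer_sim_config(200, 2000, baseline_rate_per_1000 = 63,
                            log10_cce_mean = log10(466), log10_cce_sd = 1e-9,
                            seed = 8)
  sw <- sim_swimmer_study(cfg)
  rate <- function(g) {
    x <- sw[sw$group == g, ]
    sum(x$n_ill) / sum(x$n_subjects)
  }
  excess <- rate("swimmer") - rate("nonswimmer")
  se <- sqrt(0.099 * 0.901 / 4e5 + 0.063 * 0.937 / 4e5)
  expect_lt(abs(excess - 0.036), 3 * se)
  # null exposure effect: groups share the illness probability
  null_cfg <- swimmer_sim_config(300, 1500, model = er_model(0, 0), seed = 9)
  nl <- sim_swimmer_study(null_cfg)
  r_sw <- sum(nl$n_ill[nl$group == "swimmer"]) / sum(nl$n_subjects[nl$group == "swimmer"])
  r_ns <- sum(nl$n_ill[nl$group == "nonswimmer"]) / sum(nl$n_subjects[nl$group == "nonswimmer"])
  se0 <- sqrt(2 * 0.063 * 0.937 / 450000)
  expect_lt(abs(r_sw - r_ns), 3 * se0)
  # determinism
  expect_identical(sim_swimmer_study(cfg)$n_ill, sw$n_ill)
})

test_that("simulation configs validate their inputs", {
  expect_error(cohort_sim_config(0, 100, 1, 1), "positive integer")
  expect_error(cohort_sim_config(5, 100, -1, 1), "positive")
  expect_error(cohort_sim_config(5, c(10, 10), 1, 1), "length")
  expect_error(cohort_sim_config(5, 100, 1, 1, seed = -1), "non-negative")
  expect_error(swimmer_sim_config(10, 50, baseline_rate_per_1000 = -5),
               "non-negative")
  expect_error(swimmer_sim_config(10, 50, log10_cce_sd = 0), "positive")
})
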