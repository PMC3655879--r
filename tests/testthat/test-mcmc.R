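# small posteriors shared across blocks
hcgi_cohorts <- function(seed) {
  sim_nonswimmer_cohorts(preset_cohort_config("HCGI", seed = seed))
}
small_posterior <- function(cohorts, seed, n_iter = 4000, burn_in = 1500) {
  sample_posterior(cohorts, n_chains = 2, n_iter = n_iter, burn_in = burn_in,
                   seed = seed)
}

test_that("posterior recovers the generating mean incidence", {
  cfg <- preset_cohort_config("HCGI", n_beaches = 50, subjects_per_beach = 2000,
                              seed = 41)
  post <- small_posterior(sim_nonswimmer_cohorts(cfg), seed = 42)
  mu <- post$draws$mean_incidence
  expect_true(all(mu > 0 & mu < 1))
  expect_lt(abs(mean(mu) - 0.014), 3 * sd(mu))
  expect_true(all(post$metadata$rhat < 1.1))
  expect_equal(nrow(post$draws), 2 * (4000 - 1500))
  g <- glance(post)
  expect_false(g$rhat_warning)
  expect_gt(g$acceptance, 0.1)
  expect_lt(g$acceptance, 0.6)
})

test_that("with the likelihood disabled the sampler reproduces the uniform prior", {
  post <- sample_posterior(hcgi_cohorts(1), n_chains = 2, n_iter = 110000,
                           burn_in = 10000, seed = 5, include_likelihood = FALSE)
  mu <- post$draws$mean_incidence
  thin <- mu[seq(1, length(mu), by = 20)]
  ks <- suppressWarnings(stats::ks.test(thin, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the transition kernel matches an analytic conjugate posterior", {
  # single-beach reduction: Beta(3,5) prior with 7 ill of 20 -> Beta(10,18)
  log_target <- function(th) {
    p <- plogis(th)
    dbeta(p, 10, 18, log = TRUE) + log(p) + log(1 - p)
  }
  set.seed(9)
  run <- adaptive_metropolis(log_target, 0, n_iter = 25000, burn_in = 5000)
  p <- plogis(run$draws[, 1])
  thin <- p[seq(1, length(p), by = 20)]
  expect_lt(abs(mean(p) - 10 / 28), 3 * sd(thin) / sqrt(length(thin)))
})

test_that("doubling the chain length moves interval endpoints within MC error", {
  co <- hcgi_cohorts(30)
  a <- small_posterior(co, seed = 30)
  b <- small_posterior(co, seed = 30, n_iter = 8000)
  ca <- credible_interval(a)
  cb <- credible_interval(b)
  mc_tol <- 3 * sd(a$draws$mean_incidence) / sqrt(200) # conservative n_eff
  expect_lt(abs(ca$lower - cb$lower), mc_tol)
  expect_lt(abs(ca$upper - cb$upper), mc_tol)
})

test_that("credible intervals are equal-tailed empirical quantiles", {
  expect_warning(ci <- credible_interval(rep(3.2, 500)), "draws")
  expect_equal(c(ci$lower, ci$point, ci$upper), c(3.2, 3.2, 3.2))
  set.seed(77)
  z <- rnorm(1e6)
  ci <- credible_interval(z, 0.95)
  expect_equal(ci$lower, -1.96, tolerance = 0.01)
  expect_equal(ci$upper, 1.96, tolerance = 0.01)
  bdraws <- rbeta(1e6, 4, 16)
  ci90 <- credible_interval(bdraws, 0.90)
  expect_equal(ci90$lower, qbeta(0.05, 4, 16), tolerance = 0.005)
  expect_equal(ci90$upper, qbeta(0.95, 4, 16), tolerance = 0.005)
  expect_error(credible_interval(z, 1), "between 0 and 1")
  expect_error(credible_interval(z, 0), "between 0 and 1")
})

test_that("risk-ratio draws behave like the paired-draw distribution", {
  pa <- small_posterior(hcgi_cohorts(1), seed = 21)
  pb <- small_posterior(hcgi_cohorts(2), seed = 22)
  rr <- risk_ratio_posterior(pa, pb)
  # identical populations: ratio centred near 1
  expect_lt(abs(stats::median(rr) - 1), 0.3)
  # numerator == denominator -> exactly 1
  expect_equal(risk_ratio_posterior(pa, pa), rep(1, nrow(pa$draws)))
  # cartesian oracle on thinned draws
  a <- pa$draws$mean_incidence
  b <- pb$draws$mean_incidence
  at <- a[round(seq(1, length(a), length.out = 200))]
  bt <- b[round(seq(1, length(b), length.out = 200))]
  cart <- as.numeric(outer(at, bt, "/"))
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(quantile(rr, qs) - quantile(cart, qs))), 0.02)
  # relabel-and-reciprocate invariance of quantiles
  rr_inv <- risk_ratio_posterior(pb, pa)
  expect_lt(max(abs(quantile(rr, qs) - 1 / quantile(rr_inv, 1 - qs))), 1e-6)
  # thinning aligns unequal draw counts deterministically
  long <- small_posterior(hcgi_cohorts(1), seed = 21, n_iter = 8000)
  rr2 <- risk_ratio_posterior(long, pb)
  expect_length(rr2, nrow(pb$draws))
})

test_that("beach-rate intervals come from the beta quantile function", {
  u <- beach_rate_interval(bb_params(1, 1), 0.90)
  expect_equal(c(u$lower, u$upper), c(0.05, 0.95))
  hcgi <- preset_cohort_config("HCGI")
  ci <- beach_rate_interval(bb_params(hcgi$alpha, hcgi$beta), 0.90)
  expect_equal(ci$upper / ci$lower, 2, tolerance = 0.25)
  # interval brackets the mean for unimodal shapes
  for (par in list(c(2, 8), c(23, 1600), c(5, 5), c(40, 2))) {
    p <- bb_params(par[1], par[2])
    ci <- beach_rate_interval(p, 0.90)
    expect_true(ci$lower < mean_incidence(p) && mean_incidence(p) < ci$upper)
  }
  expect_error(beach_rate_interval(bb_params(1, 1), 1.1), "0, 1")
})

test_that("split Gelman-Rubin flags divergence and passes mixed chains", {
  expect_equal(gelman_rubin(matrix(2.5, 100, 3)), 1)
  set.seed(55)
  shifted <- cbind(rnorm(500, 0), rnorm(500, 5))
  expect_gt(gelman_rubin(shifted), 1.5)
  mixed <- cbind(rnorm(10000), rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(mixed), 1.01)
  expect_error(gelman_rubin(matrix(1:100, ncol = 1)), "2 chains")
})

test_that("sampler preconditions and diagnostics guard misuse", {
  co <- hcgi_cohorts(3)
  expect_error(sample_posterior(co, n_chains = 1, n_iter = 100, burn_in = 10),
               "2 chains")
  expect_error(sample_posterior(co, n_iter = 100, burn_in = 100), "exceed")
  # proper at the validation probes but zero density where the data sit
  bad_prior <- prior_spec(
    log_prior_mean = function(mu) ifelse(mu > 0.012 & mu < 0.03, -Inf, 0),
    log_prior_conc = function(s) rep(0, length(s))
  )
  expect_error(
    sample_posterior(co, prior = bad_prior, n_chains = 2, n_iter = 200,
                     burn_in = 50, seed = 1),
    "mean incidence"
  )
})
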