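#' Prior specification for Bayesian beta-binomial inference
#'
#' The sampler works on (mean incidence, concentration) = (alpha/(alpha+beta),
#' alpha+beta). The default prior is weakly informative and proper:
#' uniform(0, 1) on the mean incidence and half-Cauchy(scale 100) on the
#' concentration. Both densities are supplied (and may be replaced) as
#' log-density functions evaluable over the whole support.
#'
#' @param log_prior_mean Function of the mean incidence in (0, 1) returning
#'   its log prior density.
#' @param log_prior_conc Function of the concentration in (0, Inf) returning
#'   its log prior density.
#' @param description Short human-readable label stored in run metadata.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(log_prior_mean, log_prior_conc, description = "custom") {
  stopifnot(is.function(log_prior_mean), is.function(log_prior_conc))
  probe_mu <- log_prior_mean(c(0.01, 0.5, 0.99))
  probe_s <- log_prior_conc(c(0.1, 10, 1e4))
  if (any(!is.finite(probe_mu)) || any(!is.finite(probe_s))) {
    abort("Prior log densities must be finite over the interior of their support.")
  }
  structure(
    list(log_prior_mean = log_prior_mean, log_prior_conc = log_prior_conc,
         description = description),
    class = "prior_spec"
  )
}

#' @rdname prior_spec
#' @param conc_scale Scale of the half-Cauchy prior on the concentration.
#' @export
default_prior <- function(conc_scale = 100) {
  prior_spec(
    log_prior_mean = function(mu) rep(0, length(mu)),
    log_prior_conc = function(s) log(2) + stats::dcauchy(s, 0, conc_scale, log = TRUE),
    description = sprintf("uniform(0,1) mean, half-Cauchy(%g) concentration", conc_scale)
  )
}

#' Adaptive random-walk Metropolis sampler
#'
#' General-purpose random-walk Metropolis with Gaussian proposals whose
#' global step scale is tuned in batches of 50 iterations towards a target
#' acceptance rate, and whose proposal covariance is re-estimated from the
#' chain history midway through burn-in. All adaptation is frozen after
#' burn-in, so the retained draws come from a fixed, valid Markov kernel.
#' Used internally by [sample_posterior()]; exposed so the transition
#' kernel can be validated against analytically known targets.
#'
#' @param log_target Function returning the log target density at a
#'   parameter vector.
#' @param init Numeric initial parameter vector with finite `log_target`.
#' @param n_iter Total iterations including burn-in.
#' @param burn_in Iterations discarded (and during which adaptation runs).
#' @param target_accept Target acceptance rate (0.3 suits a low-dimensional
#'   random walk).
#' @param init_scale Initial global step scale multiplier.
#' @return List with `draws` (matrix of post-burn-in states), `acceptance`
#'   (post-burn-in acceptance rate), and `scale` (final step scale).
#' @export
adaptive_metropolis <- function(log_target, init, n_iter, burn_in,
                                target_accept = 0.3, init_scale = 0.5) {
  d <- length(init)
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`.")
  theta <- as.numeric(init)
  lp <- log_target(theta)
  if (!is.finite(lp)) abort("`log_target` is not finite at `init`.")
  L <- diag(d)
  scale <- init_scale * 2.38 / sqrt(d)
  draws <- matrix(NA_real_, n_iter, d)
  acc <- logical(n_iter)
  recov <- floor(burn_in / 2)
  for (t in seq_len(n_iter)) {
    prop <- theta + scale * as.numeric(L %*% rnorm(d))
    lpp <- log_target(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      theta <- prop
      lp <- lpp
      acc[t] <- TRUE
    }
    draws[t, ] <- theta
    if (t <= burn_in) {
      if (t %% 50 == 0) {
        scale <- scale * exp(mean(acc[(t - 49):t]) - target_accept)
      }
      if (t == recov && t > 50) {
        cv <- stats::cov(draws[seq_len(t), , drop = FALSE]) + diag(1e-10, d)
        Lc <- tryCatch(t(chol(cv)), error = function(e) NULL)
        if (!is.null(Lc)) {
          L <- Lc
          scale <- 2.38 / sqrt(d)
        }
      }
    }
  }
  keep <- (burn_in + 1):n_iter
  list(draws = draws[keep, , drop = FALSE],
       acceptance = mean(acc[keep]),
       scale = scale)
}

#' Sample the beta-binomial posterior for beach-level illness rates
#'
#' Bayesian inference for the across-beach illness-rate distribution of one
#' case-definition population. The sampler is adaptive random-walk
#' Metropolis on the unconstrained scale (logit mean incidence, log
#' concentration), targeting the prior times the beta-binomial likelihood
#' of the observed beach counts (with the change-of-variables Jacobian).
#' Adaptation is frozen after burn-in. Acceptance rates and split Gelman-
#' Rubin statistics are recorded; Rhat above 1.1 on any tracked quantity
#' raises a warning and is flagged in the metadata.
#'
#' @param cohorts Beach cohort data frame with columns `n_subjects`,
#'   `n_ill` (>= 2 beaches).
#' @param prior A [prior_spec()]; default [default_prior()].
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Iterations per chain, including burn-in.
#' @param burn_in Burn-in iterations per chain.
#' @param seed Optional integer seed for the whole run (single seeded
#'   Mersenne-Twister stream; chains run sequentially).
#' @param include_likelihood If `FALSE`, sample the prior alone (a standard
#'   sampler validation: the mean-incidence draws must reproduce the prior).
#' @param target_accept Target acceptance rate for adaptation.
#' @return An object of class `"bb_posterior"`: list with `draws` (tibble
#'   with columns `chain`, `iter`, `mean_incidence`, `concentration`,
#'   `alpha`, `beta`) and `metadata` (seed, RNG, chains, iterations,
#'   burn-in, acceptance per chain, Rhat per quantity, prior description,
#'   warning flags). Supports [tidy()] and [glance()].
#' @examples
#' cohorts <- sim_nonswimmer_cohorts(preset_cohort_config("HCGI", seed = 1))
#' post <- sample_posterior(cohorts, n_chains = 2, n_iter = 2000,
#'                          burn_in = 500, seed = 1)
#' credible_interval(post)
#' @export
sample_posterior <- function(cohorts, prior = default_prior(), n_chains = 4,
                             n_iter = 20000, burn_in = 5000, seed = NULL,
                             include_likelihood = TRUE, target_accept = 0.3) {
  validate_cohorts(cohorts, min_beaches = 2L)
  stopifnot(inherits(prior, "prior_spec"))
  if (n_chains < 2) abort("At least 2 chains are required for convergence diagnostics.")
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`.")
  k <- cohorts$n_ill
  n <- cohorts$n_subjects

  log_target <- function(theta) {
    mu <- plogis(theta[[1]])
    s <- exp(theta[[2]])
    if (mu <= 0 || mu >= 1 || !is.finite(s) || s <= 0) return(-Inf)
    lp <- prior$log_prior_mean(mu) + log(mu) + log1p(-mu) +
      prior$log_prior_conc(s) + theta[[2]]
    if (include_likelihood) {
      lp <- lp + bb_loglik(k, n, mu * s, (1 - mu) * s)
    }
    lp
  }

  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  init0 <- if (include_likelihood) moment_init(k, n) else c(0, log(10))
  check_init_finite(init0, prior, k, n, include_likelihood)

  chains <- vector("list", n_chains)
  acceptance <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    init <- init0 + rnorm(2, 0, 0.3)
    tries <- 0
    while (!is.finite(log_target(init)) && tries < 20) {
      init <- init0 + rnorm(2, 0, 0.3)
      tries <- tries + 1
    }
    res <- adaptive_metropolis(log_target, init, n_iter, burn_in,
                               target_accept = target_accept)
    mu <- plogis(res$draws[, 1])
    s <- exp(res$draws[, 2])
    chains[[ch]] <- tibble::tibble(
      chain = ch, iter = seq_len(nrow(res$draws)),
      mean_incidence = mu, concentration = s,
      alpha = mu * s, beta = (1 - mu) * s
    )
    acceptance[ch] <- res$acceptance
  }
  draws <- dplyr::bind_rows(chains)

  rhat <- c(
    mean_incidence = gelman_rubin(draw_matrix(draws, "mean_incidence")),
    concentration = gelman_rubin(draw_matrix(draws, "concentration"))
  )
  rhat_warning <- any(rhat > 1.1)
  if (rhat_warning) {
    warn(sprintf("Gelman-Rubin Rhat exceeds 1.1 (max %.3f): chains have not converged.", max(rhat)))
  }

  structure(
    list(
      draws = draws,
      metadata = list(
        seed = seed, rng_kind = "Mersenne-Twister",
        n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
        acceptance = acceptance, rhat = rhat, rhat_warning = rhat_warning,
        prior = prior$description,
        include_likelihood = include_likelihood,
        n_beaches = nrow(cohorts)
      )
    ),
    class = "bb_posterior"
  )
}

check_init_finite <- function(theta, prior, k, n, include_likelihood) {
  mu <- plogis(theta[[1]])
  s <- exp(theta[[2]])
  if (!is.finite(prior$log_prior_mean(mu))) {
    abort("Log posterior is not finite at initialization: prior on the mean incidence evaluates to a non-finite value.")
  }
  if (!is.finite(prior$log_prior_conc(s))) {
    abort("Log posterior is not finite at initialization: prior on the concentration evaluates to a non-finite value.")
  }
  if (include_likelihood && !is.finite(bb_loglik(k, n, mu * s, (1 - mu) * s))) {
    abort("Log posterior is not finite at initialization: likelihood evaluates to a non-finite value.")
  }
  invisible(TRUE)
}

draw_matrix <- function(draws, quantity) {
  wide <- tidyr::pivot_wider(
    draws[, c("chain", "iter", quantity)],
    names_from = "chain", values_from = dplyr::all_of(quantity)
  )
  as.matrix(wide[, -1, drop = FALSE])
}

get_mean_draws <- function(x) {
  if (inherits(x, "bb_posterior")) {
    x <- dplyr::arrange(x$draws, .data$chain, .data$iter)$mean_incidence
  }
  if (!is.numeric(x)) abort("Expected a bb_posterior object or a numeric draw vector.")
  x
}

#' @export
print.bb_posterior <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("Beta-binomial posterior: %d chains x %d iterations (burn-in %d)\n",
              m$n_chains, m$n_iter, m$burn_in))
  cat(sprintf("  acceptance %.2f, Rhat(mean) %.3f, Rhat(concentration) %.3f\n",
              mean(m$acceptance), m$rhat[["mean_incidence"]], m$rhat[["concentration"]]))
  ci <- credible_interval(x)
  cat(sprintf("  mean incidence %.4g, 95%% CrI (%.4g, %.4g)\n",
              ci$point, ci$lower, ci$upper))
  invisible(x)
}

#' @export
tidy.bb_posterior <- function(x, level = 0.95, ...) {
  purrr::map_dfr(c("mean_incidence", "concentration", "alpha", "beta"), function(q) {
    v <- dplyr::arrange(x$draws, .data$chain, .data$iter)[[q]]
    lo <- (1 - level) / 2
    tibble::tibble(
      term = q, estimate = mean(v), std.error = sd(v),
      conf.low = unname(quantile(v, lo)), conf.high = unname(quantile(v, 1 - lo))
    )
  })
}

#' @export
glance.bb_posterior <- function(x, ...) {
  m <- x$metadata
  tibble::tibble(
    n_chains = m$n_chains, n_iter = m$n_iter, burn_in = m$burn_in,
    n_draws = nrow(x$draws), acceptance = mean(m$acceptance),
    rhat_max = max(m$rhat), rhat_warning = m$rhat_warning
  )
}

#' Equal-tailed credible interval from posterior draws
#'
#' Empirical-quantile interval at tail probabilities `(1-level)/2` on each
#' side, with the posterior mean as point estimate. Equal-tailed (not
#' highest-density) intervals are the conventional reporting form for these
#' models and accommodate the asymmetry typical of incidence posteriors.
#'
#' @param draws A numeric vector of draws, or a [sample_posterior()] result
#'   (in which case the mean-incidence draws are summarised).
#' @param level Interval probability in (0, 1).
#' @return A one-row tibble with columns `level`, `lower`, `point`,
#'   `upper`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a probability strictly between 0 and 1.")
  }
  v <- get_mean_draws(draws)
  if (length(v) < 1000) {
    warn(sprintf("Only %d draws: credible-interval endpoints will carry substantial Monte-Carlo error.", length(v)))
  }
  lo <- (1 - level) / 2
  q <- quantile(v, c(lo, 1 - lo), names = FALSE)
  tibble::tibble(level = level, lower = q[[1]], point = mean(v), upper = q[[2]])
}

#' Posterior draws of the risk ratio between two populations
#'
#' Elementwise ratio of the mean-incidence draws of two independently
#' sampled posteriors (e.g. NGI numerator over HCGI denominator). Draw
#' counts are aligned by deterministically thinning the longer vector with
#' a fixed stride to the shorter one's length, an unbiased pairing of
#' independent posteriors.
#'
#' @param numerator,denominator [sample_posterior()] results or numeric
#'   draw vectors.
#' @return Numeric vector of ratio draws; summarise with
#'   [credible_interval()].
#' @export
risk_ratio_posterior <- function(numerator, denominator) {
  a <- get_mean_draws(numerator)
  b <- get_mean_draws(denominator)
  n <- min(length(a), length(b))
  thin <- function(v) {
    if (length(v) == n) return(v)
    v[round(seq(1, length(v), length.out = n))]
  }
  out <- thin(a) / thin(b)
  if (n < 1000) {
    warn(sprintf("Only %d aligned draws for the risk ratio; expect Monte-Carlo noise.", n))
  }
  out
}

#' Central interval of beach-level incidence under the fitted beta model
#'
#' The across-beach illness-probability distribution is Beta(alpha, beta);
#' this returns the central `level` interval from its quantile function —
#' the range within which beach-by-beach background incidence falls
#' `level` of the time (e.g. 10-20 per 1000 for the HCGI calibration at
#' level 0.90).
#'
#' @param params A [bb_params()] object.
#' @param level Interval probability.
#' @return A one-row tibble with columns `level`, `lower`, `upper` (on the
#'   probability scale).
#' @export
beach_rate_interval <- function(params, level = 0.90) {
  params <- as_bb_params(params)
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  lo <- (1 - level) / 2
  tibble::tibble(
    level = level,
    lower = qbeta(lo, params$alpha, params$beta),
    upper = qbeta(1 - lo, params$alpha, params$beta)
  )
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain drift also registers as non-convergence). Values
#' near 1 indicate convergence; above about 1.1 the chains disagree.
#'
#' @param x A matrix of draws (iterations in rows, chains in columns) or a
#'   [sample_posterior()] result (returns a named vector for the tracked
#'   quantities).
#' @return Rhat value(s).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "bb_posterior")) {
    return(c(
      mean_incidence = gelman_rubin(draw_matrix(x$draws, "mean_incidence")),
      concentration = gelman_rubin(draw_matrix(x$draws, "concentration"))
    ))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("Gelman-Rubin requires at least 2 chains.")
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) abort("Chains are too short to split.")
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n2), j], x[(n2 + 1):(2 * n2), j])
  }))
  if (stats::var(as.numeric(halves)) < .Machine$double.eps) return(1)
  W <- mean(apply(halves, 2, var))
  B <- n2 * var(colMeans(halves))
  if (W < .Machine$double.eps) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}
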