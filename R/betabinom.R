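#' Beta-binomial parameters for across-beach illness rates
#'
#' Background gastrointestinal-illness rates among non-swimmers vary from
#' beach to beach. The package models each beach's illness probability as a
#' draw from a Beta(alpha, beta) distribution and the observed illness count
#' within a beach as binomial given that probability, so the marginal count
#' distribution is beta-binomial. `bb_params()` constructs and validates the
#' shape-parameter pair; `mean_incidence()` returns the population mean
#' illness probability alpha/(alpha + beta); `bb_concentration()` returns the
#' concentration alpha + beta (larger means less beach-to-beach spread).
#'
#' @param alpha,beta Positive shape parameters of the across-beach beta
#'   distribution of illness probabilities.
#' @return `bb_params()` returns an object of class `"bb_params"`;
#'   `mean_incidence()` and `bb_concentration()` return single numerics.
#' @examples
#' p <- bb_params(6.3, 93.7)
#' mean_incidence(p) # 0.063, i.e. 63 illnesses per 1000
#' @export
bb_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive finite number.")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive finite number.")
  }
  structure(list(alpha = alpha, beta = beta), class = "bb_params")
}

#' @export
print.bb_params <- function(x, ...) {
  cat(sprintf(
    "<bb_params> alpha = %.4g, beta = %.4g (mean incidence %.4g, concentration %.4g)\n",
    x$alpha, x$beta, mean_incidence(x), bb_concentration(x)
  ))
  invisible(x)
}

#' @rdname bb_params
#' @param params A [bb_params()] object.
#' @export
mean_incidence <- function(params) {
  params <- as_bb_params(params)
  params$alpha / (params$alpha + params$beta)
}

#' @rdname bb_params
#' @export
bb_concentration <- function(params) {
  params <- as_bb_params(params)
  params$alpha + params$beta
}

as_bb_params <- function(params) {
  if (inherits(params, "bb_params")) return(params)
  if (is.numeric(params) && length(params) == 2L) {
    return(bb_params(params[[1]], params[[2]]))
  }
  if (is.list(params) && all(c("alpha", "beta") %in% names(params))) {
    return(bb_params(params$alpha, params$beta))
  }
  abort("`params` must be a bb_params object or an (alpha, beta) pair.")
}

#' Beta-binomial probability mass function
#'
#' Marginal probability of observing `k` illnesses among `n` subjects when
#' the beach-level illness probability is Beta(alpha, beta) distributed and
#' counts are binomial given that probability. Evaluated in log space via
#' log-gamma for numerical stability:
#' `P(K = k) = C(n, k) B(k + alpha, n - k + beta) / B(alpha, beta)`.
#'
#' @param k Illness counts (vectorised); must satisfy `0 <= k <= n`.
#' @param n Numbers of subjects (vectorised).
#' @param params A [bb_params()] object.
#' @param log If `TRUE`, return log probabilities.
#' @return Numeric vector of (log) probabilities.
#' @examples
#' dbetabinom(2, 10, bb_params(1.4, 98.6))
#' sum(dbetabinom(0:50, 50, bb_params(2, 5))) # 1
#' @export
dbetabinom <- function(k, n, params, log = FALSE) {
  params <- as_bb_params(params)
  if (any(!is.finite(k)) || any(!is.finite(n))) {
    abort("`k` and `n` must be finite.")
  }
  if (any(k != floor(k)) || any(n != floor(n)) || any(n < 0)) {
    abort("`k` and `n` must be non-negative integers.")
  }
  if (any(k < 0) || any(k > n)) {
    abort("`k` must satisfy 0 <= k <= n.")
  }
  lp <- lchoose(n, k) +
    lbeta(k + params$alpha, n - k + params$beta) -
    lbeta(params$alpha, params$beta)
  if (log) lp else exp(lp)
}

# sum of beta-binomial log likelihood over beaches; k, n vectors
bb_loglik <- function(k, n, alpha, beta) {
  sum(lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta))
}

# (logit mean, log concentration) <-> (alpha, beta)
theta_to_ab <- function(theta) {
  mu <- plogis(theta[[1]])
  s <- exp(theta[[2]])
  c(alpha = mu * s, beta = (1 - mu) * s)
}

validate_cohorts <- function(cohorts, min_beaches = 1L) {
  if (!is.data.frame(cohorts)) {
    abort("`cohorts` must be a data frame with columns `n_subjects` and `n_ill`.")
  }
  missing_cols <- setdiff(c("n_subjects", "n_ill"), names(cohorts))
  if (length(missing_cols) > 0) {
    abort(paste0("`cohorts` is missing column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  n <- cohorts$n_subjects
  k <- cohorts$n_ill
  if (any(n < 1)) {
    abort("Every beach must have at least one enrolled subject (zero-enrollee beaches are rejected, not skipped).")
  }
  bad <- which(k < 0 | k > n)
  if (length(bad) > 0) {
    abort(sprintf("Row %d has n_ill outside [0, n_subjects].", bad[[1]]))
  }
  if (nrow(cohorts) < min_beaches) {
    abort(sprintf("At least %d beaches are required.", min_beaches))
  }
  invisible(cohorts)
}

#' Fit the beta-binomial model to beach cohort counts by maximum likelihood
#'
#' Maximises the product of beta-binomial probabilities over beaches by
#' numerical optimisation on the unconstrained scale (logit mean incidence,
#' log concentration), initialised from method-of-moments estimates. Standard
#' errors come from the observed information (numerical Hessian) on the
#' transformed scale, with the standard error of the mean incidence obtained
#' by the delta method.
#'
#' Underdispersed data (across-beach variance at or below the binomial-only
#' variance) drive the concentration to its upper transform bound; such fits
#' are returned with `boundary = TRUE` and a warning rather than an error.
#' Data in which no illness was observed anywhere cannot identify the
#' parameters and produce an error suggesting a Bayesian fit.
#'
#' @param cohorts A data frame of beach cohorts with columns `n_subjects`
#'   and `n_ill` (one row per beach), e.g. from [sim_nonswimmer_cohorts()]
#'   or [read_cohort_csv()].
#' @param conc_bounds Length-2 positive numeric, the search bounds for the
#'   concentration alpha + beta.
#' @param grad_tol Convergence contract: the fit is flagged converged when
#'   the sup-norm of the log-likelihood gradient on the transformed scale is
#'   below this tolerance (and no bound is active).
#' @return An object of class `"betabinom_fit"`: a list with elements
#'   `params` ([bb_params()]), `log_likelihood`, `converged`, `boundary`,
#'   `se` (named standard errors for `mean_incidence` and
#'   `log_concentration`), `vcov` (on the transformed scale), and
#'   `n_beaches`. Supports [tidy()] and [glance()].
#' @examples
#' cohorts <- sim_nonswimmer_cohorts(preset_cohort_config("NGI", seed = 1))
#' fit <- fit_betabinom(cohorts)
#' tidy(fit)
#' @export
fit_betabinom <- function(cohorts, conc_bounds = c(1e-3, 1e8), grad_tol = 1e-6) {
  validate_cohorts(cohorts, min_beaches = 2L)
  k <- cohorts$n_ill
  n <- cohorts$n_subjects
  if (all(k == 0)) {
    abort(paste(
      "All illness counts are zero: the likelihood is maximised on the",
      "boundary and the beta-binomial parameters are not identified.",
      "Consider a Bayesian fit via sample_posterior(), which regularises",
      "through the prior."
    ))
  }

  theta0 <- moment_init(k, n)
  lb <- c(qlogis(1e-9), log(conc_bounds[[1]]))
  ub <- c(qlogis(1 - 1e-9), log(conc_bounds[[2]]))
  theta0 <- pmin(pmax(theta0, lb + 1e-6), ub - 1e-6)

  negll <- function(theta) {
    ab <- theta_to_ab(theta)
    -bb_loglik(k, n, ab[[1]], ab[[2]])
  }
  opt <- optim(theta0, negll, method = "L-BFGS-B", lower = lb, upper = ub,
               control = list(factr = 1e4, maxit = 500))
  theta <- opt$par
  f_cur <- opt$value

  # Newton polish to meet the gradient-sup-norm convergence contract
  for (it in 1:20) {
    interior <- all(theta > lb + 1e-5) && all(theta < ub - 1e-5)
    if (!interior) break
    g <- pracma::grad(negll, theta)
    if (max(abs(g)) < grad_tol / 10) break
    H <- pracma::hessian(negll, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- theta - step
    damp <- 1
    while (damp > 1e-4 &&
           (any(cand <= lb) || any(cand >= ub) || negll(cand) > f_cur + 1e-12)) {
      damp <- damp / 2
      cand <- theta - damp * step
    }
    if (damp <= 1e-4) break
    theta <- cand
    f_cur <- negll(theta)
  }

  at_upper_conc <- (ub[[2]] - theta[[2]]) < 1e-6
  at_bound <- at_upper_conc || (theta[[2]] - lb[[2]]) < 1e-6
  g <- pracma::grad(negll, theta)
  converged <- max(abs(g)) < grad_tol && !at_bound
  if (at_upper_conc) {
    warn(paste(
      "Concentration estimate hit its upper bound: the data show no",
      "overdispersion beyond binomial sampling, so alpha + beta is not",
      "identified (boundary fit)."
    ))
  }

  vc <- se <- NULL
  if (!at_bound) {
    H <- pracma::hessian(negll, theta)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) > 0)) {
      mu <- plogis(theta[[1]])
      se <- c(
        mean_incidence = sqrt(vc[1, 1]) * mu * (1 - mu),
        log_concentration = sqrt(vc[2, 2])
      )
      dimnames(vc) <- rep(list(c("logit_mean", "log_concentration")), 2)
    } else {
      vc <- NULL
    }
  }

  ab <- theta_to_ab(theta)
  structure(
    list(
      params = bb_params(ab[[1]], ab[[2]]),
      log_likelihood = -f_cur,
      converged = converged,
      boundary = at_bound,
      se = se,
      vcov = vc,
      n_beaches = nrow(cohorts)
    ),
    class = "betabinom_fit"
  )
}

# method-of-moments start: pooled proportion for the mean; concentration from
# the ratio of observed to binomial-only variance of beach proportions,
# floored at 0.5
moment_init <- function(k, n) {
  mu <- sum(k) / sum(n)
  mu <- min(max(mu, 1e-8), 1 - 1e-8)
  p_hat <- k / n
  v_obs <- var(p_hat)
  v_bin <- mu * (1 - mu) / mean(n)
  n_bar <- mean(n)
  s <- if (is.na(v_obs) || v_obs <= v_bin || n_bar <= 1) {
    1e4
  } else {
    infl <- v_obs / v_bin
    max((n_bar - 1) / (infl - 1) - 1, 0.5)
  }
  c(qlogis(mu), log(max(s, 0.5)))
}

#' @export
print.betabinom_fit <- function(x, ...) {
  cat("Beta-binomial maximum-likelihood fit\n")
  cat(sprintf("  beaches: %d   log-likelihood: %.3f   converged: %s%s\n",
              x$n_beaches, x$log_likelihood, x$converged,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  mean incidence: %.4g", mean_incidence(x$params)))
  if (!is.null(x$se)) cat(sprintf(" (se %.2g)", x$se[["mean_incidence"]]))
  cat(sprintf("   concentration: %.4g\n", bb_concentration(x$params)))
  invisible(x)
}

#' @export
tidy.betabinom_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mean_incidence", "concentration", "alpha", "beta"),
    estimate = c(mean_incidence(x$params), bb_concentration(x$params),
                 x$params$alpha, x$params$beta),
    std.error = c(
      if (is.null(x$se)) NA_real_ else x$se[["mean_incidence"]],
      NA_real_, NA_real_, NA_real_
    )
  )
}

#' @export
glance.betabinom_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    boundary = x$boundary,
    n_beaches = x$n_beaches
  )
}
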