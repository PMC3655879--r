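#' Identity-link exposure-response model for swimming-associated illness
#'
#' The swimming-associated illness (SAI) rate per 1000 swimmers is modelled
#' as a linear function of water quality on the log10 scale:
#' `SAI = a + b * log10(CCE)`, where CCE is the daily-average Enterococcus
#' qPCR calibrator-cell-equivalent density per 100 mL. `er_model()`
#' constructs a model from known coefficients; `er_model_combined()` returns
#' the pooled marine-plus-freshwater NEEAR model (intercept -27.31, slope
#' 23.73) used to derive qPCR criteria.
#'
#' @param intercept,slope Model coefficients on the per-1000-swimmers scale;
#'   the slope is per log10(CCE per 100 mL).
#' @param se_intercept,se_slope Optional non-negative standard errors.
#' @param log_likelihood,n_obs Optional fit metadata.
#' @return An object of class `"er_model"`.
#' @examples
#' m <- er_model_combined()
#' predict_sai(m, 466) # ~36 per 1000
#' @export
er_model <- function(intercept, slope, se_intercept = NULL, se_slope = NULL,
                     log_likelihood = NULL, n_obs = NULL) {
  if (!is.numeric(intercept) || !is.numeric(slope) ||
      length(intercept) != 1L || length(slope) != 1L) {
    abort("`intercept` and `slope` must be single numbers.")
  }
  for (se in list(se_intercept, se_slope)) {
    if (!is.null(se) && (!is.numeric(se) || se < 0)) {
      abort("standard errors must be non-negative.")
    }
  }
  structure(
    list(intercept = intercept, slope = slope,
         se_intercept = se_intercept, se_slope = se_slope,
         log_likelihood = log_likelihood, n_obs = n_obs,
         scale = "per_1000"),
    class = "er_model"
  )
}

#' @rdname er_model
#' @export
er_model_combined <- function() {
  er_model(intercept = -27.31, slope = 23.73)
}

#' @export
print.er_model <- function(x, ...) {
  cat(sprintf("<er_model> SAI per 1000 = %.4g + %.4g * log10(CCE per 100 mL)\n",
              x$intercept, x$slope))
  if (!is.null(x$se_slope)) {
    cat(sprintf("  se(intercept) = %.3g, se(slope) = %.3g\n",
                x$se_intercept, x$se_slope))
  }
  invisible(x)
}

#' Predict the swimming-associated illness rate at a given water quality
#'
#' Evaluates `intercept + slope * log10(cce)` on the per-1000 scale. The
#' prediction may be negative below the model root (CCE around 14 per
#' 100 mL for the combined model); callers decide whether to clip —
#' simulation clips at zero, reporting does not.
#'
#' @param model An [er_model()] (or fitted [fit_identity_binomial()] object).
#' @param cce Positive Enterococcus qPCR CCE per 100 mL (vectorised).
#' @return SAI per 1000 swimmers.
#' @export
predict_sai <- function(model, cce) {
  stopifnot(inherits(model, "er_model"))
  if (any(!is.finite(cce)) || any(cce <= 0)) {
    abort("`cce` must be positive and finite.")
  }
  model$intercept + model$slope * log10(cce)
}

#' Invert the exposure-response model to a water-quality criterion
#'
#' Solves `sai_target = intercept + slope * log10(CCE)` for the criterion
#' concentration: `log10_cce = (sai_target - intercept)/slope`. Full
#' precision is retained in `cce`; `cce_display` is the nearest-integer
#' display form conventionally reported for guideline values.
#'
#' @param model An [er_model()] with positive slope (risk must increase with
#'   contamination for the inversion to define a protective criterion).
#' @param sai_target Tolerable SAI per 1000 swimmers.
#' @param detection_floor Optional CCE value below which a warning is issued
#'   (criteria below a qPCR detection floor are not practically enforceable).
#' @return A one-row tibble with columns `sai_target`, `log10_cce`, `cce`,
#'   `cce_display`.
#' @examples
#' invert_criterion(er_model_combined(), 36) # log10 2.668, criterion 466
#' @export
invert_criterion <- function(model, sai_target, detection_floor = 0) {
  stopifnot(inherits(model, "er_model"))
  if (!is.numeric(sai_target) || any(!is.finite(sai_target))) {
    abort("`sai_target` must be numeric and finite.")
  }
  if (model$slope <= 0) {
    abort("Criterion inversion requires a positive slope (risk increasing in CCE).")
  }
  l10 <- (sai_target - model$intercept) / model$slope
  cce <- 10^l10
  if (any(cce < detection_floor)) {
    warn("Criterion concentration falls below the stated detection floor.")
  }
  tibble::tibble(
    sai_target = sai_target,
    log10_cce = l10,
    cce = cce,
    cce_display = round(cce)
  )
}

validate_swimmer_table <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("day", "group", "log10_cce", "n_subjects", "n_ill")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("swimmer table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!all(data$group %in% c("swimmer", "nonswimmer"))) {
    abort('`group` must be "swimmer" or "nonswimmer".')
  }
  if (!any(data$group == "swimmer") || !any(data$group == "nonswimmer")) {
    abort("Both swimmers and non-swimmers must be present.")
  }
  if (any(data$n_ill < 0 | data$n_ill > data$n_subjects)) {
    abort("`n_ill` must lie in [0, n_subjects].")
  }
  invisible(data)
}

#' Fit the identity-link binomial exposure-response model
#'
#' Maximises the binomial likelihood in which each subject's illness
#' probability is `p0 + swim * (a + b * log10CCE)/1000`: non-swimmers share
#' a baseline probability `p0` and swimmers add the identity-link excess.
#' Because the identity link does not keep probabilities in range by
#' construction, the optimisation is constrained to fitted probabilities in
#' (1e-9, 1 - 1e-9); `p0` is parameterised on the logit scale and
#' out-of-range excess proposals are rejected by the objective. Fits whose
#' optimum presses against the probability bounds are flagged `boundary`
#' and their standard errors suppressed. Standard errors otherwise come
#' from the observed information (numerical Hessian).
#'
#' @param data Long-format day-by-group table with columns `day`, `group`
#'   (`"swimmer"`/`"nonswimmer"`), `log10_cce`, `n_subjects`, `n_ill`, e.g.
#'   from [sim_swimmer_study()].
#' @return An object of classes `"er_fit"` and `"er_model"` with elements
#'   `intercept`, `slope`, `se_intercept`, `se_slope`, `baseline_p0`,
#'   `log_likelihood`, `n_obs`, `n_par`, `converged`, `boundary`, `vcov`.
#'   Supports [tidy()], [glance()], [predict_sai()] and [invert_criterion()].
#' @examples
#' sw <- sim_swimmer_study(swimmer_sim_config(60, 200, seed = 3))
#' fit <- fit_identity_binomial(sw)
#' tidy(fit)
#' @export
fit_identity_binomial <- function(data) {
  validate_swimmer_table(data)
  sw <- data[data$group == "swimmer", ]
  ns <- data[data$group == "nonswimmer", ]
  if (length(unique(round(sw$log10_cce, 12))) < 2L) {
    abort("Slope is unidentifiable: swimmer rows span a single water-quality value.")
  }

  eps <- 1e-9
  negll <- function(theta) {
    p0 <- plogis(theta[[1]])
    p_sw <- p0 + (theta[[2]] + theta[[3]] * sw$log10_cce) / 1000
    if (any(p_sw <= eps) || any(p_sw >= 1 - eps) || p0 <= eps || p0 >= 1 - eps) {
      return(1e10)
    }
    -(sum(dbinom(ns$n_ill, ns$n_subjects, p0, log = TRUE)) +
        sum(dbinom(sw$n_ill, sw$n_subjects, p_sw, log = TRUE)))
  }

  # moment start: pooled baseline; least squares of per-day excess on log10 CCE
  p0_hat <- max(sum(ns$n_ill) / sum(ns$n_subjects), 1 / (2 * sum(ns$n_subjects)))
  excess <- (sw$n_ill / sw$n_subjects - p0_hat) * 1000
  ls <- stats::lm.fit(cbind(1, sw$log10_cce), excess)$coefficients
  theta0 <- c(qlogis(p0_hat), ls[[1]], ls[[2]])
  if (!is.finite(negll(theta0))) theta0 <- c(qlogis(p0_hat), 0, 0)

  opt <- optim(theta0, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  opt <- optim(opt$par, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  theta <- opt$par

  p0 <- plogis(theta[[1]])
  p_sw <- p0 + (theta[[2]] + theta[[3]] * sw$log10_cce) / 1000
  boundary <- any(p_sw < 1e-6) || any(p_sw > 1 - 1e-6)

  vc <- se_a <- se_b <- NULL
  if (!boundary) {
    H <- pracma::hessian(negll, theta)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) > 0)) {
      se_a <- sqrt(vc[2, 2])
      se_b <- sqrt(vc[3, 3])
      dimnames(vc) <- rep(list(c("logit_p0", "intercept", "slope")), 2)
    } else {
      vc <- NULL
    }
  } else {
    warn("Fitted probabilities at the (0, 1) boundary; standard errors suppressed.")
  }

  structure(
    list(
      intercept = theta[[2]], slope = theta[[3]],
      se_intercept = se_a, se_slope = se_b,
      baseline_p0 = p0,
      log_likelihood = -opt$value,
      n_obs = sum(data$n_subjects),
      n_par = 3L,
      converged = opt$convergence == 0L && !boundary,
      boundary = boundary,
      vcov = vc,
      scale = "per_1000"
    ),
    class = c("er_fit", "er_model")
  )
}

#' @export
print.er_fit <- function(x, ...) {
  cat("Identity-link binomial exposure-response fit\n")
  cat(sprintf("  SAI per 1000 = %.4g + %.4g * log10(CCE);  baseline p0 = %.4g\n",
              x$intercept, x$slope, x$baseline_p0))
  cat(sprintf("  n = %d subjects, log-likelihood %.3f, converged: %s%s\n",
              x$n_obs, x$log_likelihood, x$converged,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' @export
tidy.er_fit <- function(x, ...) {
  est <- c(x$intercept, x$slope, x$baseline_p0)
  se <- c(x$se_intercept %||% NA_real_, x$se_slope %||% NA_real_, NA_real_)
  tibble::tibble(
    term = c("intercept", "slope", "baseline_p0"),
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pnorm(-abs(est / se))
  )
}

#' @export
glance.er_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    n_obs = x$n_obs,
    n_par = x$n_par,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Compare the slopes of two independently fitted exposure-response models
#'
#' Two-sided z test of slope equality between independent fits (e.g. marine
#' vs freshwater strata): `z = (b1 - b2) / sqrt(se1^2 + se2^2)` referred to
#' the standard normal.
#'
#' @param model_1,model_2 [er_model()] objects carrying slope standard
#'   errors.
#' @return A one-row tibble with `estimate` (slope difference), `std.error`,
#'   `statistic` (z), `p.value`.
#' @export
compare_slopes <- function(model_1, model_2) {
  stopifnot(inherits(model_1, "er_model"), inherits(model_2, "er_model"))
  if (is.null(model_1$se_slope) || is.null(model_2$se_slope)) {
    abort("Both models must carry slope standard errors.")
  }
  d <- model_1$slope - model_2$slope
  se <- sqrt(model_1$se_slope^2 + model_2$se_slope^2)
  z <- d / se
  tibble::tibble(
    estimate = d, std.error = se, statistic = z,
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' Likelihood-ratio test of pooling strata into a combined model
#'
#' Tests whether stratum-specific exposure-response parameters improve on a
#' single combined model fitted to the pooled data:
#' `LR = 2 * (sum of stratified log-likelihoods - combined log-likelihood)`
#' referred to a chi-square with `df` equal to the parameter-count
#' difference.
#'
#' @param combined_fit An [fit_identity_binomial()] fit on the pooled data.
#' @param stratified_fits A list of fits on the disjoint strata of the same
#'   data.
#' @param df Degrees of freedom; defaults to the difference in parameter
#'   counts.
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
lrt_pooling <- function(combined_fit, stratified_fits, df = NULL) {
  stopifnot(inherits(combined_fit, "er_fit"))
  if (inherits(stratified_fits, "er_fit")) stratified_fits <- list(stratified_fits)
  ll_strat <- sum(purrr::map_dbl(stratified_fits, "log_likelihood"))
  stat <- 2 * (ll_strat - combined_fit$log_likelihood)
  if (stat < -1e-6 * max(1, abs(combined_fit$log_likelihood))) {
    abort("Stratified log-likelihood is below the combined model's: an optimisation failed (the stratified model nests the combined one).")
  }
  stat <- max(stat, 0)
  if (is.null(df)) {
    df <- sum(purrr::map_int(stratified_fits, "n_par")) - combined_fit$n_par
  }
  if (df < 1) abort("`df` must be at least 1.")
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
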