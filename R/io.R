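#' Read and write beach cohort tables
#'
#' Beach cohorts travel as plain CSV with header
#' `beach_id,definition,n_subjects,n_ill`. Reading validates the schema,
#' rejects duplicate (beach_id, definition) rows, zero-enrollee beaches and
#' counts outside \[0, n_subjects\] (naming the offending row). Writing
#' emits exactly the four canonical columns; when the table carries
#' simulation metadata (from [sim_nonswimmer_cohorts()]) a JSON sidecar
#' `<path>.meta.json` records the configuration, seed, RNG and realised
#' latent beach probabilities so simulations are fully auditable.
#'
#' @param path File path.
#' @param x Cohort data frame to write.
#' @param sidecar Write the JSON sidecar when simulation metadata is
#'   present (default `TRUE`).
#' @return `read_cohort_csv()` returns a tibble with the four canonical
#'   columns; `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("beach_id", "definition", "n_subjects", "n_ill")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x <- x[, need]
  dup <- duplicated(x[, c("beach_id", "definition")])
  if (any(dup)) {
    abort(sprintf("Duplicate (beach_id, definition) at row %d.", which(dup)[[1]]))
  }
  if (any(x$n_subjects < 1)) {
    abort(sprintf("Row %d has zero enrollees; beaches without subjects are rejected.",
                  which(x$n_subjects < 1)[[1]]))
  }
  bad <- which(x$n_ill < 0 | x$n_ill > x$n_subjects)
  if (length(bad) > 0) {
    abort(sprintf("Row %d violates 0 <= n_ill <= n_subjects.", bad[[1]]))
  }
  x$n_subjects <- as.integer(x$n_subjects)
  x$n_ill <- as.integer(x$n_ill)
  x
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(x, path, sidecar = TRUE) {
  validate_cohorts(x)
  need <- c("beach_id", "definition", "n_subjects", "n_ill")
  readr::write_csv(x[, need], path)
  cfg <- attr(x, "sim_config")
  if (sidecar && !is.null(cfg)) {
    meta <- list(
      config = unclass(cfg),
      seed = attr(x, "seed"),
      rng_kind = attr(x, "rng_kind"),
      p_true = x$p_true,
      scale = "probability"
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and write swimmer exposure-response tables
#'
#' Day-by-group CSV with header `day,group,log10_cce,n_subjects,n_ill`
#' (groups `"swimmer"`/`"nonswimmer"`), the input format of
#' [fit_identity_binomial()].
#'
#' @param path File path.
#' @param x Swimmer table to write.
#' @return `read_swimmer_csv()` returns a validated tibble;
#'   `write_swimmer_csv()` returns `path` invisibly.
#' @export
read_swimmer_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_swimmer_table(x)
  x
}

#' @rdname read_swimmer_csv
#' @export
write_swimmer_csv <- function(x, path) {
  validate_swimmer_table(x)
  readr::write_csv(x[, c("day", "group", "log10_cce", "n_subjects", "n_ill")], path)
  invisible(path)
}

#' Serialise a beta-binomial fit as JSON
#'
#' Writes `alpha`, `beta`, `mean`, `loglik`, `converged`, `se` and a
#' mandatory `scale` field (all incidences are probabilities; rates
#' elsewhere in the package are per 1000).
#'
#' @param fit A [fit_betabinom()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "betabinom_fit"))
  jsonlite::write_json(
    list(
      alpha = fit$params$alpha, beta = fit$params$beta,
      mean = mean_incidence(fit$params),
      loglik = fit$log_likelihood,
      converged = fit$converged,
      se = as.list(fit$se),
      scale = "probability"
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the inputs for [run_pipeline()]: which stages to run, the seed,
#' the translation rates (per 1000), the exposure-response model, and the
#' simulation / MCMC settings. The defaults reproduce the deterministic
#' criterion-derivation chain: HCGI baseline 14 per 1000, tolerable SAI 8
#' per 1000 (the more protective 1986 freshwater value), NGI baseline 63
#' per 1000, combined qPCR model.
#'
#' @param stages Character subset of
#'   `c("simulate", "fit", "mcmc", "translate", "criterion")`, in execution
#'   order. An empty selection is a no-op that still emits provenance.
#' @param seed Integer seed governing all randomness in the run.
#' @param ns_old,sai_old,ns_new Translation rates per 1000.
#' @param model An [er_model()] for the criterion stage.
#' @param use_posterior If `TRUE`, the translate stage propagates MCMC
#'   posterior draws of the two baselines (requires the `mcmc` stage).
#' @param n_beaches,subjects_per_beach Simulation sizes for the simulate
#'   stage.
#' @param n_chains,n_iter,burn_in MCMC settings.
#' @param out_dir Optional directory; when given, the report and stage
#'   artifacts (cohort CSVs, fit JSONs) are written there.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stages = c("translate", "criterion"),
                            seed = 1L,
                            ns_old = 14, sai_old = 8, ns_new = 63,
                            model = er_model_combined(),
                            use_posterior = FALSE,
                            n_beaches = 30L, subjects_per_beach = 1000L,
                            n_chains = 4L, n_iter = 4000L, burn_in = 1000L,
                            out_dir = NULL) {
  all_stages <- c("simulate", "fit", "mcmc", "translate", "criterion")
  stages <- as.character(stages)
  if (!all(stages %in% all_stages)) {
    abort(paste0("Unknown stage(s): ",
                 paste(setdiff(stages, all_stages), collapse = ", "), "."))
  }
  if (use_posterior && !all(c("simulate", "mcmc", "translate") %in% stages)) {
    abort("Posterior propagation through the translation requires the simulate, mcmc and translate stages.")
  }
  if (any(c("fit", "mcmc") %in% stages) && !("simulate" %in% stages)) {
    abort("The fit and mcmc stages need cohorts from the simulate stage.")
  }
  structure(
    list(stages = all_stages[all_stages %in% stages], seed = as.integer(seed),
         ns_old = ns_old, sai_old = sai_old, ns_new = ns_new,
         model = model, use_posterior = use_posterior,
         n_beaches = as.integer(n_beaches),
         subjects_per_beach = as.integer(subjects_per_beach),
         n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the risk-equivalence pipeline
#'
#' Executes the selected stages in order — simulate calibrated HCGI and NGI
#' cohorts, fit the beta-binomial model to each by maximum likelihood,
#' sample their posteriors and the risk-ratio posterior, translate the
#' tolerable illness rate across case definitions, and invert the
#' exposure-response model to a qPCR criterion — and returns a report with
#' every intermediate plus a provenance record (package version, seed, RNG
#' algorithm, resolved configuration, timestamp). With the default
#' deterministic configuration the report reproduces the published chain:
#' relative risk 1.57, translated SAI 36 per 1000, criterion 466 CCE per
#' 100 mL (display-rounded).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"pipeline_report"` with elements `provenance`
#'   and `results`. When `config$out_dir` is set the report is also written
#'   as `report.json` there, along with stage artifacts.
#' @examples
#' rep <- run_pipeline(pipeline_config())
#' rep$results$translation
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list()
  cohorts <- posts <- NULL

  if ("simulate" %in% config$stages) {
    cohorts <- purrr::map(setNames(nm = c("HCGI", "NGI")), function(lbl) {
      sim_nonswimmer_cohorts(preset_cohort_config(
        lbl, n_beaches = config$n_beaches,
        subjects_per_beach = config$subjects_per_beach,
        seed = config$seed + match(lbl, c("HCGI", "NGI")) - 1L
      ))
    })
    results$simulate <- purrr::map(cohorts, function(x) {
      list(n_beaches = nrow(x), overall_rate_per_1000 = 1000 * sum(x$n_ill) / sum(x$n_subjects))
    })
    if (!is.null(out_dir)) {
      purrr::iwalk(cohorts, function(x, lbl) {
        write_cohort_csv(x, file.path(out_dir, paste0("cohorts_", lbl, ".csv")))
      })
    }
  }

  if ("fit" %in% config$stages) {
    fits <- purrr::map(cohorts, fit_betabinom)
    results$fit <- purrr::map(fits, function(f) {
      list(alpha = f$params$alpha, beta = f$params$beta,
           mean = mean_incidence(f$params), loglik = f$log_likelihood,
           converged = f$converged, scale = "probability")
    })
    results$fit$mean_ratio_ngi_hcgi <-
      mean_incidence(fits$NGI$params) / mean_incidence(fits$HCGI$params)
    if (!is.null(out_dir)) {
      purrr::iwalk(fits, function(f, lbl) {
        write_fit_json(f, file.path(out_dir, paste0("fit_", lbl, ".json")))
      })
    }
  }

  if ("mcmc" %in% config$stages) {
    posts <- purrr::imap(cohorts, function(x, lbl) {
      sample_posterior(x, n_chains = config$n_chains, n_iter = config$n_iter,
                       burn_in = config$burn_in,
                       seed = config$seed + 100L + match(lbl, c("HCGI", "NGI")))
    })
    rr_draws <- risk_ratio_posterior(posts$NGI, posts$HCGI)
    rr_ci <- credible_interval(rr_draws)
    results$mcmc <- list(
      HCGI = as.list(credible_interval(posts$HCGI)),
      NGI = as.list(credible_interval(posts$NGI)),
      risk_ratio = list(median = stats::median(rr_draws),
                        lower = rr_ci$lower, upper = rr_ci$upper, level = rr_ci$level),
      rhat = purrr::map(posts, function(p) as.list(p$metadata$rhat)),
      scale = "probability"
    )
  }

  if ("translate" %in% config$stages) {
    tr <- translate(config$ns_old, config$sai_old, config$ns_new)
    results$translation <- c(as.list(tr), scale = "per_1000")
    if (config$use_posterior) {
      sai_draws <- translate_posterior(
        1000 * get_mean_draws(posts$HCGI),
        1000 * get_mean_draws(posts$NGI),
        config$sai_old
      )
      ci <- credible_interval(sai_draws)
      results$translation$posterior_sai_new <- list(
        median = stats::median(sai_draws), lower = ci$lower, upper = ci$upper,
        level = ci$level, scale = "per_1000"
      )
    }
  }

  if ("criterion" %in% config$stages) {
    sai_target <- if (!is.null(results$translation)) {
      results$translation$sai_new_display
    } else {
      translate(config$ns_old, config$sai_old, config$ns_new)$sai_new_display
    }
    cr <- invert_criterion(config$model, sai_target)
    results$criterion <- c(as.list(cr),
                           list(scale = "per_1000_and_cce_per_100ml"))
  }

  report <- structure(
    list(
      provenance = list(
        package = "riskbridge",
        version = as.character(packageVersion("riskbridge")),
        seed = config$seed,
        rng_kind = "Mersenne-Twister",
        stages = config$stages,
        config = config_provenance(config),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      ),
      results = results
    ),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass_report(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg$model <- list(intercept = config$model$intercept,
                    slope = config$model$slope, scale = config$model$scale)
  cfg$out_dir <- NULL
  cfg
}

unclass_report <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("riskbridge pipeline report (seed %d; stages: %s)\n",
              x$provenance$seed, paste(x$provenance$stages, collapse = ", ")))
  tr <- x$results$translation
  if (!is.null(tr)) {
    cat(sprintf("  translation: RR %.2f -> tolerable SAI %d per 1000\n",
                tr$rr_display, tr$sai_new_display))
  }
  cr <- x$results$criterion
  if (!is.null(cr)) {
    cat(sprintf("  criterion: log10(CCE) %.3f -> %d CCE per 100 mL\n",
                cr$log10_cce, cr$cce_display))
  }
  invisible(x)
}
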