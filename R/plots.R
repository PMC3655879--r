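#' Plot an exposure-response model with an optional criterion annotation
#'
#' Line plot of predicted swimming-associated illness per 1000 against
#' log10 Enterococcus qPCR CCE; when `sai_target` is given the implied
#' criterion concentration is marked.
#'
#' @param model An [er_model()] or fitted [fit_identity_binomial()] object.
#' @param cce_range Positive length-2 CCE range for the x axis.
#' @param sai_target Optional tolerable SAI per 1000 to annotate.
#' @return A ggplot object.
#' @export
plot_exposure_response <- function(model, cce_range = c(20, 2000),
                                   sai_target = NULL) {
  stopifnot(inherits(model, "er_model"))
  grid <- tibble::tibble(
    log10_cce = seq(log10(cce_range[[1]]), log10(cce_range[[2]]), length.out = 200)
  )
  grid$sai <- model$intercept + model$slope * grid$log10_cce
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$log10_cce, y = .data$sai)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(log[10] ~ "Enterococcus qPCR CCE per 100 mL"),
      y = "Swimming-associated illness per 1000"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sai_target)) {
    cr <- invert_criterion(model, sai_target)
    p <- p +
      ggplot2::geom_hline(yintercept = sai_target, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = cr$log10_cce, linetype = "dashed") +
      ggplot2::annotate("point", x = cr$log10_cce, y = sai_target, size = 2)
  }
  p
}

#' @export
autoplot.er_model <- function(object, ...) plot_exposure_response(object, ...)

#' Plot across-beach incidence densities
#'
#' Beta densities of beach-level background illness probability for one or
#' more parameter sets (e.g. the HCGI and NGI calibrations side by side).
#'
#' @param params_list A named list of [bb_params()] objects.
#' @param xlim Incidence range to display.
#' @return A ggplot object.
#' @export
plot_beach_rate_density <- function(params_list, xlim = NULL) {
  if (inherits(params_list, "bb_params")) params_list <- list(params_list)
  if (is.null(names(params_list))) {
    names(params_list) <- paste0("model_", seq_along(params_list))
  }
  if (is.null(xlim)) {
    xlim <- c(0, max(purrr::map_dbl(params_list, function(p) {
      qbeta(0.999, p$alpha, p$beta)
    })))
  }
  df <- purrr::imap_dfr(params_list, function(p, nm) {
    x <- seq(xlim[[1]], xlim[[2]], length.out = 400)
    tibble::tibble(definition = nm, incidence = x,
                   density = dbeta(x, p$alpha, p$beta))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$incidence, y = .data$density,
                                   colour = .data$definition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Beach-level background incidence (probability)",
                  y = "Density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bb_posterior <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$mean_incidence,
                               colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Mean incidence", y = "Posterior density",
                  colour = "Chain") +
    ggplot2::theme_minimal()
}
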