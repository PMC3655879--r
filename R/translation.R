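#' Relative risk implied by a tolerable swimming-associated illness rate
#'
#' With `ns` the non-swimmer (background) illness rate and `sai` the
#' tolerable swimming-associated excess, both per 1000, the swimmers' total
#' tolerated risk is `ns + sai` and the implied relative risk is
#' `(ns + sai) / ns`. Full precision is returned; 2-decimal display (the
#' conventional form, e.g. 1.57 for the 1986 freshwater criterion against
#' the pre-1986 baseline) is a formatting concern, see [format_rr()].
#'
#' @param ns Non-swimmer illness rate per 1000; must be positive.
#' @param sai Swimming-associated illness rate per 1000; non-negative.
#' @return The relative risk (dimensionless), vectorised.
#' @examples
#' relative_risk(14, 8) # 1.5714...
#' @export
relative_risk <- function(ns, sai) {
  check_rate(sai, "sai")
  check_rate(ns, "ns")
  if (any(ns == 0)) {
    abort("The non-swimmer rate `ns` must be positive: relative risk divides by it.")
  }
  (ns + sai) / ns
}

#' Translate a relative risk into a tolerable illness rate under a new baseline
#'
#' Given the new case definition's non-swimmer baseline `ns_new` and the
#' relative risk `rr` carried over from the old criterion, the equivalent
#' tolerable swimming-associated rate is `ns_new * (rr - 1)` per 1000.
#' Full precision is returned; nearest-integer display is via
#' [format_sai()].
#'
#' @param ns_new New-definition non-swimmer rate per 1000.
#' @param rr Relative risk, must be >= 1 (a protective criterion cannot
#'   imply negative excess risk).
#' @return The translated SAI per 1000, vectorised.
#' @examples
#' translate_sai(63, relative_risk(14, 8)) # 36
#' @export
translate_sai <- function(ns_new, rr) {
  check_rate(ns_new, "ns_new")
  if (any(!is.finite(rr)) || any(rr < 1)) {
    abort("`rr` must be >= 1: a protective criterion cannot have negative excess risk.")
  }
  ns_new * (rr - 1)
}

#' Two-step risk-equivalence translation between case definitions
#'
#' Composes the translation algorithm: Step 1 computes the relative risk
#' implied by the old criterion, `rr = (ns_old + sai_old)/ns_old`; Step 2
#' equates relative risks across case definitions and solves for the new
#' tolerable excess, `sai_new = ns_new * (rr - 1)`. All intermediates are
#' recorded at full precision, alongside display-rounded forms (`rr` to 2
#' decimals, `sai_new` to the nearest integer).
#'
#' @param ns_old Old-definition non-swimmer rate per 1000 (e.g. 14 HCGI).
#' @param sai_old Old tolerable swimming-associated rate per 1000 (e.g. the
#'   1986 freshwater criterion's 8 HCGI, the more protective of the 1986
#'   freshwater/marine pair; marine was 19).
#' @param ns_new New-definition non-swimmer rate per 1000 (e.g. 63 NGI).
#' @return A one-row tibble of class `"translation_result"` with columns
#'   `ns_old`, `sai_old`, `rr`, `ns_new`, `sai_new`, `rr_display`,
#'   `sai_new_display`.
#' @examples
#' translate(ns_old = 14, sai_old = 8, ns_new = 63)
#' @export
translate <- function(ns_old, sai_old, ns_new) {
  rr <- relative_risk(ns_old, sai_old)
  sai_new <- translate_sai(ns_new, rr)
  out <- tibble::tibble(
    ns_old = ns_old, sai_old = sai_old, rr = rr,
    ns_new = ns_new, sai_new = sai_new,
    rr_display = format_rr(rr),
    sai_new_display = format_sai(sai_new)
  )
  class(out) <- c("translation_result", class(out))
  out
}

#' @rdname translate
#' @param x A rate or relative risk to format for display.
#' @export
format_rr <- function(x) round(x, 2)

#' @rdname translate
#' @export
format_sai <- function(x) round(x)

#' Propagate posterior uncertainty through the translation
#'
#' Applies the deterministic two-step translation elementwise to aligned
#' posterior draws of the two non-swimmer baselines, holding the old
#' tolerable excess fixed:
#' `sai_new = ns_new * ((ns_old + sai_old)/ns_old - 1)`. Summarise with
#' [credible_interval()].
#'
#' @param ns_old_draws,ns_new_draws Equal-length numeric vectors of
#'   posterior draws of the baselines, per 1000 (e.g. 1000 *
#'   mean-incidence draws from [sample_posterior()]).
#' @param sai_old Fixed old tolerable rate per 1000.
#' @return Numeric vector of `sai_new` draws, per 1000.
#' @export
translate_posterior <- function(ns_old_draws, ns_new_draws, sai_old) {
  if (length(ns_old_draws) != length(ns_new_draws)) {
    abort("Draw vectors must be aligned to equal length (see risk_ratio_posterior() for thinning).")
  }
  if (any(ns_old_draws == 0)) {
    abort("Non-swimmer baseline draws must be positive (a zero draw makes the relative risk undefined).")
  }
  check_rate(sai_old, "sai_old")
  ns_new_draws * ((ns_old_draws + sai_old) / ns_old_draws - 1)
}

#' Ratio of illness rates between case definitions
#'
#' Simple rate ratio used to quantify how much a less stringent case
#' definition inflates the background illness rate, e.g. dropping the
#' stool-frequency requirement raises 14 per 1000 to 28 per 1000 (factor
#' 2.0) and dropping fever raises it to 52 per 1000 (factor 3.7).
#'
#' @param rate_new,rate_ref Rates per 1000; `rate_ref` must be positive.
#' @return The ratio `rate_new / rate_ref`, vectorised.
#' @examples
#' rate_ratio(63, 14) # 4.5
#' @export
rate_ratio <- function(rate_new, rate_ref) {
  check_rate(rate_new, "rate_new")
  check_rate(rate_ref, "rate_ref")
  if (any(rate_ref == 0)) abort("`rate_ref` must be positive.")
  rate_new / rate_ref
}

# rates live on the per-1000 scale end to end; validate that contract
check_rate <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1000)) {
    abort(sprintf("`%s` must be a rate in [0, 1000] illnesses per 1000 persons.", name))
  }
  invisible(x)
}
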