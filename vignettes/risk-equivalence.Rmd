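---
title: "Translating tolerable illness rates across case definitions and deriving a qPCR criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating tolerable illness rates across case definitions and deriving a qPCR criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskbridge)
```

## The problem

Recreational water-quality criteria are anchored to a *tolerable
swimming-associated illness* (SAI) rate: the excess gastrointestinal (GI)
illness among swimmers over non-swimmers, per 1000 persons, that a criterion
is designed not to exceed. When the epidemiological case definition of GI
illness changes — for example when the historical "highly credible
gastrointestinal illness" (HCGI) definition, which required fever, is
replaced by the broader NEEAR GI illness (NGI) definition, which does not —
the background illness rate changes too, and a tolerable rate stated under
the old definition cannot be carried over numerically. riskbridge implements
the risk-equivalence machinery that links the two: a beta-binomial model of
beach-level background illness with likelihood and Bayesian inference, a
relative-risk equivalence translation of the tolerable rate, and the
inversion of an identity-link exposure-response model into an *Enterococcus*
qPCR criterion concentration.

All user-facing rates are carried on the per-1000 scale end to end;
probabilities appear only inside the likelihoods. Every JSON artifact the
package writes carries an explicit `scale` field, because the single biggest
unit hazard in this material is a silent factor of 1000.

## Background illness: the beta-binomial model

Non-swimmer illness rates vary from beach to beach. Let beach $b$ enrol
$n_b$ non-swimmers and record $k_b$ illnesses. We assume

$$p_b \sim \mathrm{Beta}(\alpha, \beta), \qquad
  k_b \mid p_b \sim \mathrm{Binomial}(n_b, p_b),$$

so that marginally $k_b$ is beta-binomial and the across-beach mean
incidence is $\mu = \alpha/(\alpha+\beta)$. The pmf is evaluated in log
space via log-gamma (`dbetabinom()`), and both the maximum-likelihood fit
(`fit_betabinom()`) and the sampler work on the transformed parameters
$(\operatorname{logit}\mu, \log s)$ with $s = \alpha + \beta$: the
transform removes the positivity constraints and largely decorrelates the
likelihood surface. The MLE is initialised from method-of-moments (pooled
proportion for $\mu$; concentration from the ratio of observed to
binomial-only variance, floored at 0.5) and polished by damped Newton steps
until the gradient sup-norm on the transformed scale is below $10^{-6}$ —
the convergence flag is a testable contract, not a heuristic.
Underdispersed data drive $s$ to its upper search bound; such fits are
returned flagged `boundary` with a warning rather than silently accepted,
and data with no illnesses anywhere produce an error that points to the
Bayesian route, where the prior keeps the posterior proper.

## Bayesian inference and diagnostics

Because these studies involve relatively few beaches, interval estimates
for $\mu$ and for the NGI:HCGI risk ratio are computed by MCMC
(`sample_posterior()`). The sampler is an adaptive random-walk Metropolis
on $(\operatorname{logit}\mu, \log s)$: a deliberately transparent choice,
since the posterior-inference machinery is itself part of what the package
re-implements rather than a detail to delegate. The global step scale is
tuned in batches of 50 iterations towards a 0.3 acceptance rate and the
proposal covariance is re-estimated from the chain history midway through
burn-in; all adaptation is frozen at the end of burn-in so the retained
draws come from a fixed, valid kernel. The kernel itself is validated in
the test suite against an analytically known conjugate posterior.

The default prior is weakly informative and proper: uniform(0, 1) on the
mean incidence and half-Cauchy(scale 100) on the concentration. The priors
used in the original Bayesian analyses of these data were never published,
so the defaults are an honest, fully exposed choice (`prior_spec()`), and a
prior-only run (`include_likelihood = FALSE`) is part of the test suite to
confirm the sampler reproduces the uniform prior on $\mu$.

Defaults are 4 chains of 20 000 iterations with 5 000 burn-in — generous
for a two-parameter model; the validation harnesses in the tests use 2
chains of 4 000 (burn-in 1 500), which the split Gelman–Rubin diagnostic
(`gelman_rubin()`, warning above 1.1) shows is already well converged at
the 30–50-beach problem sizes exercised there. Credible intervals
(`credible_interval()`) are equal-tailed empirical quantiles, not HPD:
equal-tailed is the conventional reporting form for these models and
accommodates the right skew of incidence posteriors. Risk-ratio draws
(`risk_ratio_posterior()`) pair two independently sampled posteriors
elementwise after deterministically thinning the longer chain with a fixed
stride — an unbiased pairing that keeps runs reproducible.

## The translation algorithm

The equivalence contract is stated on the relative-risk scale. With $NS$
the non-swimmer rate and $SAI$ the tolerable excess (both per 1000), the
implied relative risk is

$$RR = \frac{NS + SAI}{NS},$$

and equating relative risks across case definitions gives the translated
tolerable rate

$$SAI_{\mathrm{new}} = NS_{\mathrm{new}} \times (RR_{\mathrm{old}} - 1).$$

`translate()` composes the two steps and records all intermediates at full
precision; display rounding (relative risk to 2 decimals, translated SAI to
the nearest integer) is applied only in the `*_display` columns, matching
how such figures are conventionally printed. With the historical HCGI
baseline of 14 per 1000, the 1986 freshwater tolerable excess of 8 per 1000
(the more protective of the freshwater/marine pair; marine was 19), and the
NGI baseline of 63 per 1000:

```{r translate}
translate(ns_old = 14, sai_old = 8, ns_new = 63)
```

`translate_posterior()` pushes posterior draws of the two baselines through
the same arithmetic so the translated rate inherits the MCMC uncertainty.

## Exposure-response model and criterion inversion

Swimming-associated illness is modelled additively on the risk scale
(identity link) against water quality measured as log10 *Enterococcus* qPCR
calibrator cell equivalents (CCE) per 100 mL:

$$SAI = a + b \times \log_{10}(\mathrm{CCE}),$$

with the pooled marine-plus-freshwater coefficients $a = -27.31$,
$b = 23.73$ available as `er_model_combined()`. Inverting at a tolerable
rate gives the criterion concentration
$\log_{10}\mathrm{CCE} = (SAI - a)/b$:

```{r criterion}
invert_criterion(er_model_combined(), 36)
```

Full precision (465.6 CCE here) is retained internally; the nearest-integer
`cce_display` (466) is the conventional guideline form.

`fit_identity_binomial()` estimates $(a, b)$ from day-by-group cohort
tables by maximising the binomial likelihood with per-subject probability
$p_0 + \mathrm{swim}\cdot(a + b\,\log_{10}\mathrm{CCE})/1000$. Identity-link
binomial models are not variance-stabilised and nothing keeps the linear
predictor inside $(0,1)$, so the baseline is parameterised on the logit
scale and the objective rejects any parameter vector whose fitted
probabilities leave $(10^{-9}, 1-10^{-9})$ — a hard-barrier variant of
constrained optimisation; optima pressing against the probability bounds
are flagged `boundary` and their standard errors (otherwise taken from the
observed information) suppressed. `compare_slopes()` provides the two-sided
z test for slope equality between independently fitted strata, and
`lrt_pooling()` the likelihood-ratio test of stratum-specific parameters
against a single pooled model — the two tests used to justify combining
marine and freshwater data into one model. The published p-values of those
pooling tests depended on individual-level study data that were never
released, so the package verifies the *mechanics* instead: under simulated
common truth the LRT statistic matches its chi-square reference and slope-
comparison p-values are uniform; under genuinely different slopes pooling
is usually rejected.

## What the synthetic cohorts emulate — and what they do not

The per-beach counts behind the published analyses were never deposited,
so the generators in this package are first-class, tested code rather than
fixtures. `sim_nonswimmer_cohorts()` draws latent beach probabilities from
the beta distribution and counts binomially, retaining the latent draws in
a `p_true` sidecar so recovery tests can audit the generator itself.
`preset_cohort_config()` calibrates the beta mean to the published overall
baselines (0.014 HCGI, 0.063 NGI). The concentration is not published;
the presets solve for the $s$ whose central 90% beach-rate interval spans
exactly a two-to-one range — the only dispersion statement available
(beach-by-beach background rates of roughly 10–20 per 1000 HCGI and 40–90
per 1000 NGI). That root-finding gives $s \approx 1617$ (HCGI) and
$s \approx 365$ (NGI). Per-beach sample sizes are likewise unpublished;
the presets default to 30 beaches of 1000 non-swimmers — a realistic
multi-summer beach-study scale — and both numbers are ordinary arguments.
Waders, who share the non-swimmer baseline, can be pooled into the cohort
via `wader_fraction`, mirroring how the NGI baseline was constructed.

`sim_swimmer_study()` emulates the prospective design behind the
exposure-response model: daily water quality drawn as
$\log_{10}\mathrm{CCE} \sim N(2.7, 0.4)$ — centring the design on the
criterion-relevant range, with negligible mass below the model root near
CCE 14 where predicted excess is clipped to zero — and per-subject illness
Bernoulli at baseline-plus-excess. Randomness uses a single seeded
Mersenne-Twister stream per run, recorded in the output metadata; identical
configuration and seed give bit-identical output, which the tests assert.

What the generators do **not** emulate bounds what passing tests can show:
illness is simulated at the classified-outcome level (no symptom-level
structure, follow-up windows, or reporting behaviour); there are no
covariates (age, sex, chronic conditions), whereas the original
exposure-response fits were covariate-adjusted; daily water quality is
log-normal and independent across days; and beaches differ only through
their latent rate. Parameter-recovery and coverage results therefore
validate the *statistical machinery* under its own assumptions — they do
not reproduce the published point estimates that depend on the unreleased
study data, and the headline risk ratio near 4.5 with an interval
overlapping 3.2–7.7 is checked as a property of the calibrated presets,
not as a reproduction.

## Validation scale and numerical choices

The test suite's simulation harnesses use sizes chosen to make Monte-Carlo
error small relative to the tolerances they assert: 100 replicate datasets
of 50 beaches × 2000 subjects for likelihood and Bayesian recovery of the
HCGI calibration (interval coverage within 95% ± 4%); 100 replicates of
200-day × 500-swimmer studies for exposure-response coefficient recovery;
200 replicate pairs for null calibration of the slope test; and a
quadrature oracle agreeing with the pmf to $10^{-10}$ on random parameter
grids. Degenerate inputs are handled explicitly rather than defensively:
zero-enrollee beaches are rejected at read time, single-day designs raise
a slope-unidentifiability error, a non-finite log posterior at
initialisation names the offending component, and a negative LRT statistic
beyond numerical tolerance is reported as an optimisation failure.

## Limitations

The risk-equivalence translation answers a policy question on the
relative-risk scale; whether "as protective as" should instead be read on
the absolute-excess scale is a genuine policy debate the package does not
adjudicate — it implements the relative-risk reading. The combined effect
of case definition, follow-up length and temporal change between study
eras is translated as a single factor, by design. The exposure-response
surface derives from point-source-impacted beaches; applying the criterion
machinery to non-point-source settings is outside what the model supports.
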