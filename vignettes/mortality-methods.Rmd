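---
title: "Hazard models for skeletal assemblages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard models for skeletal assemblages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohaz)
```

## The mortality model

`paleohaz` models adult attritional mortality with the Gompertz hazard
$h(t) = \alpha e^{\beta t}$ or the Gompertz–Makeham hazard
$h(t) = \alpha_1 + \alpha_2 e^{\beta t}$, where $\alpha$ (or $\alpha_2$)
sets the overall level of senescent mortality, $\beta$ the exponential
rate at which the risk of death rises with age, and $\alpha_1$ a constant
age-independent component capturing accidents, violence and acute
infection. All parameters are per calendar year; there is no age binning
anywhere in the hazard layer.

**Age origin.** Internally $t$ is years since age 15, the inclusion
threshold for adult skeletal analysis. Defining the model on $t \ge 0$
makes the left truncation exact — every likelihood automatically
conditions on survival to 15 without an extra conditioning term. Whether
published fits of this family place their origin at birth or at entry is
often unstated; the entry-age-15 convention is this package's own choice
and fitted parameters must be read relative to it (a hazard "at $t = 20$"
is the hazard at calendar age 35).

**Covariate.** A binary covariate $x$ (sex coded 0 = male, 1 = female)
acts through a proportional-hazards specification,
$h_i(t) = h(t_i)\,e^{x_i \rho}$: one parameter $\rho$ multiplying the
whole baseline, positive when the coded-1 group dies faster at every age.
The assumption that the multiplier is age-constant is substantive; an
effect confined to, say, the reproductive years can average out to
$\rho \approx 0$ and go undetected. The package deliberately does not
offer time-varying covariates (see *Limitations*).

## Likelihood and estimation

Deaths are treated as exactly observed at their point age estimates, so
each individual contributes
$x_i\rho + \ln h(t_i) - e^{x_i\rho} H(t_i)$, with
$H(t) = \alpha_1 t + (\alpha_2/\beta)(e^{\beta t} - 1)$ the cumulative
hazard. Interval-censored likelihoods for posterior age ranges are an
explicit non-goal: the chain mirrors the common practice of feeding point
estimates from Bayesian age estimation into the hazard fit, and the
recovery harness exists precisely to quantify what that shortcut costs.

`fit_mortality()` maximises this likelihood with BFGS on an unconstrained
reparameterisation: $\log$ for $\alpha_2$ and $\beta$ (and $\alpha$), and
softplus for $\alpha_1$ so the optimiser can approach the
$\alpha_1 = 0$ boundary smoothly. Starting values are moment-based —
Gompertz death ages behave approximately like a Gumbel variate of scale
$1/\beta$, so the sample SD pins $\beta$, and the level is set so that
$H(\text{median}) = \ln 2$ — and the default ten starts jitter the
transformed initials by ±20% (fixed jitter seed 20250409, restored after
use so user RNG streams are untouched; identical options give
bit-identical fits). Simulated GM-PH likelihoods at the sample sizes used
here are unimodal in practice, and the package's own simulation studies
run with two starts after checking they reproduce the ten-start optimum.

Standard errors come from the numerically differenced Hessian on the
transformed scale mapped through the delta method; a singular Hessian
yields missing standard errors with a warning rather than an error.

**Numerical safeguards.** Below $|\beta| < 10^{-8}$ the terms
$(e^{\beta t}-1)/\beta$ switch to their constant-hazard series limit to
avoid catastrophic cancellation; the likelihood returns a large finite
penalty instead of `NaN` on overflow so the optimiser can retreat.

## Intervals, tests, and wording

Wald intervals are the default (symmetric for $\rho$; built on the
transformed scale and back-transformed for positive parameters, so bounds
respect positivity). Profile-likelihood intervals — inverting the LRT by
bisection on the profiled likelihood — are available via
`profile_ci()` / `tidy(fit, ci = "profile")`, since published interval
pairs for such effects are often visibly asymmetric and the construction
behind them is rarely stated. Neither method is claimed as "the"
canonical one; at the sample sizes involved they agree to within a tenth
of the interval width.

The likelihood-ratio statistic is reported as
$2(\ell_{\text{full}} - \ell_{\text{reduced}})$, clamped at zero; some
reports print the same comparison with the opposite sign convention,
which is negative exactly when the richer model fits better. The
covariate test has df = 1. The Gompertz vs Gompertz–Makeham comparison is
offered through the same `lrt()`, with a caveat the user should know:
$\alpha_1 = 0$ lies on the parameter boundary, so the naive
$\chi^2_1$ p-value is conservative there; the naive value is what is
reported, for comparability with standard practice.

The default significance threshold is $\alpha = 0.1$, configurable.
Stratified results (`compare_strata`) are worded with care: overlapping
intervals *fail to indicate* a difference between strata — they are never
reported as showing "no difference". The same phrasing discipline is
enforced in `run_pipeline()` output.

## Age estimation

`age_posterior()` implements the transition-analysis structure
generically: each trait has a cumulative-link model
$\Pr(\text{stage} \ge j+1 \mid a) = g((a - \mu_j)/s)$ with ordered mean
ages-at-transition $\mu_j$, common dispersion $s$, and logistic or probit
$g$; traits are conditionally independent given age, and the posterior on
the age grid is the prior times the product of observed-stage
likelihoods. The actual trait sets, reference-sample parameters and
proprietary priors of existing software are not reproduced — the package
reimplements the method class, parameterised entirely by configuration,
and `fit_transition_models()` recovers the parameters from any known-age
reference table (via `MASS::polr`, or a binomial GLM when a trait has
only two stages).

Grid and summaries: ages 15–110 at 0.25-year steps; the point estimate is
the posterior mean by default (the mean/mode choice in existing tools is
not standardised; the mode is available); the credible interval is
highest-posterior-density, found by density thresholding with linear
interpolation at the cut. Every posterior is normalised to machine
precision, and a stage combination with numerically zero mass raises an
error naming the offending combination rather than returning garbage.

## Sex estimation

Sectioning points are sample-specific measurement means; a value equal to
or below the mean classifies female, strictly above classifies male. How
the per-measurement votes should be *combined* is usually left unstated
in applied work; the package uses the simplest symmetric rule consistent
with per-measurement sectioning — majority vote over available
measurements, exact ties indeterminate. The reconciliation rule against
an externally supplied morphological call prioritises post-cranial
metrics when only cranial morphology was scored; when the pelvis was
scored, the pelvis-backed morphological call wins, following the same
rationale (post-cranial evidence outranks skull-only evidence, but not
the pelvis). Indeterminate individuals are excluded from hazard fitting —
binary coding implies exclusion — and the exclusion is visible in the
returned call table.

## The simulator and what it does (not) show

`sim_config()` defaults describe the study conditions the package is
aimed at: 335 adults, female proportion 161/335, ten sites in two
chronological strata (three early, seven late; site weights proportional
to 47/34/16/2/35/10/67/42/72/10, giving strata of 97 and 238 in
expectation), baseline Gompertz–Makeham
$(\alpha_1 = 0.01, \alpha_2 = 0.005, \beta = 0.07)$ — a plausible
pre-industrial adult profile with mean age-at-death in the low 40s — and
a small positive female effect $\rho = 0.07$ on the log-hazard scale.
Trait stages are drawn from the transition models at the true age,
measurements from sex-specific normals separated by roughly 2–3 pooled
SDs, and missingness independently per cell (default 10%).

Ages are drawn by inverting the survival function:
$e^{x\rho} H(t) = -\ln U$ solved by Brent's bracketed root-finder at
tolerance $10^{-10}$ years on $[0, \text{cap} - 15]$, with draws beyond
the 110-year cap resampled and counted. One master seed spawns one child
stream per component (sexes, sites, ages, traits, metrics, missingness,
morphology), so switching a downstream component on or off does not shift
any other component's draws.

What passing simulation tests does *not* show about real assemblages: the
simulator draws from exactly the model family being fitted, with honest
random missingness and no age heaping, no preservation bias against
fragile (young/old) skeletons, no cemetery catastrophic-mortality
mixtures, and reference-matched trait models. Recovery and calibration
results are therefore best-case; the built-in estimated-vs-true
comparison in `end_to_end_recovery(estimated = TRUE)` measures only the
attenuation from age/sex re-estimation, not these field effects.

## Problem sizes used in validation

The package's own studies use: 1000 random parameter/age draws for the
quadrature oracle; 100 replicates of $n = 1000$ for covariate-effect
recovery (median bias and 95% CI coverage); 500 null replicates of
$n = 335$ for LRT calibration at $\alpha = 0.1$; 1000 fixed-seed draws
for the sampler's closed-form check; and 20,000 draws per arm for the
proportional-hazards survival power law. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the tolerances being checked
while keeping a full run in the minutes range on one core.

## Limitations

- The proportional-hazards effect is age-constant by construction;
  age-specific sex differences in mortality cannot be detected.
- Point-estimate ages ignore individual age uncertainty; expect
  attenuation of $\beta$ and inflated variance of $\hat\rho$ when ages
  come from posterior point estimates rather than known ages.
- The binary sex variable is an estimation construct, not a claim about
  the lived spectrum of sex and gender; indeterminate individuals are
  excluded, which can itself bias composition.
- No Siler juvenile component, frailty/heterogeneity terms, or
  catastrophic-mortality mixtures; the models describe adult attritional
  regimes only.
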