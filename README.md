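# paleohaz

Parametric hazard modelling of skeletal age-at-death data for
paleodemography.

Bioarchaeologists routinely ask whether a covariate — most often estimated
sex — shifted the risk of death in a past population, working from a few
hundred skeletons whose ages were themselves estimated from ordinal bone
traits. `paleohaz` implements that analysis chain for adult (15+ years)
assemblages:

- **Hazard models.** Gompertz senescent mortality, *h(t) = α e^{βt}*, and
  Gompertz–Makeham, *h(t) = α₁ + α₂ e^{βt}*, defined on *t* = years since
  age 15 so the adult inclusion rule is an exact left truncation. A binary
  covariate *x* acts through a proportional-hazards specification,
  *hᵢ(t) = h(t) e^{xᵢρ}*: `ρ > 0` means the coded-1 group (females) faced
  higher mortality at every age.
- **Maximum likelihood** fitting of these models from point age-at-death
  estimates (`fit_mortality`), with multistart optimisation on an
  unconstrained reparameterisation, delta-method standard errors, Wald and
  profile-likelihood intervals, likelihood-ratio tests of nested models
  (`lrt`, df = 1 for the covariate), and stratified comparison across time
  periods (`compare_strata`).
- **Bayesian age estimation** in the transition-analysis style: per-trait
  cumulative-link models Pr(stage | age) fitted to a known-age reference
  (`fit_transition_models`), combined with an informative attritional
  prior into a posterior over age with an HPD interval (`age_posterior`).
- **Metric sex classification** by sample-specific sectioning points
  (measurement mean; at-or-below classifies female) with majority voting
  and a reconciliation rule that prioritises post-cranial metrics over
  skull-only morphology (`classify_metric`, `reconcile_sex`).
- **A seeded assemblage simulator** (`simulate_assemblage`,
  `end_to_end_recovery`) that generates two-period, multi-site cemetery
  samples with known mortality parameters, trait stages, dimorphic
  measurements and missingness, so every stage of the pipeline can be
  validated by parameter-recovery and calibration studies.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and each
result type has an `autoplot()` method.

## Worked example

Simulate a 335-adult, ten-site, two-period assemblage with a small female
excess hazard (ρ = 0.07), fit the Gompertz–Makeham PH model, and test the
sex covariate:

```r
library(paleohaz)

cfg <- sim_config(n = 335, seed = 20260925)   # defaults: rho = 0.07, 161/335 female
a   <- simulate_assemblage(cfg)

fit <- fit_mortality(a)                       # GM baseline + sex covariate
fit
#> Gompertz-Makeham hazard fit with PH covariate, n = 335, logLik = -1345.9175
#> # A tibble: 4 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 a1     0.0106    0.00569  0.00372    0.0302
#> 2 a2     0.00536   0.00332  0.00160    0.0180
#> 3 beta   0.0694    0.0138   0.0470     0.102
#> 4 rho    0.0703    0.110   -0.146      0.286

lrt(fit, fit_mortality(a, covariate = FALSE))
#> Likelihood-ratio test: statistic = 0.4075 (df = 1), p = 0.5232
#> Failed to indicate an improvement at alpha = 0.1 (this does not
#> demonstrate the absence of an effect).
```

`a1` is the age-independent (Makeham) hazard, `a2` and `beta` the level
and rate of the senescent component, and `rho` the log-hazard effect of
being female — here 0.07 (s.e. 0.11), an interval spanning zero, so the
test fails to indicate a sex effect at α = 0.1, as expected at this sample
size and effect.

The one-call pipeline produces the per-stratum summary table:

```r
run_pipeline(list(simulate = cfg))
#> Stratum | Effect of covariate (s.e.) | CI | LRT (p)
#> All individuals (n = 335) | 0.07 (0.11) | -0.15, 0.29 | 0.41 (0.52)
#> early (n = 96) | 0.12 (0.21) | -0.28, 0.53 | —
#> late (n = 239) | 0.05 (0.13) | -0.21, 0.30 | —
```

Age estimation for a single skeleton from observed trait stages:

```r
post <- age_posterior(
  list(pubic_symphysis = 4, cranial_sutures = 2),
  default_trait_models()[c("pubic_symphysis", "cranial_sutures")],
  age_prior("gompertz_makeham", gompertz_makeham(0.01, 0.005, 0.07)))
post
#> Age-at-death posterior: mean 40.0 y, 95% HPD [21.8, 57.6]
```

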