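# tgimix

Compartmental and delay-differential models of chemotherapy-perturbed
tumor growth, with nonlinear mixed-effects estimation and
information-criterion model selection.

## What this is for

In preclinical tumor-growth-inhibition (TGI) studies, a standard
pharmacodynamic model describes a proliferating tumor compartment
Z<sub>1</sub> that grows by a biphasic tumor growth function,

TGF = λ₀ Z₁ / [1 + ((λ₀/λ₁) V)^ψ]^(1/ψ),

(exponential at rate λ₀ for small volume, linear at slope λ₁ for large
volume) and loses drug-hit cells at rate k₁·c(t)·Z₁ into a chain of
transit compartments that empty at rate k₂ — the chain producing the lag
between exposure and cell death.  The number of transit compartments is
arbitrary, and the chain can be replaced by a single compartment with an
explicit delay in elimination:

dZ₂/dt = k₁ c(t) Z₁ − k₂ Z₂(t − t₂),  Z₂(t) = 0 for t < 0.

`tgimix` implements both families (`simeoni-1`, `simeoni-2`, …,
`delay`), the unperturbed growth function (`simeoni`) and the classic
generalized logistic, Gompertz and von Bertalanffy laws (analytic
solutions), and answers the model-comparison question statistically:
individual parameters are log-normal across animals
(φᵢ = exp(μ + λᵢ), λᵢ ~ N(0, Ω)), observations carry combined
additive + proportional error y = f + (a + b·f)ε, populations are fitted
by a SAEM algorithm (`tgi_nlme()`), marginal −2·log-likelihood is
estimated by importance sampling, and candidates are ranked by AIC,
AICc, BIC and information-criterion weights
wⱼ = exp(−Δⱼ/2) / Σₘ exp(−Δₘ/2).

Because the motivating animal dataset is not public, the package ships a
synthetic-cohort generator (`generate_cohort()`) that emulates the study
design: 21 untreated + 19 cisplatin-treated mice, daily caliper
measurement (V = L·W²/2) with weekend gaps, initial volumes under
700 mm³, a single bolus at day 0 with first-order elimination, and
euthanasia censoring at ~2500 mm³.

## Worked example

```r
library(tgimix)

spec   <- default_population_spec()          # the packaged study conditions
cohort <- generate_cohort(spec, cohort_design(), seed = 42)
cohort
#> Synthetic/longitudinal tumor cohort: 40 subjects (21 control, 19 treated), 734 observations
#>   days 0-38, volumes 26.5-3402.7 mm^3

trt  <- cohort_arm(cohort, "treated")
fits <- list(
  `simeoni-1` = tgi_nlme(trt, "simeoni-1", saem_control("fast"), seed = 1),
  delay       = tgi_nlme(trt, "delay",     saem_control("fast"), seed = 1))
fits$delay
#> Population tumor growth fit: model 'delay'
#>   19 subjects, 390 observations
#>         lambda0  lambda1       V0     k1     k2     t2
#> typical  0.2212 120.8000 171.5000 0.9309 0.4910 1.7860
#> omega    0.2359   0.2584   0.6001 0.1584 0.2433 0.2347
#>   residual error: a = 17.92, b = 0.1038
#>   -2LL = 4936.45 (MC se 3), k = 14

compare_models(fits)
#> Model comparison (2 candidates; AICc n = 390, BIC sample = subjects)
#>      model    -2LL     AIC   w(AIC)    AICc  w(AICc)     BIC   w(BIC)  k
#>  simeoni-1 4969.96 4993.96 3.89E-07 4994.79 4.50E-07 5005.30 1.00E-06 12
#>      delay 4936.45 4964.45   1.0000 4965.57   1.0000 4977.67   1.0000 14
```

Typical values sit close to the generating parameters (λ₀ = 0.25,
λ₁ = 120, V₀ = 200, k₁ = 1, k₂ = 0.5, t₂ = 2; this treated-only fit
leans on just 19 animals, so V₀ and k₁ wander more than in a full
40-animal fit), and the delayed-elimination model — the generating model
here — wins every criterion decisively against the one-transit chain.  The drivers
`run_control_experiment()` / `run_treated_experiment()` run the full
simulate → fit 4 candidates → table workflow, and
`reproduce_reference_tables()` recomputes the weight columns of the
packaged reference tables (published criteria from a cisplatin mouse
study) from their printed criterion values.  A thin CLI wrapper lives at
`inst/scripts/tgi-pipeline.R` (subcommands `simulate`, `fit`, `compare`,
`reproduce-tables`).

The methods vignette
(`vignettes/tumor-growth-model-selection.Rmd`) documents the model, the
SAEM settings (annealing, multi-kernel MCMC), the numerical treatment of
the delay system, and what the synthetic cohorts do and do not emulate.

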