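# respmix

Bayesian latent-class growth modelling of treatment response in
longitudinal depression scores.

## The problem

Guided internet-based cognitive behavioural therapy (iCBT) reduces
depressive symptoms for many patients, but nonresponse is common. Given
repeated Beck Depression Inventory-II (BDI-II, 0–63) measurements taken at
irregular week offsets during treatment, plus a per-subject table of
baseline covariates (demographics, severity scales, diagnoses, cognitive
measures, expectancy/motivation items), `respmix` answers two questions
for trial analysts and methodologists:

1. **Who responds?** A restricted two-class latent growth mixture
   separates *responders* — trajectories following an exponential decay
   `b0_i · exp(−λ_i t)` with decay rates drawn from a positive group
   distribution — from *nonresponders*, whose trajectories are flat
   (λ = 0). Standardized covariates predict class membership through a
   logit link:

   `z_i ~ Bernoulli( logit⁻¹( β₀ + Σ_k β_k x_ik ) )`

   The per-subject responder probability `p_resp` is the posterior mean of
   the class indicator `z_i`.

2. **How strongly?** In a complementary hierarchical quadratic model
   `b0_i + b1_i t + b2_i t²`, covariates enter as linear predictors of the
   individual slope:

   `b1_i ~ N( α₀ + Σ_k α_k x_ik , τ² )`

   Reported `α_k` are oriented so positive always means faster symptom
   decline.

Evidence per covariate is summarised by posterior modes, 95%
highest-density intervals, directional odds ratios
(`max(p⁺,p⁻)/min(p⁺,p⁻)` over the coefficient's sign), Savage–Dickey
Bayes factors for the point null `α_k = 0`, and Jeffreys evidence
categories. Models are sampled with JAGS (via `rjags`) under weakly
informative priors; convergence (split-chain Gelman–Rubin) and posterior
predictive checks are built in. Because no individual-level trial data are
distributable for this design, a seeded synthetic-cohort generator
reproduces the study conditions (82 subjects, baseline BDI-II 21.3 ± 6.6
restricted to 10–40, treatment spans 9.6 ± 4.8 weeks in [1, 22], up to 11
occasions, a ~74/26 responder split, 20 covariates with realistic
marginals and missingness) and provides ground truth for recovery tests.

## Worked example

```r
library(respmix)

cohort <- generate_cohort(generator_config(n_subjects = 82, seed = 42))
cohort$dataset
#> study_dataset: 82 subjects, 526 observations
#>   covariates: 20 ( gender, age, marital, employment, bai , ... )

covs <- impute_covariates(
  standardize_covariates(cohort$dataset$covariates)$table, "mean")

fit <- fit_latent_class(cohort$dataset, covs,
                        sampler = sampler_config(seed = 43))
fit
#> class_posterior (exponential mixture): 82 subjects, 20 membership covariates
#>   mean p_resp: 0.734

cls <- classify(fit$p_resp, threshold = 0.5)
#> responders: 58/82 (71%)

head(evidence_table(fit$beta$coef), 4)
#>                name  mode hdi_low hdi_high or_value or_sign
#> 1               gse -1.11    -2.2    -0.14     80.6       -
#> 2 earlier_treatment -0.80    -2.5     0.69      5.9       -
#> 3            hads_a -0.53    -1.6     0.66      4.1       -
#> 4     depression_dx -0.31    -1.8     1.15      1.6       -

sp <- fit_slope_regression(cohort$dataset, covs,
                           sampler = sampler_config(seed = 44))
bf <- evidence_table(sp$alpha, prior_density_at_zero = dnorm(0),
                     include_bf = TRUE)
tail(bf[, c("name", "bf10", "category")], 4)
#>                 name bf10                    category
#> 17               gse 0.55   anecdotal evidence for H0
#> 18              swls 0.68   anecdotal evidence for H0
#> 19 earlier_treatment 0.74   anecdotal evidence for H0
#> 20           modules 9.41 substantial evidence for H1

max(convergence_report(fit)$rhat)
#> 1.021
```

Reading the output: 58 of 82 simulated subjects (71%) are classified
responders at the 0.5 posterior-probability split — close to this cohort's
generating share. The membership table sorts coefficients by posterior
mode; e.g. the `gse` row says a higher general self-efficacy score was
associated with lower responder odds *in this replicate*, with odds 80:1
that the effect direction is negative (the generator's true effect for
`gse` is zero — at n = 82, single-replicate odds ratios can be emphatic
about noise, which is exactly why the Bayes-factor column grades evidence
more conservatively). The slope Bayes factors mostly land in the
anecdotal-to-substantial H0 bands, correctly reflecting that most
generated effects are null or small.

The same analysis runs config-driven from a shell via the three pipeline
verbs (see `inst/cli/respmix` and `inst/extdata/config_template.yaml`):

```sh
Rscript inst/cli/respmix simulate config.yaml --out data/
Rscript inst/cli/respmix fit      config.yaml --out results/
Rscript inst/cli/respmix report   results/
```

`fit` writes classification, evidence and Bayes-factor CSVs,
response-probability curves, convergence and posterior-predictive reports,
and a JSON manifest; `report` renders them as one markdown summary.

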