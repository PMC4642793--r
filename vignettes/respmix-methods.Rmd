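---
title: "Modelling who responds to guided internet-based CBT: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling who responds to guided internet-based CBT: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Guided internet-based cognitive behavioural therapy (iCBT) helps many
people with mild-to-moderate depression, but a substantial minority do not
respond. Given repeated Beck Depression Inventory-II (BDI-II) measurements
collected at irregular times during treatment, plus a table of baseline
characteristics, two questions arise:

1. **Who responds?** Which patients' symptom trajectories decline under
   treatment, and which baseline covariates shift the odds of belonging to
   the responder group?
2. **How strongly?** Among declining trajectories, which covariates predict
   a steeper decline?

`respmix` answers both with hierarchical Bayesian growth models sampled by
JAGS, and summarises the evidence per covariate with posterior modes,
highest-density intervals (HDIs), directional odds ratios, Savage–Dickey
Bayes factors and Jeffreys evidence categories.

## The observation model and trajectory families

Let $y_{ij}$ be the BDI-II total of subject $i$ at $t_{ij}$ weeks after the
pre-treatment assessment ($t_{i1} = 0$). All models share a normal
observation model with a common residual SD $\sigma$:

$$y_{ij} \sim \mathrm{N}\big(\mu_i(t_{ij}),\ \sigma^2\big)$$

with one of three mean functions:

* linear: $\mu_i(t) = b_{0i} + b_{1i} t$
* quadratic: $\mu_i(t) = b_{0i} + b_{1i} t + b_{2i} t^2$
* exponential: $\mu_i(t) = b_{0i} \exp(-\lambda_i t)$, $\lambda_i \ge 0$

Subject-level coefficients are constrained by group-level normal
distributions (a hierarchical model), which regularises the many
per-subject fits and mitigates the multiple-comparison problem of
screening ~20 covariates in a small sample. `select_family()` ranks the
three families by WAIC computed from the posterior draws; on decaying
cohorts the exponential family wins, which motivates using it in the
mixture below.

The BDI-II is an integer scale in [0, 63]; the model treats it as
continuous and ignores the rounding. The synthetic generator *does* round
and clamp, so the tests exercise exactly this (mild) misspecification.

## The restricted two-class mixture: who responds?

`fit_latent_class()` assumes each subject belongs latently to one of two
classes:

* **responders** ($z_i = 1$): decay rate $\lambda_i$ drawn from a positive
  group distribution $\mathrm{N}(\mu_\lambda, \sigma_\lambda^2)$ truncated
  at 0;
* **nonresponders** ($z_i = 0$): flat trajectory, $\lambda_i = 0$.

The *restriction* — pinning the nonresponder class to zero decay — encodes
the clinical semantics directly and removes label switching by
construction: the responder class is, in every draw, the one with the
larger decay. The analogous quadratic variant pins the nonresponder
slope/curvature to zero and constrains the responder slope mean to be
non-positive. The per-draw constraint violation rate is recorded and a
warning is raised above 1%.

Standardized covariates enter through a logit link on class membership:

$$z_i \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(\beta_0 + \textstyle\sum_k \beta_k x_{ik})\big)$$

The per-subject responder probability `p_resp` is the posterior mean of
$z_i$ — not a plug-in of posterior-mean coefficients — so classification
uncertainty propagates from every level of the model. `classify()` labels
a subject a responder when `p_resp` exceeds a threshold; the default is
0.5 (the natural posterior decision rule). Because `p_resp` is typically
strongly bimodal in separable cohorts, a much lower split such as 0.05
yields a nearly identical partition; both are supported.
`response_probability_curve()` sweeps one covariate over a grid, holding
the others at baseline, and returns the posterior mean curve with a
pointwise 95% HDI.

## The slope regression: how strong is the response?

`fit_slope_regression()` uses the quadratic family (the exponential rate
is non-linear in effect: a unit change at a small rate moves trajectories
far more than the same change at a large rate, so linear covariate effects
are only interpretable on the quadratic slope). Covariates enter as linear
predictors of the individual slope:

$$b_{1i} \sim \mathrm{N}\big(\alpha_0 + \textstyle\sum_k \alpha_k x_{ik},\ \tau^2\big)$$

with the curvature $b_{2i}$ and baseline $b_{0i}$ keeping covariate-free
group priors. Because symptom decline means a *negative* slope, reported
coefficients are sign-flipped so that **positive $\alpha_k$ always means
faster symptom decline**; the raw draws remain available as `alpha_raw`.
A covariate-free call reduces exactly to the plain hierarchical quadratic
fit (tested), with $\alpha_0$ playing the slope group mean.

## Priors

All priors are weakly informative and overridable via `prior_config()`:

| parameter | prior | rationale |
|---|---|---|
| baseline group mean $\mu_{b0}$ | N(20, 10²) | keeps >95% of prior baseline mass inside the 0–63 scale |
| decay group mean $\mu_\lambda$ | N(0.1, 0.2²), $\ge 0$ | decay of order 0.1/week; half-life of weeks, not days |
| slope group mean | N(0, 2²) | a few score points per week at most |
| curvature group mean | N(0, 0.5²) | gentle bending over a ~10-week course |
| score-scale group SDs, $\sigma$ | half-N(0, 5²) | BDI-II units |
| decay-rate group SD $\sigma_\lambda$ | half-N(0, 0.5²) | per-week units; see below |
| membership $\beta_0, \beta_k$; slope $\alpha_k$ | N(0, 1²) | weakly informative on the logit / standardized-slope scale; the Savage–Dickey reference |

A single half-N(0, 5²) scale for *every* group SD would put the decay-rate
SD prior two orders of magnitude above the parameter's natural size
(~0.03–0.05/week); in practice that chain then mixes far too slowly
(split-$\hat R \approx 1.14$ where all other parameters sit below 1.02).
Scaling the decay-rate group SD prior to its per-week units — half-N(0,
0.5²), still many times wider than any plausible between-subject spread —
restores honest mixing without becoming informative. This is the one
place the package departs from a uniform group-SD scale.

Covariates are standardized before entering either regression
(`standardize_covariates()`): continuous and ordinal columns to mean 0,
SD 1 (population SD), binary columns centered only, so binary coefficients
read as full 0→1 contrasts while remaining comparable across tables. The
scaling record inverts the transform. Missing covariate values (the data
model tolerates up to 20%, warning above 11%) are mean-imputed by default
(`impute_covariates()`), i.e. set to 0 on the standardized scale — the
simplest choice that neither invents signal nor discards subjects; a
`none` strategy is provided for callers who want hard failures instead.

## The evidence layer

For each covariate's coefficient draws:

* **Posterior mode**: argmax of a Gaussian-kernel density (Silverman
  bandwidth, fixed 1024-point grid) — deterministic given the draws.
* **HDI**: narrowest contiguous interval containing the requested mass of
  sorted draws; never wider than the equal-tailed interval.
* **Directional odds ratio**: $\max(p^+, p^-)/\min(p^+, p^-)$ where $p^+$
  is the fraction of draws above zero. Draws exactly at zero count half to
  each side; the minority side is floored at $1/(2n)$ to keep the ratio
  finite, and floored ratios are flagged `saturated`. This reports the
  *direction* of an effect, not its size.
* **Savage–Dickey BF10**: prior density at zero divided by posterior
  density at zero — the standard point-null Bayes factor for nested MCMC
  models, computable from draws plus the analytic prior alone. While zero
  lies within two posterior SDs of the mean, the posterior density is the
  same kernel estimate as the mode uses; further out, kernel estimates at
  zero are dominated by Monte-Carlo noise (few draws land near zero), so a
  moment-matched normal approximation is used instead — precisely the
  regime where these coefficient posteriors are closest to normal. The
  method used is attached to the result. Bayes factors are reported for
  the slope model, where the null ($\alpha_k = 0$) is nested and the prior
  density at zero is known exactly; BF estimation inside the latent-class
  model is left out as statistically fragile, and the mixture's evidence
  is reported via odds ratios and curves instead.
* **Jeffreys categories**: >100 decisive, 30–100 very strong, 10–30
  strong, 3–10 substantial, 1–3 anecdotal (for H1; reciprocals for H0),
  exactly 1 no evidence. Boundary values go to the stronger category —
  arbitrary but fixed and documented.

## Diagnostics

`gelman_rubin()` implements the split-chain potential scale reduction
factor: each chain is halved, $W$ is the mean within-half variance, $B$
the between-half variance of means, and
$\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$. Note that for finite chains
$\hat R$ can sit marginally below 1 (identical chains give exactly
$\sqrt{(n-1)/n}$). `convergence_report()` checks all group-level
parameters (including the $\beta$ and $\alpha$ coefficient vectors)
against a default threshold of 1.05 and reports effective sample sizes.
The decay-rate group SD is the slowest-mixing parameter in the mixture
(effective samples of a few percent of draws); convergence-critical runs
should budget 4 chains × 2000+ retained draws.

`posterior_predictive()` simulates replicated datasets from the normal
observation model at sampled posterior draws on the observed time grids.
Because visit times are irregular, summaries are binned to integer weeks
(`floor(t)`); per bin the observed mean and SD are compared to the 2.5/50/
97.5% replicated envelope, with lower-tail probabilities per summary.

## The synthetic cohort generator

No individual-level trial data are available for this design, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, serving both as the test bed (with ground truth) and as
the default input of the pipeline. Its defaults emulate a primary-care
depression trial cohort:

* 82 subjects; baseline BDI-II ~ N(21.3, 6.6²) truncated to the 10–40
  inclusion window;
* flexible session schedules: total span ~ N(9.6, 4.8²) weeks truncated to
  [1, 22]; up to 11 occasions, with a per-session stopping hazard of 0.15
  (mean ~7 occasions) and jittered positive gaps;
* a ~74%/26% responder/nonresponder split: the membership intercept 1.25
  targets a marginal responder share of 0.74 after integrating the default
  covariate effects (episodes +0.5, marital +0.4, SWLS +0.45, dysfunctional
  thinking −0.45 on the logit/SD scale);
* responder decay rates ~ N(0.12, 0.04²) truncated at 0 (about half the
  baseline score shed over a 9–10 week course), nonresponders ~flat;
  residual SD 3 BDI-II points; scores rounded and clamped to [0, 63];
* 20 covariates (demographics, severity scales, diagnoses, cognitive
  measures, expectancy/motivation/usage items) with realistic marginals
  and MCAR missingness up to ~11%, matching the data model's warning
  threshold.

What it deliberately does **not** emulate: covariate correlations (each
marginal is sampled independently unless a joint spec is supplied),
informative or outcome-dependent dropout (missingness is MCAR), item-level
instrument structure, and therapist/session dynamics. Recovery tests
passing on these cohorts therefore show the estimation machinery is
sound — not that real trial data meet the model's assumptions.

In the quadratic world the generator shifts responder slopes by
$-\sum_k \alpha^{\mathrm{true}}_k x_{ik}$, so a positive configured effect
means faster decline, matching the fitted model's reporting convention.

## Numerical and design choices

* Determinism: every chain gets its own Mersenne–Twister stream derived
  from the sampler seed; identical configs give byte-identical draws,
  evidence CSVs and simulated datasets (tested).
* Family selection uses WAIC from draws; the criterion formula is emitted
  with the results table.
* $\hat R$ threshold 1.05; PPC bins are `floor(t)` weeks; HDI mass 0.95
  throughout by default.
* Degenerate inputs: empty datasets yield log-likelihood 0; constant draw
  vectors return their value as mode and a saturated Bayes factor;
  zero-variance covariates are an error at standardization; subjects need
  at least two occasions.
* Test and pipeline problem sizes (n = 25–100 subjects, 2 chains ×
  300–800 retained draws for replicate sweeps; 4 × 3000 for the
  convergence check) were chosen so each check isolates one property at
  the smallest size where the property is decidable.

## Known limitations

* A single residual SD is shared across subjects and occasions;
  autoregressive residuals and non-normal observation families are out of
  scope.
* Covariates affect class membership and the quadratic slope, but not
  within-class trajectory shape or curvature.
* Exactly two latent classes; no class-number selection.
* Mean imputation understates covariate uncertainty at the 5–11%
  missingness rates the data model allows; with much more missingness a
  model-based treatment would be needed.
* The Savage–Dickey normal-tail approximation assumes near-normal
  coefficient posteriors far from the null; with strongly skewed
  posteriors the decisive-evidence BFs would be approximate (their
  category, however, is robust).
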