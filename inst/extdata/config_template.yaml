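# respmix run configuration template.
# Exactly one of `simulate:` or `input:` must be present.

seed: 1                      # required; drives generator and sampler

output_dir: respmix-output   # where result CSVs and the manifest go

# --- synthetic cohort (remove this block when using real data) ----------
simulate:
  n_subjects: 82             # cohort size
  family: exponential        # trajectory world: exponential | quadratic
  # any generator_config() argument can be overridden here, e.g.:
  # responder_decay_mean: 0.12
  # dropout_hazard: 0.15
  # true_beta: {episodes: 0.5, marital: 0.4, swls: 0.45, warpy: -0.45}

# --- real data (remove `simulate:` above and uncomment) -----------------
# input:
#   scores: scores.csv       # long format: subject,time_weeks,bdi2
#   covariates: covariates.csv
#   kinds:                   # one entry per covariate column
#     marital: binary
#     episodes: ordinal
#     swls: continuous

standardize: true            # z-score continuous/ordinal, center binary
impute: mean                 # mean | none

analyses:                    # run in this order
  - select-family
  - latent-class
  - slope-regression

model_family: exponential    # mixture trajectory family
threshold: 0.5               # responder classification split on p_resp
rhat_threshold: 1.05         # convergence pass threshold

sampler:
  chains: 4
  adapt: 500
  warmup: 1000
  draws: 2000

prior: {}                    # prior_config() overrides, e.g. {beta_sd: 1}

# curves: [swls, warpy]      # covariates for response-probability curves
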