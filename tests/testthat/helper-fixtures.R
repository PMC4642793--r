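# Shared fixture builders: tiny deterministic datasets, a minimal covariate
# spec, well-separated cohort configs, and a fast sampler for test fits.

tiny_dataset <- function() {
  study_dataset(list(
    measurement_series("s1", c(0, 1, 3), c(21, 18, 15)),
    measurement_series("s2", c(0, 2, 5), c(30, 25, 20)),
    measurement_series("s3", c(0, 4), c(12, 12))))
}

tiny_covariates <- function(ids = c("s1", "s2", "s3")) {
  covariate_table(
    ids,
    matrix(c(0, 1, 1, 14.5, 20.1, 9.3), length(ids), 2,
           dimnames = list(NULL, c("marital", "swls"))),
    c(marital = "binary", swls = "continuous"))
}

# two-covariate spec with no missingness, for fast generator fixtures
test_cov_spec <- function() {
  list(x1 = list(kind = "continuous", mean = 0, sd = 1, missing = 0),
       marital = list(kind = "binary", p = 0.5, missing = 0))
}

# well-separated two-class world: responder decay 0.15, nonresponder flat,
# tight decay spread, residual SD 3 — the regime where observed change
# separates the classes almost perfectly
separated_config <- function(n = 100, seed = 1, intercept = log(3),
                             true_beta = c(x1 = 0), residual_sd = 3, ...) {
  generator_config(
    n_subjects = n, seed = seed,
    responder_intercept = intercept, true_beta = true_beta,
    true_alpha = c(x1 = 0),
    responder_decay_mean = 0.15, responder_decay_sd = 0.03,
    nonresponder_decay_mean = 0, nonresponder_decay_sd = 0.01,
    residual_sd = residual_sd, covariate_spec = test_cov_spec(), ...)
}

quad_config <- function(n = 100, seed = 1, true_alpha = c(x1 = 0.25), ...) {
  generator_config(
    n_subjects = n, seed = seed, family = "quadratic",
    responder_intercept = 20,        # single-class world for slope tests
    true_beta = c(x1 = 0), true_alpha = true_alpha,
    quad_b1_mean = -1.2, quad_b1_sd = 0.3,
    quad_b2_mean = 0.04, quad_b2_sd = 0.01,
    residual_sd = 3, covariate_spec = test_cov_spec(), ...)
}

quick_sampler <- function(seed = 1, draws = 600)
  sampler_config(chains = 2, adapt = 300, warmup = 300, draws = draws,
                 seed = seed)

std_imputed <- function(ct)
  impute_covariates(standardize_covariates(ct)$table, "mean")

subset_covs <- function(ct, keep) {
  ct$values <- ct$values[, keep, drop = FALSE]
  ct$kinds <- ct$kinds[keep]
  ct
}

# rank-based AUC of scores against binary labels (1 = positive class)
simple_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
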