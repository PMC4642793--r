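# Strength-of-response analysis: hierarchical quadratic growth model with
# covariates as linear predictors on the individual slope.

jags_slope_model <- function(has_covariates) {
  pred <- if (has_covariates) "alpha0 + inprod(X[i,], alpha_raw)"
          else "alpha0"
  alpha_block <- if (has_covariates) "
  for (k in 1:K) { alpha_raw[k] ~ dnorm(0, pr_alpha_tau) }" else ""
  paste0("model {
  for (j in 1:Nobs) {
    y[j] ~ dnorm(b0[subj[j]] + b1[subj[j]] * t[j] +
                 b2[subj[j]] * t[j] * t[j], y_tau)
  }
  for (i in 1:N) {
    b0[i] ~ dnorm(b0_mu, b0_tau)
    b1[i] ~ dnorm(", pred, ", b1_tau)
    b2[i] ~ dnorm(b2_mu, b2_tau)
  }
  alpha0 ~ dnorm(pr_b1_mean, pr_b1_tau)", alpha_block, "
  b0_mu ~ dnorm(pr_b0_mean, pr_b0_tau)
  b0_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b0_tau <- pow(b0_sd, -2)
  b1_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b1_tau <- pow(b1_sd, -2)
  b2_mu ~ dnorm(pr_b2_mean, pr_b2_tau)
  b2_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b2_tau <- pow(b2_sd, -2)
  sigma ~ dnorm(0, pr_sigma_tau) T(0,)
  y_tau <- pow(sigma, -2)
}")
}

#' Fit the slope-regression model
#'
#' Hierarchical quadratic growth model in which the individual linear slope
#' b1_i is regressed on standardized, imputed subject-level covariates:
#' b1_i ~ normal(alpha0 + sum_k alpha_k x_ik, tau^2).  Curvature b2 and
#' baseline b0 keep covariate-free group priors.  Coefficient priors are
#' normal(0, 1) on the raw slope scale, the reference the Savage-Dickey
#' Bayes factors use.
#'
#' Reported coefficients are sign-oriented so that a positive alpha always
#' means faster symptom decline (a more negative raw slope); the raw-scale
#' draws are available under `alpha_raw`.
#'
#' @param ds Validated `study_dataset`.
#' @param covariates Standardized, imputed `covariate_table`, or `NULL`
#'   for a covariate-free fit (which reduces to the plain hierarchical
#'   quadratic model, `alpha0` playing the slope group mean).
#' @param prior A [prior_config()].
#' @param sampler A [sampler_config()].
#' @return A `slope_posterior`: `alpha` (draws x covariate matrix, positive
#'   = faster decline), `alpha_raw` (unflipped), `alpha0` draws, and the
#'   full `posterior_draws` under `draws`.
#' @export
fit_slope_regression <- function(ds, covariates = ds$covariates,
                                 prior = prior_config(),
                                 sampler = sampler_config()) {
  validate_dataset(ds)
  X <- NULL
  if (!is.null(covariates)) {
    if (!setequal(covariates$subject_ids, names(ds$series)))
      stop("covariate subject ids do not match the dataset", call. = FALSE)
    X <- covariates$values[names(ds$series), , drop = FALSE]
    if (anyNA(X))
      stop("covariates contain missing values; impute before fitting",
           call. = FALSE)
  }
  has_cov <- !is.null(X) && ncol(X) > 0
  data <- growth_data_list(ds, prior, "quadratic")
  if (has_cov) data$pr_alpha_tau <- prior$alpha_sd^-2
  if (has_cov) {
    data$X <- X
    data$K <- ncol(X)
  }
  inits <- list(sigma = 3, b0_mu = prior$b0_mean, b0_sd = 5, alpha0 = -0.5,
                b1_sd = 0.5, b2_mu = 0, b2_sd = 0.05)
  if (has_cov) inits$alpha_raw <- rep(0, ncol(X))
  monitors <- c("alpha0", if (has_cov) "alpha_raw", "b0_mu", "b0_sd",
                "b1_sd", "b2_mu", "b2_sd", "sigma", "b0", "b1", "b2")
  samples <- run_jags(jags_slope_model(has_cov), data, monitors, sampler,
                      inits)
  pd <- new_posterior_draws(samples, list(
    model = "slope_regression", family = "quadratic",
    subject_ids = names(ds$series), long = dataset_long(ds),
    prior = prior, sampler = sampler,
    covariate_names = if (has_cov) colnames(X) else character(0)))
  alpha_raw <- NULL
  if (has_cov) {
    alpha_raw <- vector_param_matrix(pd, "alpha_raw", ncol(X))
    colnames(alpha_raw) <- colnames(X)
  }
  structure(list(alpha = if (has_cov) -alpha_raw else NULL,
                 alpha_raw = alpha_raw,
                 alpha0 = draws_of(pd, "alpha0"),
                 draws = pd),
            class = "slope_posterior")
}

#' @export
print.slope_posterior <- function(x, ...) {
  cat("slope_posterior: quadratic model,",
      if (is.null(x$alpha)) 0 else ncol(x$alpha), "slope covariates\n")
  cat("  slope group mean (alpha0) posterior mean:",
      round(mean(x$alpha0), 3), "\n")
  invisible(x)
}
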