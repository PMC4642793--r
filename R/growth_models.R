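# Trajectory mean functions, hierarchical likelihoods, MCMC fits via JAGS,
# and predictive model selection among linear/quadratic/exponential families.

TRAJECTORY_FAMILIES <- c("linear", "quadratic", "exponential")

#' Weakly informative prior configuration
#'
#' Group-level means: baseline b0 ~ normal(20, 10^2) (keeps >95\% of prior
#' predictive baseline mass inside the 0-63 scale), exponential decay
#' lambda ~ normal(0.1, 0.2^2) truncated at 0, quadratic slope
#' b1 ~ normal(0, 2^2) and curvature b2 ~ normal(0, 0.5^2).  Group SDs and
#' the residual SD get half-normal(0, 5^2) priors on the BDI-II score
#' scale; the decay-rate group SD, whose natural unit is per-week rather
#' than score points, gets half-normal(0, 0.5^2) — still several times
#' wider than any plausible between-subject decay spread, but scaled to
#' the parameter so the group SD mixes well.  Class-membership
#' coefficients beta and slope-regression coefficients alpha are
#' normal(0, 1^2) on standardized covariates — the scale the Savage-Dickey
#' Bayes factors are computed against.
#'
#' @param ... Overrides for any element.
#' @return A named list of prior constants.
#' @export
prior_config <- function(...) {
  pr <- list(b0_mean = 20, b0_sd = 10,
             lambda_mean = 0.1, lambda_sd = 0.2,
             b1_mean = 0, b1_sd = 2,
             b2_mean = 0, b2_sd = 0.5,
             group_sd_scale = 5, lambda_group_sd_scale = 0.5,
             sigma_scale = 5, beta_sd = 1, alpha_sd = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(pr))
  if (length(unknown))
    stop("unknown prior setting: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pr[names(over)] <- over
  pr
}

#' MCMC sampler configuration
#'
#' @param chains Number of chains (>= 2).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Retained iterations per chain.
#' @param seed Integer seed; each chain gets a distinct RNG stream derived
#'   from it, making runs exactly reproducible.
#' @return A named list.
#' @export
sampler_config <- function(chains = 4, adapt = 500, warmup = 1000,
                           draws = 2000, seed = 1L) {
  if (chains < 2) stop("at least 2 chains required", call. = FALSE)
  list(chains = as.integer(chains), adapt = as.integer(adapt),
       warmup = as.integer(warmup), draws = as.integer(draws),
       seed = as.integer(seed))
}

#' Expected trajectory score
#'
#' Linear: b0 + b1 t; quadratic: b0 + b1 t + b2 t^2; exponential:
#' b0 exp(-lambda t) with lambda >= 0.
#'
#' @param family One of `"linear"`, `"quadratic"`, `"exponential"`.
#' @param params Named list with the family's parameters (`b0`, `b1`,
#'   `b2`, `lambda` as applicable).
#' @param t Weeks from baseline (nonnegative).
#' @return Expected score(s), vectorized over `t`.
#' @export
mean_trajectory <- function(family, params, t) {
  family <- match.arg(family, TRAJECTORY_FAMILIES)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  switch(family,
    linear = params$b0 + params$b1 * t,
    quadratic = params$b0 + params$b1 * t + params$b2 * t^2,
    exponential = {
      if (is.null(params$lambda) || params$lambda < 0)
        stop("exponential decay rate lambda must be >= 0", call. = FALSE)
      params$b0 * exp(-params$lambda * t)
    })
}

#' Observation-model log likelihood
#'
#' Sum over all observations of the normal log density of the score given
#' the subject's mean trajectory and common residual SD `sigma`.
#'
#' @param ds A `study_dataset`.
#' @param family Trajectory family.
#' @param params List with `sigma` (> 0) and `subjects`, a named list
#'   (by subject id) of per-subject parameter lists.
#' @return Scalar log likelihood (0 for an empty dataset).
#' @export
log_likelihood <- function(ds, family, params) {
  if (is.null(params$sigma) || params$sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  total <- 0
  for (s in ds$series) {
    sp <- params$subjects[[s$subject_id]]
    if (is.null(sp))
      stop("params missing subject ", s$subject_id, call. = FALSE)
    mu <- mean_trajectory(family, sp, s$times)
    total <- total + sum(dnorm(s$scores, mu, params$sigma, log = TRUE))
  }
  total
}

# ---- posterior_draws container ------------------------------------------

new_posterior_draws <- function(coda_samples, meta) {
  mats <- lapply(coda_samples, as.matrix)   # one iter x param matrix per chain
  params <- colnames(mats[[1]])
  draws <- lapply(params, function(p)
    vapply(mats, function(m) m[, p], numeric(nrow(mats[[1]]))))
  names(draws) <- params
  structure(list(draws = draws, meta = meta), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", length(x$draws), "parameters,",
      ncol(x$draws[[1]]), "chains x", nrow(x$draws[[1]]), "draws",
      if (!is.null(x$meta$family)) paste0("(", x$meta$family, " model)"),
      "\n")
  invisible(x)
}

#' Parameter names of a posterior draws object
#' @param pd A `posterior_draws`.
#' @return Character vector.
#' @export
param_names <- function(pd) names(pd$draws)

#' Extract draws for one parameter
#'
#' @param pd A `posterior_draws`.
#' @param param Parameter name (e.g. `"lambda_mu"`, `"b0[3]"`).
#' @param combine If `TRUE` (default) return all chains concatenated as a
#'   vector; otherwise an iterations x chains matrix.
#' @return Numeric vector or matrix.
#' @export
draws_of <- function(pd, param, combine = TRUE) {
  m <- pd$draws[[param]]
  if (is.null(m)) stop("unknown parameter: ", param, call. = FALSE)
  if (combine) as.vector(m) else m
}

# total-draws x N matrix of vector-valued parameters "base[i]"; JAGS/coda
# drop the index on length-1 vectors, so fall back to the bare name
vector_param_matrix <- function(pd, base, n) {
  cols <- sprintf("%s[%d]", base, seq_len(n))
  if (n == 1 && !cols %in% names(pd$draws) && base %in% names(pd$draws))
    cols <- base
  missing <- setdiff(cols, names(pd$draws))
  if (length(missing))
    stop("draws lack vector parameter ", base, call. = FALSE)
  do.call(cbind, lapply(cols, function(p) as.vector(pd$draws[[p]])))
}
subject_param_matrix <- vector_param_matrix

#' Tidy view of posterior draws
#' @param x A `posterior_draws`.
#' @param ... Unused.
#' @return Data frame with columns chain, draw, parameter, value.
#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  n_it <- nrow(x$draws[[1]])
  n_ch <- ncol(x$draws[[1]])
  do.call(rbind, lapply(names(x$draws), function(p)
    data.frame(chain = rep(seq_len(n_ch), each = n_it),
               draw = rep(seq_len(n_it), n_ch),
               parameter = p, value = as.vector(x$draws[[p]]),
               stringsAsFactors = FALSE)))
}

#' Export draws to a columnar CSV
#'
#' @param pd A `posterior_draws`.
#' @param path Output path.
#' @param params Optional subset of parameter names (default: all).
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(pd, path, params = NULL) {
  if (!is.null(params)) pd$draws <- pd$draws[params]
  df <- as.data.frame(pd)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- JAGS machinery ------------------------------------------------------

jags_growth_model <- function(family) {
  subject_block <- switch(family,
    linear = "
    b0[i] ~ dnorm(b0_mu, b0_tau)
    b1[i] ~ dnorm(b1_mu, b1_tau)",
    quadratic = "
    b0[i] ~ dnorm(b0_mu, b0_tau)
    b1[i] ~ dnorm(b1_mu, b1_tau)
    b2[i] ~ dnorm(b2_mu, b2_tau)",
    exponential = "
    b0[i] ~ dnorm(b0_mu, b0_tau)
    lambda[i] ~ dnorm(lambda_mu, lambda_tau) T(0,)")
  mu_expr <- switch(family,
    linear = "b0[subj[j]] + b1[subj[j]] * t[j]",
    quadratic =
      "b0[subj[j]] + b1[subj[j]] * t[j] + b2[subj[j]] * t[j] * t[j]",
    exponential = "b0[subj[j]] * exp(-lambda[subj[j]] * t[j])")
  group_block <- switch(family,
    linear = "
  b1_mu ~ dnorm(pr_b1_mean, pr_b1_tau)
  b1_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b1_tau <- pow(b1_sd, -2)",
    quadratic = "
  b1_mu ~ dnorm(pr_b1_mean, pr_b1_tau)
  b1_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b1_tau <- pow(b1_sd, -2)
  b2_mu ~ dnorm(pr_b2_mean, pr_b2_tau)
  b2_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b2_tau <- pow(b2_sd, -2)",
    exponential = "
  lambda_mu ~ dnorm(pr_lambda_mean, pr_lambda_tau) T(0,)
  lambda_sd ~ dnorm(0, pr_lam_gsd_tau) T(0,)
  lambda_tau <- pow(lambda_sd, -2)")
  paste0("model {
  for (j in 1:Nobs) {
    y[j] ~ dnorm(", mu_expr, ", y_tau)
  }
  for (i in 1:N) {", subject_block, "
  }
  b0_mu ~ dnorm(pr_b0_mean, pr_b0_tau)
  b0_sd ~ dnorm(0, pr_gsd_tau) T(0,)
  b0_tau <- pow(b0_sd, -2)", group_block, "
  sigma ~ dnorm(0, pr_sigma_tau) T(0,)
  y_tau <- pow(sigma, -2)
}")
}

# prior constants actually referenced by the model for `family`
prior_data <- function(prior, family) {
  out <- list(pr_b0_mean = prior$b0_mean, pr_b0_tau = prior$b0_sd^-2,
              pr_gsd_tau = prior$group_sd_scale^-2,
              pr_sigma_tau = prior$sigma_scale^-2)
  if (family == "exponential") {
    out$pr_lambda_mean <- prior$lambda_mean
    out$pr_lambda_tau <- prior$lambda_sd^-2
    out$pr_lam_gsd_tau <- prior$lambda_group_sd_scale^-2
  } else {
    out$pr_b1_mean <- prior$b1_mean
    out$pr_b1_tau <- prior$b1_sd^-2
    if (family == "quadratic") {
      out$pr_b2_mean <- prior$b2_mean
      out$pr_b2_tau <- prior$b2_sd^-2
    }
  }
  out
}

chain_inits <- function(sampler, extra = list()) {
  lapply(seq_len(sampler$chains), function(ch)
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = sampler$seed * 100L + ch),
      extra))
}

run_jags <- function(model_string, data, monitors, sampler, inits_extra) {
  fit <- tryCatch({
    jm <- rjags::jags.model(textConnection(model_string), data = data,
                            inits = chain_inits(sampler, inits_extra),
                            n.chains = sampler$chains,
                            n.adapt = sampler$adapt, quiet = TRUE)
    if (sampler$warmup > 0)
      stats::update(jm, sampler$warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = sampler$draws,
                        progress.bar = "none")
  }, error = function(e)
    stop("fit error: MCMC sampling failed (", conditionMessage(e), ")",
         call. = FALSE))
  if (any(vapply(fit, function(m) any(!is.finite(as.matrix(m))),
                 logical(1))))
    stop("fit error: non-finite values in posterior draws", call. = FALSE)
  fit
}

growth_data_list <- function(ds, prior, family) {
  long <- dataset_long(ds)
  c(list(y = long$y, t = long$t, subj = long$subj, Nobs = nrow(long),
         N = length(ds$series)), prior_data(prior, family))
}

growth_inits <- function(family, prior) {
  base <- list(sigma = 3, b0_mu = prior$b0_mean, b0_sd = 5)
  switch(family,
    linear = c(base, list(b1_mu = 0, b1_sd = 1)),
    quadratic = c(base, list(b1_mu = 0, b1_sd = 1, b2_mu = 0, b2_sd = 0.1)),
    exponential = c(base, list(lambda_mu = prior$lambda_mean,
                               lambda_sd = 0.05)))
}

growth_monitors <- function(family) {
  switch(family,
    linear = c("b0_mu", "b0_sd", "b1_mu", "b1_sd", "sigma", "b0", "b1"),
    quadratic = c("b0_mu", "b0_sd", "b1_mu", "b1_sd", "b2_mu", "b2_sd",
                  "sigma", "b0", "b1", "b2"),
    exponential = c("b0_mu", "b0_sd", "lambda_mu", "lambda_sd", "sigma",
                    "b0", "lambda"))
}

#' Fit a single-population hierarchical growth model
#'
#' Subject-level trajectory coefficients are constrained by group-level
#' normal distributions; the observation model is normal with a common
#' residual SD.  Sampled with JAGS; two runs with identical seed and
#' sampler settings return identical draws.  Convergence is not asserted
#' here — see [convergence_report()].
#'
#' @param ds Validated `study_dataset`.
#' @param family Trajectory family.
#' @param prior A [prior_config()].
#' @param sampler A [sampler_config()].
#' @return A `posterior_draws` object carrying subject-level and
#'   group-level parameters, `sigma`, and fit metadata.
#' @export
fit_hierarchical <- function(ds, family, prior = prior_config(),
                             sampler = sampler_config()) {
  family <- match.arg(family, TRAJECTORY_FAMILIES)
  validate_dataset(ds)
  model <- jags_growth_model(family)
  samples <- run_jags(model, growth_data_list(ds, prior, family),
                      growth_monitors(family), sampler,
                      growth_inits(family, prior))
  new_posterior_draws(samples, list(
    model = "hierarchical_growth", family = family,
    subject_ids = names(ds$series), long = dataset_long(ds),
    prior = prior, sampler = sampler))
}

# S x J matrix of pointwise log likelihoods from subject-level draws.
pointwise_log_lik <- function(pd) {
  long <- pd$meta$long
  n <- length(pd$meta$subject_ids)
  family <- pd$meta$family
  sigma <- as.vector(pd$draws[["sigma"]])
  b0 <- subject_param_matrix(pd, "b0", n)
  mu_fun <- switch(family,
    linear = {
      b1 <- subject_param_matrix(pd, "b1", n)
      function(j) b0[, long$subj[j]] + b1[, long$subj[j]] * long$t[j]
    },
    quadratic = {
      b1 <- subject_param_matrix(pd, "b1", n)
      b2 <- subject_param_matrix(pd, "b2", n)
      function(j) b0[, long$subj[j]] + b1[, long$subj[j]] * long$t[j] +
        b2[, long$subj[j]] * long$t[j]^2
    },
    exponential = {
      lam <- subject_param_matrix(pd, "lambda", n)
      function(j) b0[, long$subj[j]] * exp(-lam[, long$subj[j]] * long$t[j])
    })
  ll <- matrix(NA_real_, length(sigma), nrow(long))
  for (j in seq_len(nrow(long)))
    ll[, j] <- dnorm(long$y[j], mu_fun(j), sigma, log = TRUE)
  ll
}

# WAIC from an S x J pointwise log-likelihood matrix.
waic_from_loglik <- function(ll) {
  S <- nrow(ll)
  lppd_j <- apply(ll, 2, function(col) {
    m <- max(col)
    m + log(mean(exp(col - m)))
  })
  p_j <- apply(ll, 2, var)
  elpd_j <- lppd_j - p_j
  list(elpd = sum(elpd_j), p_eff = sum(p_j),
       waic = -2 * sum(elpd_j),
       se_elpd = sqrt(length(elpd_j) * var(elpd_j)))
}

#' Rank trajectory families by out-of-sample predictive fit
#'
#' Fits each family with [fit_hierarchical()] and scores it with WAIC
#' (widely applicable information criterion) computed from the posterior
#' draws: elpd = sum_j \[log mean_s p(y_j | theta_s) - var_s log p(y_j |
#' theta_s)\]; larger elpd (smaller WAIC) is better.  A failed fit leaves a
#' row with `status` noting the failure.
#'
#' @param ds Validated `study_dataset`.
#' @param families At least two of the trajectory families.
#' @param prior,sampler Passed to [fit_hierarchical()].
#' @return Data frame (family, elpd, se_elpd, p_eff, waic, rank, status),
#'   best family first, with a `criterion` attribute documenting the score.
#' @export
select_family <- function(ds, families = TRAJECTORY_FAMILIES,
                          prior = prior_config(),
                          sampler = sampler_config()) {
  families <- match.arg(families, TRAJECTORY_FAMILIES, several.ok = TRUE)
  if (length(families) < 2)
    stop(">=2 families required for model selection", call. = FALSE)
  rows <- lapply(families, function(fam) {
    res <- tryCatch({
      pd <- fit_hierarchical(ds, fam, prior, sampler)
      w <- waic_from_loglik(pointwise_log_lik(pd))
      data.frame(family = fam, elpd = w$elpd, se_elpd = w$se_elpd,
                 p_eff = w$p_eff, waic = w$waic, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(family = fam, elpd = NA_real_, se_elpd = NA_real_,
                 p_eff = NA_real_, waic = NA_real_,
                 status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$elpd, na.last = TRUE), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "criterion") <- paste(
    "WAIC: waic = -2 * (lppd - p_waic), lppd = sum_j log mean_s",
    "p(y_j|theta_s), p_waic = sum_j var_s log p(y_j|theta_s);",
    "families ranked by elpd = lppd - p_waic (higher is better)")
  tab
}
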