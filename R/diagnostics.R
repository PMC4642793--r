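# Convergence diagnostics (split-chain Gelman-Rubin) and posterior
# predictive checks for fitted growth models.

# accept a posterior_draws directly or any fit object carrying one
as_posterior_draws <- function(x) {
  if (inherits(x, "posterior_draws")) return(x)
  if (is.list(x) && inherits(x$draws, "posterior_draws")) return(x$draws)
  stop("expected a posterior_draws object or a fit carrying one",
       call. = FALSE)
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' sqrt(((n - 1)/n W + B/n) / W) with W the mean within-half-chain variance
#' and B the between-half-chain variance of the means, n the half-chain
#' length.  Values near 1 indicate convergence.
#'
#' @param chains Iterations x chains numeric matrix (or list of equal
#'   length vectors); at least 2 chains of at least 10 draws.
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2)
    stop("at least 2 chains required", call. = FALSE)
  if (nrow(chains) < 10)
    stop("at least 10 draws per chain required", call. = FALSE)
  n_half <- floor(nrow(chains) / 2)
  halves <- cbind(chains[seq_len(n_half), , drop = FALSE],
                  chains[seq(nrow(chains) - n_half + 1, nrow(chains)),
                         , drop = FALSE])
  n <- nrow(halves)
  w <- mean(apply(halves, 2, var))
  if (w < .Machine$double.eps) return(1)   # all chains constant
  b <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence report for a fitted model
#'
#' Computes split-chain R-hat and effective sample size for each requested
#' parameter and flags the fit as passing when every R-hat is below the
#' threshold (default 1.05).
#'
#' @param pd A `posterior_draws`.
#' @param params Parameters to check; defaults to all group-level ones —
#'   unindexed parameters (group means/SDs, sigma, intercepts) plus the
#'   covariate coefficient vectors `beta` and `alpha_raw`.
#' @param threshold R-hat pass threshold.
#' @return Data frame (parameter, rhat, ess, pass) with attribute `pass`
#'   (overall flag) and `threshold`.
#' @export
convergence_report <- function(pd, params = NULL, threshold = 1.05) {
  pd <- as_posterior_draws(pd)
  if (is.null(params))
    params <- grep("\\[|^(beta|alpha_raw)(\\[|$)", param_names(pd),
                   value = TRUE, invert = TRUE) |>
      c(grep("^(beta|alpha_raw)(\\[|$)", param_names(pd), value = TRUE))
  rows <- lapply(params, function(p) {
    m <- draws_of(pd, p, combine = FALSE)
    data.frame(parameter = p,
               rhat = gelman_rubin(m),
               ess = as.numeric(coda::effectiveSize(coda::mcmc(m))["var1"]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # a discrete indicator stuck at one value gives var 0; ESS is undefined
  tab$ess <- ifelse(is.finite(tab$ess), tab$ess, NA_real_)
  tab$pass <- tab$rhat < threshold
  attr(tab, "pass") <- all(tab$pass)
  attr(tab, "threshold") <- threshold
  tab
}

# expected trajectory matrix (draws x observations) for the fit's family
ppc_mean_matrix <- function(pd) {
  long <- pd$meta$long
  n <- length(pd$meta$subject_ids)
  b0 <- subject_param_matrix(pd, "b0", n)
  if (pd$meta$family == "exponential") {
    lam <- subject_param_matrix(pd, "lambda", n)
    mu <- b0[, long$subj, drop = FALSE] *
      exp(-lam[, long$subj, drop = FALSE] *
            matrix(long$t, nrow(b0), nrow(long), byrow = TRUE))
  } else {
    b1 <- subject_param_matrix(pd, "b1", n)
    b2 <- if (pd$meta$family == "quadratic")
      subject_param_matrix(pd, "b2", n) else NULL
    tmat <- matrix(long$t, nrow(b0), nrow(long), byrow = TRUE)
    mu <- b0[, long$subj, drop = FALSE] +
      b1[, long$subj, drop = FALSE] * tmat
    if (!is.null(b2)) mu <- mu + b2[, long$subj, drop = FALSE] * tmat^2
  }
  mu
}

#' Posterior predictive check
#'
#' Simulates `n_rep` replicated datasets from the normal observation model
#' at randomly sampled posterior draws, on the observed time grids.
#' Because visit times are irregular, observations are binned to integer
#' weeks (`floor(t)`); per bin the observed mean and SD are compared to the
#' replicated envelope (2.5\%, 50\%, 97.5\% quantiles), with a lower tail
#' probability P(replicated <= observed) for each summary.
#'
#' @param ds The `study_dataset` the model was fitted to.
#' @param pd The fit's `posterior_draws` (must carry subject-level
#'   parameters).
#' @param n_rep Number of replicated datasets (error if 0; warning below
#'   50).
#' @param seed Optional integer seed for the replication RNG.
#' @return A `ppc_report` data frame: bin, n_obs, observed and replicated
#'   mean/SD summaries, and tail probabilities.  Attribute
#'   `mean_within_envelope` gives the fraction of bins whose observed mean
#'   lies inside the 95\% envelope.
#' @export
posterior_predictive <- function(ds, pd, n_rep = 200, seed = NULL) {
  pd <- as_posterior_draws(pd)
  if (n_rep == 0) stop("n_rep must be positive", call. = FALSE)
  if (n_rep < 50) warning("n_rep < 50 gives a coarse envelope",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  long <- pd$meta$long
  if (nrow(long) != nrow(dataset_long(ds)) ||
      any(abs(long$y - dataset_long(ds)$y) > 0))
    stop("fitted model does not match dataset", call. = FALSE)
  mu <- ppc_mean_matrix(pd)
  sigma <- as.vector(pd$draws[["sigma"]])
  idx <- sample.int(nrow(mu), n_rep, replace = n_rep > nrow(mu))
  bins <- floor(long$t)
  bin_levels <- sort(unique(bins))
  rep_means <- matrix(NA_real_, n_rep, length(bin_levels))
  rep_sds <- matrix(NA_real_, n_rep, length(bin_levels))
  for (r in seq_len(n_rep)) {
    y_rep <- mu[idx[r], ] + rnorm(ncol(mu), 0, sigma[idx[r]])
    rep_means[r, ] <- tapply(y_rep, bins, mean)[as.character(bin_levels)]
    rep_sds[r, ] <- tapply(y_rep, bins, sd)[as.character(bin_levels)]
  }
  obs_mean <- tapply(long$y, bins, mean)[as.character(bin_levels)]
  obs_sd <- tapply(long$y, bins, sd)[as.character(bin_levels)]
  q <- function(m, p) apply(m, 2, quantile, probs = p, na.rm = TRUE)
  tab <- data.frame(
    bin = bin_levels,
    n_obs = as.vector(table(bins)[as.character(bin_levels)]),
    obs_mean = as.vector(obs_mean), obs_sd = as.vector(obs_sd),
    mean_q025 = q(rep_means, 0.025), mean_q50 = q(rep_means, 0.5),
    mean_q975 = q(rep_means, 0.975),
    sd_q025 = q(rep_sds, 0.025), sd_q50 = q(rep_sds, 0.5),
    sd_q975 = q(rep_sds, 0.975),
    tail_prob_mean = vapply(seq_along(bin_levels), function(j)
      mean(rep_means[, j] <= obs_mean[j]), numeric(1)),
    tail_prob_sd = vapply(seq_along(bin_levels), function(j)
      mean(rep_sds[, j] <= obs_sd[j], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("ppc_report", "data.frame")
  attr(tab, "mean_within_envelope") <-
    mean(tab$obs_mean >= tab$mean_q025 & tab$obs_mean <= tab$mean_q975)
  tab
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("ppc_report:", nrow(x), "week bins; observed mean inside 95%",
      "envelope in", round(100 * attr(x, "mean_within_envelope")), "% of",
      "bins\n")
  print(as.data.frame(x)[, c("bin", "n_obs", "obs_mean", "mean_q025",
                             "mean_q975", "tail_prob_mean")], ...)
  invisible(x)
}
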