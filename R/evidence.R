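# Posterior evidence summaries: smoothed-density modes, highest-density
# intervals, directional odds ratios, Savage-Dickey Bayes factors and
# Jeffreys evidence categories.

# Deterministic kernel density estimate shared by posterior_mode() and
# savage_dickey_bf10(): Gaussian kernel, Silverman's bandwidth rule
# (stats::bw.nrd0), fixed 1024-point grid over the draw range extended by
# three bandwidths.
evidence_density <- function(draws) {
  density(draws, bw = "nrd0", kernel = "gaussian", n = 1024, cut = 3)
}

#' Posterior mode from draws
#'
#' Argmax of a smoothed (Gaussian-kernel, Silverman bandwidth, 1024-point
#' grid) density estimate over the draw range; deterministic given draws.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(draws) {
  if (length(draws) < 100)
    stop("at least 100 draws required for a mode estimate", call. = FALSE)
  if (diff(range(draws)) < .Machine$double.eps) return(draws[1])
  d <- evidence_density(draws)
  d$x[which.max(d$y)]
}

#' Highest-density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 100)
    stop("at least 100 draws required for an HDI", call. = FALSE)
  if (mass <= 0 || mass >= 1)
    stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- min(n, ceiling(mass * n))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- starts[which.min(widths)]
  c(x[i], x[i + m - 1])
}

#' Directional odds ratio of a signed coefficient
#'
#' p+ is the fraction of draws above zero (draws exactly at zero count half
#' to each side), p- = 1 - p+.  The odds ratio is max(p+, p-)/min(p+, p-)
#' with the minority side floored at 1/(2n) to keep the ratio finite; a
#' floored ratio is flagged `saturated`.  The sign is the majority side.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @return List: `or_value` (>= 1), `or_sign` (`"+"`, `"-"` or `"tie"`),
#'   `saturated` (logical).
#' @export
directional_odds <- function(draws) {
  if (length(draws) < 100)
    stop("at least 100 draws required", call. = FALSE)
  n <- length(draws)
  p_pos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / n
  p_neg <- 1 - p_pos
  floor_p <- 1 / (2 * n)
  saturated <- min(p_pos, p_neg) < floor_p
  p_pos_f <- max(p_pos, floor_p)
  p_neg_f <- max(p_neg, floor_p)
  sign <- if (p_pos == p_neg) "tie" else if (p_pos > p_neg) "+" else "-"
  list(or_value = max(p_pos_f, p_neg_f) / min(p_pos_f, p_neg_f),
       or_sign = sign, saturated = saturated)
}

#' Savage-Dickey Bayes factor for a point null at zero
#'
#' BF10 = prior density at 0 / posterior density at 0.  Valid for a nested
#' point null (coefficient = 0) when `prior_density_at_zero` comes from
#' the fit's analytic prior (e.g. dnorm(0, 0, 1) for the standard-normal
#' coefficient priors).
#'
#' The posterior density at zero is taken from the same deterministic
#' kernel estimator as [posterior_mode()] while zero lies in the central
#' posterior mass (|mean| <= 2 SD of the draws).  When zero sits further
#' out in the tail, kernel estimates there are dominated by Monte-Carlo
#' noise (few draws fall near zero), so a moment-matched normal
#' approximation dnorm(0, mean, sd) is used instead — the regime where
#' coefficient posteriors from these models are closest to normal anyway.
#' The estimate is deterministic given the draws; the method used is
#' returned in `attr(, "method")`.
#'
#' If even the floored density at zero is 0 (zero far outside the draw
#' range), a floor of 1/(range * n) is applied and the returned value
#' carries `attr(, "saturated") = TRUE`: a lower bound on the true Bayes
#' factor.
#'
#' @param draws Numeric vector of at least 1000 posterior draws.
#' @param prior_density_at_zero Positive scalar.
#' @return Positive scalar BF10 (with `method`, possibly `saturated`,
#'   attributes).
#' @export
savage_dickey_bf10 <- function(draws, prior_density_at_zero) {
  if (length(draws) < 1000)
    stop("at least 1000 draws required for a Savage-Dickey estimate",
         call. = FALSE)
  if (prior_density_at_zero <= 0)
    stop("prior density at zero must be positive", call. = FALSE)
  m <- mean(draws)
  s <- sd(draws)
  saturated <- FALSE
  if (s < .Machine$double.eps) {
    # all draws identical: density is a spike; report a saturated bound
    post0 <- if (abs(m) < .Machine$double.eps) length(draws) else 0
    saturated <- TRUE
    method <- "degenerate"
  } else if (abs(m) / s <= 2) {
    d <- evidence_density(draws)
    post0 <- approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
    method <- "kernel"
  } else {
    post0 <- dnorm(0, m, s)
    method <- "normal-tail"
  }
  if (!is.finite(post0) || post0 <= 0) {
    post0 <- 1 / (max(diff(range(draws)), .Machine$double.eps) *
                    length(draws))
    saturated <- TRUE
  }
  bf <- prior_density_at_zero / post0
  attr(bf, "method") <- method
  if (saturated) attr(bf, "saturated") <- TRUE
  bf
}

#' Jeffreys evidence category for a Bayes factor
#'
#' Maps BF10 to the conventional verbal grades: >100 decisive, 30-100 very
#' strong, 10-30 strong, 3-10 substantial, 1-3 anecdotal evidence for H1;
#' exactly 1 no evidence; and the reciprocal bands for H0.  Boundary values
#' (exactly 3, 10, 30, 100 and their reciprocals) are assigned to the
#' stronger category.
#'
#' @param bf10 Positive scalar.
#' @return Character label, e.g. `"substantial evidence for H1"`.
#' @export
jeffreys_category <- function(bf10) {
  if (!is.numeric(bf10) || is.na(bf10))
    stop("bf10 must be a number", call. = FALSE)
  if (bf10 <= 0) stop("bf10 must be > 0", call. = FALSE)
  if (bf10 >= 100) return("decisive evidence for H1")
  if (bf10 >= 30) return("very strong evidence for H1")
  if (bf10 >= 10) return("strong evidence for H1")
  if (bf10 >= 3) return("substantial evidence for H1")
  if (bf10 > 1) return("anecdotal evidence for H1")
  if (bf10 == 1) return("no evidence")
  if (bf10 <= 1 / 100) return("decisive evidence for H0")
  if (bf10 <= 1 / 30) return("very strong evidence for H0")
  if (bf10 <= 1 / 10) return("strong evidence for H0")
  if (bf10 <= 1 / 3) return("substantial evidence for H0")
  "anecdotal evidence for H0"
}

#' Assemble a per-covariate evidence table
#'
#' One row per covariate: smoothed posterior mode, HDI, directional odds
#' ratio with sign, and (optionally) Savage-Dickey BF10 with its Jeffreys
#' category.  Without Bayes factors the rows are sorted by posterior mode
#' ascending; with them, by BF10 ascending.
#'
#' @param draws_by_cov Named list (or draws x covariate matrix) of
#'   coefficient draws.
#' @param prior_density_at_zero Prior density of each coefficient at 0
#'   (scalar, from the fit's prior config); required when
#'   `include_bf = TRUE`.
#' @param include_bf Add BF10 and category columns?
#' @param mass HDI mass.
#' @return Data frame: name, mode, hdi_low, hdi_high, or_value, or_sign,
#'   or_saturated, and optionally bf10, bf10_saturated, category.
#' @export
evidence_table <- function(draws_by_cov, prior_density_at_zero = NULL,
                           include_bf = FALSE, mass = 0.95) {
  if (is.matrix(draws_by_cov))
    draws_by_cov <- setNames(
      lapply(seq_len(ncol(draws_by_cov)), function(k) draws_by_cov[, k]),
      colnames(draws_by_cov))
  if (include_bf && is.null(prior_density_at_zero))
    stop("prior_density_at_zero required when include_bf = TRUE",
         call. = FALSE)
  lens <- vapply(draws_by_cov, length, integer(1))
  if (length(unique(lens)) > 1)
    stop("all covariates must have the same number of draws",
         call. = FALSE)
  rows <- lapply(names(draws_by_cov), function(nm) {
    dr <- draws_by_cov[[nm]]
    h <- hdi(dr, mass)
    od <- directional_odds(dr)
    row <- data.frame(name = nm, mode = posterior_mode(dr),
                      hdi_low = h[1], hdi_high = h[2],
                      or_value = od$or_value, or_sign = od$or_sign,
                      or_saturated = od$saturated,
                      stringsAsFactors = FALSE)
    if (include_bf) {
      bf <- savage_dickey_bf10(dr, prior_density_at_zero)
      row$bf10 <- as.numeric(bf)
      row$bf10_saturated <- isTRUE(attr(bf, "saturated"))
      row$category <- jeffreys_category(as.numeric(bf))
    }
    row
  })
  tab <- do.call(rbind, rows)
  tab <- if (include_bf) tab[order(tab$bf10), ]
         else tab[order(tab$mode), ]
  rownames(tab) <- NULL
  tab
}

#' Write an evidence table to CSV
#'
#' Numeric columns are written twice: a 4-significant-figure display
#' column and a full-precision companion (suffix `_full`), so the table
#' can be both read by humans and round-tripped exactly.
#'
#' @param tab Data frame from [evidence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_csv <- function(tab, path) {
  out <- tab
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  for (k in num) {
    out[[paste0(k, "_full")]] <- format(tab[[k]], digits = 17,
                                        trim = TRUE, scientific = FALSE)
    out[[k]] <- signif(tab[[k]], 4)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an evidence table written by [write_evidence_csv()]
#'
#' Restores full-precision numeric columns from their `_full` companions.
#'
#' @param path CSV path.
#' @return Data frame with the original [evidence_table()] columns.
#' @export
read_evidence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  full <- grep("_full$", names(df), value = TRUE)
  for (k in full) df[[sub("_full$", "", k)]] <- as.numeric(df[[k]])
  df[setdiff(names(df), full)]
}
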