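# Evidence summaries: modes, HDIs, odds ratios, Bayes factors, categories.

test_that("posterior mode finds the density peak", {
  set.seed(101)
  draws <- rnorm(50000, 0.83, 0.1)
  expect_lt(abs(posterior_mode(draws) - 0.83), 0.05)
  # symmetric unimodal: mode ~ mean
  draws2 <- rnorm(20000, -1.4, 0.6)
  expect_lt(abs(posterior_mode(draws2) - mean(draws2)), 0.08)
  expect_equal(posterior_mode(rep(2.5, 500)), 2.5)
  expect_error(posterior_mode(rnorm(50)), "at least 100")
})

test_that("hdi matches analytic quantiles and exhausts tiny samples", {
  set.seed(102)
  z <- rnorm(100000)
  h <- hdi(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  u <- runif(100000)
  expect_lt(abs(diff(hdi(u, 0.95)) - 0.95), 0.02)
  x <- rnorm(100)
  expect_equal(hdi(x, 0.9999), range(x))
  expect_error(hdi(z, 1.2), "mass")
})

test_that("hdi is never wider than the equal-tailed interval", {
  set.seed(103)
  for (rep in 1:10) {
    draws <- switch(1 + rep %% 3,
                    rnorm(5000), rexp(5000), rbeta(5000, 2, 8))
    for (mass in c(0.5, 0.9, 0.95)) {
      eq <- quantile(draws, c((1 - mass) / 2, 1 - (1 - mass) / 2))
      expect_lte(diff(hdi(draws, mass)), unname(diff(eq)) + 1e-12)
    }
  }
  # symmetric unimodal: the two intervals agree
  z <- rnorm(100000)
  expect_equal(hdi(z, 0.95),
               unname(quantile(z, c(0.025, 0.975))), tolerance = 0.03)
})

test_that("directional odds equal a literal counting oracle", {
  oracle <- function(x) {
    n <- length(x)
    pos <- sum(x > 0) + 0.5 * sum(x == 0)
    p <- max(pos / n, 1 / (2 * n))
    q <- max(1 - pos / n, 1 / (2 * n))
    list(or = max(p, q) / min(p, q),
         sign = if (pos == n - pos) "tie" else if (pos > n - pos) "+"
                else "-")
  }
  expect_equal(directional_odds(c(rep(-1:-3, 40), rep(1, 40)))$or_value, 3)
  expect_equal(directional_odds(c(rep(-1, 60), rep(1, 60)))$or_sign, "tie")
  set.seed(104)
  for (rep in 1:200) {
    x <- round(rnorm(sample(c(100, 250, 1000), 1),
                     mean = runif(1, -2, 2)), 2)
    got <- directional_odds(x)
    want <- oracle(x)
    expect_identical(got$or_sign, want$sign)
    expect_equal(got$or_value, want$or, tolerance = 1e-12)
  }
  # one-sided sample saturates at the floor
  sat <- directional_odds(abs(rnorm(500)) + 0.01)
  expect_true(sat$saturated)
  expect_equal(sat$or_value, 500 / 0.5)
})

test_that("directional odds reproduce a majority-count example", {
  set.seed(105)
  x <- c(-abs(rnorm(9357)), abs(rnorm(643)))  # 93.57% negative
  od <- directional_odds(x)
  expect_equal(od$or_sign, "-")
  expect_equal(od$or_value, 0.9357 / 0.0643, tolerance = 1e-9)
})

test_that("Savage-Dickey BF matches the closed-form normal-normal ratio", {
  prior0 <- dnorm(0, 0, 1)
  set.seed(106)
  # posterior = prior: no-data identity, BF ~ 1
  expect_lt(abs(as.numeric(savage_dickey_bf10(rnorm(50000), prior0)) - 1),
            0.1)
  # concentrated null-centred posterior
  bf <- as.numeric(savage_dickey_bf10(rnorm(50000, 0, 0.25), prior0))
  expect_lt(abs(bf - prior0 / dnorm(0, 0, 0.25)) / 0.25, 0.1)
  # decisive: posterior far from the null
  bf2 <- as.numeric(savage_dickey_bf10(rnorm(50000, 2, 0.5), prior0))
  expect_lt(abs(bf2 - prior0 / dnorm(0, 2, 0.5)) /
              (prior0 / dnorm(0, 2, 0.5)), 0.25)
  expect_gt(bf2, 100)
  expect_error(savage_dickey_bf10(rnorm(500), prior0), "1000")
})

test_that("Jeffreys categories reproduce the conventional table", {
  expect_equal(jeffreys_category(3.24), "substantial evidence for H1")
  expect_equal(jeffreys_category(0.15), "substantial evidence for H0")
  expect_equal(jeffreys_category(1), "no evidence")
  expect_equal(jeffreys_category(150), "decisive evidence for H1")
  expect_equal(jeffreys_category(45), "very strong evidence for H1")
  expect_equal(jeffreys_category(12), "strong evidence for H1")
  expect_equal(jeffreys_category(2), "anecdotal evidence for H1")
  expect_equal(jeffreys_category(0.5), "anecdotal evidence for H0")
  expect_equal(jeffreys_category(0.05), "strong evidence for H0")
  expect_equal(jeffreys_category(0.02), "very strong evidence for H0")
  expect_equal(jeffreys_category(0.005), "decisive evidence for H0")
  # boundaries go to the stronger side
  expect_equal(jeffreys_category(3), "substantial evidence for H1")
  expect_equal(jeffreys_category(1 / 3), "substantial evidence for H0")
  expect_error(jeffreys_category(0), "> 0")
})

test_that("Jeffreys mapping is total and monotone in evidence strength", {
  grid <- 10^seq(-3, 3, length.out = 200)
  labels <- vapply(grid, jeffreys_category, character(1))
  strength <- c("decisive evidence for H0" = -5,
                "very strong evidence for H0" = -4,
                "strong evidence for H0" = -3,
                "substantial evidence for H0" = -2,
                "anecdotal evidence for H0" = -1,
                "no evidence" = 0,
                "anecdotal evidence for H1" = 1,
                "substantial evidence for H1" = 2,
                "strong evidence for H1" = 3,
                "very strong evidence for H1" = 4,
                "decisive evidence for H1" = 5)
  expect_true(all(labels %in% names(strength)))
  expect_true(all(diff(strength[labels]) >= 0))
})

test_that("evidence tables assemble, sort and round-trip", {
  set.seed(107)
  draws <- cbind(a = rnorm(2000, 1, 0.3), b = rnorm(2000, -0.5, 0.3),
                 c = rnorm(2000, 0.2, 0.3))
  tab <- evidence_table(draws)
  expect_equal(tab$name, c("b", "c", "a"))     # mode ascending
  tab_bf <- evidence_table(draws, prior_density_at_zero = dnorm(0),
                           include_bf = TRUE)
  expect_equal(tab_bf$name[order(tab_bf$bf10)], tab_bf$name)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence_csv(tab_bf, path)
  back <- read_evidence_csv(path)
  expect_equal(back$mode, tab_bf$mode, tolerance = 1e-15)
  expect_equal(back$bf10, tab_bf$bf10, tolerance = 1e-15)
  expect_identical(back$category, tab_bf$category)

  # constant-zero draws: tie sign, saturated-low BF
  tab0 <- evidence_table(list(zero = rep(0, 2000)),
                         prior_density_at_zero = dnorm(0),
                         include_bf = TRUE)
  expect_equal(tab0$mode, 0)
  expect_equal(tab0$or_sign, "tie")
  expect_true(tab0$bf10_saturated)
  expect_lt(tab0$bf10, 0.01)
})
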