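# Generator behaviour: schedules, covariate marginals, class assignment,
# trajectory shapes, determinism, and class separability.

test_that("schedules respect the duration truncation and dropout limits", {
  cfg <- generator_config(n_subjects = 40, seed = 2,
                          duration_range = c(5, 5), max_occasions = 6,
                          covariate_spec = test_cov_spec())
  set.seed(2)
  sch <- sample_schedule(cfg)
  expect_true(all(abs(sapply(sch, max) - 5) < 1e-9))
  expect_true(all(sapply(sch, function(t) t[1] == 0)))
  expect_true(all(sapply(sch, function(t) all(diff(t) > 0))))

  cfg2 <- generator_config(n_subjects = 30, seed = 3, dropout_hazard = 1,
                           covariate_spec = test_cov_spec())
  set.seed(3)
  expect_true(all(lengths(sample_schedule(cfg2)) == 2))
})

test_that("default schedule spans match the truncated-normal mean", {
  # truncated normal(9.6, 4.8) on [1, 22] has mean ~9.64; Monte-Carlo
  # band for 82 subjects
  cfg <- generator_config(seed = 4)
  set.seed(4)
  spans <- sapply(sample_schedule(cfg), max)
  expect_gt(mean(spans), 8.3)
  expect_lt(mean(spans), 10.9)
  expect_true(all(lengths(sample_schedule(cfg)) <= cfg$max_occasions))
})

test_that("covariate sampling matches the configured marginals", {
  spec <- list(allon = list(kind = "binary", p = 1, missing = 0),
               female = list(kind = "binary", p = 0.73, missing = 0),
               x = list(kind = "continuous", mean = 0, sd = 1,
                        missing = 0.1))
  cfg <- generator_config(n_subjects = 1000, seed = 5,
                          covariate_spec = spec, true_beta = c(x = 0),
                          true_alpha = c(x = 0))
  set.seed(5)
  ct <- sample_covariates(cfg)
  expect_true(all(ct$values[, "allon"] == 1))
  miss <- mean(is.na(ct$values[, "x"]))
  expect_gt(miss, 0.07)
  expect_lt(miss, 0.13)
  p_female <- mean(ct$values[, "female"])
  expect_lt(abs(p_female - 0.73), 3 * sqrt(0.73 * 0.27 / 1000))
  bad <- cfg
  bad$covariate_spec$female$p <- 1.4
  expect_error(validate_generator_config(bad), "outside \\[0, 1\\]")
})

test_that("class assignment follows the logistic model", {
  n <- 5000
  ct <- covariate_table(paste0("s", 1:n),
                        matrix(rep(c(0, 1), length.out = n), n, 1,
                               dimnames = list(NULL, "carrier")),
                        c(carrier = "binary"))
  cfg0 <- generator_config(n_subjects = n, seed = 6,
                           responder_intercept = 0, true_beta = c(),
                           true_alpha = c(), covariate_spec = list())
  set.seed(6)
  cls <- assign_classes(ct, cfg0)
  expect_lt(abs(mean(cls$labels == "responder") - 0.5),
            3 * sqrt(0.25 / n))

  cfg_ln3 <- generator_config(n_subjects = n, seed = 6,
                              responder_intercept = log(3),
                              true_beta = c(), true_alpha = c(),
                              covariate_spec = list())
  set.seed(6)
  expect_equal(unique(assign_classes(ct, cfg_ln3)$prob), 0.75,
               tolerance = 1e-12)

  cfg_sat <- generator_config(n_subjects = n, seed = 6,
                              responder_intercept = 0,
                              true_beta = c(carrier = 20),
                              true_alpha = c(), covariate_spec = list())
  set.seed(6)
  cls_sat <- assign_classes(ct, cfg_sat)
  expect_true(all(cls_sat$labels[ct$values[, "carrier"] == 1] ==
                    "responder"))

  ct$values[3, 1] <- NA
  expect_error(assign_classes(ct, cfg_sat), "impute")
})

test_that("generated responder fraction matches the logistic expectation", {
  cfg <- separated_config(n = 5000, seed = 7, intercept = log(3))
  cohort <- generate_cohort(cfg)
  frac <- mean(cohort$truth$class == "responder")
  expected <- mean(cohort$truth$p_responder_true)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 5000))
})

test_that("trajectories follow the exponential closed form", {
  # half-life construction: b0 = 20, lambda = ln2/5 => score 10 at week 5
  cfg <- generator_config(
    n_subjects = 1, seed = 8, baseline_mean = 20, baseline_sd = 1e-9,
    responder_decay_mean = log(2) / 5, responder_decay_sd = 1e-9,
    residual_sd = 1e-9, covariate_spec = list(), true_beta = c(),
    true_alpha = c())
  sim <- simulate_trajectories("responder", list(s1 = c(0, 5)), cfg)
  expect_equal(sim$dataset$series[[1]]$scores, c(20, 10))

  # flat limit: lambda ~ 0 class keeps round(b0) at all times
  cfg$nonresponder_decay_mean <- 0
  cfg$nonresponder_decay_sd <- 1e-12
  sim2 <- simulate_trajectories("nonresponder", list(s1 = c(0, 3, 7)), cfg)
  expect_true(all(sim2$dataset$series[[1]]$scores == 20))
})

test_that("scores and baselines respect clamping and truncation", {
  for (seed in c(21, 22, 23)) {
    cohort <- generate_cohort(separated_config(n = 60, seed = seed,
                                               residual_sd = 12))
    scores <- unlist(lapply(cohort$dataset$series, `[[`, "scores"))
    expect_true(all(scores >= 0 & scores <= 63))
    expect_true(all(cohort$truth$b0 >= 10 & cohort$truth$b0 <= 40))
    expect_silent(validate_dataset(cohort$dataset))
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- separated_config(n = 20, seed = 31)
  d1 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  f1 <- file.path(d1, "a.csv")
  f2 <- file.path(d1, "b.csv")
  write_long_csv(c1$dataset, f1)
  write_long_csv(c2$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(c1$truth$lambda, c2$truth$lambda)
})

test_that("degenerate cohort sizes are handled", {
  empty <- generate_cohort(separated_config(n = 0, seed = 1))
  expect_length(empty$dataset$series, 0)
  cohort <- generate_cohort(generator_config(seed = 12))
  expect_length(cohort$dataset$series, 82)
  expect_true(all(lengths(lapply(cohort$dataset$series, `[[`, "times"))
                  >= 2))
})

test_that("well-separated classes are separable from observed change", {
  cohort <- generate_cohort(separated_config(n = 100, seed = 41,
                                             intercept = log(3)))
  change <- sapply(cohort$dataset$series, function(s)
    s$scores[1] - s$scores[length(s$scores)])
  auc <- simple_auc(change, cohort$truth$class == "responder")
  expect_gt(auc, 0.9)
})
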