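# Readers, validation, standardization and imputation of trial data.

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("long CSV reading builds one series per subject, sorted by time", {
  path <- write_tmp_csv(c("subject,time_weeks,bdi2",
                          "s1,1,18", "s1,0,21", "s2,0,30", "s2,2,25"))
  ds <- read_long_csv(path)
  expect_length(ds$series, 2)
  expect_equal(ds$series[["s1"]]$scores, c(21, 18))  # sorted by time
  expect_equal(ds$series[["s1"]]$times, c(0, 1))
})

test_that("long CSV validation rejects malformed inputs", {
  expect_error(read_long_csv(write_tmp_csv(
    c("subject,week,bdi2", "s1,0,20"))), "missing column")
  expect_error(read_long_csv(write_tmp_csv(
    c("subject,time_weeks,bdi2", "s1,0,70", "s1,1,20"))),
    "score out of range")
  expect_error(read_long_csv(write_tmp_csv(
    c("subject,time_weeks,bdi2", "s1,1,20", "s1,1,19"))),
    "not strictly increasing")
  expect_error(read_long_csv(write_tmp_csv(
    c("subject,time_weeks,bdi2", "s1,1,20", "s1,2,19"))),
    "first time must be 0")
  expect_error(read_long_csv(write_tmp_csv(
    c("subject,time_weeks,bdi2", "s1,0,20"))), "at least 2")
})

test_that("write/read long CSV round trip is the identity", {
  cohort <- generate_cohort(separated_config(n = 15, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(cohort$dataset, path)
  back <- read_long_csv(path)
  expect_equal(names(back$series), names(cohort$dataset$series))
  for (id in names(back$series)) {
    expect_identical(back$series[[id]]$scores,
                     cohort$dataset$series[[id]]$scores)
    expect_equal(back$series[[id]]$times, cohort$dataset$series[[id]]$times,
                 tolerance = 1e-12)
  }
})

test_that("covariate CSV reading types and missing markers behave", {
  kinds <- c(marital = "binary", swls = "continuous")
  rows <- c("s1,0,14.5", "s2,1,", sprintf("s%d,1,%g", 3:10, 9:16))
  path <- write_tmp_csv(c("subject,marital,swls", rows))
  ct <- read_covariates_csv(path, kinds)
  expect_equal(dim(ct$values), c(10, 2))
  expect_true(is.na(ct$values["s2", "swls"]))   # empty cell is NA, not 0
  expect_equal(unname(ct$values["s1", "swls"]), 14.5)
  expect_error(read_covariates_csv(write_tmp_csv(
    c("subject,marital,swls", "s1,2,14.5", "s2,1,9", "s3,0,8")), kinds),
    "outside \\{0, 1\\}")
  expect_error(read_covariates_csv(write_tmp_csv(
    c("subject,marital", "s1,0")), c(swls = "continuous")),
    "kinds must cover")
})

test_that("covariate missingness thresholds warn and error", {
  vals <- matrix(c(1, NA, 3:10), 10, 1, dimnames = list(NULL, "x"))
  # 10% missing: below both thresholds, silent
  expect_warning(covariate_table(paste0("s", 1:10), vals,
                                 c(x = "continuous")), NA)
  vals[2:4] <- NA  # 30% missing: hard error
  expect_error(covariate_table(paste0("s", 1:10), vals,
                               c(x = "continuous")), "missing fraction")
  vals2 <- matrix(c(NA, 2:8), 8, 1, dimnames = list(NULL, "x"))
  # 12.5% missing: above the warn threshold, below the error one
  expect_warning(covariate_table(paste0("s", 1:8), vals2,
                                 c(x = "continuous")), "exceeds 0.11")
})

test_that("standardization centers, scales and is invertible", {
  ct <- covariate_table(
    c("a", "b", "c"),
    matrix(c(1, 2, 3, 0, 1, 1), 3, 2,
           dimnames = list(NULL, c("swls", "marital"))),
    c(swls = "continuous", marital = "binary"))
  res <- standardize_covariates(ct)
  # population-SD scaling: (1,2,3) maps to +-sqrt(3/2)
  expect_equal(res$table$values[, "swls"],
               c(a = -1, b = 0, c = 1) * 1.224744871391589,
               tolerance = 1e-10)
  # binary: centered only, full contrast preserved
  expect_equal(unname(res$table$values[, "marital"]),
               c(-2 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(res$scaling$scale[res$scaling$name == "marital"], 1)
  # invert
  inv <- sweep(sweep(res$table$values, 2, res$scaling$scale, "*"),
               2, res$scaling$center, "+")
  expect_equal(unname(inv), unname(ct$values), tolerance = 1e-12)
  ct$values[, "swls"] <- 5
  expect_error(standardize_covariates(ct), "zero variance")
})

test_that("standardized columns have mean 0 and unit SD (property)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    vals <- cbind(cont = rnorm(n, 50, 9),
                  ord = sample(0:4, n, replace = TRUE),
                  bin = rbinom(n, 1, 0.4))
    vals[sample(n, 2), "cont"] <- NA
    # 2/n missing can stray above the warn threshold at small n
    ct <- suppressWarnings(
      covariate_table(paste0("s", seq_len(n)), vals,
                      c(cont = "continuous", ord = "ordinal",
                        bin = "binary")))
    std <- standardize_covariates(ct)$table$values
    pop_sd <- function(v) {
      v <- v[!is.na(v)]
      sqrt(mean((v - mean(v))^2))
    }
    for (k in colnames(std))
      expect_lt(abs(mean(std[, k], na.rm = TRUE)), 1e-10)
    for (k in c("cont", "ord"))
      expect_lt(abs(pop_sd(std[, k]) - 1), 1e-10)
  }
})

test_that("imputation strategies behave as documented", {
  # standardized-looking column with one missing entry; observed mean 0,
  # so the mean strategy fills the gap with 0
  vals <- matrix(c(-1, NA, 1, -2, 2, -0.5, 0.5, 0, 0, 0), 10, 1,
                 dimnames = list(NULL, "x"))
  ct <- covariate_table(paste0("s", 1:10), vals, c(x = "continuous"))
  imp <- impute_covariates(ct, "mean")
  expect_equal(unname(imp$values[1:3, "x"]), c(-1, 0, 1))
  expect_false(anyNA(imp$values))
  expect_identical(impute_covariates(ct, "none")$values, ct$values)
  all_na <- structure(list(subject_ids = c("a", "b"),
                           values = matrix(NA_real_, 2, 1,
                                           dimnames = list(c("a", "b"),
                                                           "x")),
                           kinds = c(x = "continuous")),
                      class = "covariate_table")
  expect_error(impute_covariates(all_na, "mean"), "entirely missing")
})

test_that("dataset validation rejects synthetic corruptions (fuzz)", {
  set.seed(99)
  base <- generate_cohort(separated_config(n = 10, seed = 5))$dataset
  for (rep in 1:10) {
    bad <- base
    mode <- sample(c("shuffle", "range", "ids"), 1)
    i <- sample(length(bad$series), 1)
    if (mode == "shuffle") {
      bad$series[[i]]$times <- rev(bad$series[[i]]$times)
    } else if (mode == "range") {
      bad$series[[i]]$scores[1] <- sample(c(-4, 70, 100), 1)
    } else {
      names(bad$series)[i] <- paste0(names(bad$series)[i], "_ghost")
      bad$series[[i]]$subject_id <- names(bad$series)[i]
    }
    expect_error(validate_dataset(bad))
  }
})

test_that("attach_covariates enforces the id bijection", {
  ds <- tiny_dataset()
  ct <- tiny_covariates(c("s1", "s2", "sX"))
  expect_error(attach_covariates(ds, ct), "do not match")
  expect_silent(attach_covariates(ds, tiny_covariates()))
})
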