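# Domain types and I/O for longitudinal BDI-II series and per-subject covariates.

BDI_MIN <- 0
BDI_MAX <- 63
MISS_ERROR_FRAC <- 0.20   # hard error above this per-covariate missingness
MISS_WARN_FRAC <- 0.11    # warn above this (highest rate seen in practice)

#' Construct a single subject's measurement series
#'
#' A measurement series holds one subject's BDI-II totals \eqn{y_{ij}} at
#' times \eqn{t_{ij}} in weeks from baseline.  Times must be strictly
#' increasing and start at 0 (the pre-treatment assessment); scores must be
#' integers in \[0, 63\]; at least two observations are required, since a
#' single occasion carries no trajectory information.
#'
#' @param subject_id Scalar identifier (coerced to character).
#' @param times Numeric vector of nonnegative weeks from baseline.
#' @param scores Integer-valued BDI-II totals, same length as `times`.
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(subject_id, times, scores) {
  ms <- structure(
    list(subject_id = as.character(subject_id)[1],
         times = as.numeric(times), scores = as.numeric(scores)),
    class = "measurement_series")
  validate_series(ms)
  ms
}

validate_series <- function(ms) {
  id <- ms$subject_id
  if (length(ms$times) != length(ms$scores))
    stop("subject ", id, ": times and scores differ in length", call. = FALSE)
  if (length(ms$times) < 2)
    stop("subject ", id, ": at least 2 measurement occasions required",
         call. = FALSE)
  if (anyNA(ms$times) || anyNA(ms$scores))
    stop("subject ", id, ": missing time or score values", call. = FALSE)
  if (ms$times[1] != 0)
    stop("subject ", id, ": first time must be 0 (baseline)", call. = FALSE)
  if (any(diff(ms$times) <= 0))
    stop("subject ", id, ": times not strictly increasing", call. = FALSE)
  if (any(ms$scores < BDI_MIN | ms$scores > BDI_MAX))
    stop("subject ", id, ": score out of range [", BDI_MIN, ", ", BDI_MAX,
         "]", call. = FALSE)
  if (any(abs(ms$scores - round(ms$scores)) > 1e-8))
    stop("subject ", id, ": BDI-II scores must be integers", call. = FALSE)
  invisible(ms)
}

#' Construct a typed per-subject covariate table
#'
#' Holds the predictor values \eqn{x_{ik}} with per-covariate type tags.
#' Binary covariates must be coded 0/1; ordinal covariates integer-coded
#' with a documented order.  Missing values are `NA`.  Per-covariate
#' missingness above 20\% is an error; above 11\% a warning.
#'
#' @param subject_ids Character vector, one per row of `values`.
#' @param values Numeric matrix (subjects x covariates) with `NA` for
#'   missing; column names are the covariate labels.
#' @param kinds Named character vector mapping each covariate to one of
#'   `"binary"`, `"ordinal"`, `"continuous"`.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(subject_ids, values, kinds) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subject_ids <- as.character(subject_ids)
  if (nrow(values) != length(subject_ids))
    stop("covariate rows do not match subject ids", call. = FALSE)
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("covariate matrix must have column names", call. = FALSE)
  if (ncol(values) == 0) colnames(values) <- character(0)
  rownames(values) <- subject_ids
  ct <- structure(
    list(subject_ids = subject_ids, values = values,
         kinds = kinds[colnames(values)]),
    class = "covariate_table")
  validate_covariates(ct)
  ct
}

validate_covariates <- function(ct) {
  nm <- colnames(ct$values)
  if (anyDuplicated(ct$subject_ids))
    stop("duplicated subject ids in covariate table", call. = FALSE)
  if (length(nm) &&
      (is.null(names(ct$kinds)) || !setequal(names(ct$kinds), nm)))
    stop("kinds must name every covariate column", call. = FALSE)
  bad_kind <- setdiff(unique(ct$kinds), c("binary", "ordinal", "continuous"))
  if (length(bad_kind))
    stop("unknown covariate kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  for (k in nm) {
    v <- ct$values[, k]
    obs <- v[!is.na(v)]
    if (ct$kinds[[k]] == "binary" && length(obs) && !all(obs %in% c(0, 1)))
      stop("binary covariate '", k, "' has values outside {0, 1}",
           call. = FALSE)
    if (ct$kinds[[k]] == "ordinal" && length(obs) &&
        any(abs(obs - round(obs)) > 1e-8))
      stop("ordinal covariate '", k, "' must be integer-coded",
           call. = FALSE)
    frac <- mean(is.na(v))
    if (frac > MISS_ERROR_FRAC)
      stop("covariate '", k, "' missing fraction ", round(frac, 3),
           " exceeds ", MISS_ERROR_FRAC, call. = FALSE)
    if (frac > MISS_WARN_FRAC)
      warning("covariate '", k, "' missing fraction ", round(frac, 3),
              " exceeds ", MISS_WARN_FRAC, call. = FALSE)
  }
  invisible(ct)
}

#' Bundle measurement series with covariates
#'
#' @param series List of [measurement_series()] objects.
#' @param covariates A [covariate_table()] or `NULL` if attached later.
#' @param metadata Free-form provenance list (source file, seed,
#'   standardization applied, ...).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(series, covariates = NULL, metadata = list()) {
  names(series) <- vapply(series, function(s) s$subject_id, character(1))
  ds <- structure(list(series = series, covariates = covariates,
                       metadata = metadata),
                  class = "study_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a study dataset
#'
#' Re-runs all series-level checks and, when covariates are attached,
#' requires a one-to-one match between series and covariate subject ids.
#'
#' @param ds A `study_dataset`.
#' @return The dataset, invisibly; errors on any violation.
#' @export
validate_dataset <- function(ds) {
  ids <- names(ds$series)
  if (anyDuplicated(ids))
    stop("duplicated subject ids among series", call. = FALSE)
  for (s in ds$series) validate_series(s)
  if (!is.null(ds$covariates)) {
    validate_covariates(ds$covariates)
    if (!setequal(ids, ds$covariates$subject_ids) ||
        length(ids) != length(ds$covariates$subject_ids))
      stop("series subject ids and covariate subject ids do not match",
           call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$series, function(s) length(s$times), integer(1)))
  cat("study_dataset:", length(x$series), "subjects,", n_obs,
      "observations\n")
  if (!is.null(x$covariates))
    cat("  covariates:", ncol(x$covariates$values), "(",
        paste(head(colnames(x$covariates$values), 5), collapse = ", "),
        if (ncol(x$covariates$values) > 5) ", ..." else "", ")\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", length(x$subject_ids), "subjects x",
      ncol(x$values), "covariates\n")
  invisible(x)
}

#' Read long-format scores from CSV
#'
#' Expects one row per measurement occasion.  Builds one measurement series
#' per distinct subject id (rows sorted by time within subject) and runs
#' full validation.  Covariates are attached separately with
#' [attach_covariates()].
#'
#' @param path CSV file path (UTF-8, header row, comma-separated; missing
#'   cells are empty or `"NA"`).
#' @param id_col,time_col,score_col Column names.
#' @return A `study_dataset` without covariates.
#' @export
read_long_csv <- function(path, id_col = "subject", time_col = "time_weeks",
                          score_col = "bdi2") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_col, time_col, score_col), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tvals <- suppressWarnings(as.numeric(df[[time_col]]))
  yvals <- suppressWarnings(as.numeric(df[[score_col]]))
  if (anyNA(tvals) || anyNA(yvals))
    stop("non-numeric or missing time/score values in ", path, call. = FALSE)
  ids <- as.character(df[[id_col]])
  series <- lapply(split(seq_len(nrow(df)), factor(ids, unique(ids))),
                   function(rows) {
                     ord <- order(tvals[rows])
                     ms <- structure(
                       list(subject_id = ids[rows[1]],
                            times = tvals[rows][ord],
                            scores = yvals[rows][ord]),
                       class = "measurement_series")
                     # reject ties even after sorting
                     if (anyDuplicated(ms$times))
                       stop("subject ", ms$subject_id,
                            ": times not strictly increasing", call. = FALSE)
                     validate_series(ms)
                   })
  study_dataset(unname(series), metadata = list(source = path))
}

#' Write long-format scores to CSV
#'
#' Inverse of [read_long_csv()]: scores are written as integers, times at
#' full precision, so that a read-write-read round trip is the identity.
#'
#' @param ds A `study_dataset`.
#' @param path Output file path.
#' @param id_col,time_col,score_col Column names to emit.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path, id_col = "subject",
                           time_col = "time_weeks", score_col = "bdi2") {
  rows <- do.call(rbind, lapply(ds$series, function(s)
    data.frame(id = s$subject_id,
               time = format(s$times, digits = 17, trim = TRUE,
                             scientific = FALSE),
               score = as.integer(round(s$scores)),
               stringsAsFactors = FALSE)))
  names(rows) <- c(id_col, time_col, score_col)
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-subject covariate CSV
#'
#' One row per subject; every non-id column must be declared in `kinds`.
#' Empty cells and `"NA"` become missing markers (never 0).
#'
#' @param path CSV file path.
#' @param kinds Named character vector mapping covariate names to
#'   `"binary"`, `"ordinal"` or `"continuous"`.
#' @param id_col Subject id column name.
#' @return A `covariate_table`.
#' @export
read_covariates_csv <- function(path, kinds, id_col = "subject") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  if (!id_col %in% names(df))
    stop("missing column: ", id_col, call. = FALSE)
  if (anyDuplicated(df[[id_col]]))
    stop("more than one row per subject in ", path, call. = FALSE)
  cov_names <- setdiff(names(df), id_col)
  undeclared <- setdiff(cov_names, names(kinds))
  if (length(undeclared))
    stop("kinds must cover all covariate columns; missing: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  vals <- sapply(df[cov_names], function(col)
    suppressWarnings(as.numeric(col)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, cov_names))
  covariate_table(df[[id_col]], vals, kinds[cov_names])
}

#' Write a covariate table to CSV
#'
#' @param ct A `covariate_table`.
#' @param path Output file path.
#' @param id_col Subject id column name.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(ct, path, id_col = "subject") {
  df <- data.frame(id = ct$subject_ids, stringsAsFactors = FALSE)
  names(df) <- id_col
  for (k in colnames(ct$values)) {
    col <- format(ct$values[, k], digits = 17, trim = TRUE,
                  scientific = FALSE)
    col[is.na(ct$values[, k])] <- ""  # missing stays an empty cell
    df[[k]] <- col
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach covariates to a dataset
#'
#' @param ds A `study_dataset`.
#' @param ct A `covariate_table` whose subject ids match the series.
#' @return The dataset with covariates attached and re-validated.
#' @export
attach_covariates <- function(ds, ct) {
  ds$covariates <- ct
  validate_dataset(ds)
  ds
}

#' Standardize covariates
#'
#' Continuous and ordinal covariates are transformed to mean 0, SD 1 over
#' their non-missing entries (population SD, i.e. the n divisor, so that
#' the standardized column has unit second moment exactly).  Binary
#' covariates are centered only (observed mean subtracted, variance
#' untouched) so their coefficients read as full 0-to-1 contrast effects.
#' The returned scaling record inverts the transform.
#'
#' @param ct A `covariate_table`.
#' @return A list with elements `table` (standardized `covariate_table`)
#'   and `scaling` (data frame: name, kind, center, scale).
#' @export
standardize_covariates <- function(ct) {
  vals <- ct$values
  if (ncol(vals) == 0)
    return(list(table = ct,
                scaling = data.frame(name = character(0),
                                     kind = character(0),
                                     center = numeric(0),
                                     scale = numeric(0))))
  rec <- data.frame(name = colnames(vals),
                    kind = unname(ct$kinds[colnames(vals)]),
                    center = NA_real_, scale = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    obs <- v[!is.na(v)]
    if (!length(obs))
      stop("covariate '", colnames(vals)[j], "' is entirely missing",
           call. = FALSE)
    ctr <- mean(obs)
    if (rec$kind[j] == "binary") {
      scl <- 1
    } else {
      scl <- sqrt(mean((obs - ctr)^2))
      if (!is.finite(scl) || scl < 1e-12)
        stop("covariate '", colnames(vals)[j], "' has zero variance",
             call. = FALSE)
    }
    vals[, j] <- (v - ctr) / scl
    rec$center[j] <- ctr
    rec$scale[j] <- scl
  }
  out <- ct
  out$values <- vals
  list(table = out, scaling = rec)
}

#' Impute missing covariate values
#'
#' `"mean"` replaces missing entries by the covariate's observed mean (0
#' after standardization); `"none"` returns the table unchanged, leaving
#' downstream fits to reject missing values.
#'
#' @param ct A `covariate_table`.
#' @param strategy `"mean"` or `"none"`.
#' @return A `covariate_table`.
#' @export
impute_covariates <- function(ct, strategy = c("mean", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(ct)
  vals <- ct$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    obs <- v[!is.na(v)]
    if (!length(obs))
      stop("covariate '", colnames(vals)[j],
           "' is entirely missing; mean undefined", call. = FALSE)
    vals[is.na(v), j] <- mean(obs)
  }
  out <- ct
  out$values <- vals
  out
}

# Long-format data.frame view used by the samplers.
dataset_long <- function(ds) {
  ids <- names(ds$series)
  do.call(rbind, lapply(seq_along(ds$series), function(i) {
    s <- ds$series[[i]]
    data.frame(subj = i, subject = s$subject_id, t = s$times, y = s$scores,
               stringsAsFactors = FALSE)
  }))
}
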