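# Configuration-driven pipeline: simulate a cohort, fit the requested
# analyses, and render a human-readable report.  A single structured YAML
# config holds everything (paths or generator settings, covariate kinds,
# preprocessing switches, priors, sampler, threshold); results are CSV +
# JSON manifests so a run can be replayed exactly.

#' Read and validate a run configuration
#'
#' The YAML file must contain an integer `seed` and exactly one of
#' `simulate` (generator settings, see [generator_config()]) or `input`
#' (paths `scores`, `covariates`, and a `kinds` map).  Optional keys:
#' `output_dir`, `analyses` (subset of `select-family`, `latent-class`,
#' `slope-regression`), `model_family`, `standardize`, `impute`,
#' `threshold`, `sampler`, `prior`, `curves`.  A commented template ships
#' in `inst/extdata/config_template.yaml`.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: seed is required",
                              call. = FALSE)
  has_sim <- !is.null(cfg$simulate)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    stop("config error: exactly one of 'simulate' or 'input' must be set",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$output_dir <- cfg$output_dir %||% "respmix-output"
  cfg$analyses <- cfg$analyses %||% c("latent-class", "slope-regression")
  bad <- setdiff(cfg$analyses,
                 c("select-family", "latent-class", "slope-regression"))
  if (length(bad))
    stop("config error: unknown analysis: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg$model_family <- cfg$model_family %||% "exponential"
  cfg$standardize <- cfg$standardize %||% TRUE
  cfg$impute <- cfg$impute %||% "mean"
  cfg$threshold <- cfg$threshold %||% 0.5
  cfg$rhat_threshold <- cfg$rhat_threshold %||% 1.05
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_sampler <- function(cfg) {
  s <- cfg$sampler %||% list()
  sampler_config(chains = s$chains %||% 4, adapt = s$adapt %||% 500,
                 warmup = s$warmup %||% 1000, draws = s$draws %||% 2000,
                 seed = s$seed %||% cfg$seed)
}

config_prior <- function(cfg) do.call(prior_config, cfg$prior %||% list())

config_generator <- function(cfg) {
  args <- cfg$simulate %||% list()
  args$seed <- args$seed %||% cfg$seed
  known <- names(formals(generator_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("config error: unknown generator setting: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(args$true_beta)) args$true_beta <- unlist(args$true_beta)
  if (!is.null(args$true_alpha)) args$true_alpha <- unlist(args$true_alpha)
  if (!is.null(args$covariate_spec))   # YAML scalars arrive as lists
    args$covariate_spec <- lapply(args$covariate_spec, function(sp)
      lapply(sp, function(f) if (is.list(f)) unlist(f) else f))
  for (rng in c("baseline_range", "duration_range"))
    if (!is.null(args[[rng]])) args[[rng]] <- unlist(args[[rng]])
  do.call(generator_config, args)
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

log_stage <- function(...) message("[respmix] ", ...)

#' Simulate a cohort to disk
#'
#' Writes `scores.csv`, `covariates.csv`, `truth.csv` and `manifest.json`
#' to the configured output directory.  Identical configs produce
#' byte-identical files.
#'
#' @param config_path Path to a YAML run config with a `simulate` block.
#' @param output_dir Optional override of the config's output directory.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config_path, output_dir = NULL) {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$simulate))
    stop("config error: cmd_simulate needs a 'simulate' block",
         call. = FALSE)
  gcfg <- config_generator(cfg)
  dir <- output_dir %||% cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("simulate: generating ", gcfg$n_subjects, " subjects (seed ",
            gcfg$seed, ")")
  cohort <- generate_cohort(gcfg)
  write_long_csv(cohort$dataset, file.path(dir, "scores.csv"))
  if (!is.null(cohort$dataset$covariates))
    write_covariates_csv(cohort$dataset$covariates,
                         file.path(dir, "covariates.csv"))
  truth <- cohort$truth
  attr(truth, "config") <- NULL
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  write_manifest(dir, list(
    command = "simulate", seed = gcfg$seed,
    config_hash = rlang::hash(unclass(gcfg)),
    package_version = as.character(utils::packageVersion("respmix")),
    n_subjects = gcfg$n_subjects, family = gcfg$family,
    files = c("scores.csv", "covariates.csv", "truth.csv")))
  invisible(dir)
}

load_fit_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    cohort <- generate_cohort(config_generator(cfg))
    ds <- cohort$dataset
  } else {
    kinds <- unlist(cfg$input$kinds)
    ds <- read_long_csv(cfg$input$scores)
    if (!is.null(cfg$input$covariates)) {
      ct <- read_covariates_csv(cfg$input$covariates, kinds)
      ds <- attach_covariates(ds, ct)
    }
  }
  ds
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the configured analyses
#'
#' Loads or simulates the inputs, standardizes and imputes covariates,
#' then runs the requested analyses in order (family selection, latent
#' class, slope regression), writing all result CSVs, convergence and
#' posterior-predictive reports, evidence tables, response-probability
#' curves and a manifest into the output directory.
#'
#' @param config_path Path to a YAML run config.
#' @param output_dir Optional override of the config's output directory.
#' @return Invisibly, a list with the fitted objects and
#'   `convergence_ok`, `FALSE` if any checked parameter exceeded the
#'   configured R-hat threshold.
#' @export
cmd_fit <- function(config_path, output_dir = NULL) {
  cfg <- read_run_config(config_path)
  dir <- output_dir %||% cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sampler <- config_sampler(cfg)
  prior <- config_prior(cfg)

  ds <- stage("load-inputs", load_fit_inputs(cfg))
  covs <- NULL
  if (!is.null(ds$covariates)) {
    covs <- ds$covariates
    if (isTRUE(cfg$standardize))
      covs <- standardize_covariates(covs)$table
    covs <- impute_covariates(covs, cfg$impute)
  }

  results <- list()
  outputs <- character(0)
  convergence_ok <- TRUE
  conv_all <- list()

  check_convergence <- function(pd, label) {
    rep <- convergence_report(pd, threshold = cfg$rhat_threshold)
    rep$stage <- label
    conv_all[[label]] <<- rep
    if (!attr(rep, "pass")) convergence_ok <<- FALSE
  }

  if ("select-family" %in% cfg$analyses) {
    log_stage("select-family: ranking trajectory families")
    sel <- stage("select-family",
                 select_family(ds, prior = prior, sampler = sampler))
    write.csv(sel, file.path(dir, "family_selection.csv"),
              row.names = FALSE)
    outputs <- c(outputs, "family_selection.csv")
    results$family_selection <- sel
  }

  if ("latent-class" %in% cfg$analyses) {
    log_stage("latent-class: fitting ", cfg$model_family, " mixture")
    cpost <- stage("latent-class",
                   fit_latent_class(ds, covs, family = cfg$model_family,
                                    prior = prior, sampler = sampler))
    results$latent_class <- cpost
    cls <- classify(cpost$p_resp, cfg$threshold)
    write.csv(data.frame(subject = names(cpost$p_resp),
                         p_resp = cpost$p_resp, label = cls$labels,
                         row.names = NULL),
              file.path(dir, "classification.csv"), row.names = FALSE)
    outputs <- c(outputs, "classification.csv")
    if (!is.null(cpost$beta$coef)) {
      tab <- evidence_table(cpost$beta$coef)
      write_evidence_csv(tab, file.path(dir, "class_evidence.csv"))
      outputs <- c(outputs, "class_evidence.csv")
      curve_covs <- cfg$curves %||% colnames(cpost$beta$coef)
      grid <- seq(-2, 2, length.out = 21)
      curves <- do.call(rbind, lapply(curve_covs, function(cv)
        response_probability_curve(cpost, cv, grid)))
      write.csv(curves, file.path(dir, "response_curves.csv"),
                row.names = FALSE)
      outputs <- c(outputs, "response_curves.csv")
    }
    check_convergence(cpost$draws, "latent-class")
    ppc <- posterior_predictive(ds, cpost$draws, n_rep = 200,
                                seed = cfg$seed)
    write.csv(as.data.frame(ppc), file.path(dir, "ppc.csv"),
              row.names = FALSE)
    outputs <- c(outputs, "ppc.csv")
    results$ppc <- ppc
    write_draws_csv(cpost$draws, file.path(dir, "draws_latent_class.csv"),
                    params = grep("\\[", param_names(cpost$draws),
                                  value = TRUE, invert = TRUE))
    outputs <- c(outputs, "draws_latent_class.csv")
  }

  if ("slope-regression" %in% cfg$analyses) {
    log_stage("slope-regression: fitting quadratic slope model")
    spost <- stage("slope-regression",
                   fit_slope_regression(ds, covs, prior = prior,
                                        sampler = sampler))
    results$slope <- spost
    if (!is.null(spost$alpha)) {
      tab4 <- evidence_table(spost$alpha)
      write_evidence_csv(tab4, file.path(dir, "slope_evidence.csv"))
      tab5 <- evidence_table(spost$alpha,
                             prior_density_at_zero =
                               dnorm(0, 0, prior$alpha_sd),
                             include_bf = TRUE)
      write_evidence_csv(tab5[, c("name", "bf10", "bf10_saturated",
                                  "category")],
                         file.path(dir, "bayes_factors.csv"))
      outputs <- c(outputs, "slope_evidence.csv", "bayes_factors.csv")
    }
    check_convergence(spost$draws, "slope-regression")
    write_draws_csv(spost$draws, file.path(dir, "draws_slope.csv"),
                    params = grep("\\[", param_names(spost$draws),
                                  value = TRUE, invert = TRUE))
    outputs <- c(outputs, "draws_slope.csv")
  }

  if (length(conv_all)) {
    conv <- do.call(rbind, conv_all)
    write.csv(conv, file.path(dir, "convergence.csv"), row.names = FALSE)
    outputs <- c(outputs, "convergence.csv")
  }

  write_manifest(dir, list(
    command = "fit", seed = cfg$seed,
    analyses = cfg$analyses, model_family = cfg$model_family,
    threshold = cfg$threshold, rhat_threshold = cfg$rhat_threshold,
    sampler = sampler, convergence_ok = convergence_ok,
    package_version = as.character(utils::packageVersion("respmix")),
    files = outputs))
  results$convergence_ok <- convergence_ok
  if (!convergence_ok)
    warning("convergence check failed at R-hat threshold ",
            cfg$rhat_threshold, call. = FALSE)
  invisible(results)
}

#' Render a markdown report from a result bundle
#'
#' Concatenates the responder split, evidence tables and convergence
#' summary from a [cmd_fit()] output directory into `report.md`.  Missing
#' artifacts are flagged but do not abort the report unless nothing at all
#' is present.
#'
#' @param bundle_dir Directory written by [cmd_fit()].
#' @return The report text, invisibly; also written to
#'   `bundle_dir/report.md`.
#' @export
cmd_report <- function(bundle_dir) {
  expected <- c("manifest.json", "classification.csv",
                "class_evidence.csv", "slope_evidence.csv",
                "bayes_factors.csv", "convergence.csv", "ppc.csv")
  present <- file.exists(file.path(bundle_dir, expected))
  if (!any(present))
    stop("no result bundle in ", bundle_dir, "; expected files: ",
         paste(expected, collapse = ", "), call. = FALSE)
  lines <- c("# respmix analysis report", "")
  missing <- expected[!present]
  if (length(missing))
    lines <- c(lines, paste("Missing artifacts:",
                            paste(missing, collapse = ", ")), "")
  cls_path <- file.path(bundle_dir, "classification.csv")
  if (file.exists(cls_path)) {
    cls <- read.csv(cls_path)
    n_resp <- sum(cls$label == "responder")
    lines <- c(lines, "## Responder split",
               sprintf("%d of %d subjects (%.0f%%) classified responder;",
                       n_resp, nrow(cls), 100 * n_resp / nrow(cls)),
               sprintf("%d (%.0f%%) nonresponder.", nrow(cls) - n_resp,
                       100 * (1 - n_resp / nrow(cls))), "")
  }
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")))
  }
  ev_path <- file.path(bundle_dir, "class_evidence.csv")
  if (file.exists(ev_path)) {
    ev <- read_evidence_csv(ev_path)
    ev$OR <- paste0(signif(ev$or_value, 4), ev$or_sign)
    lines <- c(lines, "## Class-membership coefficients (beta)",
               fmt_tab(data.frame(variable = ev$name,
                                  mode = signif(ev$mode, 3),
                                  hdi = sprintf("(%.2f, %.2f)", ev$hdi_low,
                                                ev$hdi_high),
                                  OR = ev$OR)), "")
  }
  sl_path <- file.path(bundle_dir, "slope_evidence.csv")
  if (file.exists(sl_path)) {
    ev <- read_evidence_csv(sl_path)
    ev$OR <- paste0(signif(ev$or_value, 4), ev$or_sign)
    lines <- c(lines, "## Slope coefficients (alpha, + = faster decline)",
               fmt_tab(data.frame(variable = ev$name,
                                  mode = signif(ev$mode, 3),
                                  hdi = sprintf("(%.2f, %.2f)", ev$hdi_low,
                                                ev$hdi_high),
                                  OR = ev$OR)), "")
  }
  bf_path <- file.path(bundle_dir, "bayes_factors.csv")
  if (file.exists(bf_path)) {
    bf <- read_evidence_csv(bf_path)
    lines <- c(lines, "## Bayes factors (BF10, Savage-Dickey)",
               fmt_tab(data.frame(variable = bf$name,
                                  BF10 = signif(bf$bf10, 3),
                                  evidence = bf$category)), "")
  }
  cv_path <- file.path(bundle_dir, "convergence.csv")
  if (file.exists(cv_path)) {
    cv <- read.csv(cv_path)
    lines <- c(lines, "## Convergence",
               sprintf("max R-hat %.4f across %d parameters; %s",
                       max(cv$rhat), nrow(cv),
                       if (all(cv$pass)) "all within threshold"
                       else "THRESHOLD EXCEEDED"), "")
  }
  ppc_path <- file.path(bundle_dir, "ppc.csv")
  if (file.exists(ppc_path)) {
    ppc <- read.csv(ppc_path)
    inside <- mean(ppc$obs_mean >= ppc$mean_q025 &
                     ppc$obs_mean <= ppc$mean_q975)
    lines <- c(lines, "## Posterior predictive check",
               sprintf("observed weekly means inside the 95%% envelope in %.0f%% of %d bins",
                       100 * inside, nrow(ppc)), "")
  } else {
    lines <- c(lines, "_Posterior predictive check not available._", "")
  }
  text <- paste(lines, collapse = "\n")
  writeLines(text, file.path(bundle_dir, "report.md"))
  invisible(text)
}
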