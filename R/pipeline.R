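# Config-driven orchestration of the full MR workflow:
# select -> harmonize -> estimate -> diagnose -> export.

#' Pipeline configuration
#'
#' Describes one analysis run: either file paths to exposure/outcome summary
#' statistics and an LD panel, or a synthetic scenario ([simulation_truth()])
#' generated on the fly. Stochastic stages (median bootstrap, MR-PRESSO)
#' require an explicit seed.
#'
#' @param exposure_paths character vector of summary-stat file paths (one for
#'   univariable, two or more for multivariable; order defines the MVMR
#'   orientation anchor), or `NULL` when `scenario` is given.
#' @param outcome_path path to outcome summary statistics, or `NULL`.
#' @param ld_panel_paths length-2 character vector `c(r2, positions)` for
#'   [read_ld_panel()], or `NULL`.
#' @param scenario optional [simulation_truth()]; when present the study pair
#'   and panel are simulated instead of read from files.
#' @param clump a [clump_config()].
#' @param ivw_model IVW variance model: `"auto"`, `"fixed"`, `"random"`.
#' @param palindrome_eaf_window see [harmonize()].
#' @param n_boot median bootstrap replicates.
#' @param presso_n_sim,presso_alpha MR-PRESSO settings; set
#'   `presso_n_sim = 0` to skip PRESSO.
#' @param seed seed for all stochastic stages (required unless both the
#'   bootstrap and PRESSO are disabled).
#' @param out_dir output directory; created if missing. `NULL` disables file
#'   output.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure_paths = NULL, outcome_path = NULL,
                            ld_panel_paths = NULL, scenario = NULL,
                            clump = clump_config(),
                            ivw_model = c("auto", "fixed", "random"),
                            palindrome_eaf_window = 0.08,
                            n_boot = 1000, presso_n_sim = 1000,
                            presso_alpha = 0.05, seed = NULL,
                            out_dir = NULL) {
  ivw_model <- match.arg(ivw_model)
  if (is.null(scenario)) {
    if (is.null(exposure_paths) || is.null(outcome_path)) {
      stop("either a synthetic scenario or exposure/outcome paths must be ",
           "given", call. = FALSE)
    }
  } else {
    stopifnot(inherits(scenario, "simulation_truth"))
  }
  stochastic <- n_boot > 0 || presso_n_sim > 0
  if (stochastic && is.null(seed)) {
    stop("a seed is required when the bootstrap or MR-PRESSO is enabled",
         call. = FALSE)
  }
  structure(list(exposure_paths = exposure_paths,
                 outcome_path = outcome_path,
                 ld_panel_paths = ld_panel_paths, scenario = scenario,
                 clump = clump, ivw_model = ivw_model,
                 palindrome_eaf_window = palindrome_eaf_window,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 presso_alpha = presso_alpha, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `scenario`
#' block (with `theta`, `n_snps`, `r2_target`, ... as in
#' [simulation_truth()]) requests synthetic data.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    scen_args <- y$scenario
    for (fld in c("theta", "r2_target", "n_exposure")) {
      if (!is.null(scen_args[[fld]])) {
        scen_args[[fld]] <- as.numeric(unlist(scen_args[[fld]]))
      }
    }
    scenario <- do.call(simulation_truth, scen_args)
  }
  clump <- do.call(clump_config, if (is.null(y$clump)) list() else y$clump)
  args <- y[setdiff(names(y), c("scenario", "clump"))]
  do.call(pipeline_config,
          c(args, list(scenario = scenario, clump = clump)))
}

load_studies <- function(config, multivariable = FALSE) {
  if (!is.null(config$scenario)) {
    pair <- if (multivariable) simulate_mvmr(config$scenario)
            else simulate_univariable(config$scenario)
    exposures <- list(pair$exposure_stats)
    if (!is.null(pair$second_exposure_stats)) {
      exposures <- c(exposures, list(pair$second_exposure_stats))
    }
    return(list(exposures = exposures, outcome = pair$outcome_stats,
                panel = pair$panel, truth = pair$truth))
  }
  exposures <- lapply(seq_along(config$exposure_paths), function(i) {
    read_summary_stats(config$exposure_paths[i],
                       trait = sprintf("exposure_%d", i))
  })
  outcome <- read_summary_stats(config$outcome_path, trait = "outcome")
  panel <- if (!is.null(config$ld_panel_paths)) {
    read_ld_panel(config$ld_panel_paths[1L], config$ld_panel_paths[2L])
  } else NULL
  list(exposures = exposures, outcome = outcome, panel = panel, truth = NULL)
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(file.path(dir, name))
}

fmt3 <- function(x) formatC(x, format = "f", digits = 3)

#' Run the univariable MR workflow
#'
#' Executes significance filtering, LD clumping, harmonization, instrument
#' strength, the four univariable estimators (IVW, MR-Egger, simple and
#' weighted median), and the diagnostic suite (Cochran Q, Egger intercept,
#' leave-one-out, MR-PRESSO). When `out_dir` is set, writes forest-,
#' scatter-, and diagnostics-shaped delimited files, the instrument table,
#' the leave-one-out table, and a JSON run report.
#'
#' @param config a [pipeline_config()] with one exposure.
#' @return An object of class `run_report`: list with stage counts,
#'   `strength`, `estimates` (list of [mr_estimate()]), `q`, `egger_intercept`,
#'   `loo`, `presso`, and the configuration fingerprint.
#' @export
run_univariable <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- load_studies(config, multivariable = FALSE)
  if (length(st$exposures) != 1L) {
    stop("run_univariable expects exactly one exposure; use ",
         "run_multivariable for K >= 2", call. = FALSE)
  }
  exposure <- st$exposures[[1L]]
  outcome <- st$outcome

  sig <- filter_genome_wide(exposure, config$clump$p_threshold)
  if (nrow(sig$data) == 0L) {
    stop("instrument selection: no genome-wide significant variants",
         call. = FALSE)
  }
  instruments <- if (!is.null(st$panel)) {
    ld_clump(sig, st$panel, config$clump)
  } else sig
  if (nrow(instruments$data) == 0L) {
    stop("instrument selection: no variants survive clumping", call. = FALSE)
  }
  strength <- instrument_strength(instruments)
  hd <- harmonize(instruments, outcome, config$palindrome_eaf_window)
  j <- length(hd$rsids)
  if (j < 3L) stop("harmonization left fewer than 3 instruments",
                   call. = FALSE)

  est_ivw <- ivw(hd, model = config$ivw_model)
  egger <- mr_egger(hd)
  est_sm <- simple_median(hd, n_boot = config$n_boot, seed = config$seed)
  est_wm <- weighted_median(hd, n_boot = config$n_boot,
                            seed = config$seed + 1L)
  q <- cochran_q(hd)
  loo <- leave_one_out(hd)
  presso <- if (config$presso_n_sim > 0) {
    mr_presso(hd, n_sim = config$presso_n_sim,
              outlier_alpha = config$presso_alpha, seed = config$seed + 2L)
  } else NULL

  estimates <- list(ivw = est_ivw, egger = egger$slope,
                    simple_median = est_sm, weighted_median = est_wm)
  report <- structure(list(
    analysis = "univariable",
    exposure_trait = exposure$trait, outcome_trait = outcome$trait,
    n_significant = nrow(sig$data),
    n_instruments = nrow(instruments$data),
    n_dropped_harmonization = nrow(instruments$data) - j,
    n_harmonized = j,
    n_presso_outliers = if (is.null(presso)) 0L
                        else length(presso$outlier_indices),
    strength = strength, estimates = estimates,
    q = q, egger_intercept = list(intercept = egger$intercept_estimate,
                                  se = egger$intercept_se,
                                  pvalue = egger$intercept_p),
    loo = loo, presso = presso, truth = st$truth,
    config = config
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_univariable_outputs(report, hd, instruments, config$out_dir)
  }
  report
}

forest_row <- function(e) {
  data.frame(method = e$method, n_snps = e$n_snps,
             or_ = fmt3(e$or_), ci_low = fmt3(e$or_ci_low),
             ci_high = fmt3(e$or_ci_high), pvalue = signif(e$pvalue, 3),
             stringsAsFactors = FALSE)
}

write_univariable_outputs <- function(report, hd, instruments, dir) {
  write_instrument_table(instruments, file.path(dir, "instruments.tsv"))

  ests <- report$estimates
  forest <- do.call(rbind, lapply(ests, forest_row))
  if (!is.null(report$presso) &&
      length(report$presso$outlier_indices) > 0L) {
    corrected <- report$presso$corrected
    corrected$method <- "MR-PRESSO (outlier-corrected)"
    forest <- rbind(forest, forest_row(corrected))
  }
  write_tsv(forest, dir, "forest_univariable.tsv")

  scatter <- data.frame(rsid = hd$rsids, beta_exposure = hd$beta_exposure,
                        se_exposure = hd$se_exposure,
                        beta_outcome = hd$beta_outcome,
                        se_outcome = hd$se_outcome)
  write_tsv(scatter, dir, "scatter_data.tsv")
  egger_fit <- mr_egger(hd)
  lines <- data.frame(
    method = c("IVW", "MR-Egger", "Simple median", "Weighted median"),
    intercept = c(0, egger_fit$intercept_estimate, 0, 0),
    slope = c(ests$ivw$theta, egger_fit$slope$theta,
              ests$simple_median$theta, ests$weighted_median$theta))
  write_tsv(lines, dir, "fitted_lines.tsv")

  diag <- data.frame(
    method = "Univariable MR",
    outcome = report$outcome_trait, exposure = report$exposure_trait,
    q_statistic = fmt3(report$q$q_statistic), q_df = report$q$df,
    q_p = signif(report$q$pvalue, 3),
    egger_intercept = fmt3(report$egger_intercept$intercept),
    intercept_se = fmt3(report$egger_intercept$se),
    intercept_p = signif(report$egger_intercept$pvalue, 3))
  write_tsv(diag, dir, "table1_diagnostics.tsv")

  write_tsv(as.data.frame(report$loo), dir, "leave_one_out.tsv")
  jsonlite::write_json(run_report_json(report),
                       file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the multivariable MR workflow
#'
#' Executes joint clumping across the exposures, multi-study harmonization
#' anchored on the first exposure, and the multivariable estimators
#' (MVMR-IVW, MVMR-Egger, MR-Lasso) with the multivariable Cochran Q. When
#' `out_dir` is set, writes estimate- and forest-shaped delimited files and a
#' JSON run report.
#'
#' @param config a [pipeline_config()] with at least two exposures (or a
#'   two-exposure scenario).
#' @return a `run_report` with `estimates` (list of `mvmr_estimate`) and `q`.
#' @export
run_multivariable <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  multi_scenario <- !is.null(config$scenario) &&
    length(config$scenario$theta) == 2L
  if (is.null(config$scenario) && length(config$exposure_paths) < 2L) {
    stop("run_multivariable requires at least two exposures; use ",
         "run_univariable for a single exposure", call. = FALSE)
  }
  if (!is.null(config$scenario) && !multi_scenario) {
    stop("the configured scenario has a single exposure; use ",
         "run_univariable", call. = FALSE)
  }
  st <- load_studies(config, multivariable = TRUE)

  selected <- if (!is.null(st$panel)) {
    clump_joint(st$exposures, st$panel, config$clump)
  } else {
    pooled <- do.call(rbind, lapply(st$exposures, function(e) {
      suppressWarnings(filter_genome_wide(e, config$clump$p_threshold))$data
    }))
    pooled <- pooled[order(pooled$pvalue, pooled$rsid), , drop = FALSE]
    pooled <- pooled[!duplicated(pooled$rsid), , drop = FALSE]
    out <- st$exposures[[1L]]
    out$data <- pooled
    out
  }
  if (nrow(selected$data) == 0L) {
    stop("instrument selection: no variants pass in any exposure",
         call. = FALSE)
  }
  keep_sel <- function(e) {
    out <- e
    out$data <- e$data[e$data$rsid %in% selected$data$rsid, , drop = FALSE]
    out
  }
  mvhd <- harmonize_multi(lapply(st$exposures, keep_sel),
                          keep_sel(st$outcome),
                          config$palindrome_eaf_window)
  j <- length(mvhd$rsids)
  k <- length(mvhd$exposure_labels)
  if (j <= k + 1L) stop("too few harmonized instruments for MVMR",
                        call. = FALSE)

  est_ivw <- mvmr_ivw(mvhd)
  est_egger <- mvmr_egger(mvhd)
  est_lasso <- mr_lasso(mvhd)
  q <- mvmr_q(mvhd)

  report <- structure(list(
    analysis = "multivariable",
    exposure_trait = paste(mvhd$exposure_labels, collapse = "+"),
    outcome_trait = mvhd$outcome_trait,
    n_instruments = nrow(selected$data),
    n_dropped_harmonization = nrow(selected$data) - j,
    n_harmonized = j,
    estimates = list(ivw = est_ivw, egger = est_egger, lasso = est_lasso),
    q = q,
    egger_intercept = list(intercept = est_egger$intercept_estimate,
                           se = est_egger$intercept_se,
                           pvalue = est_egger$intercept_p),
    truth = st$truth, config = config
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_multivariable_outputs(report, config$out_dir)
  }
  report
}

write_multivariable_outputs <- function(report, dir) {
  tab <- do.call(rbind, lapply(report$estimates, function(e) {
    df <- as.data.frame(e)
    data.frame(method = df$method, exposure = df$exposure,
               outcome = report$outcome_trait,
               or_ = fmt3(df$or_), ci_low = fmt3(df$or_ci_low),
               ci_high = fmt3(df$or_ci_high), pvalue = signif(df$pvalue, 3),
               stringsAsFactors = FALSE)
  }))
  write_tsv(tab, dir, "table2_mvmr.tsv")
  write_tsv(tab, dir, "forest_mvmr.tsv")
  lasso <- report$estimates$lasso
  write_tsv(data.frame(lambda = lasso$lasso_lambda,
                       n_retained = lasso$n_retained,
                       n_snps = lasso$n_snps),
            dir, "mr_lasso_tuning.tsv")
  jsonlite::write_json(run_report_json(report),
                       file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Machine-readable full-precision report.
run_report_json <- function(report) {
  est_json <- function(e) {
    if (inherits(e, "mr_estimate")) {
      list(method = e$method, theta = e$theta, se = e$se,
           ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
           or_ = e$or_, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
           n_snps = e$n_snps, model_note = e$model_note)
    } else {
      list(method = e$method, n_snps = e$n_snps,
           q_statistic = e$q_statistic, q_p = e$q_p,
           lasso_lambda = e$lasso_lambda, n_retained = e$n_retained,
           exposures = lapply(e$exposures, est_json))
    }
  }
  out <- list(
    analysis = report$analysis,
    exposure = report$exposure_trait, outcome = report$outcome_trait,
    counts = list(n_significant = report$n_significant,
                  n_instruments = report$n_instruments,
                  n_dropped_harmonization = report$n_dropped_harmonization,
                  n_harmonized = report$n_harmonized,
                  n_presso_outliers = report$n_presso_outliers),
    estimates = lapply(report$estimates, est_json),
    q = list(q_statistic = report$q$q_statistic, df = report$q$df,
             pvalue = report$q$pvalue),
    egger_intercept = report$egger_intercept,
    seed = report$config$seed,
    package_version = as.character(utils::packageVersion("mrflow")))
  if (!is.null(report$strength)) {
    out$strength <- list(r2_total = report$strength$r2_total,
                         f_overall = report$strength$f_overall,
                         f_min = min(report$strength$f_per_snp),
                         k = report$strength$k)
  }
  if (!is.null(report$presso)) {
    out$presso <- list(global_p = report$presso$global_p,
                       n_outliers = length(report$presso$outlier_indices),
                       outlier_rsids = report$presso$outlier_rsids,
                       distortion_p = report$presso$distortion_p,
                       corrected = est_json(report$presso$corrected))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("MR run report (", x$analysis, "): ", x$exposure_trait, " -> ",
      x$outcome_trait, "\n", sep = "")
  cat("  instruments: ", x$n_instruments, " selected, ",
      x$n_harmonized, " harmonized\n", sep = "")
  for (e in x$estimates) {
    if (inherits(e, "mr_estimate")) {
      cat(sprintf("  %-16s OR = %.3f (%.3f-%.3f), p = %.3g\n", e$method,
                  e$or_, e$or_ci_low, e$or_ci_high, e$pvalue))
    } else {
      for (lbl in names(e$exposures)) {
        ee <- e$exposures[[lbl]]
        cat(sprintf("  %-10s %-12s OR = %.3f (%.3f-%.3f), p = %.3g\n",
                    e$method, lbl, ee$or_, ee$or_ci_low, ee$or_ci_high,
                    ee$pvalue))
      }
    }
  }
  invisible(x)
}
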