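#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown keys are rejected.
#' Either `simulation` (a [sim_config()]) or `assessments_csv` (a long-form
#' CSV path) supplies the input data; `fixture = TRUE` instead runs the
#' screening stage on the deterministic published-marginal fixture.
#'
#' @param simulation Optional [sim_config()].
#' @param assessments_csv Optional path to a long-form assessment CSV.
#' @param fixture Use [fixture_analysis_rows()] as input (screening and
#'   calibration stages only make sense with real joint structure; the
#'   fixture serves screening regression tests).
#' @param rules Named list of site [treatment_rule()]s for CSV inputs.
#' @param validation_cohort Cohort id held out for external validation
#'   (`NULL` to skip validation).
#' @param p_enter,p_remove,entry_test,firth Stepwise options (see
#'   [forward_stepwise()]).
#' @param tremor_mode `"any"` (single combined tremor indicator, default) or
#'   `"separate"` (see [tremor_parameterization()]).
#' @param pp_threshold Heterogeneity filter threshold in percentage points.
#' @param seed Seed recorded and used for any simulation.
#' @return List of class `nas_pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, assessments_csv = NULL,
                            fixture = FALSE, rules = default_site_rules(),
                            validation_cohort = "mother",
                            p_enter = 0.10, p_remove = 0.05,
                            entry_test = "lr", firth = FALSE,
                            tremor_mode = "any",
                            pp_threshold = 50, seed = 1L) {
  tremor_mode <- match.arg(tremor_mode, c("any", "separate"))
  n_src <- (!is.null(simulation)) + (!is.null(assessments_csv)) +
    isTRUE(fixture)
  if (n_src != 1) {
    stop("exactly one of simulation / assessments_csv / fixture must be set",
         call. = FALSE)
  }
  if (!is.null(simulation) && !inherits(simulation, "nas_sim_config")) {
    stop("simulation must be a sim_config()", call. = FALSE)
  }
  structure(list(simulation = simulation, assessments_csv = assessments_csv,
                 fixture = isTRUE(fixture), rules = rules,
                 validation_cohort = validation_cohort,
                 p_enter = p_enter, p_remove = p_remove,
                 entry_test = entry_test, firth = isTRUE(firth),
                 tremor_mode = tremor_mode,
                 pp_threshold = pp_threshold, seed = as.integer(seed)),
            class = "nas_pipeline_config")
}

#' Run the full derivation pipeline
#'
#' Sequences the stages end to end: obtain assessment data (simulate, read,
#' or fixture), extract one analysis row per neonate, screen the binary
#' signs across derivation cohorts, forward stepwise selection of signs
#' associated with treatment (cohort forced in), calibrate simplified-scale
#' cutpoints by weighted kappa, and validate the selected signs on the
#' held-out cohort.  All stage reports are written under `out_dir` along
#' with a machine-readable `summary.json` and a plain-text log recording the
#' options used; re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with elements `analysis`, `screen`,
#'   `univariate`, `stepwise`, `calibration`, `validation` (NULL when
#'   skipped), `summary`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "nas_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logfile, append = TRUE)
  }
  cat("", file = logfile)  # truncate
  logmsg("fnast8 pipeline | package %s | R %s",
         as.character(utils::packageVersion("fnast8")),
         paste(R.version$major, R.version$minor, sep = "."))
  logmsg("seed=%d p_enter=%g p_remove=%g entry_test=%s firth=%s pp_threshold=%g",
         config$seed, config$p_enter, config$p_remove, config$entry_test,
         config$firth, config$pp_threshold)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input data -> analysis rows -------------------------------------
  analysis <- stage("extract", {
    if (config$fixture) {
      logmsg("input: deterministic published-marginal fixture")
      fixture_analysis_rows(include_validation = TRUE)
    } else if (!is.null(config$simulation)) {
      logmsg("input: synthetic simulation (seed %d)",
             config$simulation$seed)
      sim <- simulate_cohorts(config$simulation)
      write_assessments(sim$assessments,
                        file.path(out_dir, "assessments.csv"))
      con <- file(file.path(out_dir, "truth.jsonl"), "w")
      for (i in seq_len(nrow(sim$truth))) {
        writeLines(jsonlite::toJSON(as.list(sim$truth[i, ]),
                                    auto_unbox = TRUE, digits = NA, na = "null"), con)
      }
      close(con)
      sim$analysis
    } else {
      logmsg("input: %s", config$assessments_csv)
      assess <- read_assessments(config$assessments_csv)
      extract_analysis_rows(assess, rules = config$rules)
    }
  })
  write_analysis_rows(analysis, file.path(out_dir, "analysis_rows.csv"))
  logmsg("analysis rows: %d neonates, %d treated", nrow(analysis),
         sum(analysis$treated))

  deriv <- analysis[analysis$cohort_id != (config$validation_cohort %||% ""), ]
  valid <- if (!is.null(config$validation_cohort)) {
    analysis[analysis$cohort_id == config$validation_cohort, ]
  } else {
    data.frame()
  }

  # --- screening --------------------------------------------------------
  screen <- stage("screen", screen_items(deriv, config$pp_threshold))
  scr_out <- screen
  scr_out$chi2_p_printed <- format_pvalue(scr_out$chi2_p)
  utils::write.csv(scr_out, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  candidates <- attr(screen, "candidates")
  logmsg("screening: excluded [%s]; %d candidates",
         paste(names(attr(screen, "excluded")), collapse = ", "),
         length(candidates))

  # --- selection --------------------------------------------------------
  univ <- stage("univariate", univariate_item_models(deriv, candidates))
  utils::write.csv(univ, file.path(out_dir, "univariate.csv"),
                   row.names = FALSE)
  tp <- tremor_parameterization(deriv, candidates,
                                mode = config$tremor_mode)
  sw <- stage("stepwise",
              forward_stepwise(tp$rows, tp$candidates,
                               p_enter = config$p_enter,
                               p_remove = config$p_remove,
                               entry_test = config$entry_test,
                               firth = config$firth))
  utils::write.csv(sw$trace, file.path(out_dir, "stepwise_trace.csv"),
                   row.names = FALSE)
  wt <- wald_tests(sw$fit)
  wt$or <- exp(wt$estimate)
  wt$or_lo <- exp(wt$estimate - 1.96 * wt$se)
  wt$or_hi <- exp(wt$estimate + 1.96 * wt$se)
  wt$p_printed <- format_pvalue(wt$p)
  utils::write.csv(wt, file.path(out_dir, "model.csv"), row.names = FALSE)
  logmsg("stepwise: selected [%s]; model AUC %.4f",
         paste(sw$selected, collapse = ", "), sw$auc)

  # --- calibration ------------------------------------------------------
  calib <- stage("calibrate",
                 select_thresholds(deriv$original_score,
                                   deriv$simplified_score))
  utils::write.csv(calib$grid, file.path(out_dir, "kappa_grid.csv"),
                   row.names = FALSE)
  ct <- as.data.frame.matrix(calib$crosstab)
  ct <- cbind(original = rownames(ct), ct,
              total = rowSums(calib$crosstab))
  utils::write.csv(ct, file.path(out_dir, "crosstab.csv"),
                   row.names = FALSE)
  logmsg("calibration: thresholds (%d, %d), weighted kappa %.4f",
         calib$thresholds[1], calib$thresholds[2], calib$kappa)

  # --- external validation ---------------------------------------------
  validation <- NULL
  if (nrow(valid) > 0 && length(sw$selected) > 0) {
    if ("any_tremors" %in% sw$selected) {
      valid$any_tremors <- as.integer(valid$tremors_disturbed |
                                        valid$tremors_undisturbed)
    }
    validation <- stage("validate", validate_external(valid, sw$selected))
    logmsg("validation (%s, n=%d): AUC %.4f [%.4f, %.4f]",
           config$validation_cohort, validation$n, validation$auc,
           validation$ci[1], validation$ci[2])
  } else {
    logmsg("validation stage skipped (no validation cohort or empty model)")
  }

  summary <- list(
    seed = config$seed,
    n = nrow(analysis),
    n_derivation = nrow(deriv),
    excluded_items = as.list(attr(screen, "excluded")),
    candidates = candidates,
    selected_items = sw$selected,
    model_auc = sw$auc,
    thresholds = as.list(calib$thresholds),
    weighted_kappa = calib$kappa,
    weighted_kappa_ci = calib$ci,
    validation_auc = if (is.null(validation)) NULL else validation$auc,
    validation_ci = if (is.null(validation)) NULL else validation$ci,
    options = list(p_enter = config$p_enter, p_remove = config$p_remove,
                   entry_test = config$entry_test, firth = config$firth,
                   pp_threshold = config$pp_threshold)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done")
  invisible(list(analysis = analysis, screen = screen, univariate = univ,
                 stepwise = sw, calibration = calib,
                 validation = validation, summary = summary,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
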