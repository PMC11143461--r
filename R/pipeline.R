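run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full external-validation pipeline
#'
#' Sequences every analysis stage on one cohort: feature extraction,
#' risk scoring, discrimination (overall, by year, by sex) and decile
#' calibration, model updating on a temporal split (intercept
#' recalibration and full refit, compared on the held-out years),
#' serious-illness flagging (with and without the age criterion),
#' screening test characteristics (all encounters and first visits only),
#' decision-curve net benefit, Kaplan-Meier survival on first encounters,
#' and the serious-illness-by-risk misclassification cross-tab.  Any stage
#' failure aborts with the stage name and cause.  With `out_dir` set, all
#' result tables are written as tab-separated text, updated model
#' specifications as JSON, and a `run_manifest.json` captures the
#' configuration so a run can be reproduced exactly.
#'
#' @param cohort A `synthetic_cohort` (or table list in the same format);
#'   omit to simulate one from `sim_config`.
#' @param sim_config A [cohort_config()] used when `cohort` is missing.
#' @param model A [gest_model()]; default is the shipped synthetic
#'   placeholder specification.
#' @param out_dir Optional output directory for the report bundle.
#' @param thresholds Screening cutoffs, default `c(0.05, 0.1, 0.2, 0.3)`.
#' @param dca_grid Decision-curve threshold grid.
#' @param horizon Days defining 6 months (default 183).
#' @param train_years,test_years Temporal split for model updating.
#' @param window_minutes Vital-sign extraction window.
#' @param si_catalog Serious-illness prefix catalog.
#' @param seed Optional seed applied before simulation.
#' @return Object of class `gest_report`: named list of stage results.
#' @export
run_pipeline <- function(cohort = NULL, sim_config = NULL,
                         model = gest_model_synthetic(), out_dir = NULL,
                         thresholds = c(0.05, 0.1, 0.2, 0.3),
                         dca_grid = seq(0.01, 0.50, by = 0.01),
                         horizon = 183,
                         train_years = 2017:2018, test_years = 2019:2021,
                         window_minutes = 240,
                         si_catalog = default_serious_illness_catalog(),
                         seed = NULL) {
  if (!inherits(model, "gest_model")) {
    stop("stage 'risk_model' failed: no valid model specification supplied",
         call. = FALSE)
  }
  if (is.null(cohort)) {
    cohort <- run_stage("simulate", {
      if (is.null(sim_config)) stop("neither a cohort nor a sim_config given")
      if (!is.null(seed)) {
        sim_config$seed <- as.integer(seed)
      }
      generate_cohort(sim_config)
    })
  }
  censor_date <- if (inherits(cohort$config, "cohort_config")) {
    cohort$config$censor_date
  } else {
    max(cohort$encounters$arrival_date) + horizon
  }

  features <- run_stage("extract", {
    extract_features(cohort, window_minutes = window_minutes)
  })
  scores <- run_stage("score", predict(model, features, type = "response"))
  labels <- run_stage("outcomes", {
    six_month_labels(cohort$encounters, cohort$outcomes, horizon = horizon)
  })

  validation <- run_stage("validate", {
    list(overall = auroc_delong(scores, labels),
         by_year = stratified_auroc(scores, labels, features$year),
         by_sex = stratified_auroc(scores, labels, features$sex),
         calibration = calibration_bins(scores, labels, bins = 10))
  })

  update <- run_stage("update", {
    tr <- features$year %in% train_years
    te <- features$year %in% test_years
    if (!any(tr) || !any(te) ||
        length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L) {
      list(skipped = TRUE,
           reason = "temporal split lacks records or outcome classes")
    } else {
      recal <- recalibrate_intercept(model, features[tr, ], labels[tr])
      refitted <- refit(model, features[tr, ], labels[tr])
      list(skipped = FALSE, recalibrated = recal, refitted = refitted,
           delta = attr(recal, "delta"),
           comparison = compare_updates(model, recal, refitted,
                                        features[te, ], labels[te]))
    }
  })

  si <- run_stage("serious_illness", {
    list(with_age = flag_serious_illness(cohort$encounters,
                                         cohort$diagnoses, si_catalog),
         no_age = flag_serious_illness(cohort$encounters, cohort$diagnoses,
                                       si_catalog, include_age = FALSE))
  })

  first_enc <- first_encounter_filter(cohort$encounters)
  first_idx <- match(first_enc$encounter_id, cohort$encounters$encounter_id)

  screening <- run_stage("screen", {
    list(all = characteristics_table(scores, si$with_age$flagged, labels,
                                     thresholds),
         first_visit = characteristics_table(
           scores[first_idx], si$with_age$flagged[first_idx],
           labels[first_idx], thresholds),
         no_age = characteristics_table(scores, si$no_age$flagged, labels,
                                        thresholds,
                                        binary_label = "serious_illness_no_age"))
  })

  dca <- run_stage("dca", {
    decision_curve_analysis(scores, si$with_age$flagged, labels, dca_grid)
  })

  surv <- run_stage("survival", {
    fu <- encounter_survival(first_enc, cohort$outcomes, censor_date)
    stratified_km(fu$time, fu$event, scores[first_idx],
                  si$with_age$flagged[first_idx], horizon = horizon)
  })

  crosstab <- run_stage("crosstab", {
    misclassification_crosstab(si$with_age$flagged, scores, labels)
  })

  report <- structure(
    list(features = features, scores = scores, labels = labels,
         validation = validation, update = update, serious_illness = si,
         screening = screening, decision_curves = dca, survival = surv,
         crosstab = crosstab,
         settings = list(thresholds = thresholds, horizon = horizon,
                         window_minutes = window_minutes,
                         train_years = train_years, test_years = test_years,
                         censor_date = censor_date, seed = seed)),
    class = "gest_report")
  if (!is.null(out_dir)) {
    run_stage("write_bundle", write_report_bundle(report, model, out_dir))
  }
  report
}

# flatten a list of km curves into one long table
km_curves_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(stratum = attr(cv, "stratum"), time = cv$time,
               n_risk = cv$n_risk, n_event = cv$n_event,
               n_censor = cv$n_censor, survival = cv$survival,
               stringsAsFactors = FALSE)
  }))
}

write_report_bundle <- function(report, model, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, nm) {
    utils::write.table(df, file.path(out_dir, nm), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$screening$all, "characteristics.tsv")
  wt(report$screening$first_visit, "characteristics_first_visit.tsv")
  wt(report$screening$no_age, "characteristics_no_age.tsv")
  disc <- rbind(
    data.frame(stratum = "overall", auroc = report$validation$overall$auroc,
               ci_low = report$validation$overall$ci[1],
               ci_high = report$validation$overall$ci[2],
               n_cases = report$validation$overall$n_cases,
               n_controls = report$validation$overall$n_controls,
               skipped = FALSE, stringsAsFactors = FALSE),
    report$validation$by_year, report$validation$by_sex)
  wt(disc, "discrimination.tsv")
  wt(as.data.frame(report$validation$calibration), "calibration.tsv")
  wt(as.data.frame(report$decision_curves), "decision_curves.tsv")
  wt(km_curves_table(report$survival), "survival.tsv")
  wt(report$crosstab$table, "crosstab.tsv")
  write_gest_model(model, file.path(out_dir, "model_original.json"))
  if (!isTRUE(report$update$skipped)) {
    write_gest_model(report$update$recalibrated,
                     file.path(out_dir, "model_recalibrated.json"))
    write_gest_model(report$update$refitted,
                     file.path(out_dir, "model_refit.json"))
    wt(report$update$comparison$summary, "update_comparison.tsv")
  }
  jsonlite::write_json(
    c(report$settings[c("thresholds", "horizon", "window_minutes",
                        "train_years", "test_years")],
      list(censor_date = format(report$settings$censor_date),
           seed = report$settings$seed, model = model$name,
           gestval_version = as.character(utils::packageVersion("gestval")))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.gest_report <- function(x, ...) {
  cat("External-validation report\n")
  cat(sprintf("  encounters: %d (%d deaths within horizon)\n",
              length(x$labels), sum(x$labels)))
  print(x$validation$overall)
  cat(sprintf("  serious illness prevalence: %.1f%%\n",
              100 * mean(x$serious_illness$with_age$flagged)))
  cat(sprintf("  discordant share (SI vs model risk): %.1f%%\n",
              100 * x$crosstab$discordant_share))
  invisible(x)
}
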