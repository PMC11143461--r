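#' Configuration for the synthetic ED cohort generator
#'
#' The defaults emulate the study conditions the analysis assumes: patients
#' aged 65+ (age roughly truncated-normal, mean 77, SD 8), repeat visits
#' with a geometric count (mean ~2 visits/patient), a 2017-2021 study
#' window, a 6-month mortality prevalence of 13.8% (the generator tunes
#' the outcome-model intercept by bisection to hit it), and mortality
#' ascertainment through an administrative censoring date after the window.
#'
#' @param n_patients Number of patients (positive integer).
#' @param visits_mean Mean ED visits per patient (>= 1; geometric count).
#' @param study_start,study_end Calendar window of arrivals.
#' @param censor_date Last date with reliable mortality data; must be on or
#'   after `study_end`.
#' @param true_model [gest_model()] used to assign outcomes (its intercept
#'   is retuned to `target_prevalence`).
#' @param target_prevalence Target first-visit 6-month mortality in (0, 1).
#' @param severity_loading Loading in [0, 1) of the single latent severity
#'   factor on the covariates (the generator's dependence structure).
#' @param late_death_fraction Fraction of 6-month survivors who die later,
#'   so administrative censoring is exercised.
#' @param missingness Named per-covariate missingness probabilities in
#'   [0, 1] (lab and vital covariates only).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          visits_mean = 2,
                          study_start = as.Date("2017-01-01"),
                          study_end = as.Date("2021-12-31"),
                          censor_date = as.Date("2022-12-31"),
                          true_model = gest_model_synthetic(),
                          target_prevalence = 0.138,
                          severity_loading = 0.45,
                          late_death_fraction = 0.25,
                          missingness = default_missingness_rates(),
                          seed = 1L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1,
            visits_mean >= 1,
            inherits(study_start, "Date"), inherits(study_end, "Date"),
            inherits(censor_date, "Date"))
  if (study_start >= study_end) stop("study_window start must precede end")
  if (censor_date < study_end) {
    stop("censor_date must be on or after the study window end")
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must lie in (0, 1)")
  }
  if (severity_loading < 0 || severity_loading >= 1) {
    stop("severity_loading must lie in [0, 1)")
  }
  if (late_death_fraction < 0 || late_death_fraction > 1) {
    stop("late_death_fraction must lie in [0, 1]")
  }
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness rates must lie in [0, 1]")
  }
  stopifnot(inherits(true_model, "gest_model"))
  structure(list(n_patients = as.integer(n_patients),
                 visits_mean = visits_mean,
                 study_start = study_start, study_end = study_end,
                 censor_date = censor_date, true_model = true_model,
                 target_prevalence = target_prevalence,
                 severity_loading = severity_loading,
                 late_death_fraction = late_death_fraction,
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-covariate missingness rates
#'
#' Placeholder rates for the lab and vital covariates (per-covariate
#' missingness of real cohorts is institution-specific; replace with local
#' values when known).
#'
#' @return Named numeric vector of probabilities.
#' @export
default_missingness_rates <- function() {
  c(hemoglobin = 0.05, hematocrit = 0.05, blood_urea_nitrogen = 0.06,
    red_cell_distribution_width = 0.08, lymphocyte_count = 0.08,
    mean_corpuscular_volume = 0.05, mean_heart_rate = 0.02,
    min_systolic_bp = 0.02, supplemental_oxygen = 0.10)
}

# code pools the generator draws from, per diagnosis category
DX_POOLS <- list(
  dx_secondary_cancer = c("C77.0", "C78.0", "C78.7", "C79.31", "C79.51"),
  dx_cognitive_disorder = c("F01.50", "F03.90", "F05", "G30.9", "R41.0"),
  dx_lung_cancer = c("C34.10", "C34.90"),
  dx_pancreatic_cancer = c("C25.0", "C25.9"),
  stroke_tia = c("I63.9", "I61.9", "G45.9"),
  liver_disease = c("K70.30", "K74.60", "K76.0"),
  hip_fracture = c("S72.001A", "S72.90"),
  cancer = c("C18.9", "C50.911", "C61", "C16.9"),
  heart_disease = c("I50.9", "I50.23", "I42.9"),
  lung_disease = c("J44.9", "J44.1", "J96.10", "J84.10"),
  neurodegenerative_disease = c("G20", "G12.21", "G35"),
  diabetes_with_pvd = c("E11.51", "E10.51"),
  coronary_artery_disease = c("I25.10", "I25.110"),
  chronic_kidney_disease = c("N18.3", "N18.4"),
  hiv_aids = c("B20"),
  kidney_failure = c("N17.9", "N19"))

# baseline log-odds of carrying each diagnosis category (severity tilts it)
DX_BASE_LOGIT <- c(
  dx_secondary_cancer = -3.3, dx_cognitive_disorder = -2.7,
  dx_lung_cancer = -3.9, dx_pancreatic_cancer = -4.8,
  stroke_tia = -4.0, liver_disease = -3.7, hip_fracture = -5.1,
  cancer = -2.9, heart_disease = -2.1, lung_disease = -2.2,
  neurodegenerative_disease = -7.0, diabetes_with_pvd = -2.7,
  coronary_artery_disease = -2.9, chronic_kidney_disease = -3.0,
  hiv_aids = -5.8, kidney_failure = -3.6)

# bisection for the outcome-model intercept hitting the target prevalence
tune_intercept <- function(eta0, target, lo = -30, hi = 30) {
  f <- function(b) mean(stats::plogis(b + eta0)) - target
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target_prevalence ", target, " unreachable: intercept search ",
         "bounds [", lo, ", ", hi, "] do not bracket it (coefficient scale?)")
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a seeded synthetic ED cohort
#'
#' Builds the five relational tables the analysis pipeline consumes:
#' encounters, long-format vitals and labs, dated diagnoses, prior
#' admissions, plus a per-patient outcome table.  Mechanism: one latent
#' severity factor per patient loads on all covariates; per-visit values
#' are redrawn around patient-level anchors; 6-month death is Bernoulli
#' with the probability the `true_model` assigns to the extracted
#' first-visit features (intercept tuned by bisection so the mean
#' probability equals `target_prevalence`); deaths within 6 months get a
#' death date uniform on 1..183 days after first arrival, and a configured
#' fraction of survivors die later so right-censoring is exercised.
#' Missingness is injected last via [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list of tables
#'   (`encounters`, `vitals`, `labs`, `diagnoses`, `admissions`,
#'   `outcomes`), the `config`, and `tuned_intercept`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  lam <- config$severity_loading
  ortho <- sqrt(1 - lam^2)
  sev <- stats::rnorm(n)
  mix <- function(direction = 1) direction * lam * sev + ortho * stats::rnorm(n)

  ## patient-level anchors
  lo_u <- stats::pnorm((65 - 77) / 8); hi_u <- stats::pnorm((105 - 77) / 8)
  age <- 77 + 8 * stats::qnorm(stats::runif(n, lo_u, hi_u))
  hgb <- 12.5 + 1.8 * mix(-1)
  hct <- 3 * hgb + stats::rnorm(n, 0, 1.5)
  bun <- exp(log(18) + 0.45 * mix(1))
  rdw <- pmax(11, 14.2 + 1.8 * mix(1))
  lymph <- exp(log(1.4) + 0.4 * mix(-1))
  mcv <- 90 + 5.5 * stats::rnorm(n)
  hr <- 84 + 13 * mix(1)
  sbp <- pmax(60, 132 + 19 * mix(-1))
  o2p <- stats::plogis(-2.2 + 1.2 * sev)
  adm_lambda <- exp(-0.6 + 0.7 * sev)
  sex <- sample(c("F", "M"), n, TRUE, prob = c(0.543, 0.457))
  pat_id <- sprintf("P%06d", seq_len(n))

  ## visit skeleton
  nv <- pmin(1L + stats::rgeom(n, 1 / config$visits_mean), 12L)
  window_days <- as.integer(config$study_end - config$study_start)
  first_off <- floor(stats::runif(n) * (window_days - 1))
  pid <- rep(seq_len(n), nv)
  ne <- length(pid)
  visit_no <- sequence(nv)
  gaps <- ifelse(visit_no == 1L, 0, stats::rexp(ne, 1 / 90))
  offs <- round(first_off[pid] + stats::ave(gaps, pid, FUN = cumsum))
  keep <- offs <= window_days
  pid <- pid[keep]; visit_no <- visit_no[keep]; offs <- offs[keep]
  ne <- length(pid)
  arrival <- config$study_start + offs
  enc_id <- sprintf("E%07d", seq_len(ne))

  ## per-visit covariate values around the anchors
  age_v <- age[pid] + (offs - first_off[pid]) / 365.25
  hgb_v <- hgb[pid] + 0.6 * stats::rnorm(ne)
  hct_v <- hct[pid] + 1.8 * stats::rnorm(ne)
  bun_v <- bun[pid] * exp(0.15 * stats::rnorm(ne))
  rdw_v <- rdw[pid] + 0.4 * stats::rnorm(ne)
  lymph_v <- lymph[pid] * exp(0.15 * stats::rnorm(ne))
  mcv_v <- mcv[pid] + 1.5 * stats::rnorm(ne)
  hr_v <- hr[pid] + 5 * stats::rnorm(ne)
  sbp_v <- sbp[pid] + 7 * stats::rnorm(ne)
  o2_v <- stats::runif(ne) < o2p[pid]
  ed_dx_v <- stats::runif(ne) < 0.03

  encounters <- data.frame(
    encounter_id = enc_id, patient_id = pat_id[pid],
    arrival_date = arrival, age = round(age_v, 1), sex = sex[pid],
    stringsAsFactors = FALSE)

  ## vitals: 3 HR + 3 SBP observations and 1 oxygen-device row per visit
  vit_rep <- rep(seq_len(ne), each = 3L)
  vitals <- rbind(
    data.frame(encounter_id = enc_id[vit_rep], vital = "heart_rate",
               offset_minutes = floor(stats::runif(3 * ne) * 236),
               value = round(hr_v[vit_rep] + 4 * stats::rnorm(3 * ne))),
    data.frame(encounter_id = enc_id[vit_rep], vital = "systolic_bp",
               offset_minutes = floor(stats::runif(3 * ne) * 236),
               value = round(sbp_v[vit_rep] + 6 * stats::rnorm(3 * ne))),
    data.frame(encounter_id = enc_id, vital = "o2_device",
               offset_minutes = floor(stats::runif(ne) * 240),
               value = as.numeric(o2_v)))

  ## labs: one resulted value per analyte, occasionally a later repeat
  lab_vals <- list(hemoglobin = round(hgb_v, 1), hematocrit = round(hct_v, 1),
                   blood_urea_nitrogen = round(bun_v),
                   red_cell_distribution_width = round(rdw_v, 1),
                   lymphocyte_count = round(lymph_v, 2),
                   mean_corpuscular_volume = round(mcv_v))
  labs <- do.call(rbind, lapply(names(lab_vals), function(a) {
    data.frame(encounter_id = enc_id, analyte = a,
               offset_minutes = 10 + floor(stats::runif(ne) * 230),
               value = lab_vals[[a]], stringsAsFactors = FALSE)
  }))
  rep_rows <- which(stats::runif(nrow(labs)) < 0.25)
  if (length(rep_rows)) {
    repeats <- labs[rep_rows, ]
    repeats$offset_minutes <- 241 + floor(stats::runif(length(rep_rows)) * 360)
    repeats$value <- repeats$value * exp(0.05 * stats::rnorm(length(rep_rows)))
    labs <- rbind(labs, repeats)
  }

  ## diagnosis histories (patient-level) and index-encounter ED diagnoses
  dx_rows <- lapply(names(DX_POOLS), function(nm) {
    ## chronic-disease carriage rises with severity and with age
    carrier <- which(stats::runif(n) <
                       stats::plogis(DX_BASE_LOGIT[[nm]] + 0.6 * sev +
                                       0.02 * (age - 77)))
    if (!length(carrier)) return(NULL)
    recent <- data.frame(
      patient_id = pat_id[carrier], encounter_id = NA_character_,
      code = sample(DX_POOLS[[nm]], length(carrier), TRUE),
      date = config$study_start + first_off[carrier] -
        sample(500L, length(carrier), TRUE),
      stringsAsFactors = FALSE)
    old_idx <- which(stats::runif(length(carrier)) < 0.3)
    old <- if (length(old_idx)) data.frame(
      patient_id = pat_id[carrier[old_idx]], encounter_id = NA_character_,
      code = sample(DX_POOLS[[nm]], length(old_idx), TRUE),
      date = config$study_start + first_off[carrier[old_idx]] -
        sample(400:900, length(old_idx), TRUE),
      stringsAsFactors = FALSE) else NULL
    rbind(recent, old)
  })
  ed_idx <- which(ed_dx_v)
  ed_rows <- if (length(ed_idx)) data.frame(
    patient_id = pat_id[pid[ed_idx]], encounter_id = enc_id[ed_idx],
    code = sample(c("R55", "I63.9", "G45.9"), length(ed_idx), TRUE),
    date = arrival[ed_idx], stringsAsFactors = FALSE) else NULL
  diagnoses <- do.call(rbind, c(dx_rows, list(ed_rows)))
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(),
                            encounter_id = character(), code = character(),
                            date = as.Date(character()),
                            stringsAsFactors = FALSE)
  }
  rownames(diagnoses) <- NULL

  ## prior admissions: recent (past-year) and older
  k_recent <- stats::rpois(n, adm_lambda)
  k_old <- stats::rpois(n, 0.3)
  admissions <- rbind(
    data.frame(patient_id = rep(pat_id, k_recent),
               admit_date = config$study_start + rep(first_off, k_recent) -
                 sample(365L, sum(k_recent), TRUE)),
    data.frame(patient_id = rep(pat_id, k_old),
               admit_date = config$study_start + rep(first_off, k_old) -
                 sample(366:1000, sum(k_old), TRUE)))

  ## outcomes: Bernoulli 6-month death from the tuned true model
  cohort0 <- list(encounters = encounters, vitals = vitals, labs = labs,
                  diagnoses = diagnoses, admissions = admissions)
  first_idx <- which(visit_no == 1L)
  feats <- extract_features(cohort0)
  z <- impute_and_standardize(feats[first_idx, , drop = FALSE],
                              config$true_model)$z
  eta0 <- drop(z %*% config$true_model$covariates$coefficient)
  b0 <- tune_intercept(eta0, config$target_prevalence)
  p_death <- stats::plogis(b0 + eta0)
  died6 <- stats::rbinom(n, 1L, p_death) == 1L
  first_arrival <- config$study_start + first_off
  death_date <- rep(as.Date(NA), n)
  death_date[died6] <- first_arrival[died6] + sample(183L, sum(died6), TRUE)
  late <- !died6 & stats::runif(n) < config$late_death_fraction
  death_date[late] <- first_arrival[late] + 183L +
    ceiling(stats::rexp(sum(late), 1 / 420))
  death_date[!is.na(death_date) & death_date > config$censor_date] <-
    as.Date(NA)
  outcomes <- data.frame(patient_id = pat_id, death_date = death_date,
                         stringsAsFactors = FALSE)

  ## drop visits on/after the death date, and their linked rows
  dd_enc <- death_date[pid]
  keep_enc <- is.na(dd_enc) | arrival < dd_enc
  kept_ids <- enc_id[keep_enc]
  cohort <- structure(list(
    encounters = encounters[keep_enc, , drop = FALSE],
    vitals = vitals[vitals$encounter_id %in% kept_ids, , drop = FALSE],
    labs = labs[labs$encounter_id %in% kept_ids, , drop = FALSE],
    diagnoses = diagnoses[is.na(diagnoses$encounter_id) |
                            diagnoses$encounter_id %in% kept_ids, ,
                          drop = FALSE],
    admissions = admissions, outcomes = outcomes,
    config = config, tuned_intercept = b0), class = "synthetic_cohort")
  for (nm in c("encounters", "vitals", "labs", "diagnoses")) {
    rownames(cohort[[nm]]) <- NULL
  }
  inject_missingness(cohort, config$missingness)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic ED cohort: %d patients, %d encounters (%s to %s), seed %d\n",
    x$config$n_patients, nrow(x$encounters),
    format(x$config$study_start), format(x$config$study_end),
    x$config$seed))
  cat(sprintf("  deaths known by %s: %d\n", format(x$config$censor_date),
              sum(!is.na(x$outcomes$death_date))))
  invisible(x)
}

# vital-table names behind the derived vital covariates
VITAL_NAME_MAP <- c(mean_heart_rate = "heart_rate",
                    min_systolic_bp = "systolic_bp",
                    supplemental_oxygen = "o2_device")

#' Blank covariate measurements at stated rates
#'
#' For every named covariate, each encounter's measurements of it are
#' independently removed with the stated probability (rows dropped from
#' the long vitals/labs tables, so the covariate extracts as absent).
#' Only lab and vital covariates can be blanked.
#'
#' @param cohort A `synthetic_cohort`.
#' @param rates Named per-covariate probabilities in [0, 1].
#' @param seed Optional seed (omit to continue the current RNG stream).
#' @return The cohort with rows removed.
#' @export
inject_missingness <- function(cohort, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  lab_covs <- c("hemoglobin", "hematocrit", "blood_urea_nitrogen",
                "red_cell_distribution_width", "lymphocyte_count",
                "mean_corpuscular_volume")
  unknown <- setdiff(names(rates), c(lab_covs, names(VITAL_NAME_MAP)))
  if (length(unknown)) {
    stop("unknown covariate name(s) in missingness rates: ",
         paste(unknown, collapse = ", "),
         " (blankable: ", paste(c(lab_covs, names(VITAL_NAME_MAP)),
                                collapse = ", "), ")")
  }
  enc_ids <- cohort$encounters$encounter_id
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r == 0) next
    drop_enc <- enc_ids[stats::runif(length(enc_ids)) < r]
    if (nm %in% lab_covs) {
      kill <- cohort$labs$analyte == nm & cohort$labs$encounter_id %in% drop_enc
      cohort$labs <- cohort$labs[!kill, , drop = FALSE]
    } else {
      vt <- VITAL_NAME_MAP[[nm]]
      kill <- cohort$vitals$vital == vt &
        cohort$vitals$encounter_id %in% drop_enc
      cohort$vitals <- cohort$vitals[!kill, , drop = FALSE]
    }
  }
  rownames(cohort$labs) <- NULL
  rownames(cohort$vitals) <- NULL
  cohort
}

#' Binary 6-month mortality labels for encounters
#'
#' @param encounters Encounter table.
#' @param outcomes Outcome table (`patient_id`, `death_date`).
#' @param horizon Days defining "6 months" (default 183).
#' @return Logical vector aligned with `encounters`.
#' @export
six_month_labels <- function(encounters, outcomes, horizon = 183) {
  death <- outcomes$death_date[match(encounters$patient_id,
                                     outcomes$patient_id)]
  !is.na(death) & as.numeric(death - encounters$arrival_date) <= horizon
}

#' Write a cohort's tables as delimited text
#'
#' Tab-separated files with a header row, ISO-8601 dates, plus a
#' `manifest.json` recording the generating configuration and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("encounters", "vitals", "labs", "diagnoses", "admissions",
               "outcomes")) {
    utils::write.table(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- cohort$config
  jsonlite::write_json(
    list(n_patients = cfg$n_patients, visits_mean = cfg$visits_mean,
         study_start = format(cfg$study_start),
         study_end = format(cfg$study_end),
         censor_date = format(cfg$censor_date),
         target_prevalence = cfg$target_prevalence,
         severity_loading = cfg$severity_loading,
         late_death_fraction = cfg$late_death_fraction,
         missingness = as.list(cfg$missingness), seed = cfg$seed,
         true_model = cfg$true_model$name,
         tuned_intercept = cohort$tuned_intercept,
         gestval_version = as.character(utils::packageVersion("gestval"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory holding the `.tsv` tables.
#' @return List of tables (class `synthetic_cohort`; `config` is the
#'   manifest as a plain list).
#' @export
read_cohort <- function(dir) {
  rd <- function(nm, date_cols = character()) {
    df <- utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = NA)
    for (dc in date_cols) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  manifest_path <- file.path(dir, "manifest.json")
  structure(list(
    encounters = rd("encounters", "arrival_date"),
    vitals = rd("vitals"), labs = rd("labs"),
    diagnoses = rd("diagnoses", "date"),
    admissions = rd("admissions", "admit_date"),
    outcomes = rd("outcomes", "death_date"),
    config = if (file.exists(manifest_path)) {
      jsonlite::fromJSON(manifest_path)
    }), class = "synthetic_cohort")
}
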