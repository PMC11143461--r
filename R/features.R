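#' Read an ICD-10 prefix catalog from a YAML file
#'
#' A catalog maps category names to vectors of ICD-10 code prefixes
#' (uppercase alphanumeric, optional dot).  A code belongs to a category
#' when it starts with any of the category's prefixes.
#'
#' @param path YAML file of `category: [prefix, ...]` entries.
#' @return Named list of character vectors.
#' @export
read_diagnosis_catalog <- function(path) {
  cat_list <- yaml::read_yaml(path)
  if (length(cat_list) == 0L) stop("empty diagnosis catalog: ", path)
  cat_list <- lapply(cat_list, as.character)
  empty <- vapply(cat_list, length, 1L) == 0L
  if (any(empty)) {
    stop("catalog categories without prefixes: ",
         paste(names(cat_list)[empty], collapse = ", "))
  }
  bad <- unlist(cat_list)[!grepl("^[A-Z0-9.]+$", unlist(cat_list))]
  if (length(bad) > 0L) {
    stop("malformed catalog prefix(es): ", paste(bad, collapse = ", "))
  }
  cat_list
}

#' Default catalog for the diagnosis-history covariates of the risk score
#' @return Named list of ICD-10 prefix vectors.
#' @export
default_gest_dx_catalog <- function() {
  read_diagnosis_catalog(system.file("extdata", "gest_dx_catalog.yaml",
                                     package = "gestval", mustWork = TRUE))
}

# TRUE for codes starting with any of the prefixes
match_prefixes <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

# drop syntactically invalid ICD strings, with a note
clean_codes <- function(diagnoses) {
  ok <- grepl("^[A-Z][0-9]", diagnoses$code)
  if (any(!ok)) {
    message("skipping ", sum(!ok), " malformed diagnosis code(s), e.g. '",
            diagnoses$code[!ok][1L], "'")
    diagnoses <- diagnoses[ok, , drop = FALSE]
  }
  diagnoses
}

#' Summarize early-visit vital signs for one encounter
#'
#' Only observations within the first `window_minutes` of the visit are
#' used: the mean of heart-rate observations, the minimum of systolic
#' blood pressures, and whether any oxygen-device observation indicates
#' non-room-air (value > 0).  Each summary is `NA` when the window holds
#' no observation of that kind.
#'
#' @param vitals Data frame for one encounter with columns `vital`
#'   (`"heart_rate"`, `"systolic_bp"`, `"o2_device"`), `offset_minutes`
#'   (minutes since ED arrival, must be non-negative) and `value`.
#' @param window_minutes Width of the early-visit window (default 240,
#'   i.e. the first 4 hours).
#' @return List with `mean_heart_rate`, `min_systolic_bp`,
#'   `supplemental_oxygen`.
#' @export
summarize_vitals <- function(vitals, window_minutes = 240) {
  stopifnot(window_minutes > 0)
  if (nrow(vitals) > 0 && any(vitals$offset_minutes < 0)) {
    stop("negative vital-sign observation offset(s): upstream timestamp bug")
  }
  w <- vitals[vitals$offset_minutes <= window_minutes, , drop = FALSE]
  hr <- w$value[w$vital == "heart_rate"]
  sbp <- w$value[w$vital == "systolic_bp"]
  o2 <- w$value[w$vital == "o2_device"]
  list(
    mean_heart_rate = if (length(hr)) mean(hr) else NA_real_,
    min_systolic_bp = if (length(sbp)) min(sbp) else NA_real_,
    supplemental_oxygen = if (length(o2)) any(o2 > 0) else NA)
}

#' Select per-analyte lab values for one encounter
#'
#' For each analyte the earliest resulted value in the encounter is taken,
#' mirroring screening at presentation; ties on result time are broken by
#' the lower row index (noted via [message()]).
#'
#' @param labs Data frame for one encounter with columns `analyte`,
#'   `offset_minutes`, `value`.
#' @param analytes Analyte names to extract (defaults to the six lab
#'   covariates of the risk score).
#' @return Named list of values, `NA` where the encounter has no result.
#' @export
select_labs <- function(labs,
                        analytes = c("hemoglobin", "hematocrit",
                                     "blood_urea_nitrogen",
                                     "red_cell_distribution_width",
                                     "lymphocyte_count",
                                     "mean_corpuscular_volume")) {
  if (nrow(labs) > 0 && !is.numeric(labs$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(labs$value))))[1L]
    stop("non-numeric lab result in row ", bad, " (analyte '",
         labs$analyte[bad], "')")
  }
  out <- stats::setNames(vector("list", length(analytes)), analytes)
  for (a in analytes) {
    rows <- labs[labs$analyte == a, , drop = FALSE]
    if (nrow(rows) == 0L) {
      out[[a]] <- NA_real_
    } else {
      first <- which(rows$offset_minutes == min(rows$offset_minutes))
      if (length(first) > 1L) {
        message("tied result times for '", a, "'; keeping lower row index")
      }
      out[[a]] <- rows$value[first[1L]]
    }
  }
  out
}

#' Count hospital admissions in the year before an ED arrival
#'
#' The lookback window is `[arrival - 365 days, arrival)`: an admission
#' exactly 365 days before counts, an admission on the arrival date does
#' not.
#'
#' @param admissions Data frame with columns `patient_id`, `admit_date`.
#' @param patient_id Patient to count for.
#' @param arrival_date ED arrival `Date`.
#' @return Integer count.
#' @export
count_admissions <- function(admissions, patient_id, arrival_date) {
  d <- admissions$admit_date[admissions$patient_id == patient_id]
  sum(d >= arrival_date - 365 & d < arrival_date)
}

#' Diagnosis-history flags for one encounter
#'
#' History flags are true when any code with a matching prefix is dated
#' strictly before arrival (optionally restricted to a trailing window);
#' the ED syncope/cerebrovascular flag is drawn only from codes attached
#' to the index encounter itself.
#'
#' @param diagnoses Data frame with columns `patient_id`, `encounter_id`
#'   (`NA` for history codes), `code`, `date`.
#' @param patient_id,arrival_date Identify the index encounter.
#' @param encounter_id Index encounter id (for the ED diagnosis flag).
#' @param catalog Prefix catalog, see [default_gest_dx_catalog()].
#' @param history_days Lookback for history flags in days; `NULL` (default)
#'   uses all available history.
#' @return Named logical vector, one entry per catalog category.
#' @export
flag_diagnoses <- function(diagnoses, patient_id, arrival_date,
                           encounter_id = NA,
                           catalog = default_gest_dx_catalog(),
                           history_days = NULL) {
  diagnoses <- clean_codes(diagnoses[diagnoses$patient_id == patient_id, ,
                                     drop = FALSE])
  out <- stats::setNames(logical(length(catalog)), names(catalog))
  hist_rows <- diagnoses$date < arrival_date
  if (!is.null(history_days)) {
    hist_rows <- hist_rows & diagnoses$date >= arrival_date - history_days
  }
  for (nm in names(catalog)) {
    if (nm == "ed_dx_syncope_or_cva") {
      rows <- !is.na(diagnoses$encounter_id) &
        diagnoses$encounter_id == encounter_id
    } else {
      rows <- hist_rows
    }
    out[nm] <- any(match_prefixes(diagnoses$code[rows], catalog[[nm]]))
  }
  out
}

#' Extract the risk-model feature table from encounter-linked tables
#'
#' Vectorized pipeline over all encounters of a cohort: early-window vital
#' summaries, earliest lab results, past-year admission counts and
#' diagnosis-history flags, plus age, sex and calendar year carried from
#' the encounter table.  `outpatient_cv_meds` is not extractable from
#' these tables and is omitted (it scores through its imputation value).
#'
#' @param cohort A `synthetic_cohort` or a list with elements `encounters`,
#'   `vitals`, `labs`, `diagnoses`, `admissions` in the package's table
#'   formats (see [generate_cohort()]).
#' @param window_minutes Vital-sign window, default 240 minutes.
#' @param history_days Diagnosis-history lookback; `NULL` = all history.
#' @param catalog Diagnosis prefix catalog.
#' @return Data frame, one row per encounter: bookkeeping columns
#'   (`encounter_id`, `patient_id`, `arrival_date`, `year`, `sex`) and the
#'   covariate columns, `NA` marking absent values.
#' @export
extract_features <- function(cohort, window_minutes = 240,
                             history_days = NULL,
                             catalog = default_gest_dx_catalog()) {
  enc <- cohort$encounters
  n <- nrow(enc)
  out <- data.frame(
    encounter_id = enc$encounter_id, patient_id = enc$patient_id,
    arrival_date = enc$arrival_date,
    year = as.integer(format(enc$arrival_date, "%Y")),
    sex = enc$sex, age = enc$age, stringsAsFactors = FALSE)

  ## vitals: first-window mean HR / min SBP / any supplemental oxygen
  v <- cohort$vitals
  if (nrow(v) > 0 && any(v$offset_minutes < 0)) {
    stop("negative vital-sign observation offset(s): upstream timestamp bug")
  }
  v <- v[v$offset_minutes <= window_minutes, , drop = FALSE]
  pull <- function(sub, fun) {
    agg <- tapply(sub$value, sub$encounter_id, fun)
    as.numeric(agg[match(enc$encounter_id, names(agg))])
  }
  hr <- v[v$vital == "heart_rate", , drop = FALSE]
  sbp <- v[v$vital == "systolic_bp", , drop = FALSE]
  o2 <- v[v$vital == "o2_device", , drop = FALSE]
  out$mean_heart_rate <- pull(hr, mean)
  out$min_systolic_bp <- pull(sbp, min)
  o2any <- pull(o2, function(x) as.numeric(any(x > 0)))
  out$supplemental_oxygen <- as.logical(o2any)

  ## labs: earliest result per encounter x analyte (stable tie-break)
  labs <- cohort$labs
  if (nrow(labs) > 0 && !is.numeric(labs$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(labs$value))))[1L]
    stop("non-numeric lab result in row ", bad, " (analyte '",
         labs$analyte[bad], "')")
  }
  ord <- order(labs$encounter_id, labs$analyte, labs$offset_minutes)
  labs1 <- labs[ord, , drop = FALSE]
  labs1 <- labs1[!duplicated(paste(labs1$encounter_id, labs1$analyte)), ,
                 drop = FALSE]
  for (a in c("hemoglobin", "hematocrit", "blood_urea_nitrogen",
              "red_cell_distribution_width", "lymphocyte_count",
              "mean_corpuscular_volume")) {
    sub <- labs1[labs1$analyte == a, , drop = FALSE]
    out[[a]] <- sub$value[match(enc$encounter_id, sub$encounter_id)]
  }

  ## admissions + diagnosis history, grouped per patient
  dx <- clean_codes(cohort$diagnoses)
  hist_cat <- catalog[setdiff(names(catalog), "ed_dx_syncope_or_cva")]
  for (nm in names(hist_cat)) {
    dx[[paste0(".", nm)]] <- match_prefixes(dx$code, hist_cat[[nm]])
  }
  adm_by_pat <- split(cohort$admissions$admit_date,
                      cohort$admissions$patient_id)
  dx_by_pat <- split(seq_len(nrow(dx)), dx$patient_id)
  enc_by_pat <- split(seq_len(n), enc$patient_id)
  out$admissions_past_year <- 0L
  for (nm in names(hist_cat)) out[[nm]] <- FALSE
  for (pid in names(enc_by_pat)) {
    rows <- enc_by_pat[[pid]]
    arr <- enc$arrival_date[rows]
    adm <- adm_by_pat[[pid]]
    if (!is.null(adm)) {
      out$admissions_past_year[rows] <- vapply(
        arr, function(a) sum(adm >= a - 365 & adm < a), integer(1))
    }
    drows <- dx_by_pat[[pid]]
    if (!is.null(drows)) {
      ddate <- dx$date[drows]
      for (nm in names(hist_cat)) {
        hit_dates <- ddate[dx[[paste0(".", nm)]][drows]]
        if (length(hit_dates)) {
          out[[nm]][rows] <- vapply(arr, function(a) {
            if (is.null(history_days)) any(hit_dates < a)
            else any(hit_dates < a & hit_dates >= a - history_days)
          }, logical(1))
        }
      }
    }
  }

  ## ED diagnosis flag from codes attached to the index encounter
  ed_rows <- !is.na(dx$encounter_id) &
    match_prefixes(dx$code, catalog$ed_dx_syncope_or_cva)
  out$ed_dx_syncope_or_cva <- enc$encounter_id %in% dx$encounter_id[ed_rows]
  out
}
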