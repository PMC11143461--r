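#' Default serious-illness diagnosis catalog
#'
#' Life-limiting-illness ICD-10 code families at prefix level:
#' stroke/TIA, liver disease, hip fracture, cancer, heart disease, lung
#' disease, neurodegenerative disease, diabetes with peripheral vascular
#' disease, coronary artery disease, chronic kidney disease, HIV/AIDS,
#' kidney failure and dementia.  Institutions using different code lists
#' can supply their own YAML via [read_diagnosis_catalog()].
#'
#' @return Named list of ICD-10 prefix vectors.
#' @export
default_serious_illness_catalog <- function() {
  read_diagnosis_catalog(system.file("extdata",
                                     "serious_illness_catalog.yaml",
                                     package = "gestval", mustWork = TRUE))
}

#' Serious-illness screen for a single encounter
#'
#' An encounter screens positive when any catalog category has a matching
#' diagnosis code dated within the 1-year lookback (the closed interval
#' `[arrival - lookback_days, arrival]`, so index-day codes count), or,
#' when the age criterion is enabled, when the patient is 80 or older.
#' A single qualifying category suffices.
#'
#' @param history Data frame of dated codes for the patient (`code`,
#'   `date`); may be empty.
#' @param age Age in years at the encounter.
#' @param arrival_date ED arrival `Date`.
#' @param catalog See [default_serious_illness_catalog()].
#' @param include_age Whether age >= 80 alone qualifies (default `TRUE`;
#'   set `FALSE` for the no-age-criterion sensitivity analysis).
#' @param lookback_days Lookback width, default 365.
#' @return List with `flagged`, `categories_met`, `age_criterion_met`.
#' @export
flag_encounter <- function(history, age, arrival_date,
                           catalog = default_serious_illness_catalog(),
                           include_age = TRUE, lookback_days = 365) {
  in_window <- history$date >= arrival_date - lookback_days &
    history$date <= arrival_date
  codes <- history$code[in_window]
  met <- names(catalog)[vapply(catalog, function(p) {
    any(match_prefixes(codes, p))
  }, logical(1))]
  age_met <- isTRUE(include_age) && age >= 80
  list(flagged = length(met) > 0L || age_met,
       categories_met = met,
       age_criterion_met = age_met)
}

#' Serious-illness screen for every encounter of a cohort
#'
#' Vectorized application of [flag_encounter()] across an encounter table.
#'
#' @param encounters Encounter table (`encounter_id`, `patient_id`,
#'   `arrival_date`, `age`).
#' @param diagnoses Dated diagnosis table (`patient_id`, `code`, `date`).
#' @param catalog,include_age,lookback_days See [flag_encounter()].
#' @return Data frame with `encounter_id`, logical `flagged`,
#'   `age_criterion_met`, and `categories_met` (comma-separated).
#' @export
flag_serious_illness <- function(encounters, diagnoses,
                                 catalog = default_serious_illness_catalog(),
                                 include_age = TRUE, lookback_days = 365) {
  dx <- clean_codes(diagnoses)
  for (nm in names(catalog)) {
    dx[[paste0(".", nm)]] <- match_prefixes(dx$code, catalog[[nm]])
  }
  dx_by_pat <- split(seq_len(nrow(dx)), dx$patient_id)
  enc_by_pat <- split(seq_len(nrow(encounters)), encounters$patient_id)
  n <- nrow(encounters)
  met_mat <- matrix(FALSE, n, length(catalog),
                    dimnames = list(NULL, names(catalog)))
  for (pid in names(enc_by_pat)) {
    drows <- dx_by_pat[[pid]]
    if (is.null(drows)) next
    rows <- enc_by_pat[[pid]]
    arr <- encounters$arrival_date[rows]
    ddate <- dx$date[drows]
    for (nm in names(catalog)) {
      hit_dates <- ddate[dx[[paste0(".", nm)]][drows]]
      if (length(hit_dates)) {
        met_mat[rows, nm] <- vapply(arr, function(a) {
          any(hit_dates >= a - lookback_days & hit_dates <= a)
        }, logical(1))
      }
    }
  }
  age_met <- isTRUE(include_age) & encounters$age >= 80
  data.frame(
    encounter_id = encounters$encounter_id,
    flagged = rowSums(met_mat) > 0 | age_met,
    age_criterion_met = age_met,
    categories_met = apply(met_mat, 1L, function(r) {
      paste(names(catalog)[r], collapse = ",")
    }),
    stringsAsFactors = FALSE)
}
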