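vitals_fix <- function(...) {
  rows <- list(...)
  data.frame(vital = vapply(rows, `[[`, "", 1),
             offset_minutes = as.numeric(vapply(rows, `[[`, "", 2)),
             value = as.numeric(vapply(rows, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

test_that("vital summaries respect the first-4-hours window", {
  v <- vitals_fix(c("heart_rate", "10", "80"), c("heart_rate", "60", "100"),
                  c("heart_rate", "300", "140"))
  # only the two in-window observations are averaged
  expect_equal(summarize_vitals(v)$mean_heart_rate, 90)
  v <- vitals_fix(c("systolic_bp", "5", "120"))
  expect_equal(summarize_vitals(v)$min_systolic_bp, 120)
  empty <- vitals_fix()
  s <- summarize_vitals(empty)
  expect_true(is.na(s$mean_heart_rate) && is.na(s$min_systolic_bp) &&
                is.na(s$supplemental_oxygen))
  expect_error(summarize_vitals(vitals_fix(c("heart_rate", "-5", "80"))),
               "negative")
})

test_that("shrinking the window never adds observations and matches a
           filter-then-aggregate oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(0:12, 1)
    v <- data.frame(
      vital = sample(c("heart_rate", "systolic_bp", "o2_device"), n, TRUE),
      offset_minutes = sample(0:500, max(n, 1))[seq_len(n)],
      value = round(runif(n, 0, 150)))
    w1 <- sample(50:500, 1)
    w2 <- sample(10:w1, 1)
    s1 <- summarize_vitals(v, w1)
    s2 <- summarize_vitals(v, w2)
    # oracle: filter then aggregate by hand
    for (w in c(w1, w2)) {
      sub <- v[v$offset_minutes <= w, ]
      hr <- sub$value[sub$vital == "heart_rate"]
      s <- summarize_vitals(v, w)
      expect_equal(s$mean_heart_rate,
                   if (length(hr)) mean(hr) else NA_real_)
      sbp <- sub$value[sub$vital == "systolic_bp"]
      expect_equal(s$min_systolic_bp,
                   if (length(sbp)) min(sbp) else NA_real_)
    }
    # monotone set inclusion: a summary present at w2 is present at w1
    if (!is.na(s2$mean_heart_rate)) expect_false(is.na(s1$mean_heart_rate))
    if (!is.na(s2$min_systolic_bp)) expect_false(is.na(s1$min_systolic_bp))
  }
})

test_that("lab selection takes the earliest result with a stable tie rule", {
  labs <- data.frame(analyte = "hemoglobin",
                     offset_minutes = c(30, 200), value = c(12.1, 11.0))
  expect_equal(select_labs(labs)$hemoglobin, 12.1)
  expect_true(is.na(select_labs(labs)$blood_urea_nitrogen))
  tied <- data.frame(analyte = "hemoglobin",
                     offset_minutes = c(30, 30), value = c(12.1, 12.3))
  expect_message(val <- select_labs(tied)$hemoglobin, "tied")
  expect_equal(val, 12.1)
  bad <- data.frame(analyte = "hemoglobin", offset_minutes = 1, value = "x",
                    stringsAsFactors = FALSE)
  expect_error(select_labs(bad), "non-numeric")
})

test_that("admission counting uses a [t-365, t) window", {
  arr <- as.Date("2020-06-01")
  adm <- data.frame(patient_id = "P1",
                    admit_date = arr - c(30, 400))
  expect_equal(count_admissions(adm, "P1", arr), 1)
  expect_equal(count_admissions(adm[0, ], "P1", arr), 0)
  boundary <- data.frame(patient_id = "P1", admit_date = arr - 365)
  expect_equal(count_admissions(boundary, "P1", arr), 1)  # closed lower bound
  same_day <- data.frame(patient_id = "P1", admit_date = arr)
  expect_equal(count_admissions(same_day, "P1", arr), 0)
})

test_that("diagnosis flags match on prefixes without lookahead", {
  arr <- as.Date("2020-06-01")
  dx <- data.frame(patient_id = "P1", encounter_id = NA_character_,
                   code = "C78.0", date = arr - 100,
                   stringsAsFactors = FALSE)
  flags <- flag_diagnoses(dx, "P1", arr)
  expect_true(flags[["dx_secondary_cancer"]])
  expect_false(flags[["dx_lung_cancer"]])
  # empty history
  flags <- flag_diagnoses(dx[0, ], "P1", arr)
  expect_false(any(flags))
  # code dated after arrival is invisible
  dx$code <- "C34.1"; dx$date <- arr + 10
  expect_false(flag_diagnoses(dx, "P1", arr)[["dx_lung_cancer"]])
  # malformed codes are skipped with a note
  dx2 <- data.frame(patient_id = "P1", encounter_id = NA_character_,
                    code = c("??", "C34.1"), date = arr - 10,
                    stringsAsFactors = FALSE)
  expect_message(flags <- flag_diagnoses(dx2, "P1", arr), "malformed")
  expect_true(flags[["dx_lung_cancer"]])
})

test_that("vectorized extraction agrees with the per-encounter operations", {
  co <- small_cohort()
  feats <- extract_features(co)
  set.seed(7)
  for (i in sample(nrow(co$encounters), 15)) {
    enc <- co$encounters[i, ]
    row <- feats[feats$encounter_id == enc$encounter_id, ]
    v <- co$vitals[co$vitals$encounter_id == enc$encounter_id, ]
    s <- summarize_vitals(v)
    expect_equal(row$mean_heart_rate, s$mean_heart_rate)
    expect_equal(row$min_systolic_bp, s$min_systolic_bp)
    expect_equal(row$supplemental_oxygen, s$supplemental_oxygen)
    l <- co$labs[co$labs$encounter_id == enc$encounter_id, ]
    sl <- select_labs(l)
    expect_equal(row$hemoglobin, sl$hemoglobin)
    expect_equal(row$blood_urea_nitrogen, sl$blood_urea_nitrogen)
    expect_equal(row$admissions_past_year,
                 count_admissions(co$admissions, enc$patient_id,
                                  enc$arrival_date))
    fl <- flag_diagnoses(co$diagnoses, enc$patient_id, enc$arrival_date,
                         encounter_id = enc$encounter_id)
    for (nm in names(fl)) expect_equal(row[[nm]], unname(fl[[nm]]))
  }
})

test_that("feature extraction is pure", {
  co <- small_cohort()
  expect_identical(extract_features(co), extract_features(co))
})
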