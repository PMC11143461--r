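# Shared synthetic cohorts, generated once per test run.
#
# The large cohort has no injected missingness: outcomes are drawn from the
# complete first-visit covariates, so refitting on those same covariates is
# a correctly specified parameter-recovery loop.

.cohort_cache <- new.env(parent = emptyenv())

large_cohort <- function() {
  if (is.null(.cohort_cache$large)) {
    cfg <- cohort_config(
      n_patients = 20000,
      missingness = setNames(rep(0, length(default_missingness_rates())),
                             names(default_missingness_rates())),
      seed = 20260920)
    .cohort_cache$large <- generate_cohort(cfg)
  }
  .cohort_cache$large
}

small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    .cohort_cache$small <- generate_cohort(
      cohort_config(n_patients = 1500, seed = 99))
  }
  .cohort_cache$small
}

# first-visit features/scores/labels of the large cohort under its
# (intercept-tuned) generating model
large_first_visit <- function() {
  if (is.null(.cohort_cache$large_fv)) {
    co <- large_cohort()
    truth <- co$config$true_model
    truth$intercept <- co$tuned_intercept
    fe <- first_encounter_filter(co$encounters)
    feats <- extract_features(co)
    idx <- match(fe$encounter_id, co$encounters$encounter_id)
    feats <- feats[idx, , drop = FALSE]
    .cohort_cache$large_fv <- list(
      cohort = co, truth = truth, features = feats,
      scores = predict(truth, feats, type = "response"),
      labels = six_month_labels(fe, co$outcomes),
      encounters = fe)
  }
  .cohort_cache$large_fv
}
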