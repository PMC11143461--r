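# Independent brute-force oracles used across the suite.

# AUROC by enumerating all case-control pairs (ties credit 1/2)
auc_brute <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  cases <- scores[labels]
  controls <- scores[!labels]
  pairs <- outer(cases, controls, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  mean(pairs)
}

# Kaplan-Meier by explicit risk-set recomputation at each distinct time
km_brute <- function(time, event, horizon = 183) {
  tt <- sort(unique(time[time <= horizon]))
  s <- 1
  out <- numeric(0)
  keep <- numeric(0)
  for (t in tt) {
    n_at_risk <- sum(time >= t)        # censored at t still at risk for deaths at t
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at_risk)
    out <- c(out, s)
    keep <- c(keep, t)
  }
  data.frame(time = keep, survival = out)
}

# toy model specification: standardized covariates with mean 0 / sd 1,
# so feature values are the z-scores directly
toy_model <- function(coefs, intercept = 0) {
  gest_model(
    data.frame(name = names(coefs), imputation = 0, mean = 0, sd = 1,
               coefficient = unname(coefs), standardize = TRUE),
    intercept = intercept, name = "toy")
}

# features drawn N(0,1) for a toy model
toy_features <- function(n, covs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(stats::setNames(
    lapply(covs, function(x) stats::rnorm(n)), covs))
}
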