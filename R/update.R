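#' Recalibrate a risk model's intercept for a new setting
#'
#' Fits the offset logistic model `logit P(y=1) = eta + delta` on training
#' records, where `eta` is the original linear predictor (slope fixed at 1),
#' and returns the specification with `delta` added to the intercept;
#' covariate coefficients are untouched, so discrimination is unchanged by
#' construction.  An optional intercept + slope variant (`slope = TRUE`,
#' off by default) fits `a + b * eta` and rescales every coefficient by `b`.
#'
#' @param model A [gest_model()].
#' @param features Training feature table.
#' @param outcomes Binary training outcomes; both classes required.
#' @param slope Also refit a calibration slope (default `FALSE`).
#' @return Updated [gest_model()] with attributes `delta` (and
#'   `calibration_slope` when `slope = TRUE`).
#' @export
recalibrate_intercept <- function(model, features, outcomes, slope = FALSE) {
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L) {
    stop("recalibration requires both outcome classes in the training data")
  }
  eta <- predict(model, features, type = "link")
  out <- model
  if (slope) {
    fit <- stats::glm(y ~ eta, family = stats::binomial())
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    out$covariates$coefficient <- model$covariates$coefficient * b
    out$intercept <- a + b * model$intercept
    attr(out, "delta") <- out$intercept - model$intercept
    attr(out, "calibration_slope") <- b
  } else {
    fit <- stats::glm(y ~ 1, offset = eta, family = stats::binomial())
    delta <- unname(stats::coef(fit)[1])
    out$intercept <- model$intercept + delta
    attr(out, "delta") <- delta
  }
  out$name <- paste0(model$name, "+recalibrated")
  out
}

#' Refit the logistic model on new data
#'
#' Maximum-likelihood logistic regression on the model's standardized
#' covariates (the imputation and standardization entries are retained
#' unchanged) via iteratively reweighted least squares; convergence when
#' the largest coefficient change is below `tol` (default 1e-8) or after
#' `max_iter` iterations.  Diverging coefficients are treated as evidence
#' of separation and reported as an error naming the covariate.
#'
#' @param model A [gest_model()] providing the covariate set and the
#'   imputation/standardization entries.
#' @param features Training feature table.
#' @param outcomes Binary training outcomes; both classes required.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap (default 100).
#' @return Updated [gest_model()] with refitted intercept and coefficients;
#'   attributes `se` (standard errors, `(intercept)` first), `iterations`,
#'   `converged`.
#' @export
refit <- function(model, features, outcomes, tol = 1e-8, max_iter = 100) {
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L) {
    stop("refit requires both outcome classes in the training data")
  }
  z <- impute_and_standardize(features, model)$z
  ## covariates constant in the training data (e.g. a field imputed for
  ## every record) are inestimable: hold them at their original
  ## coefficient and fit the rest around that fixed contribution
  const_col <- apply(z, 2L, function(col) max(col) - min(col) == 0)
  offset <- drop(z[, const_col, drop = FALSE] %*%
                   model$covariates$coefficient[const_col])
  if (length(offset) == 0L) offset <- rep(0, nrow(z))
  if (any(const_col)) {
    message("covariate(s) constant in training data, kept at original ",
            "coefficient: ",
            paste(colnames(z)[const_col], collapse = ", "))
  }
  X <- cbind("(intercept)" = 1, z[, !const_col, drop = FALSE])
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + offset
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zwork <- eta - offset + (y - mu) / w
    fit <- stats::lm.wfit(X, zwork, w)
    beta_new <- fit$coefficients
    if (any(is.na(beta_new))) {
      stop("refit failed: singular design (collinear covariate '",
           colnames(X)[which(is.na(beta_new))[1]], "')")
    }
    if (any(abs(beta_new) > 15)) {
      j <- which.max(abs(beta_new))
      stop("refit failed: separation detected (diverging coefficient for '",
           colnames(X)[j], "')")
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + offset
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  se_fit <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
  out <- model
  out$intercept <- unname(beta[1])
  coefs <- model$covariates$coefficient
  coefs[!const_col] <- unname(beta[-1])
  out$covariates$coefficient <- coefs
  out$name <- paste0(model$name, "+refit")
  se <- stats::setNames(rep(NA_real_, 1L + ncol(z)),
                        c("(intercept)", colnames(z)))
  se[colnames(X)] <- se_fit
  attr(out, "se") <- se
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Compare original, recalibrated and refitted models on held-out data
#'
#' Scores the validation records with each specification and reports, per
#' model, the DeLong AUROC, a decile calibration table and
#' calibration-in-the-large (mean observed minus mean predicted risk).
#'
#' @param original,recalibrated,refitted Three [gest_model()]s.
#' @param features Validation feature table.
#' @param outcomes Binary validation outcomes.
#' @param bins Calibration risk groups (default 10).
#' @return Object of class `gest_update_comparison`: named list of
#'   per-model results plus a `summary` data frame.
#' @export
compare_updates <- function(original, recalibrated, refitted,
                            features, outcomes, bins = 10) {
  y <- as.integer(outcomes)
  models <- list(original = original, recalibrated = recalibrated,
                 refit = refitted)
  res <- lapply(names(models), function(nm) {
    p <- predict(models[[nm]], features, type = "response")
    list(discrimination = auroc_delong(p, y, stratum = nm),
         calibration = calibration_bins(p, y, bins = bins),
         calibration_in_the_large = mean(y) - mean(p))
  })
  names(res) <- names(models)
  res$summary <- do.call(rbind, lapply(names(models), function(nm) {
    d <- res[[nm]]$discrimination
    data.frame(model = nm, auroc = d$auroc, ci_low = d$ci[1],
               ci_high = d$ci[2],
               calibration_in_the_large = res[[nm]]$calibration_in_the_large,
               stringsAsFactors = FALSE)
  }))
  structure(res, class = "gest_update_comparison")
}

#' @export
print.gest_update_comparison <- function(x, ...) {
  cat("Model update comparison (validation records):\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
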