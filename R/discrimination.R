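#' AUROC with a DeLong confidence interval
#'
#' The area under the ROC curve is computed with midranks, crediting ties
#' between a case and a control with 1/2.  The variance is the DeLong
#' structural-component estimator: with placement values `V10` (one per
#' case: the fraction of controls it outranks) and `V01` (one per control),
#' `var = var(V10)/m + var(V01)/n`.  The 95% CI is the normal
#' approximation `auroc +/- 1.96 sqrt(var)`, truncated to [0, 1].
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param labels Binary outcomes (logical or 0/1); both classes must be
#'   present.
#' @param stratum Label carried into the result (default `"overall"`).
#' @param conf Confidence level, default 0.95.
#' @return Object of class `delong_auroc`: list with `auroc`, `variance`,
#'   `ci` (length-2), `n_cases`, `n_controls`, `stratum`.
#' @references DeLong, DeLong & Clarke-Pearson (1988), Biometrics 44:837-45.
#' @examples
#' auroc_delong(c(.9, .8, .1, .2), c(1, 1, 0, 0))
#' @export
auroc_delong <- function(scores, labels, stratum = "overall", conf = 0.95) {
  labels <- as.logical(as.integer(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  m <- sum(labels); n <- sum(!labels)
  if (m == 0L) stop("cannot compute AUROC: no cases (positive class absent)")
  if (n == 0L) stop("cannot compute AUROC: no controls (negative class absent)")
  r_all <- rank(scores)
  v10 <- (r_all[labels] - rank(scores[labels])) / n
  v01 <- 1 - (r_all[!labels] - rank(scores[!labels])) / m
  auc <- mean(v10)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  v <- s10 / m + s01 / n
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(v)))
  structure(list(auroc = auc, variance = v, ci = ci,
                 n_cases = m, n_controls = n, stratum = stratum),
            class = "delong_auroc")
}

#' @export
print.delong_auroc <- function(x, ...) {
  cat(sprintf("AUROC [%s]: %.3f (95%% CI %.3f-%.3f); %d cases / %d controls\n",
              x$stratum, x$auroc, x$ci[1], x$ci[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' AUROC by stratum
#'
#' One DeLong AUROC per stratum (e.g. sex, race and ethnicity, calendar
#' year).  Strata lacking either outcome class are reported as skipped
#' rows, not errors.
#'
#' @param scores,labels See [auroc_delong()].
#' @param strata Stratum label per record.
#' @return Data frame with one row per stratum: `stratum`, `auroc`,
#'   `ci_low`, `ci_high`, `n_cases`, `n_controls`, logical `skipped`.
#' @export
stratified_auroc <- function(scores, labels, strata) {
  labels <- as.integer(labels)
  res <- lapply(sort(unique(strata)), function(s) {
    idx <- strata == s
    if (length(unique(labels[idx])) < 2L) {
      data.frame(stratum = as.character(s), auroc = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_cases = sum(labels[idx] == 1L),
                 n_controls = sum(labels[idx] == 0L), skipped = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      d <- auroc_delong(scores[idx], labels[idx], stratum = as.character(s))
      data.frame(stratum = d$stratum, auroc = d$auroc,
                 ci_low = d$ci[1], ci_high = d$ci[2],
                 n_cases = d$n_cases, n_controls = d$n_controls,
                 skipped = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Observed-vs-predicted calibration table
#'
#' Groups records into risk groups (deciles of the score by default, or
#' fixed probability edges) and reports the mean predicted risk and the
#' observed event rate per group.  Under fixed edges, empty groups are
#' retained with count 0 and an undefined (`NA`) observed rate.
#'
#' @param scores Predicted probabilities in [0, 1].
#' @param labels Binary outcomes.
#' @param bins Number of quantile groups (default 10).
#' @param edges Optional fixed bin edges spanning the scores (overrides
#'   `bins`).
#' @return Object of class `calibration_table`: data frame with `bin`,
#'   `lower`, `upper`, `n`, `predicted_mean`, `observed_rate`.
#' @export
calibration_bins <- function(scores, labels, bins = 10, edges = NULL) {
  stopifnot(all(scores >= 0 & scores <= 1))
  labels <- as.integer(labels)
  if (is.null(edges)) {
    edges <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1),
                                    names = FALSE))
    if (length(edges) < 2L) edges <- c(edges, edges + .Machine$double.eps)
  } else {
    edges <- sort(edges)
  }
  grp <- cut(scores, breaks = edges, include.lowest = TRUE, labels = FALSE)
  k <- length(edges) - 1L
  res <- data.frame(
    bin = seq_len(k), lower = edges[-length(edges)], upper = edges[-1L],
    n = vapply(seq_len(k), function(i) sum(grp == i, na.rm = TRUE), integer(1)))
  res$predicted_mean <- vapply(seq_len(k), function(i) {
    if (res$n[i] == 0L) NA_real_ else mean(scores[which(grp == i)])
  }, numeric(1))
  res$observed_rate <- vapply(seq_len(k), function(i) {
    if (res$n[i] == 0L) NA_real_ else mean(labels[which(grp == i)])
  }, numeric(1))
  structure(res, class = c("calibration_table", "data.frame"))
}

#' @export
plot.calibration_table <- function(x, ...) {
  occ <- x[x$n > 0, ]
  plot(occ$predicted_mean, occ$observed_rate,
       xlim = c(0, max(occ$predicted_mean, occ$observed_rate, 0.1)),
       ylim = c(0, max(occ$predicted_mean, occ$observed_rate, 0.1)),
       xlab = "Mean predicted 6-month mortality risk",
       ylab = "Observed 6-month mortality", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
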