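#' Confusion matrix at a strict probability cutoff
#'
#' A record screens positive when its score is strictly greater than the
#' threshold (a ">5%" rule is literally score > 0.05).
#'
#' @param scores Risk scores in [0, 1].
#' @param labels Binary outcomes.
#' @param threshold Cutoff probability.
#' @return Object of class `confusion_matrix`: list with integer `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  stopifnot(all(scores >= 0 & scores <= 1))
  y <- as.logical(as.integer(labels))
  pos <- scores > threshold
  structure(list(tp = sum(pos & y), fp = sum(pos & !y),
                 fn = sum(!pos & y), tn = sum(!pos & !y)),
            class = "confusion_matrix")
}

# binary screen -> confusion matrix
confusion_from_binary <- function(flags, labels) {
  y <- as.logical(as.integer(labels)); f <- as.logical(flags)
  structure(list(tp = sum(f & y), fp = sum(f & !y),
                 fn = sum(!f & y), tn = sum(!f & !y)),
            class = "confusion_matrix")
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# log-method CI for a likelihood ratio built from counts a/(a+c) over b/(b+d)
lr_log_ci <- function(lr, a, c_, b, d, conf = 0.95) {
  if (!is.finite(lr) || a == 0 || b == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a - 1 / (a + c_) + 1 / b - 1 / (b + d))
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Screening test characteristics of one operating point
#'
#' Sensitivity, specificity, predictive values, likelihood ratios and the
#' fraction screening positive, with confidence intervals (Wilson score
#' for proportions, log method for likelihood ratios; Wald available via
#' `ci_method`).  Ratios whose denominator is zero are reported as `NA`
#' rather than fabricated.
#'
#' @param cm A [confusion_at_threshold()] result.
#' @param label Screen label carried into the output row.
#' @param ci_method `"wilson"` (default) or `"wald"` for the proportion CIs.
#' @param conf Confidence level, default 0.95.
#' @return Object of class `screening_characteristics`: one-row data frame
#'   with `label`, `n`, `fraction_positive`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `lr_pos`, `lr_neg` and `_lo`/`_hi` columns.
#' @export
characteristics <- function(cm, label = "", ci_method = c("wilson", "wald"),
                            conf = 0.95) {
  ci_method <- match.arg(ci_method)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  stopifnot(n > 0)
  if (tp + fn == 0) stop("no cases present: sensitivity undefined")
  prop_ci <- function(x, d) {
    if (d == 0) return(c(NA_real_, NA_real_))
    if (ci_method == "wilson") return(wilson_ci(x, d, conf))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- x / d
    c(max(0, p - z * sqrt(p * (1 - p) / d)),
      min(1, p + z * sqrt(p * (1 - p) / d)))
  }
  sens <- tp / (tp + fn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  lr_pos <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  lr_neg <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  s_ci <- prop_ci(tp, tp + fn); sp_ci <- prop_ci(tn, tn + fp)
  ppv_ci <- prop_ci(tp, tp + fp); npv_ci <- prop_ci(tn, tn + fn)
  fr_ci <- prop_ci(tp + fp, n)
  lrp_ci <- lr_log_ci(lr_pos, tp, fn, fp, tn, conf)
  lrn_ci <- lr_log_ci(lr_neg, fn, tp, tn, fp, conf)
  out <- data.frame(
    label = label, n = n,
    fraction_positive = (tp + fp) / n,
    fraction_positive_lo = fr_ci[1], fraction_positive_hi = fr_ci[2],
    sensitivity = sens, sensitivity_lo = s_ci[1], sensitivity_hi = s_ci[2],
    specificity = spec, specificity_lo = sp_ci[1], specificity_hi = sp_ci[2],
    ppv = ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
    npv = npv, npv_lo = npv_ci[1], npv_hi = npv_ci[2],
    lr_pos = lr_pos, lr_pos_lo = lrp_ci[1], lr_pos_hi = lrp_ci[2],
    lr_neg = lr_neg, lr_neg_lo = lrn_ci[1], lr_neg_hi = lrn_ci[2],
    stringsAsFactors = FALSE)
  attr(out, "ci_method") <- ci_method
  class(out) <- c("screening_characteristics", "data.frame")
  out
}

#' Reconstruct predictive values and likelihood ratios from summary inputs
#'
#' The Bayes identities that make a published test-characteristics table
#' internally consistent: `PPV = sens * prev / frac_pos`,
#' `NPV = spec * (1 - prev) / (1 - frac_pos)`, `LR+ = sens / (1 - spec)`,
#' `LR- = (1 - sens) / spec`.  Useful to check printed tables without the
#' underlying data.
#'
#' @param sensitivity,specificity,prevalence,fraction_positive Fractions
#'   in [0, 1].
#' @return Named list with `ppv`, `npv`, `lr_pos`, `lr_neg`.
#' @export
reconstruct_characteristics <- function(sensitivity, specificity,
                                        prevalence, fraction_positive) {
  list(ppv = sensitivity * prevalence / fraction_positive,
       npv = specificity * (1 - prevalence) / (1 - fraction_positive),
       lr_pos = sensitivity / (1 - specificity),
       lr_neg = (1 - sensitivity) / specificity)
}

#' Test-characteristics table for a binary screen and a set of cutoffs
#'
#' One row for the binary criterion (e.g. serious-illness diagnoses) and
#' one per probability cutoff applied to the model scores, mirroring the
#' layout of a published screening comparison table.
#'
#' @param scores Model risk scores in [0, 1].
#' @param binary_flags Logical screen (or `NULL` to omit its row).
#' @param labels Binary outcomes.
#' @param thresholds Ascending probability cutoffs,
#'   default `c(0.05, 0.1, 0.2, 0.3)`.
#' @param binary_label Label for the binary row.
#' @param ... Passed to [characteristics()].
#' @return Data frame of stacked [characteristics()] rows.
#' @export
characteristics_table <- function(scores, binary_flags, labels,
                                  thresholds = c(0.05, 0.1, 0.2, 0.3),
                                  binary_label = "serious_illness", ...) {
  stopifnot(!is.unsorted(thresholds))
  rows <- list()
  if (!is.null(binary_flags)) {
    rows[[1]] <- characteristics(confusion_from_binary(binary_flags, labels),
                                 label = binary_label, ...)
  }
  for (t in thresholds) {
    rows[[length(rows) + 1]] <- characteristics(
      confusion_at_threshold(scores, labels, t),
      label = sprintf("model>%g%%", 100 * t), ...)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decision-curve net benefit
#'
#' Net benefit at threshold probability `p_t` is the true-positive
#' fraction minus the false-positive fraction weighted by the exchange
#' rate `p_t / (1 - p_t)`:
#' `NB(p_t) = tp/n - (fp/n) * p_t / (1 - p_t)`.
#' Strategies: `"model"` classifies positive at score > `p_t` for each
#' grid point; `"binary_criterion"` applies one fixed classification at
#' every `p_t`; `"treat_all"` classifies everyone positive;
#' `"treat_none"` no one (net benefit identically 0).
#'
#' @param x Scores (strategy `"model"`), logical flags
#'   (`"binary_criterion"`), or ignored (reference strategies).
#' @param labels Binary outcomes.
#' @param grid Threshold probabilities, strictly inside (0, 1);
#'   default `seq(0.01, 0.50, 0.01)`.
#' @param strategy Strategy name.
#' @return Object of class `decision_curve`: data frame with `threshold`,
#'   `net_benefit`, `strategy`.
#' @export
net_benefit_curve <- function(x, labels, grid = seq(0.01, 0.50, by = 0.01),
                              strategy = c("model", "binary_criterion",
                                           "treat_all", "treat_none")) {
  strategy <- match.arg(strategy)
  if (any(grid <= 0 | grid >= 1)) {
    stop("threshold grid must lie strictly inside (0, 1); ",
         "the exchange rate is undefined at p_t = 1")
  }
  y <- as.logical(as.integer(labels))
  n <- length(y)
  nb <- vapply(grid, function(pt) {
    pos <- switch(strategy,
                  model = x > pt,
                  binary_criterion = as.logical(x),
                  treat_all = rep(TRUE, n),
                  treat_none = rep(FALSE, n))
    sum(pos & y) / n - sum(pos & !y) / n * pt / (1 - pt)
  }, numeric(1))
  structure(data.frame(threshold = grid, net_benefit = nb,
                       strategy = strategy, stringsAsFactors = FALSE),
            class = c("decision_curve", "data.frame"))
}

#' Decision curve analysis comparing a model with a binary screen
#'
#' @param scores Model risk scores.
#' @param binary_flags Logical comparison screen.
#' @param labels Binary outcomes.
#' @param grid See [net_benefit_curve()].
#' @return `decision_curve` data frame stacking the four strategies.
#' @export
decision_curve_analysis <- function(scores, binary_flags, labels,
                                    grid = seq(0.01, 0.50, by = 0.01)) {
  out <- rbind(
    net_benefit_curve(scores, labels, grid, "model"),
    net_benefit_curve(binary_flags, labels, grid, "binary_criterion"),
    net_benefit_curve(NULL, labels, grid, "treat_all"),
    net_benefit_curve(NULL, labels, grid, "treat_none"))
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  strategies <- unique(x$strategy)
  cols <- stats::setNames(seq_along(strategies), strategies)
  plot(NA, xlim = range(x$threshold),
       ylim = range(x$net_benefit, 0),
       xlab = "Threshold probability", ylab = "Net benefit", ...)
  for (s in strategies) {
    sub <- x[x$strategy == s, ]
    graphics::lines(sub$threshold, sub$net_benefit, col = cols[s])
  }
  graphics::legend("topright", legend = strategies, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Serious-illness by model-risk misclassification cross-tab
#'
#' Stratifies encounters by the binary serious-illness screen and by model
#' risk band (low: score < `low_cut`; middle; high: score > `high_cut`)
#' and reports per-cell counts, shares and observed mortality.  The
#' discordant share is the fraction either serious-illness-positive but
#' low risk, or serious-illness-negative but high risk.
#'
#' @param si_flags Logical serious-illness screen.
#' @param scores Model risk scores.
#' @param labels Binary outcomes.
#' @param low_cut,high_cut Risk band edges (defaults 0.10 and 0.30).
#' @return Object of class `misclassification_crosstab`: list with `table`
#'   (6-row data frame: `serious_illness`, `risk_band`, `count`, `share`,
#'   `observed_mortality`) and scalar `discordant_share`.
#' @export
misclassification_crosstab <- function(si_flags, scores, labels,
                                       low_cut = 0.10, high_cut = 0.30) {
  stopifnot(length(si_flags) == length(scores),
            length(scores) == length(labels), low_cut < high_cut)
  si <- as.logical(si_flags)
  y <- as.integer(labels)
  band <- ifelse(scores < low_cut, "low",
                 ifelse(scores > high_cut, "high", "middle"))
  band <- factor(band, levels = c("low", "middle", "high"))
  n <- length(y)
  cells <- expand.grid(serious_illness = c(TRUE, FALSE),
                       risk_band = levels(band),
                       stringsAsFactors = FALSE)
  cells$count <- mapply(function(s, b) sum(si == s & band == b),
                        cells$serious_illness, cells$risk_band)
  cells$share <- cells$count / n
  cells$observed_mortality <- mapply(function(s, b) {
    idx <- si == s & band == b
    if (any(idx)) mean(y[idx]) else NA_real_
  }, cells$serious_illness, cells$risk_band)
  disc <- sum(si & band == "low") / n + sum(!si & band == "high") / n
  structure(list(table = cells, discordant_share = disc,
                 low_cut = low_cut, high_cut = high_cut),
            class = "misclassification_crosstab")
}

#' @export
print.misclassification_crosstab <- function(x, ...) {
  cat(sprintf(
    "Serious illness x model risk (<%g%% / >%g%%); discordant share %.1f%%\n",
    100 * x$low_cut, 100 * x$high_cut, 100 * x$discordant_share))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
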