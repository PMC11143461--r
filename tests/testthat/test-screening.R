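test_that("thresholding is strictly greater-than", {
  cm <- confusion_at_threshold(c(0.31, 0.30, 0.05), c(1, 1, 0), 0.30)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 1, tn = 1))
  cm0 <- confusion_at_threshold(c(0.2, 0.8), c(0, 1), 0)
  expect_equal(cm0$fn + cm0$tn, 0)
  cm1 <- confusion_at_threshold(c(0.2, 0.8), c(0, 1), 1)
  expect_equal(cm1$tp + cm1$fp, 0)
})

test_that("characteristics compute the standard definitions", {
  cm <- structure(list(tp = 8, fp = 2, fn = 2, tn = 8),
                  class = "confusion_matrix")
  ch <- characteristics(cm)
  expect_equal(ch$sensitivity, 0.8)
  expect_equal(ch$specificity, 0.8)
  expect_equal(ch$lr_pos, 4.0)
  expect_equal(ch$ppv, 0.8)
  expect_equal(ch$fraction_positive, 0.5)

  # degenerate: nothing screens positive
  cm0 <- structure(list(tp = 0, fp = 0, fn = 5, tn = 15),
                   class = "confusion_matrix")
  ch0 <- characteristics(cm0)
  expect_true(is.na(ch0$lr_pos))
  expect_true(is.na(ch0$ppv))
  expect_equal(ch0$npv, 0.75)

  expect_error(characteristics(structure(
    list(tp = 0, fp = 3, fn = 0, tn = 7), class = "confusion_matrix")),
    "no cases")
})

test_that("Bayes identities reconstruct predictive values from summaries", {
  # published serious-illness operating point
  rec <- reconstruct_characteristics(0.774, 0.505, 0.138, 0.534)
  expect_equal(round(100 * rec$ppv, 1), 20.0)
  expect_equal(round(rec$lr_pos, 1), 1.6)
  expect_equal(round(rec$lr_neg, 2), 0.45)

  # the same identities hold on random confusion matrices
  set.seed(17)
  for (i in 1:40) {
    counts <- rmultinom(1, sample(50:500, 1), runif(4, 0.05, 1))[, 1] + 1L
    cm <- structure(list(tp = counts[1], fp = counts[2], fn = counts[3],
                         tn = counts[4]), class = "confusion_matrix")
    ch <- characteristics(cm)
    prev <- (cm$tp + cm$fn) / ch$n
    rec <- reconstruct_characteristics(ch$sensitivity, ch$specificity,
                                       prev, ch$fraction_positive)
    expect_equal(rec$ppv, ch$ppv, tolerance = 1e-12)
    expect_equal(rec$npv, ch$npv, tolerance = 1e-12)
    expect_equal(rec$lr_pos, ch$lr_pos, tolerance = 1e-12)
  }
})

test_that("the characteristics table sweeps thresholds monotonically", {
  set.seed(18)
  s <- runif(800)
  y <- rbinom(800, 1, s)
  flags <- s > 0.5
  tab <- characteristics_table(s, flags, y)
  expect_equal(nrow(tab), 5)  # 1 binary + 4 cutoffs
  model_rows <- tab[-1, ]
  expect_true(all(diff(model_rows$fraction_positive) <= 0))
  expect_true(all(diff(model_rows$specificity) >= 0))

  # a perfect 0/1 score at threshold 0.5 is a perfect screen
  perfect <- characteristics_table(y, NULL, y, thresholds = 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("net benefit follows the exchange-rate arithmetic", {
  # treat-none is identically zero
  nb0 <- net_benefit_curve(NULL, rbinom(50, 1, 0.3), strategy = "treat_none")
  expect_true(all(nb0$net_benefit == 0))

  # single-point check: n=100, tp=20, fp=30 at p_t = 0.2
  y <- rep(c(1, 0, 0), c(20, 30, 50))
  s <- rep(c(0.9, 0.9, 0.01), c(20, 30, 50))
  nb <- net_benefit_curve(s, y, grid = 0.2, strategy = "model")
  expect_equal(nb$net_benefit, 0.20 - 0.30 * 0.25)

  # treat-all tends to prevalence as p_t -> 0
  nb_all <- net_benefit_curve(NULL, y, grid = c(0.001, 0.01),
                              strategy = "treat_all")
  expect_lt(abs(nb_all$net_benefit[1] - mean(y)), 0.001)

  expect_error(net_benefit_curve(s, y, grid = c(0.5, 1), "model"),
               "strictly inside")
})

test_that("net benefit is positive when true positives outpace the
           exchange-rate-weighted false positives", {
  set.seed(19)
  for (i in 1:20) {
    n <- 400
    s <- runif(n); y <- rbinom(n, 1, s)
    pt <- runif(1, 0.05, 0.6)
    cm <- confusion_at_threshold(s, y, pt)
    nb <- net_benefit_curve(s, y, grid = pt, "model")$net_benefit
    if (cm$fp > 0 && cm$tp / cm$fp > pt / (1 - pt)) expect_gt(nb, 0)
    # and it always reconstructs from the confusion matrix
    expect_equal(nb, cm$tp / n - cm$fp / n * pt / (1 - pt))
  }
})

test_that("a better-separated score dominates in expectation", {
  grid <- seq(0.05, 0.35, by = 0.05)
  diffs <- matrix(NA_real_, 50, length(grid))
  for (seed in 1:50) {
    set.seed(seed)
    n <- 1500
    y <- rbinom(n, 1, 0.15)
    good <- plogis(qlogis(0.15) + 1.8 * (y + rnorm(n, sd = 1)))
    weak <- plogis(qlogis(0.15) + 1.8 * (0.4 * y + rnorm(n, sd = 1)))
    nb_g <- net_benefit_curve(good, y, grid, "model")$net_benefit
    nb_w <- net_benefit_curve(weak, y, grid, "model")$net_benefit
    diffs[seed, ] <- nb_g - nb_w
  }
  expect_true(all(colMeans(diffs) > 0))
})

test_that("the misclassification cross-tab partitions the cohort", {
  # all scores mid-band and all flagged: one occupied cell
  ct <- misclassification_crosstab(rep(TRUE, 10), rep(0.2, 10),
                                   rbinom(10, 1, 0.5))
  occ <- ct$table[ct$table$count > 0, ]
  expect_equal(nrow(occ), 1)
  expect_true(occ$serious_illness && occ$risk_band == "middle")

  # hand-tallied 10-record fixture
  si <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  s <- c(0.05, 0.50, 0.40, 0.02, 0.35, 0.20, 0.09, 0.95, 0.15, 0.10)
  y <- c(0, 1, 1, 0, 1, 0, 0, 1, 0, 0)
  ct <- misclassification_crosstab(si, s, y)
  get <- function(flag, band) {
    ct$table$count[ct$table$serious_illness == flag &
                     ct$table$risk_band == band]
  }
  expect_equal(get(TRUE, "low"), 2)     # 0.05, 0.09
  expect_equal(get(TRUE, "middle"), 1)  # 0.15
  expect_equal(get(TRUE, "high"), 2)    # 0.50, 0.40
  expect_equal(get(FALSE, "low"), 1)    # 0.02
  expect_equal(get(FALSE, "middle"), 2) # 0.20, 0.10 (boundary is middle)
  expect_equal(get(FALSE, "high"), 2)   # 0.35, 0.95
  expect_equal(ct$discordant_share, (2 + 2) / 10)

  # partition identity
  expect_equal(sum(ct$table$count), 10)
  concordant <- (get(TRUE, "high") + get(FALSE, "low")) / 10
  middle <- (get(TRUE, "middle") + get(FALSE, "middle")) / 10
  expect_equal(ct$discordant_share, 1 - concordant - middle)
})

test_that("confidence intervals bracket the point estimates", {
  set.seed(20)
  s <- runif(600); y <- rbinom(600, 1, s)
  ch <- characteristics(confusion_at_threshold(s, y, 0.3))
  expect_true(ch$sensitivity_lo <= ch$sensitivity &&
                ch$sensitivity <= ch$sensitivity_hi)
  expect_true(ch$lr_pos_lo <= ch$lr_pos && ch$lr_pos <= ch$lr_pos_hi)
  wald <- characteristics(confusion_at_threshold(s, y, 0.3),
                          ci_method = "wald")
  expect_false(identical(wald$sensitivity_lo, ch$sensitivity_lo))
  expect_equal(wald$sensitivity, ch$sensitivity)
})
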