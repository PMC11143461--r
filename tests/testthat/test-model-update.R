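test_that("recalibration recovers a known intercept shift", {
  m <- toy_model(c(a = 0.8, b = -0.5), intercept = -2)
  f <- toy_features(50000, c("a", "b"), seed = 101)
  eta <- predict(m, f, type = "link")

  # data generated by the model itself: delta -> 0
  y <- rbinom(nrow(f), 1, plogis(eta))
  recal <- recalibrate_intercept(m, f, y)
  expect_lt(abs(attr(recal, "delta")), 0.05)

  # odds multiplied by k: delta estimates log(k)
  k <- 2.5
  y2 <- rbinom(nrow(f), 1, plogis(eta + log(k)))
  recal2 <- recalibrate_intercept(m, f, y2)
  fit_se <- sqrt(1 / sum(plogis(eta + log(k)) * (1 - plogis(eta + log(k)))))
  expect_lt(abs(attr(recal2, "delta") - log(k)), 3 * fit_se)

  # idempotence: recalibrating the recalibrated model moves ~nothing
  recal3 <- recalibrate_intercept(recal2, f, y2)
  expect_lt(abs(attr(recal3, "delta")), 1e-6)

  expect_error(recalibrate_intercept(m, f, rep(1, nrow(f))), "both outcome")
})

test_that("intercept recalibration cannot change discrimination", {
  m <- toy_model(c(a = 1), intercept = -1)
  f <- toy_features(500, "a", seed = 5)
  y <- rbinom(500, 1, plogis(predict(m, f, type = "link")))
  recal <- recalibrate_intercept(m, f, y)
  expect_identical(auroc_delong(predict(recal, f), y)$auroc,
                   auroc_delong(predict(m, f), y)$auroc)
})

test_that("refit matches glm and recovers generating coefficients", {
  truth <- toy_model(c(a = 0.7, b = -0.4, c = 0.2), intercept = -1.5)
  f <- toy_features(20000, c("a", "b", "c"), seed = 22)
  y <- rbinom(nrow(f), 1, predict(truth, f))

  start <- toy_model(c(a = 0, b = 0, c = 0), intercept = 0)
  rf <- refit(start, f, y)
  expect_true(attr(rf, "converged"))

  # cross-check against the standard fitter
  g <- glm(y ~ a + b + c, data = cbind(f, y = y), family = binomial())
  expect_equal(unname(coef(rf)), unname(coef(g)), tolerance = 1e-6)

  # parameter recovery within 3 standard errors
  se <- attr(rf, "se")
  est <- coef(rf)
  true_vals <- coef(truth)
  for (nm in names(true_vals)) {
    expect_lt(abs(est[[nm]] - true_vals[[nm]]), 3 * se[[nm]])
  }
})

test_that("refit is invariant to row duplication and symmetric data", {
  m <- toy_model(c(a = 0), intercept = 0)
  f <- toy_features(400, "a", seed = 33)
  y <- rbinom(400, 1, plogis(f$a))
  r1 <- refit(m, f, y)
  r2 <- refit(m, rbind(f, f), c(y, y))
  expect_equal(coef(r1), coef(r2), tolerance = 1e-9)

  # balanced symmetric data: intercept ~ 0
  f_sym <- data.frame(a = c(1, -1, 1, -1))
  y_sym <- c(1, 0, 0, 1)
  r3 <- refit(m, f_sym, y_sym)
  expect_lt(abs(r3$intercept), 1e-6)
})

test_that("refit detects separation and names the covariate", {
  f <- data.frame(a = c(rep(1, 20), rep(-1, 20)))
  y <- c(rep(1, 20), rep(0, 20))
  expect_error(refit(toy_model(c(a = 0)), f, y), "separation.*'a'")
})

test_that("the refit likelihood dominates the original specification", {
  m <- toy_model(c(a = 0.3, b = 0.3), intercept = -1)
  f <- toy_features(3000, c("a", "b"), seed = 44)
  y <- rbinom(nrow(f), 1, plogis(-0.5 + 1.2 * f$a - 0.2 * f$b))
  rf <- refit(m, f, y)
  expect_gte(logLik_gest(rf, f, y), logLik_gest(m, f, y))
})

test_that("update comparison reports all three models on held-out data", {
  m <- toy_model(c(a = 0.8), intercept = -1)
  f <- toy_features(4000, "a", seed = 55)
  y <- rbinom(nrow(f), 1, predict(m, f))
  tr <- seq_len(2000); te <- 2001:4000
  recal <- recalibrate_intercept(m, f[tr, , drop = FALSE], y[tr])
  rf <- refit(m, f[tr, , drop = FALSE], y[tr])
  cmp <- compare_updates(m, recal, rf, f[te, , drop = FALSE], y[te])
  expect_named(cmp$summary, c("model", "auroc", "ci_low", "ci_high",
                              "calibration_in_the_large"))
  # identical specs give identical metrics
  cmp2 <- compare_updates(m, m, m, f[te, , drop = FALSE], y[te])
  expect_equal(cmp2$summary$auroc, rep(cmp2$summary$auroc[1], 3))
  # recalibration leaves AUROC untouched
  expect_identical(cmp$summary$auroc[1], cmp$summary$auroc[2])

  # refit on shifted-intercept truth restores calibration-in-the-large
  shifted <- m; shifted$intercept <- m$intercept + 1
  y_sh <- rbinom(nrow(f), 1, predict(shifted, f))
  rf_sh <- refit(m, f[tr, , drop = FALSE], y_sh[tr])
  cmp_sh <- compare_updates(m, m, rf_sh, f[te, , drop = FALSE], y_sh[te])
  citl <- cmp_sh$summary$calibration_in_the_large
  expect_lt(abs(citl[cmp_sh$summary$model == "refit"]),
            abs(citl[cmp_sh$summary$model == "original"]))
})

test_that("the slope variant rescales coefficients coherently", {
  m <- toy_model(c(a = 1), intercept = -1)
  f <- toy_features(20000, "a", seed = 66)
  # truth uses half the slope of the specification
  y <- rbinom(nrow(f), 1, plogis(-1 + 0.5 * f$a))
  recal <- recalibrate_intercept(m, f, y, slope = TRUE)
  expect_equal(attr(recal, "calibration_slope"), 0.5, tolerance = 0.1)
  expect_equal(recal$covariates$coefficient[1],
               attr(recal, "calibration_slope") * 1)
})
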