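test_that("AUROC matches brute-force pair enumeration, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    pr <- sample(seq(0.1, 0.9, by = 0.1), n, TRUE)  # forces ties
    expect_equal(auroc(pr, y), auroc_by_enumeration(pr, y))
  }
})

test_that("AUROC boundary cases and monotone-transform invariance", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
  set.seed(42)
  pr <- runif(200); y <- rbinom(200, 1, pr)
  expect_equal(auroc(pr, y), auroc(qlogis(pr), y))
  expect_equal(auroc(pr, y), auroc(pr^3, y))
})

test_that("calibration intercept recovers a constructed odds shift", {
  set.seed(43)
  pr <- runif(50000, 0.05, 0.95)
  y <- rbinom(50000, 1, pr)
  expect_equal(calibration_intercept(pr, y), 0, tolerance = 0.05)
  # halve the odds of every prediction: intercept must be ~ +log(2)
  shifted <- plogis(qlogis(pr) - log(2))
  expect_equal(calibration_intercept(shifted, y), log(2), tolerance = 0.05)
  # overestimation gives a negative intercept
  inflated <- plogis(qlogis(pr) + 1)
  expect_lt(calibration_intercept(inflated, y), -0.5)
})

test_that("a well-specified model trained on RUS-balanced data shows the sampling offset", {
  # case-control theory: balancing shifts the intercept by about
  # -logit(true event fraction), so the calibration intercept on a test set
  # at the true event fraction is about logit(ef)
  cf <- calibrate_generator(3, 0.1)
  set.seed(44)
  train <- generate_dataset(20000, cf)
  bal <- undersample(train)
  fit <- fit_logit(bal)
  test <- generate_dataset(50000, cf, seed = 45)
  ci <- calibration_intercept(predict(fit, test), test$y)
  expect_equal(ci, qlogis(0.1), tolerance = 0.15)
})

test_that("calibration slope recovers constructed distortions", {
  set.seed(46)
  pr <- runif(50000, 0.02, 0.98)
  y <- rbinom(50000, 1, pr)
  expect_equal(unname(calibration_slope(pr, y)["slope"]), 1, tolerance = 0.04)
  doubled <- plogis(2 * qlogis(pr))
  expect_equal(unname(calibration_slope(doubled, y)["slope"]), 0.5,
               tolerance = 0.03)
  expect_true(is.na(calibration_slope(rep(0.3, 100), rbinom(100, 1, 0.3))["slope"]))
})

test_that("flexible calibration curve tracks the diagonal for calibrated predictions", {
  set.seed(47)
  pr <- runif(20000, 0.05, 0.95)
  y <- rbinom(20000, 1, pr)
  cc <- flexible_calibration_curve(pr, y)
  expect_true(all(cc$observed >= 0 & cc$observed <= 1))
  expect_true(!is.unsorted(cc$predicted))
  expect_lt(max(abs(cc$observed - cc$predicted)), 0.02)
  # overestimating predictions put the curve below the diagonal
  infl <- plogis(qlogis(pr) + 1)
  cc2 <- flexible_calibration_curve(infl, y)
  inner <- cc2$predicted > 0.1 & cc2$predicted < 0.9
  expect_true(all(cc2$observed[inner] < cc2$predicted[inner]))
  expect_warning(expect_null(flexible_calibration_curve(runif(20), rbinom(20, 1, 0.5))),
                 "fewer than 50")
})

test_that("classification metrics match hand counts and the Box formulas", {
  # TP=3, FN=1, TN=5, FP=1, N=10
  pr <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.4, 0.45)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  cm <- classification_metrics(pr, y, 0.5)
  expect_equal(cm[c("tp", "fn", "tn", "fp")], list(tp = 3, fn = 1, tn = 5, fp = 1))
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, cm$n)
  # ties go to high risk
  expect_equal(classification_metrics(c(0.5, 0.49), c(1, 0), 0.5)$sensitivity, 1)
})

test_that("a classify-no-one model reaches 99% accuracy at 1% event fraction", {
  y <- rep(c(1L, 0L), c(10, 990))
  cm <- classification_metrics(rep(0.001, 1000), y, 0.5)
  expect_equal(cm$accuracy, 0.99)
  expect_equal(cm$sensitivity, 0)
  expect_equal(cm$specificity, 1)
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set.seed(48)
  pr <- runif(2000); y <- rbinom(2000, 1, pr)
  ts <- seq(0.05, 0.95, by = 0.05)
  sens <- sapply(ts, function(t) classification_metrics(pr, y, t)$sensitivity)
  spec <- sapply(ts, function(t) classification_metrics(pr, y, t)$specificity)
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("Net Benefit follows its formula and reference strategies", {
  # TP = 50, FP = 100 among N = 1000 at t = 0.1
  y <- rep(c(1, 0, 1, 0), c(50, 100, 20, 830))
  pr <- rep(c(0.9, 0.9, 0.01, 0.01), c(50, 100, 20, 830))
  expect_equal(net_benefit(pr, y, 0.1), (50 - (1 / 9) * 100) / 1000,
               tolerance = 1e-12)
  # treat-none has NB 0; treat-all crosses 0 exactly at t = prevalence
  dc <- decision_curve(pr, y, thresholds = c(0.05, mean(y), 0.3))
  expect_true(all(dc$nb_none == 0))
  expect_equal(dc$nb_all[2], 0, tolerance = 1e-12)
  # a perfect predictor attains NB = prevalence at every threshold
  dcp <- decision_curve(as.numeric(y), y, thresholds = seq(0.05, 0.5, 0.05))
  expect_true(all(abs(dcp$nb_model - mean(y)) < 1e-12))
  # the prevalence bound holds for any model
  expect_true(all(dc$nb_model <= mean(y) + 1e-12))
})

test_that("strong overestimation drives Net Benefit negative at high thresholds", {
  set.seed(49)
  pr <- runif(20000, 0.01, 0.6)
  y <- rbinom(20000, 1, pr)
  infl <- plogis(qlogis(pr) + 2)  # severe overestimation
  expect_lt(net_benefit(infl, y, 0.5), 0)
})

test_that("assess_predictions assembles a coherent performance record", {
  set.seed(50)
  pr <- runif(5000); y <- rbinom(5000, 1, pr)
  rec <- assess_predictions(pr, y, thresholds = c(0.2, 0.5))
  expect_equal(rec$auroc, auroc(pr, y))
  expect_equal(rec$cal_intercept, calibration_intercept(pr, y))
  expect_equal(rec$sens_0p5,
               classification_metrics(pr, y, 0.5)$sensitivity)
  expect_equal(rec$nb_0p2, net_benefit(pr, y, 0.2))
})
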