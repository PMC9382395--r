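test_that("SLR recovers the generating coefficients at large n", {
  cf <- calibrate_generator(3, 0.3)
  d <- generate_dataset(40000, cf, seed = 21)
  fit <- fit_logit(d)
  # asymptotic SEs from the information matrix of the true model
  X1 <- cbind(1, d$x)
  w <- d$pi_true * (1 - d$pi_true)
  se <- sqrt(diag(solve(crossprod(X1 * sqrt(w)))))
  truth <- c(cf$b0, rep(cf$beta, 3))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
  expect_true(fit$converged)
  expect_false(detect_separation(fit))
})

test_that("null data yields near-zero slopes and the prevalence intercept", {
  d <- generate_dataset(20000, list(b0 = qlogis(0.2), beta = 0, p = 3), seed = 22)
  fit <- fit_logit(d)
  expect_true(all(abs(fit$coef) < 0.05))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 0.02)
})

test_that("perfect separation is detected for SLR but not for ridge", {
  x <- matrix(c(seq(-2, -0.1, length.out = 10), seq(0.1, 2, length.out = 10)))
  d <- imb_data(x, rep(c(0L, 1L), each = 10))
  fit <- fit_logit(d)
  expect_true(detect_separation(fit))
  set.seed(23)
  fr <- fit_logit(d, penalty = "ridge", lambda = 1)
  expect_false(detect_separation(fr))
  expect_true(all(is.finite(coef(fr))))
})

test_that("ridge shrinks to the null model as lambda grows", {
  set.seed(24)
  d <- generate_dataset(2000, calibrate_generator(3, 0.3))
  fit <- fit_logit(d, penalty = "ridge", lambda = 1e6)
  expect_true(all(abs(fit$coef) < 1e-3))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-3)
})

test_that("ridge at negligible lambda matches the maximum-likelihood fit", {
  set.seed(25)
  d <- generate_dataset(3000, calibrate_generator(3, 0.3))
  f0 <- fit_logit(d)
  fr <- fit_logit(d, penalty = "ridge", lambda = 1e-9)
  expect_equal(coef(fr), coef(f0), tolerance = 1e-5)
})

test_that("ridge solutions agree with glmnet at fixed lambda", {
  library(glmnet)
  set.seed(26)
  d <- generate_dataset(2000, calibrate_generator(5, 0.2))
  for (lam in c(0.001, 0.05, 1)) {
    f <- fit_logit(d, penalty = "ridge", lambda = lam)
    g <- glmnet(d$x, d$y, family = "binomial", alpha = 0, lambda = lam,
                standardize = TRUE, thresh = 1e-12)
    expect_equal(unname(coef(f)), as.numeric(coef(g)), tolerance = 1e-6)
  }
})

test_that("cross-validated lambda choice matches cv.glmnet on identical folds", {
  library(glmnet)
  set.seed(27)
  d <- generate_dataset(2000, calibrate_generator(8, 0.2))
  set.seed(28)
  f <- fit_logit(d, penalty = "ridge")
  set.seed(28)
  foldid <- imbcalib:::stratified_folds(d$y, 10)
  cv <- cv.glmnet(d$x, d$y, family = "binomial", alpha = 0,
                  lambda = imbcalib:::default_lambda_grid(), foldid = foldid)
  expect_equal(f$lambda, cv$lambda.min, tolerance = 1e-10)
})

test_that("the L2 norm of ridge slopes is non-increasing in lambda", {
  set.seed(29)
  d <- generate_dataset(1500, calibrate_generator(6, 0.3))
  path <- imbcalib:::ridge_logit_path_cpp(d$x, as.double(d$y),
                                          imbcalib:::default_lambda_grid(),
                                          1e-9, 100)
  norms <- sqrt(colSums(path$coef[-1, ]^2))  # lambda decreasing -> norms grow
  expect_true(all(diff(norms) > -1e-8))
})

test_that("CV folds are stratified and the chosen lambda is seed-reproducible", {
  y <- rep(c(1L, 0L), c(25, 2475))
  set.seed(30)
  foldid <- imbcalib:::stratified_folds(y, 10)
  expect_true(all(tabulate(foldid[y == 1], 10) >= 1))
  d <- generate_dataset(3000, calibrate_generator(3, 0.1), seed = 31)
  set.seed(32); l1 <- fit_logit(d, penalty = "ridge")$lambda
  set.seed(32); l2 <- fit_logit(d, penalty = "ridge")$lambda
  expect_identical(l1, l2)
})

test_that("restricted cubic splines have the forced dimension and linear tails", {
  x <- seq(0, 10, length.out = 200)
  b <- rcs_basis(x)
  expect_equal(ncol(b), 2)
  # beyond the upper boundary knot every basis column is linear in x
  tail_x <- seq(12, 20, by = 0.5)
  bt <- rcs_basis(tail_x, knots = rcs_knots(x))
  expect_true(all(abs(diff(diff(bt[, 1]))) < 1e-10))
  expect_true(all(abs(diff(diff(bt[, 2]))) < 1e-10))
  # same below the lower boundary knot
  bl <- rcs_basis(seq(-10, -2, by = 0.5), knots = rcs_knots(x))
  expect_true(all(abs(diff(diff(bl[, 2]))) < 1e-10))
})

test_that("spline fit collapses to the linear fit when the truth is linear", {
  cf <- calibrate_generator(2, 0.3)
  d <- generate_dataset(30000, cf, seed = 33)
  flin <- fit_logit(d)
  frcs <- fit_logit(d, rcs_vars = 1)
  grid <- imb_data(cbind(seq(-2, 2, length.out = 50), 0), rep(0L, 50))
  expect_lt(max(abs(predict(frcs, grid) - predict(flin, grid))), 0.02)
})

test_that("too few distinct values for the knots falls back to a linear term", {
  x <- cbind(a = rep(c(0, 1), 50), b = rnorm(100))
  d <- imb_data(x, rbinom(100, 1, 0.4))
  expect_warning(fit <- fit_logit(d, rcs_vars = "a"), "linear term")
  expect_equal(length(fit$coef), 2)
})

test_that("the case-study spline model beats the linear model on the curved effect", {
  d <- generate_case_study(6000, seed = 34)
  flin <- fit_logit(d)
  frcs <- fit_logit(d, rcs_vars = c("age", "diameter"))
  expect_equal(length(frcs$coef), 5)  # 2 spline pairs + papillation
  test <- generate_case_study(6000, seed = 35)
  dev <- function(p) -2 * mean(test$y * log(p) + (1 - test$y) * log(1 - p))
  expect_lt(dev(predict(frcs, test)), dev(predict(flin, test)))
})

test_that("recalibration restores average calibration and is idempotent", {
  d <- generate_dataset(5000, calibrate_generator(3, 0.1), seed = 36)
  fit <- fit_logit(d)
  # construct a known miscalibration: shift the intercept by +1.5
  bad <- fit
  bad$intercept <- bad$intercept + 1.5
  rec <- recalibrate(bad, d)
  expect_equal(rec$recal_a, -1.5, tolerance = 0.05)
  # score equation: mean predicted probability equals the event fraction
  expect_equal(mean(predict(rec, d)), mean(d$y), tolerance = 1e-7)
  # idempotence
  rec2 <- recalibrate(rec, d)
  expect_equal(rec2$recal_a, 0, tolerance = 1e-6)
  # slopes untouched
  expect_equal(rec$coef, fit$coef)
})

test_that("predictions equal the hand-rolled dot product and respect clipping", {
  fit <- structure(list(intercept = 0.5, coef = c(x1 = 1, x2 = -2),
                        basis = list(p = 2, vars = NULL, knots = NULL,
                                     names = c("x1", "x2")),
                        penalty = "none", lambda = 0, recal_a = 0),
                   class = "imblogit")
  X <- rbind(c(0, 0), c(1, 1), c(-2, 0.5))
  expect_equal(predict(fit, X), plogis(0.5 + X %*% c(1, -2))[, 1])
  # all-zero coefficients, intercept 0 -> 0.5 everywhere
  fit$intercept <- 0; fit$coef[] <- 0
  expect_equal(predict(fit, X), rep(0.5, 3))
  # clipping at extreme intercepts
  fit$intercept <- 100
  expect_equal(predict(fit, X), rep(1 - 1e-10, 3))
  expect_equal(predict(fit, X, type = "link"), rep(qlogis(1 - 1e-10), 3))
})

test_that("fit failures are reported for degenerate inputs", {
  expect_error(fit_logit(imb_data(matrix(rnorm(20)), rep(1L, 20))),
               "single class")
  expect_error(predict(fit_logit(generate_dataset(100, list(b0 = 0, beta = 0, p = 2), seed = 1)),
                       matrix(0, 2, 3)), "expects")
})

test_that("offset Newton fits agree with glm", {
  set.seed(37)
  pr <- runif(3000, 0.02, 0.9)
  y <- rbinom(3000, 1, pr)
  lp <- qlogis(pr)
  expect_equal(imbcalib:::offset_intercept_mle(lp, y),
               unname(coef(glm(y ~ 1, offset = lp, family = binomial))),
               tolerance = 1e-7)
  expect_equal(unname(imbcalib:::logistic_two_param_mle(lp, y)),
               unname(coef(glm(y ~ lp, family = binomial))),
               tolerance = 1e-6)
})
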