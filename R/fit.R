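#' Fit a (possibly ridge-penalized) logistic risk model
#'
#' The central fitting function: standard maximum-likelihood logistic
#' regression (SLR, `penalty = "none"`) or ridge (L2) logistic regression with
#' the penalty weight tuned by stratified 10-fold cross-validated binomial
#' deviance over a lambda grid (`penalty = "ridge"`). Continuous predictors
#' can be expanded with restricted cubic splines.
#'
#' The ridge penalty applies to slopes only, never the intercept; predictors
#' are standardized internally for the penalty and coefficients are returned
#' on the original scale. After cross-validation the model is refit on the
#' full training data at the selected lambda.
#'
#' Separation of an SLR fit is flagged when all fitted training probabilities
#' are numerically 0/1 (outside `(1e-8, 1 - 1e-8)`) or any standardized
#' coefficient exceeds 20 in absolute value; the model is still returned with
#' `separation = TRUE` so a simulation engine can record it.
#'
#' @param data An [imb_data] training dataset with both classes present.
#' @param penalty `"none"` (maximum likelihood) or `"ridge"`.
#' @param lambda Ridge grid (decreasing values are assumed after sorting).
#'   Default: 30 values log-spaced over `[1e-4, 1e2]`. A single value skips
#'   cross-validation.
#' @param nfolds Number of cross-validation folds (default 10), stratified by
#'   outcome so every fold contains events.
#' @param rcs_vars Columns (names or indices) to expand with restricted cubic
#'   splines; `NULL` for a linear design.
#' @param n_knots Knots per spline (default 3: knots at the 0.10/0.50/0.90
#'   quantiles, adding one nonlinear term per variable).
#' @return An object of class `imblogit` with elements `intercept`, `coef`
#'   (design-basis scale), `basis`, `penalty`, `lambda`, `cv` (grid and mean
#'   deviances), `converged`, `separation`, `recal_a`.
#' @examples
#' set.seed(1)
#' d <- generate_dataset(500, list(b0 = -1, beta = 0.4, p = 3))
#' fit <- fit_logit(d)
#' coef(fit)
#' head(predict(fit, d))
#' @seealso [recalibrate()], [predict.imblogit()], [rcs_basis()]
#' @export
fit_logit <- function(data, penalty = c("none", "ridge"), lambda = NULL,
                      nfolds = 10, rcs_vars = NULL, n_knots = 3) {
  stopifnot(inherits(data, "imb_data"))
  penalty <- match.arg(penalty)
  y <- data$y
  if (length(unique(y)) < 2L) stop("fit failure: training data has a single class")

  basis <- build_basis_spec(data$x, rcs_vars, n_knots)
  X <- apply_basis(basis, data$x)
  if (penalty == "none" && nrow(X) <= ncol(X) + 1L)
    stop("fit failure: more design columns than rows")

  if (penalty == "none") {
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    cf <- fit$coefficients
    intercept <- cf[1]
    slopes <- cf[-1]
    converged <- isTRUE(fit$converged)
    mu <- fit$fitted.values
    lambda_sel <- 0
    cv <- NULL
  } else {
    if (is.null(lambda)) lambda <- default_lambda_grid()
    lambda <- sort(unique(as.double(lambda)), decreasing = TRUE)
    if (length(lambda) > 1L) {
      foldid <- stratified_folds(y, nfolds)
      # cross-validated deviances need far less precision than the final fit
      cvm <- cv_ridge_logit_cpp(X, as.double(y), lambda, foldid,
                                max(foldid), 1e-6, 50)
      lambda_sel <- lambda[which.min(cvm)]
      cv <- list(lambda = lambda, cvm = as.double(cvm))
    } else {
      lambda_sel <- lambda
      cv <- NULL
    }
    path <- ridge_logit_path_cpp(X, as.double(y),
                                 lambda[lambda >= lambda_sel], 1e-9, 100)
    j <- ncol(path$coef)
    cf <- path$coef[, j]
    intercept <- cf[1]
    slopes <- cf[-1]
    names(slopes) <- colnames(X)
    converged <- isTRUE(path$converged[j])
    mu <- stats::plogis(intercept + drop(X %*% slopes))
  }
  names(slopes) <- colnames(X)

  sd_x <- apply(X, 2, stats::sd)
  separation <- all(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(slopes * sd_x) > 20, na.rm = TRUE)

  structure(list(intercept = unname(intercept), coef = slopes, basis = basis,
                 penalty = penalty, lambda = lambda_sel, cv = cv,
                 converged = converged, separation = separation,
                 recal_a = 0, n = length(y), event_fraction = mean(y),
                 call = match.call()),
            class = "imblogit")
}

default_lambda_grid <- function() exp(seq(log(1e2), log(1e-4), length.out = 30))

# outcome-stratified fold assignment; guarantees events in every fold when
# there are at least `nfolds` events (else nfolds is reduced)
stratified_folds <- function(y, nfolds) {
  nfolds <- min(nfolds, max(sum(y == 1L), 2L), max(sum(y == 0L), 2L))
  foldid <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Has separation been detected for a fitted model?
#'
#' @param fit An [fit_logit()] result.
#' @return `TRUE` if the fit showed (quasi-)complete separation.
#' @export
detect_separation <- function(fit) {
  stopifnot(inherits(fit, "imblogit"))
  isTRUE(fit$separation)
}

#' Recalibrate a model's intercept on a dataset
#'
#' Fits a logistic regression on `data` with the logit of the model's
#' estimated probabilities as an offset and the intercept as the only free
#' parameter, then shifts the model intercept by the fitted value `a`. Slopes
#' are untouched. By the score equation of the intercept-only MLE, the mean
#' recalibrated probability on `data` equals its observed event fraction.
#'
#' In the simulation pipeline the recalibration data is the *original
#' imbalanced* training dataset, not the artificially balanced one — that is
#' what restores the intercept after an imbalance correction.
#'
#' @param fit An [fit_logit()] result.
#' @param data The recalibration dataset ([imb_data]).
#' @return The model with updated `intercept`; `recal_a` holds the shift.
#' @export
recalibrate <- function(fit, data) {
  stopifnot(inherits(fit, "imblogit"), inherits(data, "imb_data"))
  lp <- predict(fit, data, type = "link")
  a <- offset_intercept_mle(lp, data$y)
  fit$intercept <- fit$intercept + a
  fit$recal_a <- a
  fit
}

#' Predict event probabilities or logits
#'
#' @param object An [fit_logit()] result.
#' @param newdata An [imb_data] dataset or a predictor matrix with the arity
#'   of the training predictors.
#' @param type `"response"` for probabilities (clipped to
#'   `[1e-10, 1 - 1e-10]`) or `"link"` for the corresponding logit.
#' @param ... Unused.
#' @return A numeric vector.
#' @export
predict.imblogit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "imb_data")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$basis$p)
    stop(sprintf("newdata has %d predictors; model expects %d",
                 ncol(x), object$basis$p))
  X <- apply_basis(object$basis, x)
  pr <- clip_prob(stats::plogis(object$intercept + drop(X %*% object$coef)))
  if (type == "response") pr else stats::qlogis(pr)
}

#' @export
coef.imblogit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef)
}

#' @export
print.imblogit <- function(x, ...) {
  kind <- if (x$penalty == "ridge") {
    sprintf("ridge logistic model (lambda = %.4g)", x$lambda)
  } else "maximum-likelihood logistic model"
  cat("<imblogit>", kind, "\n")
  cat(sprintf("  n = %d, event fraction = %.3f, %d design columns\n",
              x$n, x$event_fraction, length(x$coef)))
  if (!is.null(x$basis$vars))
    cat("  restricted cubic splines on:", paste(x$basis$vars, collapse = ", "), "\n")
  if (x$recal_a != 0)
    cat(sprintf("  intercept recalibrated (shift a = %.4f)\n", x$recal_a))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$separation) cat("  WARNING: separation detected\n")
  print(coef(x))
  invisible(x)
}

#' @export
summary.imblogit <- function(object, ...) {
  structure(list(fit = object), class = "summary.imblogit")
}

#' @export
print.summary.imblogit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$cv)) {
    best <- which.min(x$fit$cv$cvm)
    cat(sprintf("  CV: %d lambdas, min mean deviance %.4f at lambda %.4g\n",
                length(x$fit$cv$lambda), x$fit$cv$cvm[best],
                x$fit$cv$lambda[best]))
  }
  invisible(x)
}
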