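#' Area under the ROC curve (concordance statistic)
#'
#' Probability that a random individual with the event receives a higher
#' predicted risk than a random individual without it, computed by the
#' rank-sum formulation with midranks, so ties count 1/2.
#'
#' @param probs Predicted probabilities (any monotone score works).
#' @param y Binary outcomes.
#' @return The AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(probs, y) {
  stopifnot(length(probs) == length(y))
  auroc_cpp(as.double(probs), as.integer(y))
}

#' Calibration intercept and calibration slope
#'
#' `calibration_intercept()` is the intercept `a` of the logistic regression
#' `logit P(Y = 1) = a + LP` on the evaluation set, where `LP = logit(probs)`
#' enters as an offset (its coefficient fixed at 1). Negative values indicate
#' overestimation: predictions were on average too high.
#'
#' `calibration_slope()` fits `logit P(Y = 1) = a' + b * LP` with both
#' parameters free and returns `c(intercept = a', slope = b)`. A slope below
#' 1 indicates predictions that are too extreme.
#'
#' Probabilities are clipped to `[1e-10, 1 - 1e-10]` before taking logits;
#' the fits use dedicated Newton iterations.
#'
#' @param probs Predicted probabilities.
#' @param y Binary outcomes.
#' @return A scalar (`calibration_intercept`) or a named length-2 vector
#'   (`calibration_slope`; `slope` is `NA` for constant predictions).
#' @examples
#' set.seed(1)
#' pr <- runif(2000, 0.05, 0.95)
#' y <- rbinom(2000, 1, pr)
#' calibration_intercept(pr, y)  # near 0
#' calibration_slope(pr, y)      # slope near 1
#' @export
calibration_intercept <- function(probs, y) {
  lp <- stats::qlogis(clip_prob(probs))
  offset_intercept_mle(lp, y)
}

#' @rdname calibration_intercept
#' @export
calibration_slope <- function(probs, y) {
  lp <- stats::qlogis(clip_prob(probs))
  logistic_two_param_mle(lp, y)
}

#' Flexible calibration curve
#'
#' Smooths the observed outcome against the logit of the predicted
#' probability with loess and maps the smooth back to the probability scale
#' on an evenly spaced grid of predicted probabilities, giving the observed
#' event probability conditional on the prediction. A well calibrated model
#' tracks the diagonal.
#'
#' @param probs Predicted probabilities (`n >= 50`).
#' @param y Binary outcomes.
#' @param span Loess span (default 0.75).
#' @param grid_size Number of grid points (default 100).
#' @return A `calibration_curve` data frame with columns `predicted` and
#'   `observed`, both in `[0, 1]`.
#' @export
flexible_calibration_curve <- function(probs, y, span = 0.75, grid_size = 100) {
  if (length(probs) < 50) {
    warning("fewer than 50 observations; calibration curve omitted")
    return(NULL)
  }
  pr <- clip_prob(probs)
  lp <- stats::qlogis(pr)
  fit <- stats::loess(y ~ lp, span = span, degree = 2,
                      control = stats::loess.control(surface = "interpolate"))
  grid <- seq(max(min(pr), 1e-6), min(max(pr), 1 - 1e-6),
              length.out = grid_size)
  obs <- stats::predict(fit, newdata = data.frame(lp = stats::qlogis(grid)))
  curve <- data.frame(predicted = grid, observed = pmin(pmax(obs, 0), 1))
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$predicted, x$observed, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "Estimated probability",
                 ylab = "Observed proportion", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Classification metrics at a risk threshold
#'
#' Individuals with predicted probability `>= t` are classified high risk.
#' Returns the confusion counts and accuracy `(TP + TN) / N`, sensitivity
#' `TP / (TP + FN)` and specificity `TN / (TN + FP)`.
#'
#' @param probs Predicted probabilities.
#' @param y Binary outcomes.
#' @param threshold Risk threshold `t` in (0, 1).
#' @return Named list with `accuracy`, `sensitivity`, `specificity`, `tp`,
#'   `fp`, `tn`, `fn`, `n`.
#' @examples
#' classification_metrics(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 0, 1), 0.5)
#' @export
classification_metrics <- function(probs, y, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  high <- probs >= threshold
  tp <- sum(high & y == 1)
  fp <- sum(high & y == 0)
  fn <- sum(!high & y == 1)
  tn <- sum(!high & y == 0)
  n <- length(y)
  list(accuracy = (tp + tn) / n,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn, n = n)
}

#' Net Benefit of treating at a risk threshold
#'
#' `NB = (TP - (t / (1 - t)) * FP) / N` for the strategy "treat when the
#' predicted probability is at least `t`". The threshold encodes the accepted
#' harm-benefit trade-off: at `t = 0.1` up to 9 false positives are tolerated
#' per true positive. Treat-none has Net Benefit 0 by definition; treat-all
#' has `prevalence - (t / (1 - t)) * (1 - prevalence)`.
#'
#' @param probs Predicted probabilities.
#' @param y Binary outcomes.
#' @param threshold Risk threshold in (0, 1).
#' @return The model's Net Benefit (a scalar).
#' @examples
#' net_benefit(c(0.9, 0.05, 0.3), c(1, 0, 0), 0.1)
#' @export
net_benefit <- function(probs, y, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  cm <- classification_metrics(probs, y, threshold)
  (cm$tp - threshold / (1 - threshold) * cm$fp) / cm$n
}

#' Decision curve
#'
#' Net Benefit of the model over a range of thresholds, together with the
#' treat-all and treat-none reference strategies.
#'
#' @param probs Predicted probabilities.
#' @param y Binary outcomes.
#' @param thresholds Vector of thresholds in (0, 1); default 0.05 to 0.50 in
#'   steps of 0.05.
#' @return A `decision_curve` data frame with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, y, thresholds = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  prev <- mean(y)
  nb <- vapply(thresholds, function(t) net_benefit(probs, y, t), 0)
  out <- data.frame(threshold = thresholds, nb_model = nb,
                    nb_all = prev - thresholds / (1 - thresholds) * (1 - prev),
                    nb_none = 0)
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  ylim <- range(c(x$nb_model, x$nb_all, 0))
  graphics::plot(x$threshold, x$nb_model, type = "l", ylim = ylim,
                 xlab = "Risk threshold", ylab = "Net Benefit", ...)
  graphics::lines(x$threshold, x$nb_all, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("Model", "Treat all", "Treat none"),
                   lty = 1:3, col = c("black", "grey40", "black"), bty = "n")
  invisible(x)
}

#' Full test-set performance record for one model
#'
#' Evaluates discrimination (AUROC), calibration (intercept and slope) and,
#' per threshold, classification metrics and Net Benefit.
#'
#' @param probs Predicted probabilities on the evaluation set.
#' @param y Binary outcomes.
#' @param thresholds Risk thresholds at which classification and Net Benefit
#'   are computed.
#' @return A one-row data frame: `auroc`, `cal_intercept`, `cal_slope`, and
#'   `acc_*`, `sens_*`, `spec_*`, `nb_*` per threshold (suffix = threshold).
#' @export
assess_predictions <- function(probs, y, thresholds = 0.5) {
  cs <- calibration_slope(probs, y)
  out <- data.frame(auroc = auroc(probs, y),
                    cal_intercept = calibration_intercept(probs, y),
                    cal_slope = unname(cs["slope"]))
  for (t in thresholds) {
    cm <- classification_metrics(probs, y, t)
    suf <- gsub("\\.", "p", format(t, trim = TRUE))
    out[[paste0("acc_", suf)]] <- cm$accuracy
    out[[paste0("sens_", suf)]] <- cm$sensitivity
    out[[paste0("spec_", suf)]] <- cm$specificity
    out[[paste0("nb_", suf)]] <- (cm$tp - t / (1 - t) * cm$fp) / cm$n
  }
  out
}
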