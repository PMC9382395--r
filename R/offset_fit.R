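# The two small logistic regressions used throughout: an intercept-only fit
# with a fixed offset, and a two-parameter fit of the outcome on a linear
# predictor. Both are Newton iterations (compiled kernels in src/metrics.cpp)
# because they run on 50k-100k-row test sets at event fractions down to 1%,
# where extreme logits occur; probabilities are clipped before any logit.

# clipping policy applied before any logit
clip_prob <- function(p) pmin(pmax(p, 1e-10), 1 - 1e-10)

# MLE of `a` in logit P(Y=1) = a + offset; strictly concave, Newton with a
# step cap converges from a = 0.
offset_intercept_mle <- function(offset, y, tol = 1e-10, maxit = 100) {
  offset_intercept_mle_cpp(as.double(offset), as.double(y), tol, maxit)
}

# MLE of (a, b) in logit P(Y=1) = a + b * lp, Newton with step-halving on the
# deviance. Returns c(intercept, slope); NA slope when lp is constant.
logistic_two_param_mle <- function(lp, y, tol = 1e-9, maxit = 100) {
  if (stats::sd(lp) < 1e-12) return(c(intercept = NA_real_, slope = NA_real_))
  ab <- logistic_two_param_mle_cpp(as.double(lp), as.double(y), tol, maxit)
  c(intercept = ab[1], slope = ab[2])
}
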