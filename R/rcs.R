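#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis in the standard (Harrell)
#' parameterization: with `k` knots \eqn{t_1 < \dots < t_k} the basis has
#' `k - 1` columns — the linear term plus `k - 2` nonlinear terms — and the
#' implied function is constrained to be linear beyond the boundary knots.
#' With the default 3 knots (placed at the 0.10/0.50/0.90 quantiles) a single
#' nonlinear term is added per variable.
#'
#' @param x Numeric vector.
#' @param knots Knot locations; defaults to [rcs_knots()] of `x`.
#' @return A matrix with `length(knots) - 1` columns.
#' @examples
#' b <- rcs_basis(1:100)
#' ncol(b)  # 2 columns for 3 knots
#' @export
rcs_basis <- function(x, knots = rcs_knots(x)) {
  k <- length(knots)
  stopifnot(k >= 3, !is.unsorted(knots, strictly = TRUE))
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  denom <- (knots[k] - knots[1L])^2
  cube <- function(t) pmax(x - t, 0)^3
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (cube(knots[j]) -
      cube(knots[k - 1L]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1L]) +
      cube(knots[k]) * (knots[k - 1L] - knots[j]) / (knots[k] - knots[k - 1L])) /
      denom
  }
  out
}

#' @rdname rcs_basis
#' @param n_knots Number of knots (default 3).
#' @export
rcs_knots <- function(x, n_knots = 3) {
  probs <- if (n_knots == 3) c(0.10, 0.50, 0.90)
           else seq(0.05, 0.95, length.out = n_knots)
  unname(stats::quantile(x, probs, type = 7))
}

# A basis specification freezes, at training time, which predictor columns are
# expanded with splines and where their knots sit, so that the identical
# transform is applied at prediction time.
build_basis_spec <- function(x, rcs_vars, n_knots) {
  p <- ncol(x)
  nm <- colnames(x)
  if (is.null(rcs_vars))
    return(list(p = p, vars = NULL, knots = NULL, names = nm))
  if (is.numeric(rcs_vars)) rcs_vars <- nm[rcs_vars]
  stopifnot(all(rcs_vars %in% nm))
  knots <- list()
  keep <- character(0)
  for (v in rcs_vars) {
    kn <- rcs_knots(x[, v], n_knots)
    if (length(unique(x[, v])) < n_knots || anyDuplicated(kn)) {
      warning(sprintf("too few distinct values for %d knots on '%s'; using a linear term",
                      n_knots, v))
    } else {
      knots[[v]] <- kn
      keep <- c(keep, v)
    }
  }
  list(p = p, vars = if (length(keep)) keep else NULL,
       knots = if (length(keep)) knots else NULL, names = nm)
}

apply_basis <- function(basis, x) {
  if (is.null(colnames(x))) colnames(x) <- basis$names
  if (is.null(basis$vars)) return(x)
  cols <- list()
  for (v in basis$names) {
    if (v %in% basis$vars) {
      b <- rcs_basis(x[, v], basis$knots[[v]])
      colnames(b) <- c(v, paste0(v, "'", seq_len(ncol(b) - 1L)))
      cols[[v]] <- b
    } else {
      b <- x[, v, drop = FALSE]
      cols[[v]] <- b
    }
  }
  do.call(cbind, cols)
}
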