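# Independent oracles used across tests.

# concordance by explicit enumeration of all event/nonevent pairs
auroc_by_enumeration <- function(probs, y) {
  ev <- probs[y == 1]
  ne <- probs[y == 0]
  if (!length(ev) || !length(ne)) return(NA_real_)
  tot <- 0
  for (a in ev) for (b in ne) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}

# does `point` lie on the segment x_i -> x_j (common interpolation factor in
# [0, 1] across coordinates)?
on_segment <- function(point, xi, xj, tol = 1e-8) {
  d <- xj - xi
  r <- point - xi
  if (all(abs(d) < tol)) return(all(abs(r) < tol))
  u <- r[which.max(abs(d))] / d[which.max(abs(d))]
  if (u < -tol || u > 1 + tol) return(FALSE)
  all(abs(r - u * d) < tol)
}

# small imbalanced toy dataset with fixed geometry
toy_imbalanced <- function(n_min = 10, n_maj = 90, p = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n_min + n_maj) * p), ncol = p)
  imb_data(x, rep(c(1L, 0L), c(n_min, n_maj)))
}
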