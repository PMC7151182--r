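# Shared fixtures and independent oracles used across test files.

# random positive-definite correlation matrix from actual data, so that
# matrix-algebra results can be cross-checked against regression residuals
# computed from the same data
random_data_cor <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  X <- matrix(rnorm(n * p), n) %*% A
  list(X = X, S = stats::cor(X))
}

# brute-force partial correlation of columns i, j given all others:
# correlate the residuals of each variable regressed on the remaining p - 2
residual_pcor <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::lsfit(X[, others], X[, i])$residuals
  rj <- stats::lsfit(X[, others], X[, j])$residuals
  stats::cor(ri, rj)
}

# exhaustive grid minimization of the ML discrepancy over 1-2 free
# parameters; independent of the optimizer under test
grid_fit <- function(spec, s, lower, upper, n_grid = 61, refine = 4) {
  stopifnot(spec$q == length(lower))
  S <- s$values
  obj <- function(th) tryCatch(
    f_ml_discrepancy(S, build_sigma(spec, th)),
    error = function(e) Inf)
  lo <- lower; hi <- upper
  best <- NULL
  for (r in seq_len(refine)) {
    grids <- Map(function(l, h) seq(l, h, length.out = n_grid), lo, hi)
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, obj)
    k <- which.min(vals)
    best <- list(par = pts[k, ], value = vals[k])
    step <- vapply(grids, function(g) g[2] - g[1], numeric(1))
    lo <- pmax(lower, best$par - step)
    hi <- pmin(upper, best$par + step)
  }
  best
}

id15 <- function() paste0("V", 1:15)
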