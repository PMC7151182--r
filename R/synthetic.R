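#' Population correlation matrix from a factor structure
#'
#' Builds `Sigma = Lambda Psi t(Lambda) + Theta` with residual variances
#' completed as `1 - communality` so that the population matrix has unit
#' diagonal (i.e. it is a correlation matrix). A communality at or above 1
#' is a Heywood population and an error.
#'
#' @param loadings numeric p x m loading matrix (rows may be named).
#' @param latent_cov m x m latent covariance; defaults to the identity.
#' @param residuals optional residual variances; defaults to
#'   `1 - diag(Lambda Psi t(Lambda))`.
#' @param labels observed labels; default from `loadings` rownames.
#' @return An object of class `population_model` with `kind = "factor"`,
#'   the generating matrices, and `sigma` (the population correlation
#'   matrix).
#' @export
factor_population_sigma <- function(loadings, latent_cov = NULL,
                                    residuals = NULL, labels = NULL) {
  L <- as.matrix(loadings)
  p <- nrow(L)
  if (is.null(latent_cov)) latent_cov <- diag(ncol(L))
  if (is.null(labels))
    labels <- if (!is.null(rownames(L))) rownames(L) else
      paste0("V", seq_len(p))
  common <- L %*% latent_cov %*% t(L)
  if (is.null(residuals)) {
    if (any(diag(common) >= 1))
      stop("Heywood population: communality >= 1")
    residuals <- 1 - diag(common)
  }
  sigma <- common + diag(residuals, p)
  if (max(abs(diag(sigma) - 1)) > 1e-10)
    stop("population diagonal does not equal 1")
  diag(sigma) <- 1
  dimnames(sigma) <- list(labels, labels)
  structure(list(kind = "factor", loadings = L, latent_cov = latent_cov,
                 residuals = residuals, sigma = sigma, labels = labels,
                 p = p),
            class = "population_model")
}

#' Population correlation matrix from a sparse precision pattern
#'
#' Builds a Gaussian graphical model population: a precision matrix with
#' unit diagonal and the given edge weights, diagonally dominated into
#' positive definiteness if needed, then inverted and standardized to a
#' correlation matrix. The partial correlations of `sigma` are zero exactly
#' where the precision pattern is zero.
#'
#' @param p number of variables.
#' @param edges two-column matrix of variable indices (or labels).
#' @param weights partial-correlation-scale edge weights (recycled).
#' @param labels observed labels.
#' @return A `population_model` with `kind = "ggm"`, `precision` and
#'   `sigma`.
#' @export
ggm_population <- function(p, edges, weights = 0.3,
                           labels = paste0("V", seq_len(p))) {
  edges <- matrix(edges, ncol = 2)
  if (is.character(edges)) {
    edges <- cbind(match(edges[, 1], labels), match(edges[, 2], labels))
  }
  weights <- rep_len(weights, nrow(edges))
  K <- diag(p)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    K[i, j] <- K[j, i] <- -weights[r]  # negative precision = positive pcor
  }
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0.05) diag(K) <- diag(K) + (0.05 - ev)
  sigma <- solve(K)
  d <- 1 / sqrt(diag(sigma))
  sigma <- sigma * tcrossprod(d)
  diag(sigma) <- 1
  dimnames(sigma) <- list(labels, labels)
  prec <- solve(sigma)
  prec[abs(prec) < 1e-12] <- 0
  structure(list(kind = "ggm", precision = prec, edges = edges,
                 sigma = sigma, labels = labels, p = p),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> kind = %s, p = %d\n", x$kind, x$p))
  invisible(x)
}

#' Sample correlation matrix from a population
#'
#' Draws `n` multivariate-normal observations from the population matrix and
#' returns their sample correlation matrix.
#'
#' @param pop a `population_model`.
#' @param n sample size; a warning is issued when `n <= p`.
#' @param seed RNG seed (applied locally; the caller's RNG state is
#'   untouched).
#' @return A [cor_matrix] with `kind = "full"` and the given `n`.
#' @export
sample_correlation <- function(pop, n, seed) {
  stopifnot(inherits(pop, "population_model"))
  if (n <= pop$p) warning("n <= p: sample matrix may be singular")
  r <- with_local_seed(seed, {
    x <- MASS::mvrnorm(n, mu = rep(0, pop$p), Sigma = pop$sigma)
    stats::cor(x)
  })
  cor_matrix(r, labels = pop$labels, kind = "full", n = n)
}

#' Synthetic study bundle emulating a standardization-sample design
#'
#' Generates the three-sample layout of a test-battery standardization
#' study: one training sample pooled from five age-band sub-tables (n = 200
#' each, pooled n = 1000) and two validation samples pooled from two
#' sub-tables each (pooled n = 400), all drawn from one shared 15-subtest
#' bifactor population with a strong general factor (g loadings uniform on
#' 0.6-0.8) and weaker group factors (loadings uniform on 0.3-0.5) over the
#' [wais_factor_map()] layout. The population has a complete positive
#' manifold: all 105 population correlations are positive.
#'
#' @param seed integer seed controlling the population draw and all sample
#'   draws.
#' @param fm a [factor_map]; group memberships define the group-factor
#'   loadings (cross-loadings are not used in the population).
#' @return List with `population`, `labels`, `train` (a [cor_table_set],
#'   pooled n = 1000) and `validation` (named list of two `cor_table_set`s,
#'   pooled n = 400 each, named `gen17` and `gen63` after the age-band
#'   layout they emulate).
#' @export
make_wais_like_study <- function(seed = 1, fm = wais_factor_map()) {
  labels <- fm$labels
  p <- length(labels)
  pop <- with_local_seed(seed, {
    g <- stats::runif(p, 0.6, 0.8)
    grp <- stats::runif(p, 0.3, 0.5)
    L <- matrix(0, p, 1 + length(fm$groups),
                dimnames = list(labels, c("g", names(fm$groups))))
    L[, "g"] <- g
    for (nm in names(fm$groups)) L[fm$groups[[nm]], nm] <- grp[
      match(fm$groups[[nm]], labels)]
    factor_population_sigma(L)
  })
  draw_set <- function(n_tables, n_each, seed_base) {
    tabs <- lapply(seq_len(n_tables), function(i)
      sample_correlation(pop, n_each, seed = seed_base + i))
    cor_table_set(tabs)
  }
  list(population = pop, labels = labels,
       train = draw_set(5, 200, seed * 1000L),
       validation = list(gen17 = draw_set(2, 200, seed * 1000L + 100L),
                         gen63 = draw_set(2, 200, seed * 1000L + 200L)))
}
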