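#' Covariance-structure model specification
#'
#' A pattern-matrix description of a model for a p x p correlation matrix.
#' Two forms are supported.
#'
#' **Factor form** uses the LISREL-style decomposition
#' `Sigma = Lambda Psi t(Lambda) + Theta`. `lambda_pattern` is a p x m
#' matrix over observed variables (rows) and latent factors (columns) whose
#' cells are either a fixed numeric value (typically 0) or `NA` for a free
#' loading. `psi_pattern` is the m x m latent covariance in the same
#' free/fixed encoding; latent variances are conventionally fixed to 1 so
#' that loadings are identified. A hierarchical (second-order) structure
#' replaces `psi_pattern` with `second_order = list(gamma_pattern = m x k
#' pattern of loadings of the first-order factors on k standardized
#' second-order factors)`; first-order disturbance variances are then free,
#' so `Psi = Gamma t(Gamma) + D`. `theta_pattern` is the p x p residual
#' covariance pattern; by default a free diagonal with fixed zero
#' off-diagonals.
#'
#' **Network form** models the precision matrix directly:
#' `Sigma = solve(K)` where the diagonal of `K` is always free and the free
#' off-diagonal cells are exactly the pairs in `edges`; all other entries are
#' fixed to zero. This is the two-stage network model: an edge-selection
#' stage chooses the pattern, and the ML fit estimates edge magnitudes.
#'
#' @param name model name used in reports.
#' @param form `"factor"` or `"network"`.
#' @param observed character vector of observed-variable labels.
#' @param lambda_pattern,psi_pattern,theta_pattern factor-form patterns
#'   (numeric matrices with `NA` marking free cells). `theta_pattern`
#'   defaults to a free diagonal. `psi_pattern` defaults to a fixed identity.
#' @param second_order optional list with `gamma_pattern` (m x k pattern);
#'   overrides `psi_pattern`.
#' @param edges network-form [edge_set] (or a two-column matrix of label
#'   pairs).
#' @return An object of class `model_spec`; `$q` is the free-parameter count
#'   and `$df = p(p+1)/2 - q`.
#' @export
model_spec <- function(name, form = c("factor", "network"), observed,
                       lambda_pattern = NULL, psi_pattern = NULL,
                       theta_pattern = NULL, second_order = NULL,
                       edges = NULL) {
  form <- match.arg(form)
  observed <- as.character(observed)
  p <- length(observed)
  spec <- list(name = name, form = form, observed = observed, p = p)

  if (form == "factor") {
    lambda_pattern <- as.matrix(lambda_pattern)
    if (nrow(lambda_pattern) != p)
      stop("lambda_pattern must have one row per observed variable")
    m <- ncol(lambda_pattern)
    if (is.null(colnames(lambda_pattern)))
      colnames(lambda_pattern) <- paste0("F", seq_len(m))
    rownames(lambda_pattern) <- observed
    if (is.null(theta_pattern)) {
      theta_pattern <- matrix(0, p, p)
      diag(theta_pattern) <- NA
    }
    theta_pattern <- as.matrix(theta_pattern)
    check_sym_pattern(theta_pattern, "theta_pattern")
    if (!is.null(second_order)) {
      gp <- as.matrix(second_order$gamma_pattern)
      if (nrow(gp) != m)
        stop("gamma_pattern must have one row per first-order factor")
      spec$gamma_pattern <- gp
      spec$psi_pattern <- NULL
    } else {
      if (is.null(psi_pattern)) psi_pattern <- diag(m)
      psi_pattern <- as.matrix(psi_pattern)
      check_sym_pattern(psi_pattern, "psi_pattern")
      spec$psi_pattern <- psi_pattern
    }
    spec$lambda_pattern <- lambda_pattern
    spec$theta_pattern <- theta_pattern
    spec$m <- m
  } else {
    if (is.null(edges)) edges <- edge_set(NULL, observed)
    if (!inherits(edges, "edge_set")) edges <- edge_set(edges, observed)
    if (!all(edges$pairs %in% observed))
      stop("edge references unknown label")
    spec$edges <- edges
  }

  spec <- structure(spec, class = "model_spec")
  spec$params <- enumerate_params(spec)
  spec$q <- nrow(spec$params)
  nmom <- p * (p + 1) / 2
  if (spec$q > nmom)
    stop(sprintf("over-parameterized: %d free parameters for %d moments",
                 spec$q, nmom))
  spec$df <- nmom - spec$q
  spec
}

check_sym_pattern <- function(pat, what) {
  free <- is.na(pat)
  if (!isTRUE(all.equal(free, t(free))) ||
      any(pat[!free] != t(pat)[!free], na.rm = TRUE))
    stop(what, " must be a symmetric pattern")
}

# One row per free parameter: block, row index, column index.
enumerate_params <- function(spec) {
  rows <- list()
  add <- function(block, idx) {
    if (nrow(idx))
      rows[[length(rows) + 1]] <<- data.frame(block = block, i = idx[, 1],
                                              j = idx[, 2])
  }
  if (spec$form == "factor") {
    add("lambda", which(is.na(spec$lambda_pattern), arr.ind = TRUE))
    if (!is.null(spec$gamma_pattern)) {
      add("gamma", which(is.na(spec$gamma_pattern), arr.ind = TRUE))
      add("dist", cbind(seq_len(spec$m), seq_len(spec$m)))
    } else {
      free <- which(is.na(spec$psi_pattern) & row(spec$psi_pattern) >=
                      col(spec$psi_pattern), arr.ind = TRUE)
      add("psi", free)
    }
    free <- which(is.na(spec$theta_pattern) & row(spec$theta_pattern) >=
                    col(spec$theta_pattern), arr.ind = TRUE)
    add("theta", free)
  } else {
    p <- spec$p
    add("prec_diag", cbind(seq_len(p), seq_len(p)))
    if (spec$edges$E) {
      ij <- cbind(match(spec$edges$pairs[, 1], spec$observed),
                  match(spec$edges$pairs[, 2], spec$observed))
      add("prec_off", ij)
    }
  }
  if (!length(rows))
    return(data.frame(block = character(0), i = integer(0), j = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degrees of freedom of a model specification
#'
#' `df = p(p+1)/2 - q` with `q` the number of distinct free parameters; for
#' the network form `q = p + E`, so `df = p(p-1)/2 - E`.
#'
#' @param spec a [model_spec].
#' @return Integer degrees of freedom.
#' @export
count_df <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  spec$df
}

# Assemble the component matrices at a parameter vector.
spec_matrices <- function(spec, theta_vec) {
  stopifnot(length(theta_vec) == spec$q)
  pr <- spec$params
  out <- list()
  if (spec$form == "factor") {
    L <- spec$lambda_pattern
    Th <- spec$theta_pattern
    for (k in which(pr$block == "lambda"))
      L[pr$i[k], pr$j[k]] <- theta_vec[k]
    for (k in which(pr$block == "theta")) {
      Th[pr$i[k], pr$j[k]] <- theta_vec[k]
      Th[pr$j[k], pr$i[k]] <- theta_vec[k]
    }
    if (!is.null(spec$gamma_pattern)) {
      G <- spec$gamma_pattern
      for (k in which(pr$block == "gamma"))
        G[pr$i[k], pr$j[k]] <- theta_vec[k]
      D <- diag(theta_vec[pr$block == "dist"], spec$m)
      Psi <- tcrossprod(G) + D
      out$gamma <- G
      out$dist <- diag(D)
    } else {
      Psi <- spec$psi_pattern
      for (k in which(pr$block == "psi")) {
        Psi[pr$i[k], pr$j[k]] <- theta_vec[k]
        Psi[pr$j[k], pr$i[k]] <- theta_vec[k]
      }
    }
    out$lambda <- L
    out$psi <- Psi
    out$theta <- Th
  } else {
    K <- matrix(0, spec$p, spec$p)
    for (k in seq_len(nrow(pr))) {
      K[pr$i[k], pr$j[k]] <- theta_vec[k]
      K[pr$j[k], pr$i[k]] <- theta_vec[k]
    }
    out$K <- K
  }
  out
}

#' Implied covariance matrix of a model at a parameter vector
#'
#' Factor form: `Sigma = Lambda Psi t(Lambda) + Theta` (with
#' `Psi = Gamma t(Gamma) + D` for second-order specifications). Network
#' form: `Sigma = solve(K)` for the assembled precision matrix.
#'
#' @param spec a [model_spec].
#' @param theta_vec numeric vector of free-parameter values, length `spec$q`.
#' @return The implied p x p matrix; for the network form an error if the
#'   assembled precision matrix is singular.
#' @export
build_sigma <- function(spec, theta_vec) {
  mats <- spec_matrices(spec, theta_vec)
  if (spec$form == "factor") {
    Sig <- mats$lambda %*% mats$psi %*% t(mats$lambda) + mats$theta
  } else {
    Sig <- solve(mats$K)
  }
  Sig <- (Sig + t(Sig)) / 2
  dimnames(Sig) <- list(spec$observed, spec$observed)
  Sig
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s form): p = %d, q = %d, df = %d\n",
              x$name, x$form, x$p, x$q, x$df))
  invisible(x)
}
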