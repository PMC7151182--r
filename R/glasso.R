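#' Graphical lasso for a sparse precision matrix
#'
#' Estimates a sparse inverse of a correlation (or covariance) matrix by
#' L1-penalized maximum likelihood: `theta` maximizes
#' `log det(T) - tr(S T) - lam * sum(|T[i, j]|, i != j)` with the diagonal
#' unpenalized. The solver is the classical block coordinate-descent
#' algorithm: each column's off-diagonal block solves a lasso regression
#' against the current covariance estimate, cycled until the working
#' covariance stabilizes; the precision matrix is then recovered column by
#' column.
#'
#' @param s a [cor_matrix] (or plain symmetric matrix) to fit.
#' @param lam penalty, `lam >= 0`. At `lam = 0` the input must be positive
#'   definite and the solution is its direct inverse.
#' @param tol convergence tolerance on the working covariance update,
#'   relative to the mean absolute off-diagonal of `s`.
#' @param max_sweeps maximum number of full column sweeps.
#' @param zero_tol entries of `theta` below this magnitude count as absent
#'   edges.
#' @param warm optional `glasso_solution` used to warm-start the lasso
#'   coefficients (speeds up path computation).
#' @return An object of class `glasso_solution` with elements `lam`, `theta`
#'   (precision estimate), `w` (its inverse), `pcor` (implied partial
#'   correlations `-theta[i,j]/sqrt(theta[i,i] theta[j,j])`), `edges` (an
#'   [edge_set]), `s` (the input matrix), `labels`, `kkt` (max KKT residual)
#'   and `sweeps`.
#' @export
glasso_fit <- function(s, lam, tol = 1e-7, max_sweeps = 500,
                       zero_tol = 1e-8, warm = NULL) {
  if (inherits(s, "cor_matrix")) {
    labels <- s$labels
    S <- s$values
  } else {
    S <- as.matrix(s)
    labels <- if (!is.null(colnames(S))) colnames(S) else
      paste0("V", seq_len(ncol(S)))
  }
  p <- ncol(S)
  if (lam < 0) stop("penalty must be non-negative")

  if (lam == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12)
      stop("input must be positive definite when lam = 0")
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    return(finish_glasso(S, theta, lam, labels, zero_tol, kkt = 0,
                         sweeps = 0L, B = -theta / diag(theta)[col(theta)]))
  }

  W <- S
  # B[, j] holds the lasso coefficients of column j on the others
  B <- if (!is.null(warm) && !is.null(warm$B) && ncol(warm$B) == p)
    warm$B else matrix(0, p, p)
  scale_ref <- mean(abs(S[row(S) != col(S)]))
  if (scale_ref == 0) scale_ref <- 1
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    delta <- 0
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, lam, beta = B[idx, j])
      B[idx, j] <- beta
      w12 <- as.vector(W11 %*% beta)
      delta <- max(delta, max(abs(W[idx, j] - w12)))
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (delta < tol * scale_ref || sweeps >= max_sweeps) break
  }

  # recover precision column-wise: theta_jj = 1/(w_jj - w12' beta)
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    tjj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    theta[j, j] <- tjj
    theta[idx, j] <- -B[idx, j] * tjj
  }
  theta <- (theta + t(theta)) / 2
  theta[abs(theta) < zero_tol & row(theta) != col(theta)] <- 0

  # KKT residual for the penalized problem: |W - S| <= lam off-diagonal,
  # with equality of sign where theta is nonzero
  R <- W - S
  diag(R) <- 0
  viol <- pmax(abs(R) - lam, 0)
  nz <- theta != 0 & row(theta) != col(theta)
  viol[nz] <- abs(R[nz] - lam * sign(theta[nz]))
  kkt <- max(viol)
  if (sweeps >= max_sweeps && kkt > 1e-4)
    stop(sprintf("graphical lasso did not converge in %d sweeps (KKT residual %.3e)",
                 max_sweeps, kkt))
  finish_glasso(S, theta, lam, labels, zero_tol, kkt, sweeps, B)
}

finish_glasso <- function(S, theta, lam, labels, zero_tol, kkt, sweeps, B) {
  dimnames(theta) <- list(labels, labels)
  w <- solve(theta)
  d <- 1 / sqrt(diag(theta))
  pcor <- -theta * tcrossprod(d)
  diag(pcor) <- 1
  edges <- edge_set_from_theta(theta, labels, zero_tol)
  structure(list(lam = lam, theta = theta, w = w, pcor = pcor,
                 edges = edges, s = S, labels = labels, kkt = kkt,
                 sweeps = sweeps, B = B),
            class = "glasso_solution")
}

# coordinate descent for 0.5 b'Wb - s'b + lam |b|_1
lasso_cd <- function(W11, s12, lam, beta, tol = 1e-10, max_iter = 1000) {
  k <- length(s12)
  if (k == 0) return(numeric(0))
  Wb <- as.vector(W11 %*% beta)
  for (it in seq_len(max_iter)) {
    dmax <- 0
    for (m in seq_len(k)) {
      old <- beta[m]
      resid <- s12[m] - Wb[m] + W11[m, m] * old
      new <- sign(resid) * max(abs(resid) - lam, 0) / W11[m, m]
      if (new != old) {
        beta[m] <- new
        Wb <- Wb + W11[, m] * (new - old)
        dmax <- max(dmax, abs(new - old))
      }
    }
    if (dmax < tol) break
  }
  beta
}

#' Edge set of a Gaussian graphical model
#'
#' Unordered variable pairs with nonzero precision entries.
#'
#' @param pairs two-column character matrix of label pairs (may have zero
#'   rows).
#' @param labels the full variable label set the pairs refer to.
#' @return An object of class `edge_set` with elements `pairs`, `E` (edge
#'   count) and `labels`.
#' @export
edge_set <- function(pairs, labels) {
  pairs <- if (is.null(pairs) || !length(pairs)) {
    matrix(character(0), 0, 2)
  } else {
    matrix(as.character(pairs), ncol = 2)
  }
  if (nrow(pairs)) {
    if (!all(pairs %in% labels)) stop("edge references unknown label")
    if (any(pairs[, 1] == pairs[, 2])) stop("self-edges are not allowed")
    ord <- t(apply(pairs, 1, function(r) r[order(match(r, labels))]))
    key <- paste(ord[, 1], ord[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
    pairs <- ord[order(match(ord[, 1], labels), match(ord[, 2], labels)), ,
                 drop = FALSE]
  }
  structure(list(pairs = pairs, E = nrow(pairs), labels = labels),
            class = "edge_set")
}

edge_set_from_theta <- function(theta, labels, zero_tol = 1e-8) {
  p <- ncol(theta)
  ut <- which(upper.tri(theta) & abs(theta) > zero_tol, arr.ind = TRUE)
  pairs <- cbind(labels[ut[, 1]], labels[ut[, 2]])
  edge_set(pairs, labels)
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %d edges over %d variables\n", x$E,
              length(x$labels)))
  invisible(x)
}

#' Penalty path for the graphical lasso
#'
#' Log-spaced descending grid of `n_lambda` penalties from
#' `lam_max = max |s[i, j]|` (off-diagonal) down to `lam_max * ratio`. At
#' `lam_max` the solution is the empty graph, so the grid spans the full
#' sparsity range.
#'
#' @param s a [cor_matrix] or plain symmetric matrix.
#' @param n_lambda number of penalties (>= 2).
#' @param ratio smallest penalty as a fraction of `lam_max`, in (0, 1).
#' @return Numeric vector of penalties in decreasing order; a single 0 (with
#'   a warning) when all off-diagonals are zero.
#' @export
lambda_path <- function(s, n_lambda = 100, ratio = 0.01) {
  S <- if (inherits(s, "cor_matrix")) s$values else as.matrix(s)
  if (n_lambda < 2) stop("n_lambda must be at least 2")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  lmax <- max(abs(S[row(S) != col(S)]))
  if (lmax == 0) {
    warning("all off-diagonal entries are zero; returning lambda = 0")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Extended BIC of a graphical-lasso solution
#'
#' `EBIC = -n * (log det(theta) - tr(S theta)) + E * log(n)
#'  + 4 * E * gamma * log(p)`, where `E` is the edge count. `gamma = 0`
#' recovers the ordinary BIC; larger `gamma` favors sparser graphs.
#'
#' @param sol a `glasso_solution`.
#' @param n sample size. A warning is issued when `n <= p`.
#' @param gamma EBIC hyperparameter, `gamma >= 0`.
#' @param s sample matrix used in the likelihood term; defaults to the matrix
#'   the solution was fitted to.
#' @return The EBIC score (smaller is better).
#' @export
ebic_score <- function(sol, n, gamma = 0.5, s = sol$s) {
  S <- if (inherits(s, "cor_matrix")) s$values else as.matrix(s)
  p <- ncol(S)
  if (n <= p) warning("sample size n <= p; EBIC is poorly calibrated")
  ch <- tryCatch(chol(sol$theta), error = function(e) NULL)
  if (is.null(ch)) stop("precision estimate is not positive definite")
  loglik_kernel <- 2 * sum(log(diag(ch))) - sum(S * sol$theta)
  E <- sol$edges$E
  -n * loglik_kernel + E * log(n) + 4 * E * gamma * log(p)
}

#' Select a network by graphical lasso with EBIC
#'
#' Fits the graphical lasso along a descending penalty path and keeps the
#' solution with the lowest extended BIC, ties going to the larger penalty
#' (sparser graph). In replication mode the input is a partial-correlation
#' matrix, mirroring the published procedure of feeding the partial matrix to
#' the selector; the conventional usage passes the full matrix.
#'
#' @param s a [cor_matrix] (kind full or partial).
#' @param n sample size for the EBIC; defaults to `s$n`.
#' @param gamma EBIC hyperparameter.
#' @param n_lambda,ratio path controls, see [lambda_path()].
#' @return An object of class `ggm_path` with elements `input_kind`, `gamma`,
#'   `lambdas`, `solutions`, `ebic`, `selected` (index of the chosen
#'   solution), and `edges` of the selected solution.
#' @export
select_network <- function(s, n = NULL, gamma = 0.5, n_lambda = 100,
                           ratio = 0.01) {
  stopifnot(inherits(s, "cor_matrix"))
  if (is.null(n)) n <- s$n
  lams <- lambda_path(s, n_lambda, ratio)
  sols <- vector("list", length(lams))
  warm <- NULL
  for (i in seq_along(lams)) {
    sols[[i]] <- glasso_fit(s, lams[i], warm = warm)
    warm <- sols[[i]]
  }
  scores <- vapply(sols, ebic_score, numeric(1), n = n, gamma = gamma)
  sel <- which.min(scores) # first minimum = largest lambda on a descending path
  structure(list(input_kind = s$kind, gamma = gamma, lambdas = lams,
                 solutions = sols, ebic = scores, selected = sel,
                 edges = sols[[sel]]$edges, n = n),
            class = "ggm_path")
}

#' @export
print.ggm_path <- function(x, ...) {
  sel <- x$solutions[[x$selected]]
  cat(sprintf(paste0("<ggm_path> %d penalties on %s matrix (gamma = %g); ",
                     "selected lambda = %.4g with %d edges\n"),
              length(x$lambdas), x$input_kind, x$gamma, sel$lam, sel$edges$E))
  invisible(x)
}
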