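#' Labeled correlation matrix
#'
#' Container for a square correlation matrix together with its variable
#' labels, its kind (`"full"` for ordinary product-moment correlations,
#' `"partial"` for correlations conditioned on all remaining variables) and
#' the sample size it was computed from.
#'
#' @param values numeric p x p matrix of correlations; must be symmetric
#'   (within 1e-12 after construction), with unit diagonal and off-diagonal
#'   entries in \[-1, 1\].
#' @param labels character vector of variable names, one per row/column.
#'   Defaults to the column names of `values`.
#' @param kind `"full"` or `"partial"`.
#' @param n positive integer sample size.
#' @return An object of class `cor_matrix`: a list with elements `values`
#'   (with dimnames set to the labels), `labels`, `kind`, `n`, and `p`.
#' @examples
#' m <- cor_matrix(matrix(c(1, .5, .5, 1), 2), labels = c("a", "b"), n = 100)
#' m$p
#' @export
cor_matrix <- function(values, labels = colnames(values),
                       kind = c("full", "partial"), n) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  p <- nrow(values)
  if (ncol(values) != p) stop("correlation matrix must be square")
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  labels <- as.character(labels)
  if (length(labels) != p) stop("need one label per variable")
  if (anyDuplicated(labels)) stop("variable labels must be unique")
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n))
    stop("'n' must be a positive integer sample size")
  if (any(!is.finite(values))) stop("correlation matrix has non-finite entries")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-12) stop("matrix is asymmetric (max |m - t(m)| = ",
                         format(asym), ")")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop("diagonal entries must equal 1")
  diag(values) <- 1
  off <- values[upper.tri(values)]
  if (length(off) && max(abs(off)) > 1 + 1e-12)
    stop("correlation out of range: off-diagonal entry outside [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind,
                 n = as.integer(n), p = p),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<cor_matrix> %d variables, kind = %s, n = %d\n",
              x$p, x$kind, x$n))
  print(round(x$values, digits))
  invisible(x)
}

#' Set of correlation tables sharing one variable layout
#'
#' A collection of [cor_matrix] objects over identical labels, typically the
#' per-age-band sub-tables of one normative sample, together with the pooled
#' sample size. Used as input to [fisher_average()].
#'
#' @param tables list of `cor_matrix` objects with identical label order and
#'   identical kind.
#' @param sample_n pooled sample size for the combined sample; defaults to the
#'   sum of per-table sample sizes.
#' @return An object of class `cor_table_set`.
#' @export
cor_table_set <- function(tables, sample_n = NULL) {
  if (!length(tables)) stop("need at least one table")
  if (!all(vapply(tables, inherits, logical(1), "cor_matrix")))
    stop("all tables must be cor_matrix objects")
  labels <- tables[[1]]$labels
  for (t in tables) {
    if (!identical(t$labels, labels)) stop("tables have mismatched labels")
    if (!identical(t$kind, tables[[1]]$kind)) stop("tables mix kinds")
  }
  if (is.null(sample_n)) sample_n <- sum(vapply(tables, `[[`, numeric(1), "n"))
  structure(list(tables = tables, labels = labels,
                 sample_n = as.integer(sample_n), kind = tables[[1]]$kind),
            class = "cor_table_set")
}

#' @export
print.cor_table_set <- function(x, ...) {
  cat(sprintf("<cor_table_set> %d tables, %d variables, pooled n = %d\n",
              length(x$tables), length(x$labels), x$sample_n))
  invisible(x)
}

#' Read a correlation matrix from CSV
#'
#' Expects a header row of variable labels and a first column of labels; the
#' body is numeric. Mild asymmetry (at most 1e-8, e.g. from rounding on
#' write) is repaired by averaging the matrix with its transpose; anything
#' larger is an error, as are out-of-range correlations or a non-unit
#' diagonal. Sample size and kind come from an optional sidecar JSON file
#' `<path>.json` (`{"n": 1000, "kind": "full"}`) or from the arguments,
#' which take precedence.
#'
#' @param path CSV file path.
#' @param n sample size; overrides the sidecar if given.
#' @param kind `"full"` or `"partial"`; overrides the sidecar if given.
#' @return A [cor_matrix].
#' @export
read_corr_csv <- function(path, n = NULL, kind = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  body <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(body) <- "double"
  if (nrow(body) != ncol(body)) stop("CSV body is not square")
  if (!identical(labels, colnames(body)))
    stop("row labels do not match column labels")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(n)) n <- meta$n
  if (is.null(kind)) kind <- if (is.null(meta$kind)) "full" else meta$kind
  if (is.null(n)) stop("sample size not given and no sidecar ", sidecar)
  asym <- max(abs(body - t(body)))
  if (asym > 1e-8) stop("matrix is asymmetric (max |m - t(m)| = ",
                        format(asym), ")")
  body <- (body + t(body)) / 2
  off <- body[upper.tri(body)]
  if (length(off) && max(abs(off)) > 1)
    stop("correlation out of range: off-diagonal entry outside [-1, 1]")
  cor_matrix(body, labels = labels, kind = kind, n = n)
}

#' Write a correlation matrix to CSV
#'
#' Writes labels as the header row and first column, values at 10 significant
#' digits, plus a sidecar JSON `<path>.json` recording `n` and `kind` so the
#' matrix round-trips through [read_corr_csv()].
#'
#' @param m a [cor_matrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(m, path) {
  stopifnot(inherits(m, "cor_matrix"))
  body <- matrix(sprintf("%.10g", m$values), m$p, m$p)
  df <- data.frame(label = m$labels, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("", m$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(list(n = m$n, kind = m$kind), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Pool correlation tables through Fisher's z transform
#'
#' Combines several correlation tables over the same variables into one by
#' transforming every off-diagonal entry to Fisher's z (`atanh`), averaging
#' the z values across tables entrywise (unweighted), and back-transforming
#' (`tanh`). This is the conventional way to pool tabled correlations from
#' sub-samples of a normative sample.
#'
#' @param tables a [cor_table_set], or a list of [cor_matrix] coercible to
#'   one.
#' @param n sample size to stamp on the pooled matrix; defaults to the table
#'   set's pooled `sample_n`.
#' @return A [cor_matrix] of the shared kind with the pooled sample size.
#' @export
fisher_average <- function(tables, n = NULL) {
  if (!inherits(tables, "cor_table_set")) tables <- cor_table_set(tables)
  if (is.null(n)) n <- tables$sample_n
  zs <- lapply(tables$tables, function(t) {
    v <- t$values
    off <- v[row(v) != col(v)]
    if (any(abs(off) >= 1))
      stop("cannot Fisher-transform a correlation of magnitude 1")
    atanh(v)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- tanh(zbar)
  diag(r) <- 1
  cor_matrix(r, labels = tables$labels, kind = tables$kind, n = n)
}

#' Partial-correlation transform
#'
#' Converts a full correlation matrix into the matrix of pairwise partial
#' correlations, each entry conditioning on all remaining variables: with
#' `K = solve(m$values)`, `pcor[i, j] = -K[i, j] / sqrt(K[i, i] * K[j, j])`.
#' The diagonal is set to 1 and the result is flagged `kind = "partial"`.
#'
#' A pooled matrix can fail to be positive definite; by default that is an
#' error naming the offending eigenvalue. With `repair_pd = TRUE` the matrix
#' is first projected to the nearest correlation matrix by clipping
#' eigenvalues at `1e-6` and rescaling to unit diagonal.
#'
#' @param m a [cor_matrix] with `kind == "full"`.
#' @param repair_pd repair a non-positive-definite input instead of erroring.
#' @return A [cor_matrix] with `kind = "partial"`.
#' @export
to_partial <- function(m, repair_pd = FALSE) {
  stopifnot(inherits(m, "cor_matrix"))
  if (m$kind != "full")
    stop("to_partial expects a full correlation matrix")
  v <- m$values
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    if (!repair_pd)
      stop(sprintf(paste0("matrix is not positive definite (smallest ",
                          "eigenvalue %.3e); rerun with repair_pd = TRUE ",
                          "to project to the nearest PD correlation matrix"),
                   min(ev)))
    v <- repair_pd_matrix(v)
  }
  K <- solve(v)
  d <- 1 / sqrt(diag(K))
  pc <- -K * tcrossprod(d)
  diag(pc) <- 1
  cor_matrix(pc, labels = m$labels, kind = "partial", n = m$n)
}

# Eigenvalue clipping at 1e-6 followed by rescaling to unit diagonal.
repair_pd_matrix <- function(v, floor = 1e-6) {
  e <- eigen(v, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  v2 <- e$vectors %*% (lam * t(e$vectors))
  d <- 1 / sqrt(diag(v2))
  v2 <- v2 * tcrossprod(d)
  (v2 + t(v2)) / 2
}
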