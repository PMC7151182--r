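#' Run the full network-versus-latent-variable comparison
#'
#' Orchestrates the whole study on a bundle of correlation table sets (e.g.
#' from [make_wais_like_study()] or read from disk): pools each sample's
#' sub-tables by Fisher-z averaging, derives the partial-correlation
#' matrices, selects a network once by EBIC graphical lasso (on the partial
#' matrix in replication mode, or on the full matrix with
#' `select_on = "full"`), then fits the baseline and every requested model
#' to both the partial and the full training matrix, computing RMSEA, CFI,
#' both AIC conventions against the matching baseline, and frozen-weight
#' generalization chi-squares on every validation sample of the matching
#' kind.
#'
#' A model that fails to converge is kept as a flagged row rather than
#' aborting the run. The baseline chi-square ratio
#' `chi2_baseline(partial) / chi2_baseline(full)` is reported as a
#' diagnostic of how much common covariance the partial transform removes.
#'
#' @param study list with `train` (a [cor_table_set]) and `validation`
#'   (named list of `cor_table_set`s), as returned by
#'   [make_wais_like_study()].
#' @param fm a [factor_map] describing the battery layout.
#' @param models character vector of models to fit, any of
#'   `"correlated_factors"`, `"hierarchical"`, `"bifactor"`,
#'   `"pentafactor"`, `"network"`.
#' @param gamma,n_lambda,ratio EBIC selection settings, see
#'   [select_network()].
#' @param select_on which training matrix feeds the selector: `"partial"`
#'   (replication of the published procedure) or `"full"`.
#' @param n_starts,seed estimation settings passed to [fit_ml()].
#' @param repair_pd repair pooled matrices that lose positive definiteness
#'   (see [to_partial()]).
#' @return An object of class `comparison_result`: `reports` (named list of
#'   `data.frame`s for `partial` and `full`), `baseline_ratio`, `selection`
#'   (the [select_network()] result), `fits` (nested list of
#'   [fit_ml()] results), `matrices`, and `config`.
#' @export
run_comparison <- function(study, fm = wais_factor_map(),
                           models = c("correlated_factors", "hierarchical",
                                      "bifactor", "pentafactor", "network"),
                           gamma = 0.5, n_lambda = 100, ratio = 0.01,
                           select_on = c("partial", "full"),
                           n_starts = 10, seed = 42, repair_pd = TRUE) {
  select_on <- match.arg(select_on)
  models <- match.arg(models, several.ok = TRUE)
  labels <- study$train$labels
  if (!identical(sort(labels), sort(fm$labels)))
    stop("factor map labels do not match study labels")

  pool <- function(ts) fisher_average(ts)
  mats <- list(full = list(train = pool(study$train)))
  mats$full$validation <- lapply(study$validation, pool)
  mats$partial <- list(
    train = to_partial(mats$full$train, repair_pd = repair_pd),
    validation = lapply(mats$full$validation, to_partial,
                        repair_pd = repair_pd))

  specs <- list()
  if ("correlated_factors" %in% models)
    specs$correlated_factors <- build_correlated_factors(fm)
  if ("hierarchical" %in% models)
    specs$hierarchical <- build_hierarchical(fm)
  if ("bifactor" %in% models)
    specs$bifactor <- build_bifactor(fm)
  if ("pentafactor" %in% models)
    specs$pentafactor <- build_pentafactor(fm)
  selection <- NULL
  if ("network" %in% models) {
    selection <- select_network(mats[[select_on]]$train, gamma = gamma,
                                n_lambda = n_lambda, ratio = ratio)
    specs$network <- build_network_model(selection$edges, labels)
  }

  fits <- list()
  reports <- list()
  for (kind in c("partial", "full")) {
    train <- mats[[kind]]$train
    vals <- mats[[kind]]$validation
    base_fit <- fit_ml(build_baseline(labels), train, n_starts = 1,
                       seed = seed)
    rows <- fit_indices(base_fit, baseline = NULL, validations = vals)
    kind_fits <- list(baseline = base_fit)
    for (nm in names(specs)) {
      fit <- tryCatch(
        suppressWarnings(fit_ml(specs[[nm]], train, n_starts = n_starts,
                                seed = seed)),
        error = function(e) NULL)
      if (is.null(fit)) {
        flag <- data.frame(model = specs[[nm]]$name, chi2 = NA, df =
                             specs[[nm]]$df, rmsea = NA, cfi = NA,
                           aic_m2df = NA, aic_p2q = NA, converged = FALSE)
        for (v in names(vals)) flag[[paste0("gen_", v)]] <- NA
        rows <- rbind(rows, flag)
        next
      }
      kind_fits[[nm]] <- fit
      rows <- rbind(rows, fit_indices(fit, baseline = base_fit,
                                      validations = vals))
    }
    rownames(rows) <- NULL
    fits[[kind]] <- kind_fits
    reports[[kind]] <- rows
  }

  baseline_ratio <- fits$partial$baseline$chi2 / fits$full$baseline$chi2
  structure(list(reports = reports, baseline_ratio = baseline_ratio,
                 selection = selection, fits = fits, matrices = mats,
                 config = list(models = models, gamma = gamma,
                               n_lambda = n_lambda, ratio = ratio,
                               select_on = select_on, n_starts = n_starts,
                               seed = seed, repair_pd = repair_pd)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  for (kind in names(x$reports)) {
    cat(sprintf("\n== %s correlation matrix ==\n",
                if (kind == "full") "Uncorrected (full)" else "Partial"))
    print(format_report(x$reports[[kind]]), row.names = FALSE)
  }
  cat(sprintf("\nBaseline chi2 ratio (partial / full): %.3f\n",
              x$baseline_ratio))
  invisible(x)
}

# report with the published tables' display precision
format_report <- function(rep) {
  out <- rep
  for (cl in c("chi2", "aic_m2df", "aic_p2q",
               grep("^gen_", names(out), value = TRUE)))
    out[[cl]] <- ifelse(is.na(rep[[cl]]), "-", sprintf("%.2f", rep[[cl]]))
  for (cl in c("rmsea", "cfi"))
    out[[cl]] <- ifelse(is.na(rep[[cl]]), "-", sprintf("%.4f", rep[[cl]]))
  out
}

#' Write comparison reports to TSV
#'
#' One TSV per matrix kind, columns in the order of the published tables
#' (model, chi-square, df, RMSEA, CFI, both Akaike conventions, then one
#' generalization column per validation sample), values at display
#' precision, plus full-precision JSON alongside.
#'
#' @param result a [run_comparison()] result.
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (kind in names(result$reports)) {
    tsv <- file.path(dir, paste0("report_", kind, ".tsv"))
    utils::write.table(format_report(result$reports[[kind]]), tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, tsv)
  }
  js <- file.path(dir, "report.json")
  jsonlite::write_json(
    c(result$reports,
      list(baseline_ratio = result$baseline_ratio,
           manifest = replicate_design(result))),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(files, js))
}

#' Provenance manifest of a comparison run
#'
#' Captures everything needed to re-run the analysis bit-identically:
#' configuration (seeds, selection settings), the selected penalty and edge
#' count, per-model parameter counts and degrees of freedom, convergence
#' flags, and the package version.
#'
#' @param result a [run_comparison()] result.
#' @return A named list (serializable to JSON).
#' @export
replicate_design <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  sel <- result$selection
  per_model <- lapply(names(result$fits$partial), function(nm) {
    f <- result$fits$partial[[nm]]
    ff <- result$fits$full[[nm]]
    list(model = f$spec$name, q = f$spec$q, df = f$df,
         converged_partial = f$converged,
         converged_full = if (!is.null(ff)) ff$converged else NA)
  })
  list(config = result$config,
       selection = if (is.null(sel)) NULL else
         list(input_kind = sel$input_kind, gamma = sel$gamma,
              lambda_star = sel$solutions[[sel$selected]]$lam,
              E = sel$edges$E, n_lambda = length(sel$lambdas)),
       models = per_model,
       baseline_ratio = result$baseline_ratio,
       version = as.character(utils::packageVersion("netlvm")))
}
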