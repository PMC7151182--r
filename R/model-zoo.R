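#' Default 15-subtest factor map for a WAIS-like battery
#'
#' Four group factors over 15 subtest labels: Verbal Comprehension (SI, VC,
#' IN, CO), Perceptual Reasoning (BD, MR, VP, PCm, FW), Working Memory (DS,
#' AR, LN) and Processing Speed (SS, CD, CA). The two default cross-loadings
#' (Arithmetic on Verbal Comprehension, Figure Weights on Working Memory)
#' reflect the well-known verbal and working-memory demands of those
#' subtests; they are used by [build_correlated_factors()] only. The map is
#' a named fixture for this battery layout, fully overridable.
#'
#' @param cross_loadings named list mapping variable label to an extra group
#'   factor it loads on.
#' @return A `factor_map`: list with `groups` (named list of label vectors),
#'   `labels` (all observed labels in order) and `cross_loadings`.
#' @export
wais_factor_map <- function(cross_loadings = list(AR = "VC", FW = "WM")) {
  groups <- list(VC = c("SI", "VC", "IN", "CO"),
                 PR = c("BD", "MR", "VP", "PCm", "FW"),
                 WM = c("DS", "AR", "LN"),
                 PS = c("SS", "CD", "CA"))
  factor_map(groups, cross_loadings)
}

#' Construct a factor map
#'
#' @param groups named list of group-factor name -> observed labels.
#' @param cross_loadings named list: variable label -> extra factor name.
#' @return A `factor_map` object.
#' @export
factor_map <- function(groups, cross_loadings = list()) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("group names must be present and unique")
  if (any(!lengths(groups))) stop("empty group")
  labels <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(labels)) stop("a variable appears in two groups")
  for (v in names(cross_loadings)) {
    if (!v %in% labels) stop("cross-loading variable not in map: ", v)
    if (!cross_loadings[[v]] %in% names(groups))
      stop("cross-loading factor not in map: ", cross_loadings[[v]])
  }
  structure(list(groups = groups, labels = labels,
                 cross_loadings = cross_loadings),
            class = "factor_map")
}

# p x m pattern with NA at group memberships (optionally + cross-loadings)
group_lambda_pattern <- function(fm, cross = FALSE) {
  p <- length(fm$labels)
  m <- length(fm$groups)
  L <- matrix(0, p, m, dimnames = list(fm$labels, names(fm$groups)))
  for (g in names(fm$groups)) L[fm$groups[[g]], g] <- NA
  if (cross)
    for (v in names(fm$cross_loadings)) L[v, fm$cross_loadings[[v]]] <- NA
  L
}

#' Baseline (independence) model
#'
#' All covariances fixed to zero, variances free: the reference model for
#' the comparative fit index. Expressed in precision form with an empty edge
#' set; `df = p(p+1)/2 - p` (105 for p = 15).
#'
#' @param labels observed-variable labels.
#' @return A [model_spec].
#' @export
build_baseline <- function(labels) {
  model_spec("Baseline", form = "network", observed = labels,
             edges = edge_set(NULL, labels))
}

#' Correlated group-factor model
#'
#' Each subtest loads on its group factor (plus any cross-loadings in the
#' map); factor variances are fixed to 1, factor correlations and residual
#' variances are free. With the default map's two cross-loadings,
#' q = 17 + 15 + 6 = 38 and df = 82 for p = 15.
#'
#' @param fm a [factor_map].
#' @param cross include the map's cross-loadings (default `TRUE`).
#' @return A [model_spec].
#' @export
build_correlated_factors <- function(fm, cross = TRUE) {
  L <- group_lambda_pattern(fm, cross = cross)
  m <- ncol(L)
  Psi <- matrix(NA_real_, m, m)
  diag(Psi) <- 1
  model_spec("Correlated Factors", form = "factor", observed = fm$labels,
             lambda_pattern = L, psi_pattern = Psi)
}

#' Hierarchical (second-order) factor model
#'
#' Group factors as in the map with free loadings and a standardized
#' second-order general factor on which every group factor loads;
#' first-order disturbance variances are free. q = 15 + 15 + 4 + 4 = 38 and
#' df = 82 for the default map.
#'
#' @param fm a [factor_map].
#' @return A [model_spec]. Fewer than three group factors triggers an
#'   identification warning.
#' @export
build_hierarchical <- function(fm) {
  L <- group_lambda_pattern(fm, cross = FALSE)
  m <- ncol(L)
  if (m < 3)
    warning("second-order structure with fewer than 3 first-order factors ",
            "is not identified without extra constraints")
  gamma <- matrix(NA_real_, m, 1, dimnames = list(colnames(L), "g"))
  model_spec("Hierarchical", form = "factor", observed = fm$labels,
             lambda_pattern = L,
             second_order = list(gamma_pattern = gamma))
}

#' Bifactor model
#'
#' An orthogonal general factor loading on every subtest plus orthogonal
#' group factors per the map; all latent variances fixed to 1. With all
#' loadings free, q = 15 + 15 + 15 = 45 and df = 75. Fixing chosen group
#' loadings to zero (e.g. to stabilize estimation on a partial-correlation
#' matrix) raises df accordingly.
#'
#' @param fm a [factor_map].
#' @param fix_group_loadings character vector of variable labels whose group
#'   loading is fixed to 0.
#' @return A [model_spec].
#' @export
build_bifactor <- function(fm, fix_group_loadings = NULL) {
  Lg <- group_lambda_pattern(fm, cross = FALSE)
  g <- matrix(NA_real_, nrow(Lg), 1, dimnames = list(fm$labels, "g"))
  L <- cbind(g, Lg)
  for (v in fix_group_loadings) {
    gi <- which(is.na(L[v, -1])) + 1L
    L[v, gi] <- 0
  }
  m <- ncol(L)
  model_spec("Bifactor", form = "factor", observed = fm$labels,
             lambda_pattern = L, psi_pattern = diag(m))
}

#' Default general-factor exclusion pattern for the penta-factor model
#'
#' Four mutually orthogonal broad general factors: the first loads on every
#' subtest; each of the others omits one three-subtest block (fixed-zero
#' loadings), which anchors the factors against rotational indeterminacy.
#' Nine fixed zeros leave 51 free general loadings.
#'
#' @return Named list: general-factor name -> labels with fixed-zero
#'   loadings.
#' @export
pentafactor_general_pattern <- function() {
  list(G1 = character(0),
       G2 = c("DS", "AR", "LN"),
       G3 = c("SS", "CD", "CA"),
       G4 = c("SI", "VC", "IN"))
}

#' Penta-factor model
#'
#' The map's four correlated group factors plus four mutually uncorrelated
#' general factors, each general factor loading broadly per the exclusion
#' pattern and orthogonal to the group factors. With the default pattern,
#' q = 15 (group loadings) + 51 (general loadings) + 6 (group correlations)
#' + 15 (residuals) = 87 and df = 33.
#'
#' @param fm a [factor_map].
#' @param general named list of general-factor name -> labels with
#'   fixed-zero loadings; see [pentafactor_general_pattern()].
#' @return A [model_spec].
#' @export
build_pentafactor <- function(fm, general = pentafactor_general_pattern()) {
  Lg <- group_lambda_pattern(fm, cross = FALSE)
  m <- ncol(Lg)
  k <- length(general)
  p <- length(fm$labels)
  Lgen <- matrix(NA_real_, p, k, dimnames = list(fm$labels, names(general)))
  for (gname in names(general)) Lgen[general[[gname]], gname] <- 0
  L <- cbind(Lg, Lgen)
  Psi <- matrix(0, m + k, m + k)
  diag(Psi) <- 1
  Psi[seq_len(m), seq_len(m)][upper.tri(diag(m))] <- NA
  Psi[seq_len(m), seq_len(m)][lower.tri(diag(m))] <- NA
  model_spec("Penta-factor", form = "factor", observed = fm$labels,
             lambda_pattern = L, psi_pattern = Psi)
}

#' Network model from a selected edge set
#'
#' Precision-form specification with a free diagonal and free off-diagonal
#' entries exactly at the selected edges; everything else is fixed to zero.
#' This is the second stage of the two-stage network analysis: the
#' regularized selection chooses which partial correlations exist, the ML
#' fit estimates their magnitude. `df = p(p-1)/2 - E`.
#'
#' @param edges an [edge_set] (e.g. from [select_network()]`$edges`).
#' @param labels observed labels; defaults to the edge set's labels.
#' @param name model name for reports.
#' @return A [model_spec].
#' @export
build_network_model <- function(edges, labels = edges$labels,
                                name = "EBIC Network") {
  if (!inherits(edges, "edge_set")) edges <- edge_set(edges, labels)
  model_spec(name, form = "network", observed = labels, edges = edges)
}
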