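## PCA-based Euclidean Distance Synergy (PEDS): the displacement of the
## combination treatment from control in variance-weighted principal
## component space, relative to the additive expectation of the two
## single-drug displacements. PEDS > 1 is read as synergistic.

#' Prepare a cleaned feature table for PCA
#'
#' Keeps the four treatment groups (ctrl, drug1, drug2, comb), log-transforms
#' intensities with a small positive offset and mean-centers each feature.
#'
#' @param ft A cleaned, normalized [feature_table()] with no missing values
#'   in the treatment groups, or a numeric samples x features matrix with a
#'   `group` argument.
#' @param group Sample group labels when `ft` is a bare matrix.
#' @param offset Positive offset added before the log transform (default 1).
#' @param log_transform Apply `log(x + offset)` (default `TRUE`).
#' @return Object of class `profile_matrix`: centered samples x features
#'   matrix with attributes `group`, `offset` and `center`.
#' @export
preprocess_profiles <- function(ft, group = NULL, offset = 1,
                                log_transform = TRUE) {
  if (inherits(ft, "feature_table")) {
    keep <- ft$samples$group %in% .ft_treatment_groups
    x <- t(ft$intensity[, keep, drop = FALSE])
    group <- ft$samples$group[keep]
  } else {
    x <- as.matrix(ft)
    if (is.null(group) || length(group) != nrow(x))
      stop("group labels required, one per sample row")
  }
  missing_groups <- setdiff(.ft_treatment_groups, unique(group))
  if (length(missing_groups))
    stop("missing treatment group(s): ", paste(missing_groups, collapse = ", "))
  if (any(table(group) < 2L))
    stop("every treatment group needs at least 2 replicates")
  if (anyNA(x)) stop("profile matrix must be complete (impute first)")
  if (log_transform) x <- log(x + offset)
  ctr <- colMeans(x)
  x <- sweep(x, 2L, ctr)
  structure(x, group = group, offset = offset, center = ctr,
            log_transform = log_transform, class = "profile_matrix")
}

#' Fit PCA and summarize per-group scores
#'
#' Singular-value-decomposition PCA of the centered profile matrix. All
#' components with nonzero singular value are retained by default; the
#' per-component proportions of variance sum to 1 over the retained set
#' when nothing is truncated.
#'
#' @param pm A `profile_matrix` from [preprocess_profiles()].
#' @param cum_gamma Optional cumulative variance threshold in (0, 1]; when
#'   given, the smallest leading component set reaching it is retained.
#' @return Object of class `pca_scores`: list with `scores` (samples x
#'   components), `gamma` (variance proportions), `centroids` (4 x
#'   components group means), `loadings`, `group`.
#' @export
fit_pca <- function(pm, cum_gamma = NULL) {
  stopifnot(inherits(pm, "profile_matrix"))
  x <- unclass(pm)
  attributes(x)[c("group", "offset", "center", "log_transform")] <- NULL
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  nz <- p$sdev > max(p$sdev) * 1e-12
  if (!any(nz)) stop("rank-0 profile matrix: no variance to decompose")
  scores <- p$x[, nz, drop = FALSE]
  gamma <- p$sdev[nz]^2 / sum(p$sdev[nz]^2)
  if (!is.null(cum_gamma)) {
    k <- which(cumsum(gamma) >= cum_gamma)[1L]
    scores <- scores[, seq_len(k), drop = FALSE]
    gamma <- gamma[seq_len(k)]
  }
  grp <- attr(pm, "group")
  centroids <- do.call(rbind, lapply(.ft_treatment_groups, function(g)
    colMeans(scores[grp == g, , drop = FALSE])))
  rownames(centroids) <- .ft_treatment_groups
  structure(list(scores = scores, gamma = gamma, centroids = centroids,
                 loadings = p$rotation[, nz, drop = FALSE][, seq_along(gamma), drop = FALSE],
                 group = grp),
            class = "pca_scores")
}

#' PEDS synergy statistic
#'
#' Computes the variance-weighted Euclidean distance from the control
#' centroid to the combination centroid, divided by the distance from
#' control to the additive expectation (the midpoint of the summed
#' single-drug displacements):
#' \deqn{PEDS = \sqrt{\sum_i \gamma_i (p_{comb,i}-p_{ctrl,i})^2} \Big/
#'   \tfrac{1}{2}\sqrt{\sum_i \gamma_i (p_{drug1,i}+p_{drug2,i}-2 p_{ctrl,i})^2}}
#' PEDS equals 1 exactly when the combination displacement is the additive
#' midpoint, and values above 1 are classified synergistic. The variant
#' without the 1/2 factor is available via `denominator = "sum"`.
#'
#' @param scores A `pca_scores` object from [fit_pca()].
#' @param denominator `"half_sum"` (default, additive midpoint) or `"sum"`.
#' @return Object of class `peds_score`: list with `value`, `synergistic`
#'   (`value > 1`), `n_components`, `numerator`, `denominator`.
#' @export
peds <- function(scores, denominator = c("half_sum", "sum")) {
  stopifnot(inherits(scores, "pca_scores"))
  denominator <- match.arg(denominator)
  p <- scores$centroids
  g <- scores$gamma
  num <- sqrt(sum(g * (p["comb", ] - p["ctrl", ])^2))
  dvec <- p["drug1", ] + p["drug2", ] - 2 * p["ctrl", ]
  den <- sqrt(sum(g * dvec^2))
  if (denominator == "half_sum") den <- den / 2
  if (den == 0)
    stop("additive displacement undefined: both single drugs match control")
  structure(list(value = num / den, synergistic = num / den > 1,
                 n_components = length(g), numerator = num,
                 denominator = den, form = denominator),
            class = "peds_score")
}

#' @export
print.peds_score <- function(x, ...) {
  cat(sprintf("PEDS = %.4f (%s; %d components)\n", x$value,
              if (x$synergistic) "synergistic" else "not synergistic",
              x$n_components))
  invisible(x)
}

#' PEDS over a collection of drug combinations
#'
#' Fits a PCA per combination (on its own four groups only, no pooling) and
#' returns the PEDS values ranked in descending order.
#'
#' @param combinations Named list of cleaned [feature_table()]s or
#'   `profile_matrix` objects, one per drug combination.
#' @param denominator Passed to [peds()].
#' @param cum_gamma Passed to [fit_pca()].
#' @return Data frame with `combination`, `peds`, `synergistic`,
#'   `n_components`, ranked by decreasing PEDS.
#' @export
peds_screen <- function(combinations, denominator = "half_sum",
                        cum_gamma = NULL) {
  if (is.null(names(combinations)))
    names(combinations) <- paste0("combo", seq_along(combinations))
  rows <- lapply(names(combinations), function(nm) {
    x <- combinations[[nm]]
    if (!inherits(x, "profile_matrix")) x <- preprocess_profiles(x)
    s <- peds(fit_pca(x, cum_gamma = cum_gamma), denominator = denominator)
    data.frame(combination = nm, peds = s$value, synergistic = s$synergistic,
               n_components = s$n_components, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(-out$peds), , drop = FALSE]
}
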