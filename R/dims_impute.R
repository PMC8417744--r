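## Iterative random-forest imputation of missing feature intensities
## (missForest-style): initialize with feature means, refit a per-feature
## regression forest on the other features, iterate until the change in the
## imputed values stagnates.

#' Random-forest imputation of missing intensities
#'
#' Missing cells are initialized with feature means; then, feature by
#' feature (in order of increasing missingness), a random forest regressing
#' the feature on all other features is fitted on the observed samples and
#' used to re-predict the missing cells. Iteration stops when the relative
#' change in imputed values rises (stagnation) or after `max_iter` rounds.
#' Observed values are never altered, and the result is deterministic for a
#' fixed seed.
#'
#' @param ft A [feature_table()] in which every feature has at least one
#'   observed value.
#' @param seed Integer seed for the forests.
#' @param ntree Trees per forest (default 100).
#' @param max_iter Maximum refinement rounds (default 10).
#' @return The completed `feature_table`, with attribute
#'   `imputation_report`: list with `n_imputed`, `iterations`, `converged`,
#'   `ntree` and per-feature missing counts.
#' @export
impute_missing <- function(ft, seed = 1L, ntree = 100L, max_iter = 10L) {
  stopifnot(inherits(ft, "feature_table"))
  X <- t(ft$intensity)                      # samples x features
  miss <- is.na(X)
  if (!any(miss)) {
    attr(ft, "imputation_report") <- list(n_imputed = 0L, iterations = 0L,
                                          converged = TRUE, ntree = ntree)
    return(ft)
  }
  if (any(colSums(!miss) == 0L))
    stop("feature with no observed values reached imputation: ",
         paste(colnames(X)[colSums(!miss) == 0L], collapse = ", "))

  set.seed(seed)
  fmeans <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(miss) > 0L)) X[miss[, j], j] <- fmeans[j]

  ord <- order(colSums(miss))
  ord <- ord[colSums(miss)[ord] > 0L]
  prev <- X[miss]
  err_prev <- Inf
  it <- 0L
  converged <- FALSE
  X_best <- X
  while (it < max_iter) {
    it <- it + 1L
    for (j in ord) {
      obs <- !miss[, j]
      if (ncol(X) < 2L) { next }
      # constant features trip randomForest's few-unique-values warning;
      # regression is still the intended behaviour there
      fit <- suppressWarnings(
        randomForest::randomForest(x = X[obs, -j, drop = FALSE],
                                   y = X[obs, j], ntree = ntree))
      X[!obs, j] <- predict(fit, X[!obs, -j, drop = FALSE])
    }
    cur <- X[miss]
    err <- sum((cur - prev)^2) / max(sum(cur^2), .Machine$double.eps)
    if (err >= err_prev) { converged <- TRUE; X <- X_best; break }
    X_best <- X
    prev <- cur
    err_prev <- err
  }
  ft$intensity <- t(X_best)
  attr(ft, "imputation_report") <- list(
    n_imputed = sum(miss), iterations = it, converged = converged,
    ntree = ntree, missing_per_feature = colSums(miss)[colSums(miss) > 0L])
  ft
}
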