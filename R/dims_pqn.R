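## Probabilistic quotient normalization: per-sample division by the median
## of feature-wise quotients against a reference spectrum, correcting
## sample-to-sample dilution while preserving within-sample ratios.

#' Probabilistic quotient normalization
#'
#' Each sample is divided by the median of its feature-wise quotients
#' against a reference spectrum (the feature-wise median of QC samples, or
#' of all non-blank samples). A sample equal to `c` times the reference is
#' scaled by exactly `1/c`; the reference spectrum itself has quotient 1.
#'
#' @param ft A [feature_table()] (missing values allowed; quotients use the
#'   shared non-missing features).
#' @param reference `"all_median"` (default) or `"qc_median"`.
#' @return Normalized `feature_table` with attribute `pqn_factors` (the
#'   per-sample dilution quotients divided out).
#' @export
pqn_normalize <- function(ft, reference = c("all_median", "qc_median")) {
  reference <- match.arg(reference)
  grp <- ft$samples$group
  ref_cols <- if (reference == "qc_median") which(grp == "qc")
              else which(grp != "blank")
  if (length(ref_cols) == 0L)
    stop("no samples available to build the ", reference, " reference spectrum")
  ref <- apply(ft$intensity[, ref_cols, drop = FALSE], 1L, median, na.rm = TRUE)

  factors <- numeric(ncol(ft$intensity))
  for (s in seq_len(ncol(ft$intensity))) {
    x <- ft$intensity[, s]
    ok <- !is.na(x) & !is.na(ref) & ref > 0
    if (sum(ok) < 3L)
      stop("sample ", ft$samples$sample_id[s],
           " shares fewer than 3 non-missing features with the reference")
    factors[s] <- median(x[ok] / ref[ok])
    ft$intensity[, s] <- x / factors[s]
  }
  attr(ft, "pqn_factors") <- stats::setNames(factors, ft$samples$sample_id)
  ft
}
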