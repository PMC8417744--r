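## Feature-table container for DIMS intensities: features x samples with
## explicit missing values and a closed group vocabulary.

.ft_groups <- c("ctrl", "drug1", "drug2", "comb", "blank", "qc")
.ft_treatment_groups <- c("ctrl", "drug1", "drug2", "comb")

#' Construct a feature table
#'
#' @param intensity Numeric matrix, features x samples; missing measurements
#'   as `NA` (zeros count as detected values, not missing). Row names are
#'   feature ids, column names sample ids.
#' @param group Character vector (one per sample) drawn from
#'   `ctrl, drug1, drug2, comb, blank, qc`.
#' @param replicate Optional replicate ids per sample (defaults to running
#'   index within group).
#' @param feature_meta Optional data frame of per-feature annotation (m/z,
#'   polarity, metabolite name...), row-aligned with `intensity`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensity, group, replicate = NULL,
                          feature_meta = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("F", seq_len(nrow(intensity)))
  if (anyDuplicated(rownames(intensity)))
    stop("feature ids must be unique")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("S", seq_len(ncol(intensity)))
  if (length(group) != ncol(intensity))
    stop("one group label per sample required")
  bad <- setdiff(unique(group), .ft_groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(intensity[!is.na(intensity)] < 0))
    stop("intensities must be non-negative")
  if (is.null(replicate))
    replicate <- as.integer(stats::ave(seq_along(group), group, FUN = seq_along))
  samples <- data.frame(sample_id = colnames(intensity), group = group,
                        replicate = replicate, stringsAsFactors = FALSE)
  if (!is.null(feature_meta) && nrow(feature_meta) != nrow(intensity))
    stop("feature_meta must align with intensity rows")
  structure(list(intensity = intensity, samples = samples,
                 features = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$intensity), " features x ",
      ncol(x$intensity), " samples (",
      sum(is.na(x$intensity)), " missing)\n", sep = "")
  print(table(x$samples$group))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

.ft_subset_features <- function(ft, keep) {
  ft$intensity <- ft$intensity[keep, , drop = FALSE]
  if (!is.null(ft$features)) ft$features <- ft$features[keep, , drop = FALSE]
  ft
}

#' Replicate filter
#'
#' Keeps a feature iff it is detected (non-missing) in at least
#' `min_present` replicates of at least one treatment group (ctrl, drug1,
#' drug2, comb). Groups declaring fewer than `min_present` replicates are
#' skipped with a warning.
#'
#' @param ft A [feature_table()].
#' @param min_present Minimum detections within a group (default 4).
#' @param group_size Declared replicates per group (default 5).
#' @return Filtered `feature_table`.
#' @export
replicate_filter <- function(ft, min_present = 4L, group_size = 5L) {
  grp <- ft$samples$group
  use_groups <- intersect(.ft_treatment_groups, unique(grp))
  keep <- rep(FALSE, nrow(ft$intensity))
  for (g in use_groups) {
    cols <- which(grp == g)
    if (length(cols) < min_present) {
      warning("group '", g, "' has fewer than ", min_present,
              " replicates; skipped")
      next
    }
    keep <- keep | rowSums(!is.na(ft$intensity[, cols, drop = FALSE])) >= min_present
  }
  .ft_subset_features(ft, keep)
}

#' Blank filter
#'
#' Keeps a feature iff the mean of its non-blank intensities exceeds
#' `min_snr` times the mean of its blank intensities (strict inequality).
#' Features with zero or entirely missing blank signal are kept.
#'
#' @param ft A [feature_table()].
#' @param min_snr Signal-to-noise threshold (default 3).
#' @return Filtered `feature_table`.
#' @export
blank_filter <- function(ft, min_snr = 3) {
  blank_cols <- ft$samples$group == "blank"
  if (!any(blank_cols))
    stop("no blank samples present; skip the blank filter explicitly if intended")
  bm <- rowMeans(ft$intensity[, blank_cols, drop = FALSE], na.rm = TRUE)
  sm <- rowMeans(ft$intensity[, !blank_cols, drop = FALSE], na.rm = TRUE)
  keep <- is.nan(bm) | bm == 0 | (!is.nan(sm) & sm / bm > min_snr)
  .ft_subset_features(ft, keep)
}

#' Sample filter
#'
#' Keeps a feature iff it is detected in strictly more than `min_fraction`
#' of all non-blank samples.
#'
#' @param ft A [feature_table()].
#' @param min_fraction Fraction threshold (default 0.5).
#' @return Filtered `feature_table`.
#' @export
sample_filter <- function(ft, min_fraction = 0.5) {
  cols <- ft$samples$group != "blank"
  n <- sum(cols)
  if (n == 0L) stop("no non-blank samples present")
  det <- rowSums(!is.na(ft$intensity[, cols, drop = FALSE]))
  .ft_subset_features(ft, det / n > min_fraction)
}

#' Run the full cleaning cascade
#'
#' Applies the filters in the fixed order replicate -> blank -> sample,
#' then random-forest imputation. Each individual filter is idempotent, so
#' applying the cascade twice equals applying it once.
#'
#' @param ft A [feature_table()].
#' @param seed Seed for the imputation forests.
#' @param min_present,group_size,min_snr,min_fraction Filter parameters.
#' @return Cleaned `feature_table` with no missing values.
#' @export
clean_features <- function(ft, seed = 1L, min_present = 4L, group_size = 5L,
                           min_snr = 3, min_fraction = 0.5) {
  ft <- replicate_filter(ft, min_present, group_size)
  ft <- blank_filter(ft, min_snr)
  ft <- sample_filter(ft, min_fraction)
  impute_missing(ft, seed = seed)
}
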