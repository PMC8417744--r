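## Critical values for Dixon's Q (ratio r10 = gap/range), two-sided,
## n = 3..10, from the standard published tables.
.dixon_q_table <- list(
  "0.9"  = c(`3` = 0.941, `4` = 0.765, `5` = 0.642, `6` = 0.560,
             `7` = 0.507, `8` = 0.468, `9` = 0.437, `10` = 0.412),
  "0.95" = c(`3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
             `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466),
  "0.99" = c(`3` = 0.994, `4` = 0.926, `5` = 0.821, `6` = 0.740,
             `7` = 0.680, `8` = 0.634, `9` = 0.598, `10` = 0.568)
)

#' Dixon's Q outlier test for small replicate sets
#'
#' Tests the most extreme value of a small sample against the tabulated
#' critical value of the Q = gap/range statistic and removes it if the test
#' rejects. At most one value is ever removed (single-pass), which makes the
#' filter idempotent after one application.
#'
#' @param values Numeric vector of 3 to 10 replicate measurements.
#' @param confidence Confidence level; one of 0.90, 0.95 (default) or 0.99,
#'   the levels present in the packaged critical-value table.
#' @return A list with elements `values` (retained values, original order),
#'   `rejected` (the removed value, or `NULL`), `outlier` (logical flag),
#'   `q` (the observed Q statistic) and `q_crit` (the critical value).
#' @examples
#' dixon_q_filter(c(1.0, 1.1, 1.2, 5.0))$rejected  # 5.0
#' dixon_q_filter(c(1.0, 1.1, 1.2, 1.3))$outlier   # FALSE
#' @export
dixon_q_filter <- function(values, confidence = 0.95) {
  if (length(values) < 3L)
    stop("insufficient replicates: Dixon's Q requires at least 3 values")
  if (length(values) > 10L)
    stop("Dixon's Q critical-value table covers at most 10 values")
  if (!all(is.finite(values)))
    stop("non-finite value in replicate set")
  key <- as.character(confidence)
  if (!key %in% names(.dixon_q_table))
    stop("confidence level must be one of 0.9, 0.95, 0.99")
  crit <- .dixon_q_table[[key]][[as.character(length(values))]]

  s <- sort(values)
  rng <- s[length(s)] - s[1L]
  if (rng == 0) {
    return(list(values = values, rejected = NULL, outlier = FALSE,
                q = 0, q_crit = crit))
  }
  gap_low <- s[2L] - s[1L]
  gap_high <- s[length(s)] - s[length(s) - 1L]
  if (gap_high >= gap_low) {
    q <- gap_high / rng
    suspect <- s[length(s)]
  } else {
    q <- gap_low / rng
    suspect <- s[1L]
  }
  if (q > crit) {
    drop <- which(values == suspect)[1L]
    list(values = values[-drop], rejected = suspect, outlier = TRUE,
         q = q, q_crit = crit)
  } else {
    list(values = values, rejected = NULL, outlier = FALSE,
         q = q, q_crit = crit)
  }
}
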