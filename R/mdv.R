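## Mass isotopomer distribution vectors (MDVs): construction, natural
## abundance correction by non-negative least squares, and the enrichment
## summary statistics used to read tracer experiments.

#' Construct an MDV
#'
#' A mass isotopomer distribution vector holds the fractional abundances of
#' the M+0 ... M+k isotopologues of a metabolite. Fractions must be
#' non-negative and are normalized to sum to 1.
#'
#' @param fractions Numeric vector of isotopologue fractions (M+0 first).
#' @param sd Optional per-isotopologue standard deviations.
#' @param corrected Logical: has natural abundance been corrected?
#' @return Object of class `mdv`: numeric fraction vector with attributes
#'   `sd` and `corrected`.
#' @export
mdv <- function(fractions, sd = NULL, corrected = FALSE) {
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("MDV fractions must be finite and non-negative")
  s <- sum(fractions)
  if (s <= 0) stop("MDV fractions sum to zero")
  structure(fractions / s, sd = sd, corrected = corrected, class = "mdv")
}

#' @export
print.mdv <- function(x, ...) {
  cat("MDV (", if (isTRUE(attr(x, "corrected"))) "corrected" else "raw",
      "): ", paste(sprintf("M+%d %.4f", seq_along(x) - 1, unclass(x)),
                   collapse = "  "), "\n", sep = "")
  invisible(x)
}

## Mass-shift distribution contributed by natural abundance of `n` atoms of
## one element, as a vector over shifts 0..max_shift.
.element_shift_dist <- function(n, ab, max_shift) {
  out <- c(1, rep(0, max_shift))
  if (n == 0L || length(ab) == 0L) return(out)
  p0 <- 1 - sum(ab)
  single <- c(p0, rep(0, max_shift))
  for (s in names(ab)) {
    sh <- as.integer(s)
    if (sh <= max_shift) single[sh + 1L] <- ab[[s]]
  }
  for (i in seq_len(n)) out <- .conv_trunc(out, single, max_shift)
  out
}

.conv_trunc <- function(a, b, max_shift) {
  out <- rep(0, max_shift + 1L)
  for (i in seq_along(a)) {
    j <- seq_len(min(length(b), max_shift + 2L - i))
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

#' Natural-abundance correction matrix
#'
#' Builds the lower-triangular matrix `M` such that `raw = M %*% true`,
#' where entry `M[i, j]` is the probability that a molecule carrying `j-1`
#' tracer-derived heavy atoms is observed at nominal mass shift `i-1` due to
#' natural isotope abundance in its remaining atoms. Tracer atoms are
#' attributed to carbon first, then nitrogen (nominal-mass convention for
#' dual 13C/15N tracers); H, O and S natural abundance always contribute.
#'
#' @param formula `elemental_formula` or formula string of the metabolite.
#' @param n_shifts Number of rows/columns (length of the MDV).
#' @param tracer_elements Elements assumed tracer-derived (default C and N).
#' @param abundances Natural-abundance constants, see [natural_abundances()].
#' @return `n_shifts` x `n_shifts` correction matrix.
#' @export
correction_matrix <- function(formula, n_shifts,
                              tracer_elements = c("C", "N"),
                              abundances = natural_abundances()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  cnt <- function(el) if (el %in% names(formula)) as.integer(formula[[el]]) else 0L
  capacity <- sum(vapply(tracer_elements, cnt, integer(1)))
  if (n_shifts - 1L > capacity)
    stop("MDV longer than the number of correctable tracer atoms")
  K <- n_shifts - 1L
  M <- matrix(0, n_shifts, n_shifts)
  for (j in 0:K) {
    ## assign j tracer-labeled atoms to the tracer elements in order
    remaining <- j
    dist <- c(1, rep(0, K))
    for (el in names(.monoisotopic)) {
      n_el <- cnt(el)
      if (el %in% tracer_elements) {
        lab <- min(remaining, n_el)
        remaining <- remaining - lab
        n_el <- n_el - lab
      }
      dist <- .conv_trunc(dist, .element_shift_dist(n_el, abundances[[el]], K), K)
    }
    M[, j + 1L] <- c(rep(0, j), dist[seq_len(K + 1L - j)])
  }
  M
}

#' Correct an isotopologue vector for natural isotope abundance
#'
#' Solves `raw = M %*% x` for the tracer-only isotopologue amounts `x` by
#' non-negative least squares and renormalizes to fractions. Standard
#' deviations are propagated linearly through the (triangular) inverse of
#' the correction matrix.
#'
#' @param raw Numeric vector of raw isotopologue intensities or fractions
#'   (M+0 first), or an `mdv`.
#' @param formula Metabolite formula (string or `elemental_formula`).
#' @param tracer_elements Elements assumed tracer-derived (default C and N).
#' @param abundances Natural-abundance constants; set all to zero for an
#'   identity correction.
#' @param sd Optional per-isotopologue SDs of `raw`.
#' @return Corrected `mdv` with propagated SDs and attribute `amounts`
#'   (the unnormalized NNLS solution).
#' @export
correct_natural_abundance <- function(raw, formula,
                                      tracer_elements = c("C", "N"),
                                      abundances = natural_abundances(),
                                      sd = NULL) {
  if (inherits(raw, "mdv")) {
    if (is.null(sd)) sd <- attr(raw, "sd")
    raw <- unclass(raw)
  }
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("raw intensities must be finite and non-negative")
  M <- correction_matrix(formula, length(raw), tracer_elements, abundances)
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stop("ill-conditioned correction matrix (condition number ",
         format(kap, digits = 3), ")")
  x <- pracma::lsqnonneg(M, raw)$x
  if (sum(x) <= 0) stop("natural-abundance correction annihilated the signal")
  sd_out <- NULL
  if (!is.null(sd)) {
    Minv <- backsolve(M, diag(length(raw)), upper.tri = FALSE)
    sd_out <- sqrt((Minv^2) %*% sd^2)[, 1] / sum(x)
  }
  out <- mdv(x, sd = sd_out, corrected = TRUE)
  attr(out, "amounts") <- x
  out
}

#' Summed enrichment fraction over selected isotopologues
#'
#' @param x An `mdv`.
#' @param isotopologues Integer vector of isotopologue indices (`0` = M+0).
#' @return Sum of the selected fractions.
#' @export
enrichment_fraction <- function(x, isotopologues) {
  idx <- isotopologues + 1L
  if (any(idx < 1L) || any(idx > length(x)))
    stop("isotopologue index out of range")
  sum(unclass(x)[idx])
}

#' Relative fraction of one isotopologue among a pair
#'
#' The statistic `m_a / (m_a + m_b)` used, e.g., for the citrate
#' M+5 / (M+4 + M+5) reductive-carboxylation readout. Returns `NA` when both
#' fractions are zero.
#'
#' @param x An `mdv`.
#' @param a,b Isotopologue indices (`a` in the numerator).
#' @return Fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
isotopologue_ratio <- function(x, a = 5L, b = 4L) {
  ma <- enrichment_fraction(x, a)
  mb <- enrichment_fraction(x, b)
  if (ma + mb == 0) return(NA_real_)
  ma / (ma + mb)
}

#' Total-pool ratio of two metabolites
#'
#' Ratio of summed isotopologue intensities (total pools), e.g. the
#' alpha-ketoglutarate / citrate or NAD / NADH readouts. Undetected
#' denominators yield `NA` (excluded from plots rather than plotted as 0).
#'
#' @param a,b Numeric vectors of isotopologue intensities.
#' @return `sum(a) / sum(b)`, or `NA_real_` if `sum(b)` is 0.
#' @export
pool_ratio <- function(a, b) {
  if (any(c(a, b) < 0)) stop("pool intensities must be non-negative")
  if (sum(b) == 0) return(NA_real_)
  sum(a) / sum(b)
}
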