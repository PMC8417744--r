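## Elemental formulas, monoisotopic masses, and isotope constants shared by
## feature annotation and tracer arithmetic.

## Monoisotopic masses (Da) of the lightest isotope, standard values.
.monoisotopic <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)
.proton_mass <- 1.00727646

## Natural abundances of the heavier stable isotopes (fraction of atoms),
## standard IUPAC values; shifts are in nominal mass units.
.natural_abundance <- list(
  C = c(`1` = 0.0107),                 # 13C
  H = c(`1` = 0.000115),               # 2H
  N = c(`1` = 0.00364),                # 15N
  O = c(`1` = 0.00038, `2` = 0.00205), # 17O, 18O
  S = c(`1` = 0.0075, `2` = 0.0425),   # 33S, 34S
  P = numeric(0)                       # monoisotopic
)

#' Parse an elemental formula
#'
#' Parses a Hill-notation-like formula string over the elements C, H, N, O,
#' P and S into an element-count vector.
#'
#' @param text Formula string, e.g. `"C5H10N2O3"`.
#' @return Named integer vector of element counts, class `elemental_formula`.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || anyNA(m) || m[1] == -1)
    stop("cannot parse formula: ", text)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.monoisotopic))
      stop("unknown element symbol '", el, "' in formula ", text)
    if (n < 1L) stop("element counts must be positive in formula ", text)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(counts, class = "elemental_formula")
}

#' Monoisotopic mass of a formula
#'
#' @param formula An `elemental_formula` or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")  # 180.0634
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(.monoisotopic[names(formula)] * as.integer(formula))
}

#' Theoretical m/z of an adduct
#'
#' @param formula An `elemental_formula` or formula string.
#' @param adduct Adduct name: `"[M+H]+"` or `"[M-H]-"`.
#' @return Theoretical m/z in Da.
#' @export
adduct_mz <- function(formula, adduct = c("[M+H]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  m <- monoisotopic_mass(formula)
  switch(adduct, "[M+H]+" = m + .proton_mass, "[M-H]-" = m - .proton_mass)
}

#' Default natural-abundance constants
#'
#' Standard IUPAC fractional abundances of heavier stable isotopes used in
#' the natural-abundance correction, overridable per element.
#'
#' @return Named list, one entry per element, each a vector of abundances
#'   named by nominal mass shift.
#' @export
natural_abundances <- function() .natural_abundance
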