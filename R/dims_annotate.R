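## ppm-window annotation of centroided DIMS peaks against a small
## metabolite formula database.

#' Annotate peaks against a formula database by mass accuracy
#'
#' Matches observed m/z values to the theoretical adduct masses of database
#' formulas within an inclusive ppm window. Peaks matching several database
#' entries retain every match, flagged ambiguous.
#'
#' @param peaks Data frame with columns `mz`, `intensity` and `polarity`
#'   (`"positive"` or `"negative"`); an optional `sample_id` column is
#'   carried through.
#' @param db Data frame with columns `name` and `formula` (optional `id`).
#' @param window_ppm Inclusive annotation window in ppm (default 5).
#' @param adducts Named list mapping polarity to adduct names; defaults to
#'   protonated/deprotonated molecules.
#' @return Data frame of annotation records: observed `mz`, `intensity`,
#'   `polarity`, `name`, `formula`, `adduct`, `theoretical_mz`, `ppm_error`,
#'   `ambiguous`.
#' @export
annotate_features <- function(peaks, db, window_ppm = 5,
                              adducts = list(positive = "[M+H]+",
                                             negative = "[M-H]-")) {
  stopifnot(all(c("mz", "intensity", "polarity") %in% names(peaks)),
            all(c("name", "formula") %in% names(db)))
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0))
    stop("m/z values must be positive and finite")
  theo <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    f <- tryCatch(parse_formula(db$formula[i]),
                  error = function(e) stop("db row ", i, " (", db$name[i],
                                           "): ", conditionMessage(e)))
    do.call(rbind, lapply(names(adducts), function(pol) {
      data.frame(name = db$name[i], formula = db$formula[i], polarity = pol,
                 adduct = adducts[[pol]][1L],
                 theoretical_mz = adduct_mz(f, adducts[[pol]][1L]),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    cand <- theo[theo$polarity == peaks$polarity[i], , drop = FALSE]
    ppm <- (peaks$mz[i] - cand$theoretical_mz) / cand$theoretical_mz * 1e6
    hit <- abs(ppm) <= window_ppm
    if (!any(hit)) return(NULL)
    data.frame(peaks[i, intersect(c("sample_id", "mz", "intensity", "polarity"),
                                  names(peaks)), drop = FALSE],
               cand[hit, c("name", "formula", "adduct", "theoretical_mz")],
               ppm_error = ppm[hit], ambiguous = sum(hit) > 1L,
               row.names = NULL)
  }))
  if (is.null(out))
    out <- data.frame(mz = numeric(0), intensity = numeric(0),
                      polarity = character(0), name = character(0),
                      formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      ambiguous = logical(0))
  rownames(out) <- NULL
  out
}

#' Packaged mini formula database
#'
#' A small table of common polar metabolites (name, elemental formula,
#' HMDB-style id) for annotation examples and tests.
#'
#' @return Data frame with columns `name`, `formula`, `id`.
#' @export
mini_formula_db <- function() {
  read.delim(system.file("extdata", "mini_formula_db.tsv",
                         package = "synerflux"), stringsAsFactors = FALSE)
}
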