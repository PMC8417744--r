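## Primary-screen analytics: relative viability from plate luminescence,
## Bliss independence indices, dose-series Bliss, and two-criterion hit
## selection.

.well_cols <- c("plate_id", "well_id", "cell_line", "drug_id", "drug_conc",
                "partner_conc", "oxygen", "replicate", "signal")
.treat_keys <- c("cell_line", "drug_id", "drug_conc", "partner_conc", "oxygen")

#' Relative viability from plate luminescence records
#'
#' Reduces long-format well records to per-treatment relative viabilities.
#' Replicate signals are (optionally) cleaned with Dixon's Q test, averaged
#' by arithmetic mean, and divided by the mean of the matching control group
#' within the same cell line and oxygen condition. Viabilities above 1 are
#' preserved, not clipped.
#'
#' @param records Data frame of well records with columns `plate_id`,
#'   `well_id`, `cell_line`, `drug_id`, `drug_conc`, `partner_conc`,
#'   `oxygen`, `replicate`, `signal` (non-negative luminescence).
#' @param control_selector Named list identifying the control arm, matched
#'   against the treatment-key columns (default `list(drug_id = "DMSO")`).
#' @param dixon Apply Dixon's Q replicate filtering when a group holds 3-10
#'   replicates (default `TRUE`).
#' @param confidence Confidence level passed to [dixon_q_filter()].
#' @return Data frame keyed by (`cell_line`, `drug_id`, `drug_conc`,
#'   `partner_conc`, `oxygen`) with `relative_viability`,
#'   `n_replicates_used` and `sd`.
#' @export
relative_viability <- function(records, control_selector = list(drug_id = "DMSO"),
                               dixon = TRUE, confidence = 0.95) {
  miss <- setdiff(.well_cols, names(records))
  if (length(miss))
    stop("missing well-record columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$signal)) || any(records$signal < 0))
    stop("signals must be finite and non-negative")

  key <- interaction(records[.treat_keys], drop = TRUE, lex.order = TRUE)
  grp <- split(records, key)
  stat <- lapply(grp, function(g) {
    x <- g$signal
    if (dixon && length(x) >= 3L && length(x) <= 10L)
      x <- dixon_q_filter(x, confidence)$values
    data.frame(g[1L, .treat_keys, drop = FALSE],
               mean_signal = mean(x), n_replicates_used = length(x),
               sd_signal = if (length(x) > 1L) sd(x) else 0,
               row.names = NULL)
  })
  stat <- do.call(rbind, stat)

  is_ctrl <- rep(TRUE, nrow(stat))
  for (nm in names(control_selector))
    is_ctrl <- is_ctrl & stat[[nm]] == control_selector[[nm]]
  if (!any(is_ctrl)) stop("missing control group")

  out <- lapply(split(stat, stat[c("cell_line", "oxygen")], drop = TRUE),
                function(s) {
    ctrl <- s[is_ctrl[match(interaction(s[.treat_keys]),
                            interaction(stat[.treat_keys]))], , drop = FALSE]
    if (nrow(ctrl) == 0L)
      stop("missing control group for cell line ", s$cell_line[1L],
           " under ", s$oxygen[1L])
    cm <- mean(ctrl$mean_signal)
    if (cm == 0) stop("zero control mean for cell line ", s$cell_line[1L])
    data.frame(s[.treat_keys],
               relative_viability = s$mean_signal / cm,
               n_replicates_used = s$n_replicates_used,
               sd = s$sd_signal / cm, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bliss independence synergy index
#'
#' Bliss index = `v_drug * v_partner - v_combo` on the (uncapped) relative
#' viability scale. Positive values indicate synergy; values of at least 0.1
#' are conventionally flagged as strong synergism.
#'
#' @param v_drug,v_partner,v_combo Relative viabilities (finite, `>= 0`;
#'   values above 1 are allowed). Vectorized.
#' @return Numeric Bliss index (expected minus observed combined viability).
#' @examples
#' bliss_index(0.5, 0.5, 0.25)  # exact Bliss additivity: 0
#' @export
bliss_index <- function(v_drug, v_partner, v_combo) {
  v <- c(v_drug, v_partner, v_combo)
  if (any(!is.finite(v))) stop("viabilities must be finite")
  if (any(v < 0)) stop("viabilities must be non-negative")
  v_drug * v_partner - v_combo
}

#' Classify a Bliss index
#'
#' @param bi Numeric Bliss index (vectorized).
#' @return Character vector: `"strong synergism"` (`bi >= 0.1`, inclusive),
#'   `"synergistic"` (`bi > 0`), `"antagonistic"` (`bi < 0`) or `"additive"`.
#' @export
bliss_class <- function(bi) {
  ifelse(bi >= 0.1, "strong synergism",
         ifelse(bi > 0, "synergistic",
                ifelse(bi < 0, "antagonistic", "additive")))
}

#' Geometric concentration grid for serial-dilution dose series
#'
#' @param from Lowest dose (default 0.0128 nM).
#' @param ratio Dilution ratio between successive doses (default 5).
#' @param n Number of doses (default 9; the defaults span 0.0128-5000 nM).
#' @return Numeric vector of doses in increasing order.
#' @export
bliss_dose_grid <- function(from = 0.0128, ratio = 5, n = 9) {
  from * ratio^(seq_len(n) - 1)
}

#' Per-concentration Bliss indices over a dose series
#'
#' Computes a Bliss index at each concentration of a serial-dose experiment
#' in which the drug is titrated against a single fixed partner dose.
#'
#' @param drug Data frame with columns `conc` and `viability` for the drug
#'   alone.
#' @param combo Data frame with columns `conc` and `viability` for the
#'   drug + partner combination, on the identical concentration grid.
#' @param v_partner Relative viability of the partner alone at its fixed dose.
#' @return Data frame with `conc`, `v_drug`, `v_partner`, `v_combo`,
#'   `bliss_index` and `class`.
#' @export
dose_series_bliss <- function(drug, combo, v_partner) {
  if (nrow(drug) != nrow(combo) ||
      !isTRUE(all.equal(sort(drug$conc), sort(combo$conc))))
    stop("mismatched concentration grids between drug-alone and combination arms")
  drug <- drug[order(drug$conc), ]
  combo <- combo[order(combo$conc), ]
  bi <- bliss_index(drug$viability, v_partner, combo$viability)
  data.frame(conc = drug$conc, v_drug = drug$viability,
             v_partner = v_partner, v_combo = combo$viability,
             bliss_index = bi, class = bliss_class(bi), row.names = NULL)
}

#' Hit-selection criteria for the primary screen
#'
#' @param stromal_min_viability Minimum relative viability required of every
#'   stromal (normal) cell line in both arms (default 0.8).
#' @param leukemia_bliss_threshold Bliss index above which a combination is a
#'   hit (default 0.1).
#' @param leukemia_kill_viability Viability below which a drug qualifies by
#'   killing leukemia cells in both arms (default 0.5).
#' @return An object of class `hit_criteria`.
#' @export
hit_criteria <- function(stromal_min_viability = 0.8,
                         leukemia_bliss_threshold = 0.1,
                         leukemia_kill_viability = 0.5) {
  v <- c(stromal_min_viability, leukemia_bliss_threshold,
         leukemia_kill_viability)
  if (any(!is.finite(v))) stop("criteria thresholds must be finite")
  if (stromal_min_viability <= 0 || stromal_min_viability > 1.5)
    stop("stromal_min_viability must lie in (0, 1.5]")
  structure(list(stromal_min_viability = stromal_min_viability,
                 leukemia_bliss_threshold = leukemia_bliss_threshold,
                 leukemia_kill_viability = leukemia_kill_viability),
            class = "hit_criteria")
}

#' Two-criterion hit selection for the primary screen
#'
#' A drug is a hit under a given oxygen condition iff (1) every stromal cell
#' line keeps relative viability above the stromal threshold in both arms
#' (with and without the partner drug) and (2) some leukemia cell line shows
#' either a Bliss index above the synergy threshold or viability below the
#' kill threshold in both arms. The overall hit set is the union across
#' oxygen conditions.
#'
#' @param leukemia Data frame with columns `drug_id`, `cell_line`, `oxygen`,
#'   `v_without`, `v_with` (relative viabilities without/with the partner)
#'   and `bliss_index`.
#' @param stromal Data frame with columns `drug_id`, `cell_line`, `oxygen`,
#'   `v_without`, `v_with`.
#' @param criteria A [hit_criteria()] object.
#' @return An object of class `hit_report`: list with `hits` (drug ids,
#'   union across conditions), `by_oxygen` (named list of per-condition hit
#'   sets) and `audit` (per drug x condition data frame recording which
#'   clause fired).
#' @export
select_hits <- function(leukemia, stromal, criteria = hit_criteria()) {
  stopifnot(inherits(criteria, "hit_criteria"))
  for (d in unique(leukemia$drug_id)) {
    rows <- leukemia[leukemia$drug_id == d, ]
    if (any(!is.finite(rows$v_without)) || any(!is.finite(rows$v_with)))
      stop("drug ", d, " is missing a treatment arm")
    if (!d %in% stromal$drug_id)
      stop("drug ", d, " is missing from the stromal table")
  }
  audit <- do.call(rbind, lapply(split(leukemia,
                                       leukemia[c("drug_id", "oxygen")],
                                       drop = TRUE), function(lk) {
    d <- lk$drug_id[1L]; ox <- lk$oxygen[1L]
    st <- stromal[stromal$drug_id == d & stromal$oxygen == ox, ]
    if (nrow(st) == 0L) stop("drug ", d, " is missing stromal data under ", ox)
    stromal_ok <- all(st$v_without > criteria$stromal_min_viability) &&
      all(st$v_with > criteria$stromal_min_viability)
    bliss_clause <- any(lk$bliss_index > criteria$leukemia_bliss_threshold)
    kill_clause <- any(lk$v_without < criteria$leukemia_kill_viability &
                       lk$v_with < criteria$leukemia_kill_viability)
    data.frame(drug_id = d, oxygen = ox, stromal_ok = stromal_ok,
               bliss_clause = bliss_clause, kill_clause = kill_clause,
               hit = stromal_ok && (bliss_clause || kill_clause),
               clause = if (!stromal_ok) "stromal_fail"
                        else if (bliss_clause) "bliss"
                        else if (kill_clause) "kill" else "none",
               row.names = NULL)
  }))
  rownames(audit) <- NULL
  by_oxygen <- lapply(split(audit, audit$oxygen),
                      function(a) sort(unique(a$drug_id[a$hit])))
  hits <- sort(unique(unlist(by_oxygen, use.names = FALSE)))
  structure(list(hits = hits, by_oxygen = by_oxygen, audit = audit,
                 criteria = criteria),
            class = "hit_report")
}

#' @export
print.hit_report <- function(x, ...) {
  cat("Primary-screen hit report\n")
  for (ox in names(x$by_oxygen))
    cat("  ", ox, ": ", length(x$by_oxygen[[ox]]), " hits\n", sep = "")
  cat("  union: ", length(x$hits), " drugs\n", sep = "")
  invisible(x)
}
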