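## Packaged primary-screen summary for OCI-AML3 (21 selected drugs, 100 nM,
## with/without 30 nM IACS-010759, hypoxia and normoxia) and the
## partner-viability reconstruction used to audit the printed Bliss indices.

#' Packaged OCI-AML3 primary-screen summary table
#'
#' Relative viabilities of OCI-AML3 under 21 selected drugs alone
#' (`*_alone`), in combination with the OXPHOS inhibitor IACS-010759
#' (`*_combo`), and the reported Bliss indices, under hypoxia and normoxia.
#'
#' @return Data frame with one row per drug.
#' @export
primary_screen_table <- function() {
  read.csv(system.file("extdata", "primary_screen_oci_aml3.csv",
                       package = "synerflux"), stringsAsFactors = FALSE)
}

#' Least-squares estimate of the partner single-agent viability
#'
#' In a screen reporting per-drug viabilities `v_drug` (drug alone), combo
#' viabilities `v_combo` and Bliss indices `bi = v_drug * v_partner -
#' v_combo`, the shared partner viability can be recovered by least squares:
#' `v_hat = sum(v_drug * (bi + v_combo)) / sum(v_drug^2)`.
#'
#' @param v_drug,v_combo,bi Numeric vectors over screen rows.
#' @return Scalar estimate of the partner's single-agent relative viability.
#' @export
partner_viability_ls <- function(v_drug, v_combo, bi) {
  if (length(v_drug) == 0L) stop("no rows to estimate from")
  sum(v_drug * (bi + v_combo)) / sum(v_drug^2)
}

#' Reconstruct screen Bliss indices via leave-one-out partner estimation
#'
#' For each row of a primary-screen summary, estimates the partner viability
#' by least squares over the other rows ([partner_viability_ls()]) and
#' recomputes the row's Bliss index with [bliss_index()]. Agreement with the
#' reported indices audits the internal consistency of the screen table.
#'
#' @param screen Data frame as returned by [primary_screen_table()].
#' @param condition `"hypoxia"` or `"normoxia"`.
#' @return Data frame with `drug_id`, `drug_name`, `v_drug`, `v_combo`,
#'   `reported_bliss`, `partner_viability_hat`, `reconstructed_bliss`.
#' @export
reconstruct_bliss <- function(screen = primary_screen_table(),
                              condition = c("hypoxia", "normoxia")) {
  condition <- match.arg(condition)
  d <- screen[[paste0(condition, "_alone")]]
  v <- screen[[paste0(condition, "_combo")]]
  b <- screen[[paste0(condition, "_bliss")]]
  vhat <- vapply(seq_along(d), function(i) {
    partner_viability_ls(d[-i], v[-i], b[-i])
  }, numeric(1))
  data.frame(drug_id = screen$drug_id, drug_name = screen$drug_name,
             v_drug = d, v_combo = v, reported_bliss = b,
             partner_viability_hat = vhat,
             reconstructed_bliss = bliss_index(d, vhat, v),
             row.names = NULL)
}
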