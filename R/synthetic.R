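## Synthetic-data generators: every input the pipeline consumes (plate
## readouts, feature tables, tracer MDV sets) built from declared ground
## truth, bit-reproducible under a fixed seed. Ground truth is always
## emitted next to the generated data.

## lognormal multiplicative noise with unit mean and the given CV
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Specification of a synthetic screening plate
#'
#' @param drugs Character vector of drug ids.
#' @param cell_lines Named character vector mapping cell-line name to type
#'   (`"leukemia"` or `"stromal"`).
#' @param true_viability Matrix (drugs x cell lines) of true single-agent
#'   relative viabilities.
#' @param partner_viability Named numeric: true partner single-agent
#'   viability per cell line.
#' @param interaction Matrix (drugs x cell lines) of true Bliss-scale
#'   interaction terms (combination viability = `v_drug * v_partner -
#'   interaction`).
#' @param replicates Replicates per well group (default 4).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   luminescence noise (default 0.05).
#' @param control_level Mean control luminescence (default 10000).
#' @param oxygen Oxygen condition label (default `"hypoxia"`).
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(drugs, cell_lines, true_viability, partner_viability,
                       interaction = NULL, replicates = 4L, noise_cv = 0.05,
                       control_level = 1e4, oxygen = "hypoxia") {
  if (is.null(interaction))
    interaction <- matrix(0, length(drugs), length(cell_lines))
  dimnames(true_viability) <- dimnames(interaction) <-
    list(drugs, names(cell_lines))
  if (any(true_viability < 0) || any(partner_viability < 0))
    stop("true viabilities must be non-negative")
  if (noise_cv < 0) stop("noise CV must be non-negative")
  structure(list(drugs = drugs, cell_lines = cell_lines,
                 true_viability = true_viability,
                 partner_viability = partner_viability,
                 interaction = interaction, replicates = as.integer(replicates),
                 noise_cv = noise_cv, control_level = control_level,
                 oxygen = oxygen), class = "plate_spec")
}

#' Generate synthetic plate well records
#'
#' Emits long-format well records for control, partner-alone, drug-alone
#' and combination wells of every (drug, cell line) pair, with signals
#' `control_level * viability * lognormal noise`, plus the ground-truth
#' table of planted viabilities and interactions.
#'
#' @param spec A [plate_spec()].
#' @param seed Integer seed.
#' @return List with `records` (well records, see [relative_viability()])
#'   and `truth` (per drug x cell line: true viabilities, interaction and
#'   the implied Bliss index).
#' @export
gen_plate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(seed)
  rows <- list()
  add <- function(cl, drug, drug_conc, partner_conc, viab) {
    sig <- spec$control_level * viab *
      .lognoise(spec$replicates, spec$noise_cv)
    rows[[length(rows) + 1L]] <<- data.frame(
      plate_id = "P1", well_id = paste0(cl, "_", drug, "_", partner_conc),
      cell_line = cl, drug_id = drug, drug_conc = drug_conc,
      partner_conc = partner_conc, oxygen = spec$oxygen,
      replicate = seq_len(spec$replicates), signal = sig,
      stringsAsFactors = FALSE)
  }
  truth <- list()
  for (cl in names(spec$cell_lines)) {
    add(cl, "DMSO", 0, 0, 1)
    add(cl, "PARTNER", 0, 30, spec$partner_viability[[cl]])
    for (d in spec$drugs) {
      v1 <- spec$true_viability[d, cl]
      vc <- v1 * spec$partner_viability[[cl]] - spec$interaction[d, cl]
      if (vc < 0) vc <- 0
      add(cl, d, 100, 0, v1)
      add(cl, d, 100, 30, vc)
      truth[[length(truth) + 1L]] <- data.frame(
        drug_id = d, cell_line = cl, type = spec$cell_lines[[cl]],
        v_drug = v1, v_partner = spec$partner_viability[[cl]],
        v_combo = vc, interaction = spec$interaction[d, cl],
        bliss_index = v1 * spec$partner_viability[[cl]] - vc,
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Specification of a synthetic DIMS feature table
#'
#' Group means in log-intensity space: ctrl baseline, ctrl + d1, ctrl + d2
#' and ctrl + alpha * (d1 + d2) / 2 for the combination, so `alpha = 1` is
#' the additive boundary and `alpha > 1` super-additive.
#'
#' @param n_features Number of regular features.
#' @param d1,d2 Per-feature displacement vectors (log scale) for the two
#'   single drugs; scalars are expanded via a random direction drawn at
#'   generation time.
#' @param alpha Combination rule multiplier (default 1).
#' @param noise_sd Replicate noise SD in log space (default 0.1).
#' @param missing_rate Fraction of cells masked as missing, capped at one
#'   per feature and group so cleaning keeps regular features (default 0).
#' @param n_blank_features Planted blank-dominated features (default 0).
#' @param n_lowrep_features Planted features detected in too few replicates
#'   (default 0).
#' @param replicates Replicates per treatment group (default 5).
#' @param n_blanks Blank samples (default 3).
#' @param baseline_log Mean log10-scale baseline intensity (default 6).
#' @return Object of class `omics_spec`.
#' @export
omics_spec <- function(n_features = 50L, d1 = 1, d2 = 1, alpha = 1,
                       noise_sd = 0.1, missing_rate = 0,
                       n_blank_features = 0L, n_lowrep_features = 0L,
                       replicates = 5L, n_blanks = 3L, baseline_log = 6) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (missing_rate < 0 || missing_rate > 1) stop("missing rate must lie in [0, 1]")
  structure(as.list(environment()), class = "omics_spec")
}

#' Generate a synthetic feature table with ground truth
#'
#' @param spec An [omics_spec()].
#' @param seed Integer seed.
#' @return List with `table` (a [feature_table()], intensities on the raw
#'   scale, missing cells as `NA`) and `truth` (displacements, alpha,
#'   planted feature ids).
#' @export
gen_feature_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "omics_spec"))
  set.seed(seed)
  p <- spec$n_features
  d1 <- if (length(spec$d1) == 1L) spec$d1 * .unit_dir(p) else spec$d1
  d2 <- if (length(spec$d2) == 1L) spec$d2 * .unit_dir(p) else spec$d2
  base <- rnorm(p, spec$baseline_log, 0.5)
  shift <- list(ctrl = rep(0, p), drug1 = d1, drug2 = d2,
                comb = spec$alpha * (d1 + d2) / 2)
  groups <- c(rep(names(shift), each = spec$replicates),
              rep("blank", spec$n_blanks))
  logx <- sapply(seq_along(groups), function(s) {
    g <- groups[s]
    mu <- if (g == "blank") base - 4 else base + shift[[g]]
    mu + rnorm(p, 0, spec$noise_sd)
  })
  x <- exp(logx)
  ids <- paste0("F", seq_len(p))

  extra <- NULL; extra_ids <- character(0)
  blank_ids <- lowrep_ids <- character(0)
  if (spec$n_blank_features > 0L) {
    blank_ids <- paste0("BLANKF", seq_len(spec$n_blank_features))
    bx <- t(sapply(seq_len(spec$n_blank_features), function(i) {
      lvl <- exp(rnorm(1, spec$baseline_log, 0.3))
      ifelse(groups == "blank", lvl, lvl * 0.5) *
        exp(rnorm(length(groups), 0, spec$noise_sd))
    }))
    extra <- rbind(extra, bx); extra_ids <- c(extra_ids, blank_ids)
  }
  if (spec$n_lowrep_features > 0L) {
    lowrep_ids <- paste0("LOWF", seq_len(spec$n_lowrep_features))
    lx <- t(sapply(seq_len(spec$n_lowrep_features), function(i) {
      v <- exp(rnorm(length(groups), spec$baseline_log, spec$noise_sd))
      for (g in setdiff(unique(groups), "blank")) {
        cols <- which(groups == g)
        v[sample(cols, max(0L, length(cols) - 3L))] <- NA  # detected <= 3/group
      }
      v[groups == "blank"] <- NA
      v
    }))
    extra <- rbind(extra, lx); extra_ids <- c(extra_ids, lowrep_ids)
  }
  mat <- rbind(x, extra)
  rownames(mat) <- c(ids, extra_ids)

  if (spec$missing_rate > 0) {
    for (i in seq_len(p)) {
      for (g in unique(groups)) {
        cols <- which(groups == g)
        cand <- cols[runif(length(cols)) < spec$missing_rate]
        if (length(cand)) mat[i, cand[1L]] <- NA  # at most one per group
      }
    }
  }
  ft <- feature_table(mat, groups)
  list(table = ft,
       truth = list(d1 = d1, d2 = d2, alpha = spec$alpha, baseline = base,
                    blank_features = blank_ids, lowrep_features = lowrep_ids))
}

.unit_dir <- function(p) {
  z <- rnorm(p)
  z / sqrt(sum(z^2)) * sqrt(p)   # unit average squared component
}

#' Generate a synthetic tracer dataset from known fluxes
#'
#' Simulates steady-state MDVs for the true flux vector, perturbs each
#' replicate with Gaussian noise truncated at zero and renormalized, and
#' averages replicates into a [measured_mdv_set()] carrying the specified
#' SDs.
#'
#' @param model A `flux_model`.
#' @param flux Admissible true flux vector.
#' @param tracer A [tracer_spec()].
#' @param targets Measured metabolites (default: all internal).
#' @param sd Measurement SD per isotopologue fraction (default 0.005).
#' @param replicates Replicates averaged per metabolite (default 3).
#' @param seed Integer seed.
#' @return List with `data` (a `measured_mdv_set`) and `truth` (the flux
#'   vector and noiseless MDVs).
#' @export
gen_tracer_dataset <- function(model, flux, tracer, targets = NULL,
                               sd = 0.005, replicates = 3L, seed = 1L) {
  if (!is_admissible(model, if (is.null(names(flux))) flux
                            else flux[model$reactions$id]))
    stop("true flux vector is not admissible for this model")
  clean <- simulate_mdv(model, flux, tracer, targets)
  set.seed(seed)
  noisy <- lapply(clean, function(m) {
    reps <- replicate(replicates, {
      x <- pmax(unclass(m) + rnorm(length(m), 0, sd), 0)
      x / sum(x)
    })
    mdv(rowMeans(reps), sd = rep(sd, length(m)), corrected = TRUE)
  })
  list(data = measured_mdv_set(list(list(tracer = tracer, mdvs = noisy)),
                               sd_floor = if (sd > 0) min(sd, 1e-3) else 1e-6),
       truth = list(flux = flux, mdvs = clean))
}
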