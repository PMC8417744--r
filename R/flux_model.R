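## Atom-mapped metabolic network model: JSON ingest, validation (letter
## conservation), stoichiometric matrix, and the free-flux parametrization
## of the steady-state null space with glucose uptake pinned at 100.

#' Build a flux model from a parsed model list
#'
#' @param x List with elements `metabolites` (id, atoms, external),
#'   `reactions` (id, lb, ub, mappings) and `uptake` (reaction, value).
#'   Each mapping has `weight`, `substrates` and `products`, both lists of
#'   `(met, atoms)` entries where `atoms` is a lowercase letter string
#'   assigning atom positions.
#' @return Object of class `flux_model`.
#' @export
flux_model <- function(x) {
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, atoms = as.integer(m$atoms),
               external = isTRUE(m$external), stringsAsFactors = FALSE)))
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  natoms <- stats::setNames(mets$atoms, mets$id)
  is_ext <- stats::setNames(mets$external, mets$id)

  rxn_ids <- vapply(x$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  lb <- vapply(x$reactions, function(r) as.numeric(r$lb %||% 0), numeric(1))
  ub <- vapply(x$reactions, function(r) as.numeric(r$ub %||% 1000), numeric(1))
  if (any(lb > ub)) stop("infeasible bounds: lb > ub for ",
                         paste(rxn_ids[lb > ub], collapse = ", "))

  side_counts <- function(side) {
    tab <- table(vapply(side, `[[`, character(1), "met"))
    stats::setNames(as.integer(tab), names(tab))
  }
  mappings <- vector("list", length(x$reactions))
  internal <- mets$id[!mets$external]
  S <- matrix(0, length(internal), length(rxn_ids),
              dimnames = list(internal, rxn_ids))
  for (k in seq_along(x$reactions)) {
    r <- x$reactions[[k]]
    maps <- r$mappings
    if (is.null(maps) || !length(maps)) stop("reaction ", r$id, " has no atom mapping")
    ref_sub <- NULL; ref_prod <- NULL
    w_sum <- 0
    for (m in maps) {
      for (ent in c(m$substrates, m$products)) {
        if (!ent$met %in% mets$id)
          stop("reaction ", r$id, " references unknown metabolite ", ent$met)
        if (nchar(ent$atoms) != natoms[[ent$met]])
          stop("reaction ", r$id, ": atom string for ", ent$met,
               " has length ", nchar(ent$atoms), ", expected ", natoms[[ent$met]])
      }
      sub_letters <- sort(strsplit(paste(vapply(m$substrates, `[[`,
                                                character(1), "atoms"),
                                         collapse = ""), "")[[1]])
      prod_letters <- sort(strsplit(paste(vapply(m$products, `[[`,
                                                 character(1), "atoms"),
                                          collapse = ""), "")[[1]])
      if (!identical(sub_letters, prod_letters))
        stop("reaction ", r$id, ": atom letters not conserved between sides")
      cs <- side_counts(m$substrates); cp <- side_counts(m$products)
      if (is.null(ref_sub)) { ref_sub <- cs; ref_prod <- cp }
      else if (!identical(ref_sub[order(names(ref_sub))], cs[order(names(cs))]) ||
               !identical(ref_prod[order(names(ref_prod))], cp[order(names(cp))]))
        stop("reaction ", r$id, ": mapping variants disagree on stoichiometry")
      w_sum <- w_sum + (m$weight %||% 1)
    }
    if (abs(w_sum - 1) > 1e-9)
      stop("reaction ", r$id, ": mapping weights must sum to 1")
    for (met in names(ref_sub))
      if (!is_ext[[met]]) S[met, r$id] <- S[met, r$id] - ref_sub[[met]]
    for (met in names(ref_prod))
      if (!is_ext[[met]]) S[met, r$id] <- S[met, r$id] + ref_prod[[met]]
    mappings[[k]] <- maps
  }
  names(mappings) <- rxn_ids

  upr <- x$uptake$reaction
  upv <- as.numeric(x$uptake$value %||% 100)
  if (!upr %in% rxn_ids) stop("uptake reaction ", upr, " not in model")

  ## steady-state null space with the uptake flux pinned: A v = b
  A <- rbind(S, as.numeric(rxn_ids == upr))
  b <- c(rep(0, nrow(S)), upv)
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  dinv <- c(1 / sv$d[seq_len(r)], rep(0, length(sv$d) - r))
  v0 <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (dinv * (t(sv$u[, seq_along(sv$d), drop = FALSE]) %*% b))
  if (max(abs(A %*% v0 - b)) > 1e-6)
    stop("no steady-state flux satisfies the uptake constraint")
  N <- sv$v[, -seq_len(r), drop = FALSE]

  structure(list(name = x$name %||% "flux model", metabolites = mets,
                 reactions = data.frame(id = rxn_ids, lb = lb, ub = ub,
                                        stringsAsFactors = FALSE),
                 mappings = mappings, S = S,
                 uptake = list(reaction = upr, value = upv),
                 v0 = drop(v0), N = N,
                 cache = new.env(parent = emptyenv())),
            class = "flux_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an atom-mapped flux model from JSON
#'
#' Validates atom-letter conservation per reaction, assembles the
#' stoichiometric matrix over internal metabolites, and parametrizes the
#' steady-state solution set (with the designated uptake flux pinned to its
#' value) as `v = v0 + N theta`.
#'
#' @param file Path to a model JSON file.
#' @return Object of class `flux_model`.
#' @export
load_model <- function(file) {
  flux_model(jsonlite::read_json(file))
}

#' Write a flux model back to JSON (lossless round trip)
#'
#' @param model A `flux_model`.
#' @param file Output path.
#' @export
write_model <- function(model, file) {
  x <- list(name = model$name,
            metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
              list(id = model$metabolites$id[i],
                   atoms = model$metabolites$atoms[i],
                   external = model$metabolites$external[i])),
            reactions = lapply(seq_len(nrow(model$reactions)), function(i)
              list(id = model$reactions$id[i], lb = model$reactions$lb[i],
                   ub = model$reactions$ub[i],
                   mappings = model$mappings[[i]])),
            uptake = model$uptake)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Packaged central-carbon network model
#'
#' A curated 53-reaction, 34-metabolite atom-mapped model of glycolysis,
#' the (lumped oxidative) pentose phosphate pathway, the oxidative and
#' reductive TCA cycle and glutaminolysis, with glucose uptake pinned at
#' 100 flux units. The reaction set is a synthetic curation assembled for
#' this package, not a published reconstruction.
#'
#' @return Object of class `flux_model`.
#' @export
default_model <- function() {
  load_model(system.file("extdata", "central_carbon_model.json",
                         package = "synerflux"))
}

#' @export
print.flux_model <- function(x, ...) {
  cat("Flux model '", x$name, "': ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(!x$metabolites$external), " internal), ",
      ncol(x$N), " free fluxes; ", x$uptake$reaction, " = ",
      x$uptake$value, "\n", sep = "")
  invisible(x)
}

#' Number of free fluxes of a model
#' @param model A `flux_model`.
#' @return Integer dimension of the constrained null space.
#' @export
n_free <- function(model) ncol(model$N)

#' Flux vector from free-flux coordinates
#'
#' @param model A `flux_model`.
#' @param theta Numeric vector of length [n_free()].
#' @return Named flux vector `v0 + N theta` (satisfies `S v = 0` and the
#'   uptake constraint by construction; bounds are not enforced here).
#' @export
flux_from_free <- function(model, theta) {
  stats::setNames(drop(model$v0 + model$N %*% theta), model$reactions$id)
}

#' Check admissibility of a flux vector
#'
#' @param model A `flux_model`.
#' @param v Flux vector.
#' @param tol Numerical tolerance.
#' @return `TRUE` iff `S v = 0`, the uptake constraint holds and all bounds
#'   are respected within `tol`.
#' @export
is_admissible <- function(model, v, tol = 1e-6) {
  max(abs(model$S %*% v)) <= tol &&
    abs(v[model$uptake$reaction] - model$uptake$value) <= tol &&
    all(v >= model$reactions$lb - tol) && all(v <= model$reactions$ub + tol)
}

#' Approximate analytic center of the flux polytope
#'
#' Maximizes the sum of log-distances to the (non-pinned) bounds over the
#' free-flux coordinates, yielding a comfortably interior steady-state flux
#' — a sensible ground truth for synthetic tracer data.
#'
#' @param model A `flux_model`.
#' @return List with `v` and `theta`, as for [feasible_flux()].
#' @export
interior_flux <- function(model) {
  start <- feasible_flux(model)
  if (n_free(model) == 0L) return(start)   # solution set is a point
  lb <- model$reactions$lb; ub <- model$reactions$ub
  free <- which(ub - lb > 1e-9)
  barrier <- function(th) {
    v <- drop(model$v0 + model$N %*% th)
    d1 <- v[free] - lb[free]; d2 <- ub[free] - v[free]
    if (any(d1 <= 0) || any(d2 <= 0)) return(1e10)
    -sum(log(d1)) - sum(log(d2))
  }
  ## nudge the start strictly inside before applying the barrier
  th <- start$theta
  if (!is.finite(barrier(th)) || barrier(th) >= 1e10) {
    pen <- function(t_) {
      v <- drop(model$v0 + model$N %*% t_)
      sum(pmax(lb[free] + 1e-3 - v[free], 0)^2) +
        sum(pmax(v[free] - ub[free] + 1e-3, 0)^2)
    }
    th <- optim(th, pen, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))$par
  }
  fit <- optim(th, barrier, method = "BFGS", control = list(maxit = 500))
  ## derivative-free polish: the barrier gradient is ill-scaled near faces
  fit <- optim(fit$par, barrier, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-12))
  list(v = flux_from_free(model, fit$par), theta = drop(fit$par))
}

#' Find a bounds-feasible steady-state flux
#'
#' Minimizes the squared bound violation over the free-flux coordinates
#' (quasi-Newton), starting from the minimum-norm steady-state solution.
#'
#' @param model A `flux_model`.
#' @param theta0 Optional starting coordinates (default 0).
#' @return List with `v` (feasible flux vector) and `theta`.
#' @export
feasible_flux <- function(model, theta0 = NULL) {
  k <- n_free(model)
  if (is.null(theta0)) theta0 <- rep(0, k)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  pen <- function(th) {
    v <- model$v0 + model$N %*% th
    sum(pmax(lb - v, 0)^2) + sum(pmax(v - ub, 0)^2)
  }
  if (pen(theta0) > 0) {
    fit <- optim(theta0, pen, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    theta0 <- fit$par
    if (pen(theta0) > 1e-10)
      stop("no feasible steady-state flux within bounds")
  }
  list(v = flux_from_free(model, theta0), theta = drop(theta0))
}
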