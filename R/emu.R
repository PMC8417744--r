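## Elementary metabolite unit (EMU) decomposition: steady-state MDV
## simulation as a size-ordered cascade of linear balance systems. The
## network is decomposed backwards from the requested metabolites into the
## minimal set of EMUs (metabolite fragments) whose mass distributions are
## needed; condensation reactions become convolutions of smaller EMUs.

#' Define a labeled-substrate tracer
#'
#' @param substrate External metabolite id carrying the label.
#' @param labeled_positions Integer vector of labeled atom positions, or a
#'   list of such vectors for isotopomer mixtures.
#' @param fraction Fraction(s) of the substrate pool carrying each labeling
#'   pattern; any remainder is unlabeled.
#' @param name Display name.
#' @return Object of class `tracer_spec`.
#' @export
tracer_spec <- function(substrate, labeled_positions, fraction = 1,
                        name = NULL) {
  if (!is.list(labeled_positions)) labeled_positions <- list(labeled_positions)
  if (length(fraction) != length(labeled_positions))
    stop("one fraction per labeling pattern required")
  if (any(fraction < 0) || sum(fraction) > 1 + 1e-12)
    stop("labeling fractions must be non-negative and sum to at most 1")
  iso <- mapply(function(p, f) list(positions = as.integer(p), fraction = f),
                labeled_positions, fraction, SIMPLIFY = FALSE)
  rest <- 1 - sum(fraction)
  if (rest > 1e-12)
    iso <- c(iso, list(list(positions = integer(0), fraction = rest)))
  structure(list(substrate = substrate, isotopomers = iso,
                 name = name %||% paste0(substrate, "-tracer")),
            class = "tracer_spec")
}

#' 1,2-13C2 glucose tracer (fully labeled pool)
#' @return A [tracer_spec()].
#' @export
tracer_glucose_12 <- function()
  tracer_spec("GLC_x", 1:2, 1, "1,2-13C2-glucose")

#' U-13C5 glutamine tracer (carbon skeleton of 13C5,15N2-glutamine)
#' @return A [tracer_spec()].
#' @export
tracer_glutamine_5 <- function()
  tracer_spec("GLN_x", 1:5, 1, "13C5-glutamine")

.tracer_key <- function(tracer)
  paste(tracer$substrate,
        paste(vapply(tracer$isotopomers, function(i)
          paste0(paste(i$positions, collapse = "."), ":", i$fraction),
          character(1)), collapse = "|"))

## MDV of an external-substrate EMU over atom positions `pos`.
.input_mdv <- function(met, pos, tracer) {
  n <- length(pos)
  out <- numeric(n + 1L)
  if (!is.null(tracer) && met == tracer$substrate) {
    for (iso in tracer$isotopomers) {
      m <- sum(pos %in% iso$positions)
      out[m + 1L] <- out[m + 1L] + iso$fraction
    }
  } else out[1L] <- 1
  out
}

#' Build the EMU cascade for a model, tracer and target set
#'
#' @param model A `flux_model`.
#' @param tracer A [tracer_spec()].
#' @param targets Internal metabolite ids whose full MDVs are required.
#' @return An opaque `emu_system` list consumed by [simulate_mdv()] and the
#'   sampler; cached on the model.
#' @export
build_emu_system <- function(model, tracer, targets) {
  key <- paste(.tracer_key(tracer), paste(sort(targets), collapse = ","))
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])

  natoms <- stats::setNames(model$metabolites$atoms, model$metabolites$id)
  is_ext <- stats::setNames(model$metabolites$external, model$metabolites$id)
  bad <- setdiff(targets, model$metabolites$id[!model$metabolites$external])
  if (length(bad)) stop("unknown internal target metabolite(s): ",
                        paste(bad, collapse = ", "))

  ## expanded mapping variants with reaction indices
  variants <- list()
  for (r in seq_along(model$mappings))
    for (m in model$mappings[[r]])
      variants[[length(variants) + 1L]] <-
        list(rxn = r, weight = m$weight %||% 1,
             substrates = lapply(m$substrates, function(e)
               list(met = e$met, atoms = strsplit(e$atoms, "")[[1]])),
             products = lapply(m$products, function(e)
               list(met = e$met, atoms = strsplit(e$atoms, "")[[1]])))

  ## total consumption terms per internal metabolite: list of (rxn, count)
  cons <- list()
  for (r in seq_along(model$mappings)) {
    m <- model$mappings[[r]][[1L]]
    for (e in m$substrates) {
      if (is_ext[[e$met]]) next
      cons[[e$met]] <- c(cons[[e$met]] %||% list(),
                         list(c(rxn = r, count = 1)))
    }
  }

  emu_key <- function(met, pos) paste0(met, "|", paste(pos, collapse = ","))
  need <- new.env(parent = emptyenv())   # key -> list(met, pos, size)
  queue <- lapply(targets, function(tg) list(met = tg, pos = seq_len(natoms[[tg]])))
  terms <- list()                        # key -> list of production terms
  while (length(queue)) {
    e <- queue[[1L]]; queue <- queue[-1L]
    k <- emu_key(e$met, e$pos)
    if (!is.null(need[[k]])) next
    need[[k]] <- list(met = e$met, pos = e$pos, size = length(e$pos))
    if (is.null(cons[[e$met]]))
      stop("metabolite pool ", e$met, " has zero throughput (never consumed)")
    tl <- list()
    for (v in variants) {
      for (pe in v$products) {
        if (pe$met != e$met) next
        letters <- pe$atoms[e$pos]
        sources <- list()
        for (se in v$substrates) {
          sp <- which(se$atoms %in% letters)
          if (length(sp))
            sources[[length(sources) + 1L]] <- list(met = se$met, pos = sp)
        }
        stopifnot(sum(vapply(sources, function(s) length(s$pos), integer(1)))
                  == length(e$pos))
        tl[[length(tl) + 1L]] <- list(rxn = v$rxn, weight = v$weight,
                                      sources = sources)
        for (s in sources)
          if (!is_ext[[s$met]])
            queue[[length(queue) + 1L]] <- list(met = s$met, pos = s$pos)
      }
    }
    if (!length(tl))
      stop("metabolite pool ", e$met, " has zero production in the network")
    terms[[k]] <- tl
  }

  emus <- mget(ls(need), envir = need)
  sizes <- sort(unique(vapply(emus, `[[`, integer(1) + 0, "size")))

  ## slot allocation: internal EMUs, external inputs, convolution nodes
  slot_of <- new.env(parent = emptyenv())
  n_slots <- 0L
  new_slot <- function() { n_slots <<- n_slots + 1L; n_slots }
  inputs <- list()                       # list of (slot, values)
  input_slot <- function(met, pos) {
    k <- paste0("in:", emu_key(met, pos))
    if (is.null(slot_of[[k]])) {
      slot_of[[k]] <- new_slot()
      inputs[[length(inputs) + 1L]] <<-
        list(slot = slot_of[[k]], values = .input_mdv(met, pos, tracer))
    }
    slot_of[[k]]
  }
  for (k in names(emus)) slot_of[[k]] <- new_slot()

  levels <- list()
  conv_memo <- new.env(parent = emptyenv())
  for (s in sizes) {
    rows <- emus[vapply(emus, function(e) e$size == s, logical(1))]
    row_keys <- names(rows)
    row_index <- stats::setNames(seq_along(row_keys), row_keys)
    A <- list(i = integer(0), j = integer(0), r = integer(0), w = numeric(0))
    B <- list(i = integer(0), r = integer(0), slot = integer(0), w = numeric(0))
    convs <- list()
    source_slot <- function(src) {       # slot of one source EMU (any size)
      if (is_ext[[src$met]]) input_slot(src$met, src$pos)
      else slot_of[[emu_key(src$met, src$pos)]]
    }
    term_slot <- function(sources) {     # slot holding the term's MDV
      slots <- vapply(sources, source_slot, integer(1))
      while (length(slots) > 1L) {
        k2 <- paste0("conv:", slots[1L], ":", slots[2L])
        if (is.null(conv_memo[[k2]])) {
          conv_memo[[k2]] <- new_slot()
          convs[[length(convs) + 1L]] <<-
            c(out = conv_memo[[k2]], a = slots[1L], b = slots[2L])
        }
        slots <- c(conv_memo[[k2]], slots[-(1:2)])
      }
      slots
    }
    for (k in row_keys) {
      i <- row_index[[k]]
      for (cc in cons[[rows[[k]]$met]]) {
        A$i <- c(A$i, i); A$j <- c(A$j, i)
        A$r <- c(A$r, cc[["rxn"]]); A$w <- c(A$w, -cc[["count"]])
      }
      for (tm in terms[[k]]) {
        if (length(tm$sources) == 1L && !is_ext[[tm$sources[[1L]]$met]]) {
          jk <- emu_key(tm$sources[[1L]]$met, tm$sources[[1L]]$pos)
          A$i <- c(A$i, i); A$j <- c(A$j, row_index[[jk]])
          A$r <- c(A$r, tm$rxn); A$w <- c(A$w, tm$weight)
        } else {
          B$i <- c(B$i, i); B$r <- c(B$r, tm$rxn)
          B$slot <- c(B$slot, term_slot(tm$sources)); B$w <- c(B$w, tm$weight)
        }
      }
    }
    levels[[length(levels) + 1L]] <- list(
      size = s, n = length(row_keys),
      conv = if (length(convs)) do.call(rbind, convs)
             else matrix(integer(0), 0L, 3L),
      A_i = A$i, A_j = A$j, A_r = A$r, A_w = A$w,
      B_i = B$i, B_r = B$r, B_slot = B$slot, B_w = B$w,
      out_slots = vapply(row_keys, function(k) slot_of[[k]], integer(1)),
      emu_keys = row_keys)
  }

  target_slots <- vapply(targets, function(tg)
    slot_of[[emu_key(tg, seq_len(natoms[[tg]]))]], integer(1))
  sys <- list(levels = levels, inputs = inputs, n_slots = n_slots,
              targets = stats::setNames(target_slots, targets),
              n_rxn = nrow(model$reactions), tracer = tracer$name)
  model$cache[[key]] <- sys
  sys
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the EMU cascade for an admissible flux vector and a tracer,
#' returning the MDV of each requested metabolite. Every returned MDV sums
#' to 1.
#'
#' @param model A `flux_model`.
#' @param flux Named or ordered flux vector satisfying `S v = 0`, the
#'   uptake constraint and the bounds.
#' @param tracer A [tracer_spec()].
#' @param targets Internal metabolite ids (default: all internal).
#' @param check Verify admissibility of `flux` first (default `TRUE`).
#' @return Named list of [mdv()] objects.
#' @export
simulate_mdv <- function(model, flux, tracer, targets = NULL, check = TRUE) {
  if (is.null(targets))
    targets <- model$metabolites$id[!model$metabolites$external]
  if (!is.null(names(flux))) flux <- flux[model$reactions$id]
  if (check && !is_admissible(model, flux))
    stop("flux vector is not admissible (steady state, uptake, bounds)")
  sys <- build_emu_system(model, tracer, targets)
  out <- emu_simulate_cpp(sys, as.numeric(flux))
  res <- lapply(seq_along(targets), function(i) {
    x <- out[[i]]
    if (abs(sum(x) - 1) > 1e-6)
      stop("simulated MDV for ", targets[i], " does not sum to 1 (",
           format(sum(x)), "); singular EMU subsystem?")
    x <- pmax(x, 0) + 0   # "+ 0" normalizes any negative zero
    mdv(x / sum(x), corrected = TRUE)
  })
  names(res) <- targets
  res
}
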