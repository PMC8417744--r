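# Independent brute-force isotopomer balance solver, used as the oracle for
# simulate_mdv(). Represents every internal metabolite's full isotopomer
# distribution (2^n states, bit k set = atom k labeled) and iterates the
# steady-state balance p(state) = production(state) / consumption_flux to a
# fixed point. No EMU decomposition anywhere.

oracle_mdv <- function(model, flux, tracer, targets,
                       tol = 1e-13, max_iter = 20000) {
  if (!is.null(names(flux))) flux <- flux[model$reactions$id]
  natoms <- stats::setNames(model$metabolites$atoms, model$metabolites$id)
  is_ext <- stats::setNames(model$metabolites$external, model$metabolites$id)
  mets <- model$metabolites$id

  # state distributions
  p <- list()
  for (m in mets) {
    n <- natoms[[m]]
    v <- numeric(2^n)
    if (is_ext[[m]] && m == tracer$substrate) {
      for (iso in tracer$isotopomers) {
        mask <- sum(2^(iso$positions - 1L))
        v[mask + 1L] <- v[mask + 1L] + iso$fraction
      }
    } else v[1L] <- 1
    p[[m]] <- v
  }

  # consumption flux per internal metabolite
  cons <- stats::setNames(numeric(length(mets)), mets)
  for (r in seq_along(model$mappings)) {
    mp <- model$mappings[[r]][[1L]]
    for (e in mp$substrates)
      if (!is_ext[[e$met]]) cons[e$met] <- cons[e$met] + flux[r]
  }

  # production terms: for each internal product entry, the per-atom origin
  terms <- list()
  for (r in seq_along(model$mappings)) {
    for (mp in model$mappings[[r]]) {
      w <- if (is.null(mp$weight)) 1 else mp$weight
      sub_atoms <- lapply(mp$substrates, function(e) strsplit(e$atoms, "")[[1]])
      sub_mets <- vapply(mp$substrates, `[[`, character(1), "met")
      for (pe in mp$products) {
        if (is_ext[[pe$met]]) next
        letters <- strsplit(pe$atoms, "")[[1]]
        origin <- lapply(seq_along(sub_mets), function(si) {
          hit <- match(sub_atoms[[si]], letters)     # sub pos -> product pos
          list(met = sub_mets[si], sub_pos = which(!is.na(hit)),
               prod_pos = hit[!is.na(hit)])
        })
        origin <- Filter(function(o) length(o$sub_pos) > 0L, origin)
        terms[[length(terms) + 1L]] <- list(met = pe$met, rxn = r, w = w,
                                            origin = origin)
      }
    }
  }

  # marginal distribution of a substrate over a position subset
  marginal <- function(dist, n, pos) {
    k <- length(pos)
    out <- numeric(2^k)
    for (s in 0:(2^n - 1)) {
      bits <- bitwAnd(s, 2^(pos - 1L)) > 0
      sub <- sum(2^(seq_len(k) - 1L)[bits])
      out[sub + 1L] <- out[sub + 1L] + dist[s + 1L]
    }
    out
  }

  internal <- mets[!is_ext[mets]]
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (m in internal) {
      n <- natoms[[m]]
      prod <- numeric(2^n)
      for (tm in terms) {
        if (tm$met != m) next
        v_r <- flux[tm$rxn] * tm$w
        if (v_r == 0) next
        # contribution over all product states by independence of substrates
        contrib <- rep(1, 2^n)
        known_mask <- 0L
        part <- list()
        for (o in tm$origin) {
          mg <- marginal(p[[o$met]], natoms[[o$met]], o$sub_pos)
          part[[length(part) + 1L]] <- list(prod_pos = o$prod_pos, mg = mg)
        }
        for (s in 0:(2^n - 1)) {
          pr <- 1
          for (pt in part) {
            bits <- bitwAnd(s, 2^(pt$prod_pos - 1L)) > 0
            idx <- sum(2^(seq_along(pt$prod_pos) - 1L)[bits])
            pr <- pr * pt$mg[idx + 1L]
          }
          prod[s + 1L] <- prod[s + 1L] + v_r * pr
        }
      }
      new_p <- prod / cons[[m]]
      delta <- max(delta, max(abs(new_p - p[[m]])))
      p[[m]] <- new_p
    }
    if (delta < tol) break
  }

  out <- lapply(targets, function(m) {
    n <- natoms[[m]]
    mdv_ <- numeric(n + 1L)
    for (s in 0:(2^n - 1)) {
      k <- sum(bitwAnd(s, 2^(0:(n - 1L))) > 0)
      mdv_[k + 1L] <- mdv_[k + 1L] + p[[m]][s + 1L]
    }
    mdv_
  })
  names(out) <- targets
  out
}
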