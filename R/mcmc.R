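## Flux posterior sampling: Gaussian-error likelihood exp(-RSS/2) over
## measured isotope fractions, random-walk Metropolis-Hastings in the free
## flux coordinates, flux ratios vs. citrate synthase, and Cohen's-d
## comparison between conditions.

#' Bundle measured MDVs for model fitting
#'
#' @param experiments List of tracer experiments, each a list with elements
#'   `tracer` (a [tracer_spec()]) and `mdvs` (named list of [mdv()] objects
#'   with `sd` attributes; names are internal model metabolites).
#' @param sd_floor Lower floor applied to every SD (default `1e-3`); SDs of
#'   0 without a floor are an error at [rss()] time.
#' @return Object of class `measured_mdv_set`.
#' @export
measured_mdv_set <- function(experiments, sd_floor = 1e-3) {
  for (e in experiments) {
    if (!inherits(e$tracer, "tracer_spec")) stop("each experiment needs a tracer_spec")
    if (is.null(names(e$mdvs))) stop("mdvs must be named by metabolite")
  }
  if (!is.null(sd_floor)) {
    experiments <- lapply(experiments, function(e) {
      e$mdvs <- lapply(e$mdvs, function(m) {
        s <- attr(m, "sd")
        if (is.null(s)) s <- rep(0, length(m))
        attr(m, "sd") <- pmax(s, sd_floor)
        m
      })
      e
    })
  }
  structure(list(experiments = experiments, sd_floor = sd_floor),
            class = "measured_mdv_set")
}

#' Weighted residual sum of squares between simulated and measured MDVs
#'
#' `sum(((sim - meas) / sd)^2)` over every covered isotopologue of every
#' metabolite of every tracer experiment.
#'
#' @param simulated Named list of [mdv()]s (one tracer experiment), or a
#'   list of such lists aligned with `measured$experiments`.
#' @param measured A [measured_mdv_set()], or a named list of measured
#'   [mdv()]s for the single-experiment case.
#' @return Non-negative scalar.
#' @export
rss <- function(simulated, measured) {
  if (inherits(measured, "measured_mdv_set")) {
    if (length(simulated) && inherits(simulated[[1L]], "mdv"))
      simulated <- list(simulated)
    exps <- measured$experiments
  } else {
    exps <- list(list(mdvs = measured))
    simulated <- list(simulated)
  }
  total <- 0
  for (e in seq_along(exps)) {
    for (met in names(exps[[e]]$mdvs)) {
      m <- exps[[e]]$mdvs[[met]]
      s <- simulated[[e]][[met]]
      if (is.null(s)) stop("no simulated MDV for measured metabolite ", met)
      if (length(s) != length(m))
        stop("isotopologue coverage mismatch for ", met)
      sd_m <- attr(m, "sd")
      if (is.null(sd_m)) stop("measured MDV for ", met, " carries no SDs")
      if (any(sd_m <= 0))
        stop("zero SD for ", met, " and no floor configured")
      total <- total + sum(((unclass(s) - unclass(m)) / sd_m)^2)
    }
  }
  total
}

#' Metropolis-Hastings sampling schedule
#'
#' @param chains Number of independent chains.
#' @param steps Proposals per chain.
#' @param burn_in Discarded initial steps per chain (must be `< steps`).
#' @param thin Keep every `thin`-th post-burn-in step.
#' @return Object of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(chains, steps, burn_in, thin) {
  stopifnot(chains >= 1, steps >= 1, thin >= 1)
  if (burn_in >= steps) stop("burn_in must be smaller than steps")
  structure(list(chains = as.integer(chains), steps = as.integer(steps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "mcmc_schedule")
}

#' Retained sample count of a schedule
#' @param schedule An [mcmc_schedule()].
#' @return `chains * floor((steps - burn_in) / thin)`.
#' @export
n_retained <- function(schedule)
  schedule$chains * ((schedule$steps - schedule$burn_in) %/% schedule$thin)

#' Desk-scale default schedule (4 chains x 50,000 steps)
#' @return An [mcmc_schedule()].
#' @export
desk_schedule <- function() mcmc_schedule(4L, 50000L, 25000L, 10L)

#' Full published-scale schedule (8 chains x 5,000,000 steps)
#'
#' Burn-in of 2,500,000 and thinning of 1,000 retain 2,500 samples per
#' chain, 20,000 in total.
#' @return An [mcmc_schedule()].
#' @export
full_schedule <- function() mcmc_schedule(8L, 5000000L, 2500000L, 1000L)

#' Fit flux posteriors by Metropolis-Hastings sampling
#'
#' Random-walk proposals in the free-flux coordinates of the steady-state
#' null space (Gaussian steps, rejected outside bounds), accepted with
#' probability `min(1, exp(-(RSS' - RSS) / 2))` — the Gaussian-error reading
#' of minimizing the residual sum of squares between measured and simulated
#' isotope fractions. The proposal scale adapts toward ~30% acceptance
#' during burn-in and is frozen afterwards. Per-chain seeds are derived
#' deterministically from the master seed (seed + chain index).
#'
#' @param model A `flux_model`.
#' @param data A [measured_mdv_set()].
#' @param schedule An [mcmc_schedule()] (default [desk_schedule()]).
#' @param seed Master integer seed.
#' @param sigma0 Initial proposal SD in free-flux units (default 2).
#' @param init_optim Refine the feasible start by a short quasi-Newton
#'   descent on the RSS before sampling (default `TRUE`).
#' @return Object of class `mfa_fit`: list with `samples` (retained flux
#'   vectors, rows = samples, columns = reactions), `rss`, `chain`,
#'   `acceptance` (per chain), `schedule`, `model`.
#' @export
mfa_fit <- function(model, data, schedule = desk_schedule(), seed = 1L,
                    sigma0 = 2, init_optim = TRUE) {
  stopifnot(inherits(model, "flux_model"),
            inherits(data, "measured_mdv_set"),
            inherits(schedule, "mcmc_schedule"))
  systems <- lapply(data$experiments, function(e)
    build_emu_system(model, e$tracer, names(e$mdvs)))
  meas <- lapply(data$experiments, function(e)
    list(values = lapply(e$mdvs, function(m) as.numeric(unclass(m))),
         sds = lapply(e$mdvs, function(m) as.numeric(attr(m, "sd")))))

  start <- feasible_flux(model)
  theta0 <- start$theta
  lb <- model$reactions$lb; ub <- model$reactions$ub
  obj <- function(th) {
    v <- model$v0 + model$N %*% th
    pen <- sum(pmax(lb - v, 0)^2) + sum(pmax(v - ub, 0)^2)
    sim <- lapply(seq_along(systems), function(e)
      tryCatch(emu_simulate_cpp(systems[[e]], as.numeric(pmin(pmax(v, lb), ub))),
               error = function(err) NULL))
    if (any(vapply(sim, is.null, logical(1)))) return(1e10)
    r <- 0
    for (e in seq_along(sim))
      r <- r + sum(unlist(mapply(function(s, m, sd_)
        sum(((s - m) / sd_)^2), sim[[e]], meas[[e]]$values, meas[[e]]$sds,
        SIMPLIFY = FALSE)))
    r + 1e4 * pen
  }
  if (init_optim) {
    fit0 <- optim(theta0, obj, method = "BFGS",
                  control = list(maxit = 200, reltol = 1e-10))
    v_try <- flux_from_free(model, fit0$par)
    if (all(v_try >= lb - 1e-9) && all(v_try <= ub + 1e-9))
      theta0 <- fit0$par
  }

  keep_per_chain <- (schedule$steps - schedule$burn_in) %/% schedule$thin
  samples <- vector("list", schedule$chains)
  rss_kept <- vector("list", schedule$chains)
  acceptance <- numeric(schedule$chains)
  warn <- character(0)
  for (ch in seq_len(schedule$chains)) {
    set.seed(seed + ch)
    res <- mh_run_cpp(systems, meas, model$v0, model$N, lb, ub, theta0,
                      sigma0, schedule$steps, schedule$burn_in,
                      schedule$thin, 500L, 0.3)
    th <- res$theta
    samples[[ch]] <- t(apply(th, 1L, function(t_) flux_from_free(model, t_)))
    rss_kept[[ch]] <- res$rss
    acceptance[ch] <- res$acceptance
    if (res$acceptance < 0.05 || res$acceptance > 0.7)
      warn <- c(warn, sprintf("chain %d acceptance rate %.3f outside [0.05, 0.7]",
                              ch, res$acceptance))
  }
  for (w in warn) warning(w)
  out <- structure(list(
    samples = do.call(rbind, samples),
    rss = unlist(rss_kept),
    chain = rep(seq_len(schedule$chains), each = keep_per_chain),
    acceptance = acceptance, schedule = schedule, seed = seed,
    model = model, data = data, warnings = warn), class = "mfa_fit")
  colnames(out$samples) <- model$reactions$id
  out
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("Flux posterior fit: ", nrow(x$samples), " retained samples (",
      x$schedule$chains, " chains), median RSS ",
      format(median(x$rss), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mfa_fit <- function(object, probs = c(0.025, 0.975), ...) {
  qs <- t(apply(object$samples, 2L, quantile, probs = probs))
  out <- data.frame(reaction = colnames(object$samples),
                    mean = colMeans(object$samples),
                    sd = apply(object$samples, 2L, sd),
                    qs, check.names = FALSE, row.names = NULL)
  names(out)[4:5] <- paste0("q", probs * 100)
  class(out) <- c("summary.mfa_fit", "data.frame")
  out
}

#' @export
coef.mfa_fit <- function(object, ...) colMeans(object$samples)

#' @export
plot.mfa_fit <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(oldpar))
  graphics::plot(x$rss, type = "l", xlab = "retained sample", ylab = "RSS",
                 main = "RSS trace", ...)
  graphics::boxplot(x$samples[, order(-colMeans(x$samples))[1:min(10, ncol(x$samples))]],
                    las = 2, main = "largest posterior fluxes",
                    ylab = "flux (glucose uptake = 100)")
  invisible(x)
}

#' Simulate MDV sets from the flux posterior
#'
#' Draws `nsim` retained posterior flux vectors and simulates the measured
#' metabolites' MDVs for each tracer experiment — posterior predictive
#' labeling patterns without measurement noise.
#'
#' @param object An `mfa_fit`.
#' @param nsim Number of posterior draws (default 1).
#' @param seed Optional seed for the draw.
#' @param ... Unused.
#' @return List of length `nsim`; each element is a list over experiments of
#'   named MDV lists.
#' @export
simulate.mfa_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$samples), nsim, replace = nsim > nrow(object$samples))
  lapply(idx, function(i) {
    v <- object$samples[i, ]
    lapply(object$data$experiments, function(e)
      simulate_mdv(object$model, v, e$tracer, names(e$mdvs), check = FALSE))
  })
}

#' Residual isotope fractions at the posterior mean flux
#'
#' @param object An `mfa_fit`.
#' @param ... Unused.
#' @return Data frame with `experiment`, `metabolite`, `isotopologue`,
#'   `measured`, `simulated`, `sd` and the standardized `residual`.
#' @export
residuals.mfa_fit <- function(object, ...) {
  v <- coef(object)
  out <- list()
  for (e in seq_along(object$data$experiments)) {
    exp_ <- object$data$experiments[[e]]
    sim <- simulate_mdv(object$model, v, exp_$tracer, names(exp_$mdvs),
                        check = FALSE)
    for (met in names(exp_$mdvs)) {
      meas <- exp_$mdvs[[met]]
      out[[length(out) + 1L]] <- data.frame(
        experiment = e, metabolite = met,
        isotopologue = seq_along(meas) - 1L,
        measured = as.numeric(meas), simulated = as.numeric(sim[[met]]),
        sd = attr(meas, "sd"),
        residual = (as.numeric(sim[[met]]) - as.numeric(meas)) / attr(meas, "sd"))
    }
  }
  do.call(rbind, out)
}

#' Per-sample log10 flux ratios against a reference reaction
#'
#' For each reaction and retained posterior sample, `log10(v / v_ref)` with
#' the reference defaulting to citrate synthase. Nonpositive fluxes are
#' floored at `epsilon` and flagged.
#'
#' @param fit An `mfa_fit`, or a samples matrix (columns = reactions).
#' @param reference Reference reaction id (default `"CS"`).
#' @param epsilon Flux floor (default `1e-6` x the uptake value).
#' @return Matrix of log10 ratios (same shape as the samples matrix, the
#'   reference column dropped is retained as all-zero), with attribute
#'   `n_floored`.
#' @export
flux_ratios <- function(fit, reference = "CS", epsilon = NULL) {
  samples <- if (inherits(fit, "mfa_fit")) fit$samples else as.matrix(fit)
  if (is.null(epsilon)) {
    up <- if (inherits(fit, "mfa_fit")) fit$model$uptake$value else 100
    epsilon <- 1e-6 * up
  }
  if (!reference %in% colnames(samples))
    stop("reference reaction ", reference, " not present in samples")
  ref <- samples[, reference]
  if (mean(ref <= epsilon) > 0.01)
    stop("reference flux ", reference, " is at or below epsilon in more than 1% of samples")
  n_floored <- sum(samples <= epsilon)
  out <- log10(pmax(samples, epsilon) / pmax(ref, epsilon))
  attr(out, "n_floored") <- n_floored
  out
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled SD weighted by
#' `n - 1`. Magnitude labels use the conventional absolute thresholds
#' 0.2 / 0.5 / 0.8 (inclusive).
#'
#' @param a,b Numeric sample sets (e.g. log10 flux-ratio samples of a
#'   treated and a control condition).
#' @return List with `d`, `magnitude` (negligible/small/medium/large) and
#'   `n_a`, `n_b`. Zero pooled SD yields `d = NA` and magnitude
#'   `"undefined"`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both sample sets must be non-empty")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (!is.finite(sp) || sp == 0)
    return(list(d = NA_real_, magnitude = "undefined", n_a = na, n_b = nb))
  d <- (mean(a) - mean(b)) / sp
  list(d = d, magnitude = .d_magnitude(d), n_a = na, n_b = nb)
}

.d_magnitude <- function(d) {
  ad <- abs(d)
  if (is.na(ad)) "undefined"
  else if (ad >= 0.8) "large"
  else if (ad >= 0.5) "medium"
  else if (ad >= 0.2) "small"
  else "negligible"
}

#' Compare flux-ratio posteriors between two conditions
#'
#' Per-reaction Cohen's d between the log10 flux-ratio samples of a treated
#' and a control condition (sign convention: treated minus control).
#' Reactions with `d < -0.8` are flagged as large decreases.
#'
#' @param treated,control Log10 flux-ratio matrices from [flux_ratios()]
#'   with matching columns.
#' @return Data frame with `reaction`, `d`, `magnitude`,
#'   `large_decrease`.
#' @export
compare_flux_ratios <- function(treated, control) {
  stopifnot(identical(colnames(treated), colnames(control)))
  rows <- lapply(colnames(treated), function(rx) {
    cd <- cohens_d(treated[, rx], control[, rx])
    data.frame(reaction = rx, d = cd$d, magnitude = cd$magnitude,
               large_decrease = !is.na(cd$d) && cd$d < -0.8,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
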