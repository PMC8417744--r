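# Metropolis-Hastings flux sampling: schedule bookkeeping, RSS, posterior
# invariants, flux ratios and Cohen's d.

test_that("schedule bookkeeping yields the documented retained counts", {
  full <- full_schedule()
  expect_equal(full$chains, 8L)
  expect_equal(full$steps, 5000000L)
  expect_equal(full$burn_in, 2500000L)
  expect_equal(full$thin, 1000L)
  expect_equal(n_retained(full), 20000L)
  expect_equal(n_retained(mcmc_schedule(8, 5000, 2500, 1)), 20000L)
  expect_equal(n_retained(desk_schedule()), 10000L)
  expect_error(mcmc_schedule(4, 100, 100, 1), "burn_in")
})

test_that("rss matches its definition", {
  meas <- list(A = mdv(c(0.5, 0.5), sd = c(0.1, 0.1)))
  sim_eq <- list(A = mdv(c(0.5, 0.5)))
  expect_equal(rss(sim_eq, meas), 0)
  sim_off <- list(A = mdv(c(0.7, 0.3)))   # both residuals 2 SD -> 4 + 4
  expect_equal(rss(sim_off, meas), 8)
  meas2 <- c(meas, list(B = mdv(c(0.6, 0.4), sd = c(0.1, 0.1))))
  sim2 <- c(sim_off, list(B = mdv(c(0.65, 0.35))))  # adds 0.5 SD^2 twice
  expect_equal(rss(sim2, meas2), 8 + 0.25 + 0.25)
  meas_zero <- list(A = mdv(c(0.5, 0.5), sd = c(0, 0.1)))
  expect_error(rss(sim_eq, meas_zero), "zero SD")
  expect_error(rss(list(B = mdv(c(1, 0))), meas), "no simulated MDV")
})

test_that("a reduced run retains exactly the scheduled number of samples", {
  m <- toy_model("branched")
  iv <- interior_flux(m)
  gt <- gen_tracer_dataset(m, iv$v, tracer_spec("GLC_x", 1:2, 1),
                           targets = c("PYR", "LAC", "OAA"), seed = 2)
  sch <- mcmc_schedule(8, 5000, 2500, 1)
  fit <- suppressWarnings(mfa_fit(m, gt$data, schedule = sch, seed = 4))
  expect_equal(nrow(fit$samples), 20000L)
  expect_equal(nrow(fit$samples), n_retained(sch))
  expect_equal(as.vector(table(fit$chain)), rep(2500L, 8L))
})

test_that("every retained sample satisfies steady state and bounds", {
  m <- toy_model("branched")
  iv <- interior_flux(m)
  gt <- gen_tracer_dataset(m, iv$v, tracer_spec("GLC_x", 1:2, 1),
                           targets = c("PYR", "LAC", "OAA"), seed = 5)
  fit <- suppressWarnings(
    mfa_fit(m, gt$data, schedule = mcmc_schedule(2, 4000, 2000, 2), seed = 9))
  S_dev <- apply(fit$samples, 1L, function(v) max(abs(m$S %*% v)))
  expect_lt(max(S_dev), 1e-9 * 100)
  tol <- 1e-5
  expect_true(all(t(fit$samples) >= m$reactions$lb - tol))
  expect_true(all(t(fit$samples) <= m$reactions$ub + tol))
  expect_equal(unname(fit$samples[, "GLCup"]), rep(100, nrow(fit$samples)),
               tolerance = 1e-9)
})

test_that("identical fits are reproducible for a fixed seed", {
  m <- toy_model("branched")
  iv <- interior_flux(m)
  gt <- gen_tracer_dataset(m, iv$v, tracer_spec("GLC_x", 1:2, 1),
                           targets = c("PYR", "LAC", "OAA"), seed = 2)
  sch <- mcmc_schedule(2, 2000, 1000, 5)
  f1 <- suppressWarnings(mfa_fit(m, gt$data, schedule = sch, seed = 11))
  f2 <- suppressWarnings(mfa_fit(m, gt$data, schedule = sch, seed = 11))
  expect_identical(f1$samples, f2$samples)
})

test_that("with flat data the chain samples the bounded polytope stably", {
  m <- toy_model("branched")
  iv <- interior_flux(m)
  sim <- simulate_mdv(m, iv$v, tracer_spec("GLC_x", 1:2, 1),
                      targets = c("PYR", "OAA"))
  flat <- measured_mdv_set(list(list(
    tracer = tracer_spec("GLC_x", 1:2, 1),
    mdvs = lapply(sim, function(x) mdv(unclass(x), sd = rep(1e3, length(x)))))),
    sd_floor = NULL)
  fits <- lapply(c(21, 22), function(s)
    suppressWarnings(mfa_fit(m, flat, mcmc_schedule(2, 30000, 10000, 10),
                             seed = s, init_optim = FALSE)))
  mu <- sapply(fits, function(f) colMeans(f$samples))
  spread <- sapply(fits, function(f) apply(f$samples, 2, sd))
  # marginal means agree across seeds within Monte-Carlo error
  expect_lt(max(abs(mu[, 1] - mu[, 2]) / pmax(spread[, 1], 1e-6)), 0.35)
})

test_that("flux ratios against citrate synthase behave as log10 ratios", {
  samples <- cbind(CS = c(10, 20), RXA = c(10, 20), RXB = c(100, 200),
                   RXZ = c(0, 0))
  fr <- flux_ratios(samples, reference = "CS", epsilon = 1e-4)
  expect_equal(unname(fr[, "RXA"]), c(0, 0))
  expect_equal(unname(fr[, "RXB"]), c(1, 1))
  expect_equal(attr(fr, "n_floored"), 2L)
  # doubling both fluxes leaves the ratio unchanged
  fr2 <- flux_ratios(2 * samples[, 1:3], reference = "CS", epsilon = 1e-4)
  expect_equal(fr2[, "RXB"], fr[, "RXB"])
  bad <- cbind(CS = c(0, 0, 1), RX = c(1, 1, 1))
  expect_error(flux_ratios(bad, reference = "CS", epsilon = 1e-4), "1%")
})

test_that("cohens_d magnitudes, inclusive thresholds and antisymmetry", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$magnitude, "negligible")
  set.seed(13)
  a <- rnorm(500, 1, 1); b <- rnorm(500, 0, 1)
  cd <- cohens_d(a, b)
  expect_equal(cd$d, 1, tolerance = 0.15)
  expect_equal(cd$magnitude, "large")
  # exact threshold |d| = 0.8 labels large (inclusive)
  x <- c(-1, 0, 1); y <- x + 0.8
  expect_equal(cohens_d(y, x)$d, 0.8)
  expect_equal(cohens_d(y, x)$magnitude, "large")
  expect_equal(cohens_d(x + 0.5, x)$magnitude, "medium")
  expect_equal(cohens_d(x + 0.25, x)$magnitude, "small")
  # antisymmetry
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  # degenerate: zero pooled SD
  expect_equal(cohens_d(c(1, 1), c(2, 2))$magnitude, "undefined")
})

test_that("condition comparison flags large decreases", {
  set.seed(14)
  treated <- cbind(A = rnorm(400, -1, 0.5), B = rnorm(400, 0, 0.5))
  control <- cbind(A = rnorm(400, 0, 0.5), B = rnorm(400, 0, 0.5))
  cmp <- compare_flux_ratios(treated, control)
  expect_true(cmp$large_decrease[cmp$reaction == "A"])
  expect_false(cmp$large_decrease[cmp$reaction == "B"])
  expect_equal(cmp$magnitude[cmp$reaction == "A"], "large")
})
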