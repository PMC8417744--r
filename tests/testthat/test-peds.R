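# PEDS: preprocessing, PCA score summaries, the synergy statistic and its
# invariances, and recovery of planted combination effects.

scores_from_centroids <- function(centroids, gamma) {
  structure(list(scores = NULL, gamma = gamma, centroids = centroids,
                 loadings = NULL, group = NULL), class = "pca_scores")
}

test_that("preprocessing centers features and removes global scaling", {
  m <- matrix(5, 8, 10, dimnames = list(NULL, paste0("F", 1:10)))
  g <- rep(c("ctrl", "drug1", "drug2", "comb"), each = 2)
  pm <- preprocess_profiles(m, group = g)
  expect_equal(max(abs(pm)), 0)                       # all-equal -> all-zero
  set.seed(4)
  m2 <- matrix(exp(rnorm(80, 8, 1)), 8, 10)
  pm1 <- preprocess_profiles(m2, group = g, offset = 0)
  pm2 <- preprocess_profiles(2 * m2, group = g, offset = 0)
  expect_equal(unclass(pm1), unclass(pm2), tolerance = 1e-12,
               ignore_attr = TRUE)                    # doubling removed
  expect_lt(max(abs(colMeans(pm1))), 1e-9)            # centering contract
  expect_error(preprocess_profiles(m2, group = rep("ctrl", 8)), "missing")
})

test_that("fit_pca satisfies the SVD identities", {
  set.seed(8)
  g <- rep(c("ctrl", "drug1", "drug2", "comb"), each = 3)
  m <- matrix(exp(rnorm(12 * 20, 8, 0.5)), 12, 20)
  m[g == "drug1", 1:5] <- m[g == "drug1", 1:5] * 3
  pm <- preprocess_profiles(m, group = g)
  ps <- fit_pca(pm)
  expect_equal(sum(ps$gamma), 1, tolerance = 1e-9)
  recon <- ps$scores %*% t(ps$loadings)
  expect_lt(max(abs(recon - unclass(pm))), 1e-8)
  # duplicated replicates: the centroid equals the replicate score
  m2 <- m; m2[2, ] <- m2[1, ]; m2[3, ] <- m2[1, ]
  ps2 <- fit_pca(preprocess_profiles(m2, group = g))
  expect_equal(ps2$centroids["ctrl", ], ps2$scores[1, ], tolerance = 1e-8)
  expect_error(fit_pca(preprocess_profiles(matrix(1, 8, 4),
                                           group = rep(c("ctrl", "drug1",
                                                         "drug2", "comb"),
                                                       each = 2))),
               "rank-0")
})

test_that("peds identities: zero, additive boundary, scalar case", {
  cent <- rbind(ctrl = c(0, 0), drug1 = c(1, 0), drug2 = c(0, 1),
                comb = c(0, 0))
  expect_equal(peds(scores_from_centroids(cent, c(0.6, 0.4)))$value, 0)
  cent["comb", ] <- c(0.5, 0.5)   # midpoint of summed displacements
  expect_equal(peds(scores_from_centroids(cent, c(0.6, 0.4)))$value, 1)
  cent1 <- rbind(ctrl = 0, drug1 = 1, drug2 = 1, comb = 3)
  p <- peds(scores_from_centroids(cent1, 1))
  expect_equal(p$value, 3)
  expect_true(p$synergistic)
  # alternative denominator without the 1/2
  expect_equal(peds(scores_from_centroids(cent1, 1), denominator = "sum")$value,
               1.5)
  cent0 <- rbind(ctrl = c(0, 0), drug1 = c(0, 0), drug2 = c(0, 0),
                 comb = c(1, 0))
  expect_error(peds(scores_from_centroids(cent0, c(0.5, 0.5))), "undefined")
})

test_that("peds invariances: drug relabeling and displacement scaling", {
  set.seed(12)
  for (i in 1:20) {
    cent <- matrix(rnorm(8), 4, 2,
                   dimnames = list(c("ctrl", "drug1", "drug2", "comb"), NULL))
    gam <- runif(2); gam <- gam / sum(gam)
    v1 <- peds(scores_from_centroids(cent, gam))$value
    swapped <- cent[c("ctrl", "drug2", "drug1", "comb"), ]
    rownames(swapped) <- c("ctrl", "drug1", "drug2", "comb")
    expect_equal(peds(scores_from_centroids(swapped, gam))$value, v1)
    scaled <- cent
    c0 <- cent["ctrl", ]
    for (r in rownames(scaled)) scaled[r, ] <- c0 + 3.7 * (cent[r, ] - c0)
    expect_equal(peds(scores_from_centroids(scaled, gam))$value, v1)
  }
})

test_that("planted alpha is recovered as noise vanishes", {
  for (alpha in c(0.5, 1, 2)) {
    gen <- gen_feature_table(omics_spec(n_features = 40, alpha = alpha,
                                        noise_sd = 1e-4, n_blanks = 0),
                             seed = 31)
    ps <- fit_pca(preprocess_profiles(gen$table, offset = 0))
    expect_equal(peds(ps)$value, alpha, tolerance = 0.02)
  }
})

test_that("planted super-additive displacement scores PEDS > 1 across seeds", {
  vals <- vapply(1:100, function(s) {
    gen <- gen_feature_table(omics_spec(n_features = 30, alpha = 2,
                                        noise_sd = 0.1, n_blanks = 0),
                             seed = s)
    peds(fit_pca(preprocess_profiles(gen$table, offset = 0)))$value
  }, numeric(1))
  expect_gte(mean(vals > 1), 0.95)
  expect_equal(mean(vals), 2, tolerance = 0.1)
})

test_that("peds_screen ranks deterministically", {
  gen_add <- gen_feature_table(omics_spec(n_features = 30, alpha = 1,
                                          noise_sd = 1e-4, n_blanks = 0),
                               seed = 5)
  gen_syn <- gen_feature_table(omics_spec(n_features = 30, alpha = 3,
                                          noise_sd = 1e-4, n_blanks = 0),
                               seed = 5)
  out <- peds_screen(list(additive = gen_add$table, planted = gen_syn$table))
  expect_equal(out$combination, c("planted", "additive"))
  expect_equal(out$peds, c(3, 1), tolerance = 0.02)
  out2 <- peds_screen(list(additive = gen_add$table, planted = gen_syn$table))
  expect_identical(out, out2)
})
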