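# DIMS feature processing: ppm annotation, the cleaning cascade,
# random-forest imputation, and probabilistic quotient normalization.

test_that("annotation window in ppm is inclusive and signed", {
  db <- data.frame(name = "Glutamine", formula = "C5H10N2O3")
  peak <- function(mz) data.frame(mz = mz, intensity = 1e5,
                                  polarity = "positive")
  hit <- annotate_features(peak(147.0770), db)
  expect_equal(nrow(hit), 1L)
  # (147.0770 - 147.07641866) / 147.07641866 * 1e6, inside the 5 ppm window
  expect_equal(hit$ppm_error, 3.9527, tolerance = 1e-4)
  exact <- annotate_features(peak(147.0764186557), db)
  expect_equal(exact$ppm_error, 0, tolerance = 1e-6)
  far <- annotate_features(peak(147.0790), db)   # ~ +17.7 ppm
  expect_equal(nrow(far), 0L)
  # window 0 keeps only the exact theoretical mass
  expect_equal(nrow(annotate_features(peak(147.0770), db, window_ppm = 0)), 0L)
  th <- adduct_mz("C5H10N2O3", "[M+H]+")
  expect_equal(nrow(annotate_features(peak(th), db, window_ppm = 0)), 1L)
})

test_that("isobaric database entries are all retained and flagged ambiguous", {
  db <- data.frame(name = c("Citrate", "Isocitrate"),
                   formula = c("C6H8O7", "C6H8O7"))
  hits <- annotate_features(data.frame(mz = 191.0197, intensity = 1,
                                       polarity = "negative"), db)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$ambiguous))
  expect_error(annotate_features(data.frame(mz = 100, intensity = 1,
                                            polarity = "positive"),
                                 data.frame(name = "bad", formula = "Qq3")),
               "bad")
})

make_ft <- function(mat, groups) feature_table(mat, groups)

test_that("replicate filter keeps features seen in >= 4 of 5 replicates of a group", {
  groups <- c(rep("ctrl", 5), rep("comb", 5), rep("blank", 2))
  m <- matrix(100, 3, 12, dimnames = list(c("in_comb", "nowhere", "in_ctrl"), NULL))
  m["in_comb", 1:5] <- NA; m["in_comb", 6] <- NA        # 4/5 in comb only
  m["nowhere", c(1, 2, 6, 7)] <- NA                     # 3/5 everywhere
  ft <- replicate_filter(make_ft(m, groups))
  expect_setequal(rownames(ft$intensity), c("in_comb", "in_ctrl"))
  # undersized group is skipped with a warning
  g2 <- c(rep("ctrl", 2), rep("comb", 5))
  m2 <- matrix(1, 1, 7)
  expect_warning(replicate_filter(make_ft(m2, g2)), "ctrl")
})

test_that("blank filter applies strict SNR > 3 and keeps zero-blank features", {
  groups <- c(rep("ctrl", 4), rep("blank", 2))
  m <- rbind(kept = c(rep(400, 4), 100, 100),
             removed = c(rep(200, 4), 100, 100),
             boundary = c(rep(300, 4), 100, 100),   # ratio exactly 3: removed
             zeroblank = c(rep(50, 4), 0, 0),
             nablank = c(rep(50, 4), NA, NA))
  ft <- blank_filter(make_ft(m, groups))
  expect_setequal(rownames(ft$intensity), c("kept", "zeroblank", "nablank"))
  expect_error(blank_filter(make_ft(m[, 1:4], groups[1:4])), "blank")
})

test_that("sample filter requires detection in strictly more than half", {
  groups <- c(rep("ctrl", 5), rep("comb", 5), rep("blank", 2))
  m <- rbind(six = c(rep(1, 6), rep(NA, 4), 1, 1),    # 6/10 non-blank
             five = c(rep(1, 5), rep(NA, 5), 1, 1),   # 5/10: removed
             all = rep(1, 12))
  ft <- sample_filter(make_ft(m, groups))
  expect_setequal(rownames(ft$intensity), c("six", "all"))
})

test_that("random-forest imputation honours its contracts", {
  set.seed(99)
  n <- 20
  base <- matrix(exp(rnorm(8 * n, 8, 1)), 8, n)
  rownames(base) <- paste0("F", 1:8)
  base[2, ] <- 7.0                      # constant feature
  groups <- rep(c("ctrl", "drug1", "drug2", "comb"), each = 5)

  ft_complete <- make_ft(base, groups)
  out <- impute_missing(ft_complete, seed = 1)
  expect_identical(out$intensity, ft_complete$intensity)   # identity on complete

  m <- base
  m[2, 4] <- NA                          # one hole in the constant feature
  m[5, c(2, 9)] <- NA
  ft <- make_ft(m, groups)
  imp <- impute_missing(ft, seed = 1)
  expect_false(anyNA(imp$intensity))
  expect_equal(imp$intensity[2, 4], 7.0, tolerance = 1e-6)
  obs <- !is.na(m)
  expect_identical(imp$intensity[obs], m[obs])             # observed untouched
  imp2 <- impute_missing(ft, seed = 1)
  expect_identical(imp$intensity, imp2$intensity)          # deterministic
  rep <- attr(imp, "imputation_report")
  expect_equal(rep$n_imputed, 3L)
  expect_equal(rep$ntree, 100L)
})

test_that("PQN recovers constructed dilution factors exactly", {
  set.seed(3)
  ref <- exp(rnorm(30, 8, 1))
  dil <- c(1, 2, 0.5, 1.3, 1, 0.8)
  m <- sapply(dil, function(f) ref * f)
  rownames(m) <- paste0("F", 1:30)
  ft <- make_ft(m, c("ctrl", "ctrl", "drug1", "drug1", "qc", "qc"))
  out <- pqn_normalize(ft)
  expect_equal(unname(attr(out, "pqn_factors")), dil)
  for (s in seq_along(dil)) expect_equal(unname(out$intensity[, s]), ref)
  # identity: a sample equal to the reference is unchanged
  expect_equal(out$intensity[, 1], m[, 1], ignore_attr = TRUE)
  # within-sample ratios preserved
  raw_ratio <- unname(m[1, 2] / m[5, 2])
  expect_equal(unname(out$intensity[1, 2] / out$intensity[5, 2]), raw_ratio)
  # permutation invariance of the feature order
  perm <- sample(30)
  ft_p <- make_ft(m[perm, ], c("ctrl", "ctrl", "drug1", "drug1", "qc", "qc"))
  out_p <- pqn_normalize(ft_p)
  expect_equal(out_p$intensity, out$intensity[perm, ])
})

test_that("pqn qc reference and failure modes", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("F", 1:3), NULL))
  ft <- make_ft(m, c("ctrl", "ctrl", "qc", "qc"))
  out <- pqn_normalize(ft, reference = "qc_median")
  expect_equal(dim(out$intensity), dim(m))
  ft2 <- make_ft(matrix(c(1, NA, NA, 2, 2, 2), 3, 2,
                        dimnames = list(paste0("F", 1:3), NULL)),
                 c("ctrl", "ctrl"))
  expect_error(pqn_normalize(ft2), "fewer than 3")
})

test_that("cleaning cascade removes exactly the planted features and is idempotent", {
  spec <- omics_spec(n_features = 30, noise_sd = 0.1, missing_rate = 0.05,
                     n_blank_features = 4, n_lowrep_features = 3)
  gen <- gen_feature_table(spec, seed = 21)
  cleaned <- suppressWarnings(clean_features(gen$table, seed = 2))
  removed <- setdiff(rownames(gen$table$intensity), rownames(cleaned$intensity))
  expect_setequal(removed, c(gen$truth$blank_features, gen$truth$lowrep_features))
  expect_false(anyNA(cleaned$intensity))
  # applying the cascade to its own output changes nothing
  twice <- suppressWarnings(clean_features(cleaned, seed = 2))
  expect_equal(twice$intensity, cleaned$intensity)
})
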