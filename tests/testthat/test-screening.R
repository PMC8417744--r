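# Relative viability, Bliss indices, dose-series scoring and hit selection.

make_records <- function(df) {
  # df: cell_line, drug_id, partner_conc, signals (list)
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    sig <- df$signals[[i]]
    data.frame(plate_id = "P1", well_id = paste0("W", i),
               cell_line = df$cell_line[i], drug_id = df$drug_id[i],
               drug_conc = ifelse(df$drug_id[i] == "DMSO", 0, 100),
               partner_conc = df$partner_conc[i], oxygen = "hypoxia",
               replicate = seq_along(sig), signal = sig)
  }))
}

test_that("relative viability is mean signal over mean control signal", {
  rec <- make_records(data.frame(
    cell_line = "OCI-AML3",
    drug_id = c("DMSO", "D1", "D2", "D3"),
    partner_conc = 0,
    signals = I(list(c(10000, 10000, 10000, 10000),
                     c(5000, 5000, 5000, 5000),
                     c(10000, 10000, 10000, 10000),
                     c(11010, 11010, 11010, 11010)))))
  vt <- relative_viability(rec)
  v <- function(d) vt$relative_viability[vt$drug_id == d]
  expect_equal(v("DMSO"), 1)           # control maps to exactly 1
  expect_equal(v("D1"), 0.5)
  expect_equal(v("D2"), 1)
  expect_equal(v("D3"), 1.101)         # uncapped, preserved above 1
})

test_that("Dixon filtering removes a planted outlier before averaging", {
  rec <- make_records(data.frame(
    cell_line = "A", drug_id = c("DMSO", "D1"), partner_conc = 0,
    signals = I(list(rep(10000, 4), c(5000, 5100, 5200, 25000)))))
  vt <- relative_viability(rec)
  expect_equal(vt$n_replicates_used[vt$drug_id == "D1"], 3L)
  expect_equal(vt$relative_viability[vt$drug_id == "D1"], 0.51)
  vt2 <- relative_viability(rec, dixon = FALSE)
  expect_equal(vt2$n_replicates_used[vt2$drug_id == "D1"], 4L)
})

test_that("relative viability error conditions", {
  rec <- make_records(data.frame(
    cell_line = "A", drug_id = "D1", partner_conc = 0,
    signals = I(list(rep(100, 4)))))
  expect_error(relative_viability(rec), "control")
  rec0 <- make_records(data.frame(
    cell_line = "A", drug_id = c("DMSO", "D1"), partner_conc = 0,
    signals = I(list(rep(0, 4), rep(100, 4)))))
  expect_error(relative_viability(rec0), "zero control mean")
})

test_that("bliss_index matches its definition and validates input", {
  expect_equal(bliss_index(0.5, 0.5, 0.25), 0)
  expect_equal(bliss_index(1, 1, 1), 0)
  expect_error(bliss_index(-0.1, 0.5, 0.5), "non-negative")
  expect_error(bliss_index(Inf, 0.5, 0.5), "finite")
  # reported AC220 hypoxia row: least-squares partner viability over the
  # other screen rows reproduces the printed index 0.134 within 0.005
  scr <- primary_screen_table()
  i <- which(scr$drug_id == "S1526")
  vhat <- partner_viability_ls(scr$hypoxia_alone[-i], scr$hypoxia_combo[-i],
                               scr$hypoxia_bliss[-i])
  expect_equal(bliss_index(1.101, vhat, 0.855), 0.134, tolerance = 0.005 / 0.134)
})

test_that("bliss additivity holds for any viability pair (property)", {
  set.seed(7)
  va <- runif(200, 0, 1.3); vb <- runif(200, 0, 1.3)
  expect_equal(bliss_index(va, vb, va * vb), rep(0, 200))
})

test_that("screen-wide reconstruction reproduces every printed Bliss index", {
  for (cond in c("hypoxia", "normoxia")) {
    rec <- reconstruct_bliss(condition = cond)
    expect_lt(max(abs(rec$reconstructed_bliss - rec$reported_bliss)), 0.006)
  }
})

test_that("dose-series Bliss over the geometric grid", {
  grid <- bliss_dose_grid()
  expect_length(grid, 9L)
  expect_equal(grid[1], 0.0128)
  expect_equal(grid[9], 5000)          # 0.0128 * 5^8
  drug <- data.frame(conc = grid, viability = 0.8)
  combo <- data.frame(conc = grid, viability = 0.72)
  res <- dose_series_bliss(drug, combo, v_partner = 0.9)
  expect_equal(res$bliss_index, rep(0, 9))
  combo$viability[5] <- 0.60
  res <- dose_series_bliss(drug, combo, v_partner = 0.9)
  expect_equal(res$bliss_index[5], 0.12)
  expect_equal(res$bliss_index[-5], rep(0, 8))
  expect_error(dose_series_bliss(drug[-1, ], combo, 0.9), "grid")
})

make_hit_tables <- function(n_hyp = 19, n_norm = 5, n_both = 3) {
  # drugs hit under hypoxia only, normoxia only, both, neither
  drugs <- paste0("D", 1:25)
  hyp_hits <- drugs[1:n_hyp]
  norm_hits <- c(drugs[1:n_both], drugs[(n_hyp + 1):(n_hyp + n_norm - n_both)])
  leuk <- do.call(rbind, lapply(drugs, function(d) {
    do.call(rbind, lapply(c("hypoxia", "normoxia"), function(ox) {
      hit <- (ox == "hypoxia" && d %in% hyp_hits) ||
             (ox == "normoxia" && d %in% norm_hits)
      data.frame(drug_id = d, cell_line = "OCI-AML3", oxygen = ox,
                 v_without = 0.9, v_with = 0.8,
                 bliss_index = if (hit) 0.15 else 0.02)
    }))
  }))
  stromal <- do.call(rbind, lapply(drugs, function(d)
    do.call(rbind, lapply(c("hypoxia", "normoxia"), function(ox)
      data.frame(drug_id = d, cell_line = c("HS-5", "HS-27A", "MSC"),
                 oxygen = ox, v_without = 0.95, v_with = 0.92)))))
  list(leukemia = leuk, stromal = stromal)
}

test_that("hit-set union across oxygen conditions: 19 + 5 - 3 = 21", {
  tabs <- make_hit_tables()
  rep <- select_hits(tabs$leukemia, tabs$stromal)
  expect_length(rep$by_oxygen$hypoxia, 19L)
  expect_length(rep$by_oxygen$normoxia, 5L)
  expect_length(intersect(rep$by_oxygen$hypoxia, rep$by_oxygen$normoxia), 3L)
  expect_length(rep$hits, 21L)
})

test_that("both criteria and the audit trail behave as specified", {
  leuk <- data.frame(drug_id = c("A", "B", "C"), cell_line = "L",
                     oxygen = "hypoxia",
                     v_without = c(0.9, 0.4, 0.9),
                     v_with = c(0.8, 0.45, 0.8),
                     bliss_index = c(0.134, 0.02, 0.05))
  stromal <- data.frame(drug_id = rep(c("A", "B", "C"), each = 2),
                        cell_line = rep(c("S1", "S2"), 3), oxygen = "hypoxia",
                        v_without = c(0.95, 0.93, 0.9, 0.9, 0.9, 0.7),
                        v_with = c(0.95, 0.93, 0.9, 0.9, 0.9, 0.9))
  rep <- select_hits(leuk, stromal)
  audit <- rep$audit
  expect_equal(audit$clause[audit$drug_id == "A"], "bliss")
  expect_equal(audit$clause[audit$drug_id == "B"], "kill")
  # C: one stromal line at 0.7 violates criterion 1 regardless of Bliss
  expect_equal(audit$clause[audit$drug_id == "C"], "stromal_fail")
  expect_setequal(rep$hits, c("A", "B"))
  # kill clause is conjunctive: failing one arm disqualifies
  leuk$v_with[2] <- 0.6
  expect_false("B" %in% select_hits(leuk, stromal)$hits)
})

test_that("raising the Bliss threshold never adds a hit (monotonicity)", {
  tabs <- make_hit_tables()
  set.seed(1)
  tabs$leukemia$bliss_index <- runif(nrow(tabs$leukemia), -0.1, 0.3)
  prev <- NULL
  for (thr in c(0.05, 0.1, 0.15, 0.2, 0.25)) {
    hits <- select_hits(tabs$leukemia, tabs$stromal,
                        hit_criteria(leukemia_bliss_threshold = thr))$hits
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
  }
})

test_that("missing arms and malformed criteria are rejected", {
  tabs <- make_hit_tables(3, 2, 1)
  leuk <- tabs$leukemia
  leuk$v_with[leuk$drug_id == "D1"] <- NA
  expect_error(select_hits(leuk, tabs$stromal), "D1")
  expect_error(hit_criteria(stromal_min_viability = 2), "0, 1.5")
  expect_error(hit_criteria(leukemia_bliss_threshold = NA), "finite")
})
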