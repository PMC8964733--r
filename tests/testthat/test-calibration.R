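# build a synthetic candidate list for cascade tests
fake_candidate <- function(combo, rm, aicc, auc, k = 3, failed = FALSE) {
  structure(list(combo = combo, rm = rm, aicc = aicc, mean_test_auc = auc,
                 k_nonzero = k, failed = failed),
            class = "candidate_model")
}

test_that("eligibility applies the record, cell and native-extent bounds", {
  g <- tiny_grid(10, 8)
  native9 <- make_native_region(g, 1, blob_cells = list(c(3, 3)), seed = 1)
  native8 <- make_native_region(g, 1, blob_cells = list(c(4, 2)), seed = 1,
                                min_cells = 1)
  cells9 <- mask_cells(native9)
  raw <- filter_records(records_at_cells(g, cells9[c(1, 1, 2, 2, 3)], 2001:2005),
                        native9)
  e <- eligibility(raw, native9)
  expect_true(e$model_1_ok)
  # 5 records in one cell fail the cell condition
  raw1 <- filter_records(records_at_cells(g, rep(cells9[1], 5), 2001:2005),
                         native9)
  expect_false(eligibility(raw1, native9)$model_1_ok)
  # a native region of 8 cells is ineligible regardless of records
  cells8 <- mask_cells(native8)
  raw8 <- filter_records(records_at_cells(g, cells8[1:8], 2001:2008), native8)
  expect_false(eligibility(raw8, native8)$model_1_ok)
  # filtered data types need at least 3 points
  first_two_cells <- !duplicated(raw$records$cell) &
    raw$records$cell %in% raw$records$cell[1:3]
  thin2 <- occurrence_set(
    "thinned",
    raw$records[which(first_two_cells)[1:2], c("lon", "lat", "year")], g)
  expect_false(eligibility(raw, native9, thin2)$model_3_ok)
})

test_that("partitioning switches from jackknife to blocks at 25 points", {
  set.seed(4)
  pts24 <- data.frame(lon = runif(24, 0, 5), lat = runif(24, 0, 4))
  s24 <- partition(pts24)
  expect_equal(s24$method, "jackknife")
  expect_equal(s24$k, 24)
  expect_equal(sort(unique(s24$fold)), 1:24)
  pts25 <- rbind(pts24, data.frame(lon = 2.5, lat = 2))
  s25 <- partition(pts25)
  expect_equal(s25$method, "block")
  expect_equal(s25$k, 4)
  expect_error(partition(pts24[1, , drop = FALSE]), "at least 2")
})

test_that("block partitioning on a uniform grid yields equal quadrants", {
  pts <- expand.grid(lon = seq(0.25, 3.25, length.out = 7),
                     lat = seq(0.25, 1.75, length.out = 4))
  expect_equal(nrow(pts), 28)
  s <- partition(pts)
  expect_equal(as.integer(sort(table(s$fold))), c(7L, 7L, 7L, 7L))
  # for tie-free point sets the background assignment along the stored
  # split lines reproduces the point folds
  set.seed(8)
  ptsr <- data.frame(lon = runif(32, 0, 6), lat = runif(32, 0, 4))
  sr <- partition(ptsr)
  expect_equal(assign_background(sr, ptsr$lon, ptsr$lat), sr$fold)
  # fold sizes never differ by more than 2
  for (n in c(25, 27, 31, 40)) {
    set.seed(n)
    p <- data.frame(lon = runif(n, 0, 6), lat = runif(n, 0, 4))
    sz <- table(partition(p)$fold)
    expect_lte(max(sz) - min(sz), 2)
  }
})

test_that("jackknife cross-validation runs one fold per point", {
  w <- make_world(tiny_grid(15, 12), seed = 23)
  occ <- simulate_species(w, 5, seed = 2)
  raw <- filter_records(occ, w$native)
  fe <- build_features(w$env, w$native, c("BIO1", "BIO2"), "lq")
  scheme <- partition(raw$records)
  expect_equal(scheme$method, "jackknife")
  cand <- crossvalidate(raw$records, fe, rm = 1, scheme)
  expect_false(cand$failed)
  expect_equal(cand$k_folds, nrow(raw$records))
  expect_equal(cand$n_folds_used, nrow(raw$records))
  # degree of overfit is exactly the difference of the mean AUCs
  expect_equal(cand$doo, cand$mean_train_auc - cand$mean_test_auc)
})

test_that("the AICc cascade falls back to testing AUC exactly when specified", {
  # unique finite minimum: AICc decides
  cands <- list(fake_candidate("l", 1, 100, 0.70),
                fake_candidate("lq", 1, 90, 0.60),
                fake_candidate("h", 1, 95, 0.65))
  pick <- cascade_pick(cands)
  expect_equal(pick$best, 2)
  expect_equal(pick$criterion, "aicc")
  # >= 50% unavailable: AUC decides (3 of 6 missing)
  cands6 <- list(fake_candidate("l", 1, NA, 0.70),
                 fake_candidate("lq", 1, NA, 0.72),
                 fake_candidate("h", 1, NA, 0.90),
                 fake_candidate("lqh", 1, 80, 0.60),
                 fake_candidate("lqhp", 1, 70, 0.65),
                 fake_candidate("lqhpt", 1, 75, 0.64))
  pick6 <- cascade_pick(cands6)
  expect_equal(pick6$criterion, "test_auc")
  expect_equal(pick6$best, 3)
  # tied minimum (within 1e-9): no unique winner, AUC decides
  tied <- list(fake_candidate("l", 1, 50, 0.70),
               fake_candidate("lq", 1, 50 + 1e-12, 0.80),
               fake_candidate("h", 1, 60, 0.75))
  pickt <- cascade_pick(tied)
  expect_equal(pickt$criterion, "test_auc")
  expect_equal(pickt$best, 2)
  # under 50% missing with a unique minimum: still AICc
  cands5 <- list(fake_candidate("l", 1, NA, 0.9),
                 fake_candidate("lq", 1, 40, 0.5),
                 fake_candidate("h", 1, 45, 0.6))
  expect_equal(cascade_pick(cands5)$criterion, "aicc")
  expect_equal(cascade_pick(cands5)$best, 2)
  # failed candidates never win
  cands_f <- list(fake_candidate("l", 1, 10, 0.99, failed = TRUE),
                  fake_candidate("lq", 1, 90, 0.60))
  expect_equal(cascade_pick(cands_f)$best, 2)
})

test_that("variable selection prunes correlated variables by importance", {
  g <- tiny_grid(20, 15)
  w <- make_world(g, n_climate = 3, n_landcover = 0, n_active = 1, seed = 29)
  # duplicate the informative variable: rho = 1 pair
  env <- w$env
  env$layers$BIO1_copy <- env$layers$BIO1
  env <- env_stack(g, env$layers)
  occ <- simulate_species(w, 40, seed = 3)
  raw <- filter_records(occ, w$native)
  vs <- select_variables(raw, w$native, env, n_knots = 5, seed = 1)
  expect_equal(vs$n_models, 6)
  sel <- vs$selected
  expect_false(all(c("BIO1", "BIO1_copy") %in% sel))
  expect_true(any(c("BIO1", "BIO1_copy") %in% sel))
  # the kept member of the tied pair is the more important one
  pair_imp <- vs$importance[c("BIO1", "BIO1_copy")]
  expect_true(names(which.max(pair_imp)) %in% sel)
  # output is always pairwise uncorrelated below the bound
  if (length(sel) > 1) {
    rho <- vs$rho[sel, sel]
    expect_true(all(abs(rho[upper.tri(rho)]) < 0.7))
  }
})

test_that("uncorrelated variables all survive pruning", {
  g <- tiny_grid(12, 10, cell_size = 1, lon_min = 0, lat_min = 0)
  set.seed(7)
  # independent noise layers: pairwise correlations near zero
  env <- env_stack(g, list(BIO1 = matrix(rnorm(120), 10),
                           BIO2 = matrix(rnorm(120), 10),
                           BIO3 = matrix(rnorm(120), 10)))
  native <- full_mask(g)
  w <- list(env = env, native = native,
            true_suitability = plogis(2 * env$layers$BIO1),
            bias_layer = matrix(1, 10, 12))
  class(w) <- "synthetic_world"
  occ <- simulate_species(w, 40, seed = 4)
  raw <- filter_records(occ, native)
  vs <- select_variables(raw, native, env, n_knots = 5, seed = 2)
  expect_setequal(vs$selected, c("BIO1", "BIO2", "BIO3"))
})

test_that("the harmonic-mean winner follows the documented arithmetic", {
  hm <- function(a, b) 2 * a * b / (a + b)
  expect_equal(hm(0.9, 0.5), 0.642857142857, tolerance = 1e-9)
  expect_equal(hm(0.8, 0.7), 0.746666666667, tolerance = 1e-9)
  expect_gt(hm(0.8, 0.7), hm(0.9, 0.5))
})

test_that("the candidate grid enumerates 30 models per eligible data type", {
  w <- eligible_world(seed = 7, n_cols = 25, n_rows = 25)
  occ <- simulate_species(w, 40, seed = 3)
  raw <- filter_records(occ, w$native)
  pres <- to_presence_cells(raw)
  thinned <- thin(pres, seed = 5)
  vs_vars <- c("BIO1", "BIO2")
  sel <- run_candidate_grid(raw, pres, thinned, w$native, w$env, vs_vars,
                            n_knots = 5)
  n_types <- sum(c(TRUE, isTRUE(sel$eligibility$model_2_ok),
                   isTRUE(sel$eligibility$model_3_ok)))
  expect_equal(sel$n_grid_models, 30 * n_types)
  for (ty in names(sel$candidates)) {
    expect_equal(length(sel$candidates[[ty]]), 30)
    combos <- vapply(sel$candidates[[ty]], function(c) c$combo, character(1))
    rms <- vapply(sel$candidates[[ty]], function(c) c$rm, numeric(1))
    expect_equal(sort(unique(combos)), sort(MAXENT_COMBOS))
    expect_equal(sort(unique(rms)), sort(MAXENT_RMS))
  }
  # overall winner maximizes the harmonic mean among per-type winners
  hm <- sel$harmonic_mean
  expect_equal(unname(hm[sel$overall_best_type]), max(hm))
})
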