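# a small two-variable stack with independent gradients
two_var_env <- function(g = tiny_grid(10, 8)) {
  ew <- matrix(rep(seq_len(g$n_cols), each = g$n_rows), g$n_rows, g$n_cols)
  ns <- matrix(rep(seq_len(g$n_rows), times = g$n_cols), g$n_rows, g$n_cols)
  env_stack(g, list(BIO1 = ew * 1.0, BIO2 = ns * 1.0))
}

test_that("feature expansions enumerate the documented descriptor counts", {
  g <- tiny_grid(10, 8)
  env3 <- env_stack(g, list(a = matrix(runif(80), 8), b = matrix(runif(80), 8),
                            c = matrix(runif(80), 8)))
  native <- full_mask(g)
  expect_equal(nrow(build_features(env3, native, c("a", "b", "c"),
                                   "lq")$descriptors), 6)
  expect_equal(nrow(build_features(env3, native, "a", "l")$descriptors), 1)
  # 2 vars, 10 knots, lqhpt: 2 + 2 + 40 + 1 + 20 = 65
  expect_equal(nrow(build_features(env3, native, c("a", "b"), "lqhpt",
                                   n_knots = 10)$descriptors), 65)
  expect_error(build_features(env3, native, character(), "l"), "empty")
  # constant variables are dropped with a warning
  envc <- env_stack(g, list(a = matrix(runif(80), 8), k = matrix(1, 8, 10)))
  expect_warning(fe <- build_features(envc, native, c("a", "k"), "l"),
                 "constant")
  expect_equal(fe$variables, "a")
})

test_that("scaled base features stay in [0,1] and clamp outside training bounds", {
  env <- two_var_env()
  native <- full_mask(env$grid)
  fe <- build_features(env, native, c("BIO1", "BIO2"), "l")
  expect_true(all(fe$F_bg >= 0 & fe$F_bg <= 1))
  env2 <- env
  env2$layers$BIO1 <- env$layers$BIO1 * 10  # far outside training range
  Fm <- feature_matrix(fe, env2, seq_len(n_cells(env$grid)))
  expect_true(all(Fm >= 0 & Fm <= 1))
})

test_that("fitting recovers the direction of a separable gradient", {
  env <- two_var_env()
  native <- full_mask(env$grid)
  fe <- build_features(env, native, "BIO1", "l")
  # presences concentrated at the high end of BIO1
  pres <- which(env$layers$BIO1 >= 9)[1:10]
  fit <- fit_maxent(fe, pres, rm = 1)
  expect_gt(fit$beta[1], 0)
  # fitted objective no worse than the null model's
  Fb <- fe$F_bg
  fbar <- colMeans(Fb[match(pres, fe$cells), , drop = FALSE])
  obj_at <- function(b) log(sum(exp(Fb %*% b))) - sum(fbar * b)
  expect_lte(obj_at(fit$beta), obj_at(0 * fit$beta) + 1e-9)
})

test_that("raw predictions form a probability distribution over the background", {
  w <- make_world(tiny_grid(15, 12), seed = 3)
  occ <- simulate_species(w, 30, seed = 1)
  raw <- filter_records(occ, w$native)
  fe <- build_features(w$env, w$native, c("BIO1", "BIO2"), "lq")
  fit <- fit_maxent(fe, raw$records$cell, rm = 1)
  pred <- predict_raw(fit)
  expect_equal(sum(pred), 1, tolerance = 1e-9)
  # identical environments give identical raw values
  g <- tiny_grid(4, 1, cell_size = 1, lon_min = 0, lat_min = 0)
  env <- env_stack(g, list(x = matrix(c(1, 2, 2, 5), 1, 4)))
  fe2 <- build_features(env, full_mask(g), "x", "l")
  fit2 <- fit_maxent(fe2, c(3, 4), rm = 1)
  p2 <- predict_raw(fit2)
  expect_equal(p2[2], p2[3])
})

test_that("an infinite regularization multiplier collapses to the uniform model", {
  env <- two_var_env()
  native <- full_mask(env$grid)
  fe <- build_features(env, native, c("BIO1", "BIO2"), "lqh", n_knots = 5)
  pres <- which(env$layers$BIO1 >= 9)[1:8]
  fit <- fit_maxent(fe, pres, rm = 1e9)
  expect_true(all(fit$beta == 0))
  N <- length(fe$cells)
  expect_equal(predict_raw(fit), rep(1 / N, N), tolerance = 1e-12)
  # and its cloglog is 1 - exp(-1) everywhere (H = log N)
  expect_equal(fit$entropy, log(N), tolerance = 1e-9)
  expect_equal(predict_cloglog(fit, predict_raw(fit)),
               rep(1 - exp(-1), N), tolerance = 1e-9)
})

test_that("a hand-built toy model reproduces closed-form raw predictions", {
  g <- tiny_grid(4, 1, cell_size = 1, lon_min = 0, lat_min = 0)
  env <- env_stack(g, list(x = matrix(c(0, 1, 2, 3), 1, 4)))
  fe <- build_features(env, full_mask(g), "x", "l")
  fit <- fit_maxent(fe, 4, rm = 1)
  beta <- 1.7
  fit$beta <- beta
  s <- c(0, 1, 2, 3) / 3                 # scaled feature values
  Z <- sum(exp(beta * s))
  fit$log_normalizer <- log(Z)
  expect_equal(predict_raw(fit), exp(beta * s) / Z, tolerance = 1e-12)
})

test_that("cloglog transform is anchored at zero and strictly monotone", {
  w <- make_world(tiny_grid(15, 12), seed = 5)
  occ <- simulate_species(w, 30, seed = 2)
  raw <- filter_records(occ, w$native)
  fe <- build_features(w$env, w$native, c("BIO1", "BIO2"), "lq")
  fit <- fit_maxent(fe, raw$records$cell, rm = 1)
  expect_equal(predict_cloglog(fit, 0), 0)
  p <- sort(unique(predict_raw(fit)))
  cl <- predict_cloglog(fit, p)
  expect_true(all(diff(cl) > 0))
  expect_true(all(cl > 0 & cl < 1))
})

test_that("permutation importances are normalized percentages", {
  env <- two_var_env()
  native <- full_mask(env$grid)
  pres <- which(env$layers$BIO1 >= 9)[1:10]
  fe1 <- build_features(env, native, "BIO1", "l")
  fit1 <- fit_maxent(fe1, pres, rm = 1)
  imp1 <- permutation_importance(fit1, pres, env = env, seed = 1)
  expect_equal(unname(imp1), 100)
  fe2 <- build_features(env, native, c("BIO1", "BIO2"), "l")
  fit2 <- fit_maxent(fe2, pres, rm = 1)
  imp2 <- permutation_importance(fit2, pres, env = env, seed = 1)
  expect_equal(sum(imp2), 100, tolerance = 1e-6)
  # a variable whose coefficients are all zero moves nothing
  fit2$beta[2] <- 0
  imp0 <- permutation_importance(fit2, pres, env = env, seed = 1)
  expect_equal(unname(imp0["BIO2"]), 0)
})

test_that("AICc follows the corrected formula and its unavailability rules", {
  # uniform model: K = 0, n = 5 presences, N = 20 cells
  g <- tiny_grid(20, 1, cell_size = 0.5, lon_min = 0, lat_min = 0)
  env <- env_stack(g, list(x = matrix(runif(20), 1, 20)))
  fe <- build_features(env, full_mask(g), "x", "l")
  fit <- fit_maxent(fe, c(1, 3, 5, 7, 9), rm = 1e9)
  raw <- predict_raw(fit)
  expect_equal(aicc(fit, c(1, 3, 5, 7, 9), raw), 10 * log(20),
               tolerance = 1e-9)
  # denominator rule: K >= n - 1 is unavailable
  fitK <- fit
  fitK$beta <- 4
  expect_true(is.na(aicc(fitK, c(1, 2), predict_raw(fitK))))
  # increasing likelihood at fixed K strictly decreases AICc
  raw2 <- raw
  raw2[c(1, 3, 5, 7, 9)] <- raw2[c(1, 3, 5, 7, 9)] * 2
  expect_lt(aicc(fit, c(1, 3, 5, 7, 9), raw2),
            aicc(fit, c(1, 3, 5, 7, 9), raw))
})

test_that("the penalized objective has a unique optimum across restarts", {
  w <- make_world(tiny_grid(15, 12), seed = 8)
  occ <- simulate_species(w, 40, seed = 3)
  raw <- filter_records(occ, w$native)
  fe <- build_features(w$env, w$native, c("BIO1", "BIO2"), "lqh", n_knots = 5)
  f0 <- fit_maxent(fe, raw$records$cell, rm = 1)
  set.seed(42)
  for (r in 1:3) {
    init <- rnorm(length(f0$beta), sd = 0.5)
    fr <- fit_maxent(fe, raw$records$cell, rm = 1, beta_init = init)
    expect_equal(fr$objective, f0$objective, tolerance = 1e-5)
  }
})

test_that("models round-trip through JSON serialization", {
  w <- make_world(tiny_grid(15, 12), seed = 10)
  occ <- simulate_species(w, 30, seed = 4)
  raw <- filter_records(occ, w$native)
  fe <- build_features(w$env, w$native, c("BIO1", "LC1"), "lqh", n_knots = 5)
  fit <- fit_maxent(fe, raw$records$cell, rm = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(fit, path)
  back <- read_maxent_model(path, w$env)
  expect_equal(predict_raw(back), predict_raw(fit), tolerance = 1e-12)
  expect_equal(back$entropy, fit$entropy, tolerance = 1e-12)
})
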