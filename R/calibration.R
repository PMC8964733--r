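#' Eligibility of a species for maxent prediction
#'
#' A species gets a prediction at all only if the raw data comprise at
#' least 5 records spread across at least 3 cells, and the native region
#' spans at least 9 cells (Model 1). The presence-cell model (Model 2)
#' and the thinned model (Model 3) additionally require at least 3
#' points of the corresponding data type.
#'
#' @param raw an [occurrence_set()] of kind `"raw"`.
#' @param native a [region_mask()].
#' @param thinned optional thinned [occurrence_set()]; without it
#'   `model_3_ok` is `NA`.
#' @param min_records,min_cells,min_native,min_filtered the four bounds
#'   (defaults 5, 3, 9, 3).
#' @return list with logical fields `model_1_ok`, `model_2_ok`,
#'   `model_3_ok` plus the underlying counts.
#' @export
eligibility <- function(raw, native, thinned = NULL, min_records = 5,
                        min_cells = 3, min_native = 9, min_filtered = 3) {
  n_raw <- nrow(raw$records)
  n_occ <- length(raw$cells)
  n_native <- sum(native$member)
  n_thin <- if (is.null(thinned)) NA_integer_ else nrow(thinned$records)
  native_ok <- n_native >= min_native
  list(model_1_ok = n_raw >= min_records && n_occ >= min_cells && native_ok,
       model_2_ok = n_occ >= min_filtered && native_ok,
       model_3_ok = if (is.na(n_thin)) NA else n_thin >= min_filtered && native_ok,
       n_raw_records = n_raw, n_occupied_cells = n_occ,
       n_native_cells = n_native, n_thinned = n_thin)
}

#' Partition occurrence points for cross-validation
#'
#' Fewer than 25 points: leave-one-out jackknife with `k = n`. Otherwise
#' spatial block partitioning with `k = 4`: the points are split at the
#' median longitude, then each half at that half's median latitude,
#' yielding four spatial bins whose sizes differ by at most 2. The split
#' lines are stored so background cells can be assigned to the same
#' blocks.
#'
#' @param points data.frame with `lon` and `lat` columns (n >= 2).
#' @param block_threshold sample size at which block partitioning starts
#'   (default 25).
#' @return object of class `partition_scheme` with fields `method`
#'   (`"jackknife"` or `"block"`), `k`, `fold` (per point) and, for block
#'   partitioning, the split lines.
#' @export
partition <- function(points, block_threshold = 25) {
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points to partition")
  if (n < block_threshold) {
    return(structure(list(method = "jackknife", k = n, fold = seq_len(n)),
                     class = "partition_scheme"))
  }
  ord <- order(points$lon, points$lat)
  n_west <- ceiling(n / 2)
  west <- ord[seq_len(n_west)]
  east <- ord[-seq_len(n_west)]
  lon_split <- (max(points$lon[west]) + min(points$lon[east])) / 2
  split_half <- function(idx) {
    o <- idx[order(points$lat[idx], points$lon[idx])]
    ns <- ceiling(length(o) / 2)
    south <- o[seq_len(ns)]
    north <- o[-seq_len(ns)]
    lat_split <- (max(points$lat[south]) + min(points$lat[north])) / 2
    list(south = south, north = north, lat_split = lat_split)
  }
  w <- split_half(west)
  e <- split_half(east)
  fold <- integer(n)
  fold[w$south] <- 1L; fold[w$north] <- 2L
  fold[e$south] <- 3L; fold[e$north] <- 4L
  structure(list(method = "block", k = 4L, fold = fold,
                 lon_split = lon_split,
                 lat_split_west = w$lat_split, lat_split_east = e$lat_split),
            class = "partition_scheme")
}

#' Assign background cells to the blocks of a partition scheme
#'
#' @param scheme a block [partition()] scheme.
#' @param lon,lat coordinates of the background cells.
#' @return integer fold per cell (all 0 for jackknife schemes, whose
#'   folds share the full background).
#' @export
assign_background <- function(scheme, lon, lat) {
  if (scheme$method != "block") return(rep(0L, length(lon)))
  west <- lon <= scheme$lon_split
  fold <- integer(length(lon))
  fold[west] <- ifelse(lat[west] <= scheme$lat_split_west, 1L, 2L)
  fold[!west] <- ifelse(lat[!west] <= scheme$lat_split_east, 3L, 4L)
  fold
}

#' Cross-validated calibration of one candidate model
#'
#' Fits one maxent model per fold on the training presences (full
#' background for jackknife; the training blocks' background cells for
#' block partitioning), records training and testing AUC per fold, and
#' aggregates their means; the degree of overfit is the difference of the
#' two means. A full-data model is then refitted on all points and its
#' AICc computed over the full native background. Folds without training
#' presences (or whose fit fails) are skipped and flagged; a candidate
#' with no successful fold is marked failed.
#'
#' @param points data.frame with `lon`, `lat`, `cell` columns for the
#'   occurrence data type being calibrated.
#' @param expansion a [build_features()] result (its cells are the full
#'   background).
#' @param rm regularization multiplier.
#' @param scheme a [partition()] scheme for `points`.
#' @return object of class `candidate_model`.
#' @export
crossvalidate <- function(points, expansion, rm, scheme) {
  stopifnot(nrow(points) == length(scheme$fold))
  bg_cells <- expansion$cells
  cc <- cell_centers(expansion$grid, bg_cells)
  bg_fold <- assign_background(scheme, cc$lon, cc$lat)
  eta_of <- function(model, cells) {
    rows <- bg_rows(expansion, cells)
    drop(expansion$F_bg[rows, , drop = FALSE] %*% model$beta)
  }
  train_auc <- test_auc <- rep(NA_real_, scheme$k)
  skipped <- logical(scheme$k)
  for (f in seq_len(scheme$k)) {
    train_p <- points$cell[scheme$fold != f]
    test_p <- points$cell[scheme$fold == f]
    if (length(train_p) == 0 || length(test_p) == 0) {
      skipped[f] <- TRUE
      next
    }
    if (scheme$method == "block") {
      train_bg <- bg_cells[bg_fold != f]
      test_bg <- bg_cells[bg_fold == f]
      if (length(test_bg) == 0) test_bg <- bg_cells
      if (length(train_bg) < 2) {
        skipped[f] <- TRUE
        next
      }
      # presences must lie in their background for fitting
      train_p_fit <- train_p[train_p %in% train_bg]
      if (length(train_p_fit) == 0) {
        skipped[f] <- TRUE
        next
      }
    } else {
      train_bg <- bg_cells
      test_bg <- bg_cells
      train_p_fit <- train_p
    }
    fit <- tryCatch(fit_maxent(expansion, train_p_fit, train_bg, rm),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped[f] <- TRUE
      next
    }
    train_auc[f] <- roc_auc(eta_of(fit, train_p_fit), eta_of(fit, train_bg))
    test_auc[f] <- roc_auc(eta_of(fit, test_p), eta_of(fit, test_bg))
  }
  ok <- !skipped
  if (!any(ok)) {
    return(structure(list(combo = expansion$combo, rm = rm, failed = TRUE),
                     class = "candidate_model"))
  }
  full <- tryCatch(fit_maxent(expansion, points$cell, bg_cells, rm),
                   error = function(e) NULL)
  if (is.null(full)) {
    return(structure(list(combo = expansion$combo, rm = rm, failed = TRUE),
                     class = "candidate_model"))
  }
  raw_full <- predict_raw(full)
  mtr <- mean(train_auc[ok]); mte <- mean(test_auc[ok])
  structure(list(combo = expansion$combo, rm = rm,
                 mean_train_auc = mtr, mean_test_auc = mte,
                 doo = mtr - mte,
                 aicc = aicc(full, points$cell, raw_full),
                 k_nonzero = sum(full$beta != 0),
                 n_points = nrow(points), k_folds = scheme$k,
                 n_folds_used = sum(ok), model = full,
                 failed = FALSE),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("<candidate_model:%s rm=%g> FAILED\n", x$combo, x$rm))
  } else {
    cat(sprintf("<candidate_model:%s rm=%g> test AUC %.3f, DOO %.3f, AICc %s, K=%d\n",
                x$combo, x$rm, x$mean_test_auc, x$doo,
                ifelse(is.na(x$aicc), "unavailable", sprintf("%.2f", x$aicc)),
                x$k_nonzero))
  }
  invisible(x)
}

#' Pick the best candidate by the AICc-then-AUC cascade
#'
#' The winner is the candidate with the unique minimum AICc. If AICc is
#' unavailable for at least half the candidates, or no unique minimum
#' exists (ties within 1e-9), the candidate with the highest mean
#' testing AUC wins instead (ties broken by lower AICc where available,
#' then lower K, then input order). Failed candidates are excluded.
#'
#' @param candidates list of [crossvalidate()] results.
#' @return list with fields `best` (index into `candidates`) and
#'   `criterion` (`"aicc"` or `"test_auc"`).
#' @export
cascade_pick <- function(candidates) {
  ok <- which(!vapply(candidates, function(c) isTRUE(c$failed), logical(1)))
  if (length(ok) == 0) stop("all candidates failed")
  aic <- vapply(candidates[ok], function(c) c$aicc, numeric(1))
  auc <- vapply(candidates[ok], function(c) c$mean_test_auc, numeric(1))
  kk <- vapply(candidates[ok], function(c) c$k_nonzero, numeric(1))
  frac_missing <- mean(is.na(aic))
  use_auc <- frac_missing >= 0.5
  if (!use_auc) {
    fin <- which(!is.na(aic))
    best_val <- min(aic[fin])
    at_min <- fin[aic[fin] <= best_val + 1e-9]
    if (length(at_min) == 1) {
      return(list(best = ok[at_min], criterion = "aicc"))
    }
    use_auc <- TRUE  # no unique AICc minimum
  }
  o <- order(-auc, ifelse(is.na(aic), Inf, aic), kk, seq_along(ok))
  list(best = ok[o[1]], criterion = "test_auc")
}

#' Model 0: select uncorrelated environmental variables
#'
#' Fits the six feature-class combinations (regularization multiplier 1)
#' on the raw data with all candidate variables, picks the winner by the
#' AICc-then-AUC cascade, computes permutation importances on the
#' winner's full-data model, computes Spearman rank correlations between
#' all variable pairs over the native background cells, and greedily
#' keeps variables in order of decreasing importance, admitting a
#' variable only if `|rho| < rho_max` against every variable already
#' kept. The returned set is therefore pairwise uncorrelated at the
#' chosen bound.
#'
#' @param raw an [occurrence_set()] of kind `"raw"`.
#' @param native a [region_mask()].
#' @param env an [env_stack()].
#' @param variables candidate variable codes (default: all layers).
#' @param rho_max collinearity bound (default 0.7).
#' @param n_knots hinge/threshold knots per variable.
#' @param seed integer seed (permutation importances).
#' @return list with fields `selected`, `importance`, `rho`,
#'   `candidates`, `winner` (index), `criterion`, `n_models`.
#' @export
select_variables <- function(raw, native, env,
                             variables = names(env$layers), rho_max = 0.7,
                             n_knots = 50, seed = 1) {
  points <- raw$records
  scheme <- partition(points)
  candidates <- list()
  for (combo in MAXENT_COMBOS) {
    expn <- build_features(env, native, variables, combo, n_knots)
    candidates[[combo]] <- crossvalidate(points, expn, rm = 1, scheme)
  }
  pick <- cascade_pick(candidates)
  winner <- candidates[[pick$best]]
  imp <- permutation_importance(winner$model, points$cell,
                                env = env, seed = seed)
  cells <- mask_cells(native)
  V <- vapply(variables, function(v) env$layers[[v]][cells],
              numeric(length(cells)))
  rho <- cor(V, method = "spearman")
  # greedy importance-ordered pruning; variables dropped as constant
  # during feature building carry no importance and are never kept
  imp_all <- setNames(rep(0, length(variables)), variables)
  imp_all[names(imp)] <- imp
  ord <- names(sort(imp_all, decreasing = TRUE))
  kept <- character()
  for (v in ord) {
    if (!v %in% names(imp)) next
    if (all(abs(rho[v, kept]) < rho_max)) kept <- c(kept, v)
  }
  list(selected = kept, importance = imp, rho = rho,
       candidates = candidates, winner = pick$best,
       criterion = pick$criterion, n_models = length(candidates))
}

#' Fit and select across the Models 1-3 candidate grid
#'
#' For each eligible occurrence data type (raw = Model 1, presence cells
#' = Model 2, thinned = Model 3) every combination of the six feature
#' classes and five regularization multipliers is calibrated by
#' cross-validation (30 candidates per data type, up to 90 in total).
#' Within each data type the best candidate is chosen by the
#' AICc-then-AUC cascade; across data types the overall winner maximizes
#' the harmonic mean of evaluation AUC and AUC_PR computed against the
#' species' presence cells over the native background (ties broken by
#' higher AUC, then fewer nonzero coefficients, then the data-type order
#' raw, cells, thinned).
#'
#' @param raw,presence,thinned the three [occurrence_set()]s.
#' @param native a [region_mask()].
#' @param env an [env_stack()].
#' @param selected_variables variables from [select_variables()].
#' @param rms regularization multipliers (default `MAXENT_RMS`).
#' @param combos feature combinations (default `MAXENT_COMBOS`).
#' @param n_knots hinge/threshold knots per variable.
#' @return object of class `selection_result` with the full candidate
#'   grid, per-data-type winners, evaluation reports and the overall
#'   best model.
#' @export
run_candidate_grid <- function(raw, presence, thinned, native, env,
                               selected_variables, rms = MAXENT_RMS,
                               combos = MAXENT_COMBOS, n_knots = 50) {
  elig <- eligibility(raw, native, thinned)
  if (!elig$model_1_ok)
    stop("species not eligible for maxent prediction (Model 1 conditions)")
  sets <- list(raw = raw$records,
               presence_cells = presence$records,
               thinned = thinned$records)
  type_ok <- c(raw = TRUE,
               presence_cells = isTRUE(elig$model_2_ok),
               thinned = isTRUE(elig$model_3_ok))
  model_ids <- c(raw = 1L, presence_cells = 2L, thinned = 3L)
  grid_cands <- list()
  best_per_model <- list()
  eval_per_model <- list()
  n_fits <- 0L
  presence_cell_ids <- presence$cells
  for (ty in names(sets)) {
    if (!type_ok[[ty]]) next
    points <- sets[[ty]]
    scheme <- partition(points)
    cands <- list()
    for (combo in combos) {
      expn <- build_features(env, native, selected_variables, combo, n_knots)
      for (rm in rms) {
        cand <- crossvalidate(points, expn, rm, scheme)
        cand$data_type <- ty
        cand$model_id <- model_ids[[ty]]
        cands[[paste(combo, rm, sep = "_")]] <- cand
        n_fits <- n_fits + 1L
      }
    }
    grid_cands[[ty]] <- cands
    not_all_failed <- any(!vapply(cands, function(c) isTRUE(c$failed),
                                  logical(1)))
    if (!not_all_failed) next
    pick <- cascade_pick(cands)
    best <- cands[[pick$best]]
    best$criterion <- pick$criterion
    best_per_model[[ty]] <- best
    raw_pred <- predict_raw(best$model)
    eval_per_model[[ty]] <- evaluate(raw_pred, presence_cell_ids, native,
                                     "presence_background")
  }
  if (length(best_per_model) == 0) stop("no prediction: all candidates failed")
  hm <- vapply(names(best_per_model), function(ty) {
    e <- eval_per_model[[ty]]
    2 * e$auc * e$auc_pr / (e$auc + e$auc_pr)
  }, numeric(1))
  auc <- vapply(eval_per_model, function(e) e$auc, numeric(1))
  kk <- vapply(best_per_model, function(b) b$k_nonzero, numeric(1))
  type_rank <- match(names(best_per_model),
                     c("raw", "presence_cells", "thinned"))
  o <- order(-hm, -auc, kk, type_rank)
  overall <- names(best_per_model)[o[1]]
  structure(list(candidates = grid_cands,
                 best_per_model = best_per_model,
                 eval_per_model = eval_per_model,
                 harmonic_mean = hm,
                 overall_best_type = overall,
                 overall_best = best_per_model[[overall]],
                 overall_eval = eval_per_model[[overall]],
                 selected_variables = selected_variables,
                 n_grid_models = n_fits,
                 eligibility = elig),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d grid candidates over %d data types; best: %s (%s rm=%g), AUC %.3f / AUC_PR %.3f\n",
              x$n_grid_models, length(x$candidates), x$overall_best_type,
              x$overall_best$combo, x$overall_best$rm,
              x$overall_eval$auc, x$overall_eval$auc_pr))
  invisible(x)
}
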