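#' Default pipeline configuration
#'
#' All defaults mirror the workflow constants: temporal window 2000-2020
#' with a 25-record escape, eligibility bounds 5 records / 3 cells /
#' 9 native cells (3 points for the filtered data types), thinning at two
#' cell widths, collinearity bound 0.7, regularization multipliers
#' `{1, 2, 3, 5, 10}` and the six feature-class combinations.
#'
#' @param ... overrides of any default field.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(year_lo = 2000, year_hi = 2020, min_recent = 25,
              min_records = 5, min_cells = 3, min_native = 9,
              min_filtered = 3, thin_dist_cells = 2, thin_reps = 10,
              rho_max = 0.7, rms = MAXENT_RMS, combos = MAXENT_COMBOS,
              n_knots = 50)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the per-species range-estimation pipeline
#'
#' Executes the full workflow for one species: occurrence filtering into
#' the raw data type, per-cell counts and Moran's I, presence cells and
#' thinned data, eligibility, Model 0 variable selection, the Models 1-3
#' candidate grid, evaluation, and bundle assembly. Deterministic for a
#' given seed. If the species is not eligible for a prediction, the
#' bundle carries only occurrences and the native region and the
#' metadata row notes "no prediction".
#'
#' @param occurrences occurrence data.frame (see [filter_records()]).
#' @param env an [env_stack()].
#' @param native a [region_mask()].
#' @param species species name for the metadata.
#' @param seed integer seed (thinning, permutation importances).
#' @param config a [pipeline_config()].
#' @return list with elements `bundle` (named list of layers on the
#'   grid), `metadata` (one-row data.frame), `selection` (the
#'   `selection_result` or `NULL`), `variable_selection`, `sets` and
#'   `log`.
#' @export
run_pipeline <- function(occurrences, env, native, species = "species",
                         seed = 1, config = pipeline_config()) {
  grid <- env$grid
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  raw <- filter_records(occurrences, native, config$year_lo, config$year_hi,
                        config$min_recent)
  note("filtered to %d raw records in %d cells", nrow(raw$records),
       length(raw$cells))
  counts <- count_per_cell(raw, grid)
  moran <- tryCatch(morans_index(counts, native), error = function(e) NA_real_)
  presence <- to_presence_cells(raw)
  thinned <- if (nrow(presence$records) > 0)
    thin(presence, config$thin_dist_cells, config$thin_reps,
         seed = sub_seed(seed, 11))
  else occurrence_set("thinned", presence$records, grid)
  note("presence cells: %d; thinned: %d", nrow(presence$records),
       nrow(thinned$records))
  elig <- eligibility(raw, native, thinned, config$min_records,
                      config$min_cells, config$min_native,
                      config$min_filtered)

  bundle <- list("Native region" = ifelse(native$member, 1, NA_real_),
                 "Presence cells" = {
                   cl <- matrix(NA_real_, grid$n_rows, grid$n_cols)
                   cl[native$member] <- 0
                   cl[raw$cells] <- raw$counts
                   cl
                 })
  meta <- data.frame(species = species,
                     n_raw_records = nrow(raw$records),
                     n_presence_cells = nrow(presence$records),
                     n_thinned = nrow(thinned$records),
                     n_native_cells = sum(native$member),
                     bbox_lon_min = NA_real_, bbox_lon_max = NA_real_,
                     bbox_lat_min = NA_real_, bbox_lat_max = NA_real_,
                     morans_i = moran,
                     prediction = FALSE, n_models_fitted = 0L,
                     training_data_type = NA_character_,
                     n_training = NA_integer_,
                     combo = NA_character_, rm = NA_real_,
                     variables = NA_character_, k_nonzero = NA_integer_,
                     aicc = NA_real_, mean_test_auc = NA_real_,
                     doo = NA_real_, eval_auc = NA_real_,
                     eval_auc_pr = NA_real_, eval_max_f1 = NA_real_,
                     threshold_no_omission = NA_real_,
                     threshold_max_f1 = NA_real_,
                     note = "", stringsAsFactors = FALSE)
  cc <- cell_centers(grid, mask_cells(native))
  h <- grid$cell_size / 2
  meta$bbox_lon_min <- min(cc$lon) - h
  meta$bbox_lon_max <- max(cc$lon) + h
  meta$bbox_lat_min <- min(cc$lat) - h
  meta$bbox_lat_max <- max(cc$lat) + h

  sets <- list(raw = raw, presence = presence, thinned = thinned)
  if (!elig$model_1_ok) {
    note("not eligible for prediction (records %d, cells %d, native %d)",
         elig$n_raw_records, elig$n_occupied_cells, elig$n_native_cells)
    meta$note <- "no prediction"
    return(list(bundle = bundle, metadata = meta, selection = NULL,
                variable_selection = NULL, sets = sets, log = log,
                eligibility = elig, grid = grid))
  }

  vs <- select_variables(raw, native, env, rho_max = config$rho_max,
                         n_knots = config$n_knots, seed = sub_seed(seed, 12))
  note("Model 0: %d combos, winner by %s; selected variables: %s",
       vs$n_models, vs$criterion, paste(vs$selected, collapse = ", "))
  sel <- run_candidate_grid(raw, presence, thinned, native, env,
                            vs$selected, rms = config$rms,
                            combos = config$combos, n_knots = config$n_knots)
  note("candidate grid: %d models over %d data types; best: %s",
       sel$n_grid_models, length(sel$candidates), sel$overall_best_type)

  native_cells <- mask_cells(native)
  to_layer <- function(values) {
    l <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    l[native_cells] <- values
    l
  }
  best <- sel$overall_best
  raw_pred <- predict_raw(best$model)
  cloglog_pred <- predict_cloglog(best$model, raw_pred)
  bundle[["Maxent prediction"]] <- to_layer(cloglog_pred)
  bundle[["Maxent prediction (raw)"]] <- to_layer(raw_pred)
  for (ty in names(sel$best_per_model)) {
    b <- sel$best_per_model[[ty]]
    bundle[[paste("Model", b$model_id)]] <-
      to_layer(predict_cloglog(b$model, predict_raw(b$model)))
  }
  thr <- binary_thresholds(cloglog_pred, presence$cells, native)

  ev <- sel$overall_eval
  meta$prediction <- TRUE
  meta$n_models_fitted <- vs$n_models + sel$n_grid_models
  meta$training_data_type <- sel$overall_best_type
  meta$n_training <- best$n_points
  meta$combo <- best$combo
  meta$rm <- best$rm
  meta$variables <- paste(sel$selected_variables, collapse = ";")
  meta$k_nonzero <- best$k_nonzero
  meta$aicc <- best$aicc
  meta$mean_test_auc <- best$mean_test_auc
  meta$doo <- best$doo
  meta$eval_auc <- ev$auc
  meta$eval_auc_pr <- ev$auc_pr
  meta$eval_max_f1 <- ev$max_f1
  meta$threshold_no_omission <- thr$no_omission
  meta$threshold_max_f1 <- thr$max_f1
  note("best model %s rm=%g: eval AUC %.3f, AUC_PR %.3f",
       best$combo, best$rm, ev$auc, ev$auc_pr)

  list(bundle = bundle, metadata = meta, selection = sel,
       variable_selection = vs, sets = sets, log = log,
       eligibility = elig, grid = grid)
}

#' Write a species bundle to disk
#'
#' The bundle is serialized as one long-format CSV per layer plus a JSON
#' manifest carrying the grid, the species name and the layer variable
#' names ("Maxent prediction", "Presence cells", "Native region",
#' "Model 1".."Model 3"). The `basic` set holds the best prediction and
#' shared layers; the `advanced` set holds the per-data-type model
#' layers.
#'
#' @param result a [run_pipeline()] result (or a list with `bundle`,
#'   `grid` and `metadata$species`).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  manifest <- list(species = result$metadata$species,
                   grid = unclass(result$grid), layers = list())
  for (nm in names(result$bundle)) {
    file <- paste0(slug(nm), ".csv")
    write.csv(layer_to_df(result$bundle[[nm]]), file.path(dir, file),
              row.names = FALSE)
    manifest$layers[[nm]] <- file
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a species bundle back
#'
#' @param dir a directory written by [write_bundle()].
#' @return list with `species`, `grid` and `layers` (named matrices).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grid <- do.call(grid_spec, manifest$grid[c("lon_min", "lat_min", "n_cols",
                                             "n_rows", "cell_size")])
  layers <- lapply(manifest$layers, function(f)
    df_to_layer(read.csv(file.path(dir, f)), grid))
  list(species = manifest$species, grid = grid, layers = layers)
}

#' Write the species metadata table
#'
#' One row per species; species without a prediction keep their
#' occurrence fields filled and their model fields empty.
#'
#' @param results list of [run_pipeline()] results (or their `metadata`
#'   rows).
#' @param path output CSV path.
#' @return invisibly, the combined data.frame.
#' @export
write_metadata <- function(results, path) {
  rows <- lapply(results, function(r)
    if (is.data.frame(r)) r else r$metadata)
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
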