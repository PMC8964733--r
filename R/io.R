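#' Read an occurrence CSV
#'
#' Expects GBIF-like columns (`species`, `decimalLongitude`,
#' `decimalLatitude`, `year`, optionally `issue` and the synthetic
#' generator's `contaminant_type`).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_occurrences <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write an occurrence table to CSV
#'
#' @param table occurrence data.frame.
#' @param path output path.
#' @export
write_occurrences <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
}

#' Read polygons from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries in a
#' `FeatureCollection`, a bare `GeometryCollection`, or a single
#' geometry. Interior rings are kept, so holes are honoured by the
#' even-odd rasterization rule.
#'
#' @param path GeoJSON file path.
#' @return list of polygons suitable for [rasterize_regions()].
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- switch(g$type,
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    GeometryCollection = g$geometries,
    list(g))
  out <- list()
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    colnames(m) <- c("lon", "lat")
    m
  }
  for (geom in geoms) {
    if (geom$type == "Polygon") {
      out[[length(out) + 1]] <- lapply(geom$coordinates, ring_to_matrix)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates)
        out[[length(out) + 1]] <- lapply(poly, ring_to_matrix)
    } else {
      stop("unsupported geometry type: ", geom$type)
    }
  }
  if (length(out) == 0) stop("no polygons found in ", path)
  out
}

#' Serialize a fitted maxent model to JSON
#'
#' Stores the feature descriptors, coefficients, scaling bounds,
#' normalizer, entropy and settings; [read_maxent_model()] restores a
#' model usable for prediction on new environments (the cached
#' background matrix is not stored).
#'
#' @param model a [fit_maxent()] result.
#' @param path output path.
#' @export
write_maxent_model <- function(model, path) {
  e <- model$expansion
  obj <- list(combo = e$combo, variables = e$variables,
              bounds = as.data.frame(t(e$bounds)),
              descriptors = e$descriptors, n_knots = e$n_knots,
              grid = unclass(e$grid), cells = e$cells,
              beta = model$beta, rm = model$rm,
              log_normalizer = model$log_normalizer,
              entropy = model$entropy, n_presence = model$n_presence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Restore a maxent model from JSON
#'
#' @param path a file written by [write_maxent_model()].
#' @param env an [env_stack()] providing the background values (needed to
#'   rebuild the cached background feature matrix).
#' @return a `maxent_model`.
#' @export
read_maxent_model <- function(path, env) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- do.call(grid_spec, obj$grid[c("lon_min", "lat_min", "n_cols",
                                     "n_rows", "cell_size")])
  bounds <- t(as.matrix(obj$bounds))
  dimnames(bounds) <- list(NULL, obj$variables)
  expn <- structure(list(combo = obj$combo, variables = obj$variables,
                         bounds = bounds,
                         descriptors = as.data.frame(obj$descriptors),
                         n_knots = obj$n_knots,
                         cells = as.integer(obj$cells), grid = g),
                    class = "feature_expansion")
  expn$F_bg <- feature_matrix(expn, env, expn$cells)
  structure(list(expansion = expn, beta = as.numeric(obj$beta),
                 rm = obj$rm, log_normalizer = obj$log_normalizer,
                 entropy = obj$entropy, n_presence = obj$n_presence,
                 background_cells = as.integer(obj$cells)),
            class = "maxent_model")
}

# long-format layer serialization used by the bundle writer
layer_to_df <- function(layer) {
  idx <- which(!is.na(layer))
  data.frame(cell = idx, value = as.numeric(layer[idx]))
}

df_to_layer <- function(df, grid) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[df$cell] <- df$value
  out
}
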