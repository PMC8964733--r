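#' Define a regular latitude/longitude modelling grid
#'
#' The modelling grid is an unprojected regular lat/lon raster. The default
#' cell size of 0.5 degrees (30 arc minutes, roughly 56 km at the equator)
#' matches the resolution at which native regions and environmental layers
#' are handled throughout the package. Cells are indexed in R's column-major
#' matrix order: row 1 is the southernmost latitude band, column 1 the
#' westernmost longitude band, and a cell id is `row + (col - 1) * n_rows`.
#'
#' @param lon_min,lat_min south-west corner of the grid, in degrees.
#' @param n_cols,n_rows number of longitude columns / latitude rows.
#' @param cell_size cell edge length in degrees (default 0.5).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lat_min, n_cols, n_rows, cell_size = 0.5) {
  stopifnot(is.numeric(lon_min), is.numeric(lat_min),
            is.numeric(n_cols), is.numeric(n_rows), is.numeric(cell_size))
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (n_cols < 1 || n_rows < 1) stop("n_cols and n_rows must be >= 1")
  lon_max <- lon_min + n_cols * cell_size
  lat_max <- lat_min + n_rows * cell_size
  if (lon_min < -180 - 1e-9 || lon_max > 180 + 1e-9 ||
      lat_min < -90 - 1e-9 || lat_max > 90 + 1e-9) {
    stop("grid extent must lie within [-180,180] x [-90,90]")
  }
  structure(list(lon_min = lon_min, lat_min = lat_min,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 cell_size = cell_size),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$lon_min, x$lat_min))
  invisible(x)
}

grid_lon_max <- function(grid) grid$lon_min + grid$n_cols * grid$cell_size
grid_lat_max <- function(grid) grid$lat_min + grid$n_rows * grid$cell_size

#' Number of cells in a grid
#' @param grid a [grid_spec()].
#' @return integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Locate points on the grid
#'
#' Cell membership uses half-open intervals `[edge, edge + cell_size)`;
#' points exactly on the global east/north boundary of the grid are
#' assigned to the last column/row. Points outside the grid return `NA`.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return integer vector of cell ids (`NA` outside the grid).
#' @export
cell_of <- function(grid, lon, lat) {
  cs <- grid$cell_size
  col <- floor((lon - grid$lon_min) / cs) + 1
  row <- floor((lat - grid$lat_min) / cs) + 1
  col[!is.na(lon) & lon == grid_lon_max(grid)] <- grid$n_cols
  row[!is.na(lat) & lat == grid_lat_max(grid)] <- grid$n_rows
  bad <- is.na(lon) | is.na(lat) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  idx <- as.integer(row + (col - 1) * grid$n_rows)
  idx[bad] <- NA_integer_
  idx
}

#' Cell-center coordinates
#'
#' @param grid a [grid_spec()].
#' @param cells integer cell ids; default all cells.
#' @return data.frame with columns `cell`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  data.frame(cell = cells,
             lon = grid$lon_min + (col - 0.5) * grid$cell_size,
             lat = grid$lat_min + (row - 0.5) * grid$cell_size)
}

#' Bundle named environmental layers on a common grid
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric matrices (`n_rows` x `n_cols`),
#'   one per environmental variable.
#' @param fraction_layers character vector of layer names that are
#'   land-cover fractions; these are checked to lie in `[0, 1]`.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, fraction_layers = character()) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols)
      stop("layer '", nm, "' does not match the grid dimensions")
    if (all(is.na(l)))
      stop("layer '", nm, "' is entirely missing")
  }
  for (nm in fraction_layers) {
    v <- layers[[nm]]
    if (is.null(v)) stop("fraction layer '", nm, "' not found")
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      stop("fraction layer '", nm, "' has values outside [0, 1]")
  }
  structure(list(grid = grid, layers = layers,
                 fraction_layers = fraction_layers),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Native-region membership mask
#'
#' @param grid a [grid_spec()].
#' @param member logical matrix (`n_rows` x `n_cols`), `TRUE` inside the
#'   native regions. Must contain at least one member cell.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(grid, member) {
  stopifnot(inherits(grid, "grid_spec"), is.logical(member))
  if (!is.matrix(member) || nrow(member) != grid$n_rows ||
      ncol(member) != grid$n_cols)
    stop("member mask does not match the grid dimensions")
  member[is.na(member)] <- FALSE
  if (!any(member)) stop("mask has no member cells")
  structure(list(grid = grid, member = member), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d member cells on %d x %d grid\n",
              sum(x$member), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Member cell ids of a mask
#' @param mask a [region_mask()].
#' @return integer vector of cell ids.
#' @export
mask_cells <- function(mask) which(mask$member)

# Even-odd ray-casting point-in-polygon test for one ring.
# Vertices on an edge may fall on either side; cell centers of a regular
# grid generically avoid polygon edges.
point_in_ring <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / denom
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}

# A polygon is a list of rings (matrix/data.frame with lon, lat columns);
# interior holes are handled by even-odd parity across the rings.
as_rings <- function(polygon) {
  if (is.matrix(polygon) || is.data.frame(polygon)) list(polygon) else polygon
}

point_in_polygon <- function(px, py, polygon) {
  inside <- rep(FALSE, length(px))
  for (ring in as_rings(polygon)) {
    ring <- as.matrix(ring[, 1:2])
    inside <- xor(inside, point_in_ring(px, py, ring[, 1], ring[, 2]))
  }
  inside
}

#' Rasterize polygons into a native-region mask
#'
#' A grid cell belongs to the mask iff its center lies inside any of the
#' polygons (cell-center containment; see the methods vignette for why
#' this rule rather than fractional coverage). Polygon holes are honoured
#' through even-odd parity.
#'
#' @param polygons a list of polygons; each polygon is a two-column
#'   matrix/data.frame of (lon, lat) vertices, or a list of such rings
#'   (outer ring plus holes). See [read_geojson_polygons()].
#' @param grid a [grid_spec()].
#' @return a [region_mask()].
#' @export
rasterize_regions <- function(polygons, grid) {
  if (length(polygons) == 0) stop("empty polygon set")
  cc <- cell_centers(grid)
  member <- rep(FALSE, n_cells(grid))
  for (poly in polygons) {
    member <- member | point_in_polygon(cc$lon, cc$lat, poly)
  }
  if (!any(member)) stop("empty native region")
  region_mask(grid, matrix(member, grid$n_rows, grid$n_cols))
}

#' Convert a mask to cell-outline polygons
#'
#' Each member cell becomes one square polygon tracing its edges. Useful
#' for round-tripping masks through polygon form.
#'
#' @param mask a [region_mask()].
#' @return list of 4-vertex polygons.
#' @export
mask_to_polygons <- function(mask) {
  g <- mask$grid
  cells <- mask_cells(mask)
  cc <- cell_centers(g, cells)
  h <- g$cell_size / 2
  lapply(seq_along(cells), function(i) {
    cbind(lon = cc$lon[i] + c(-h, h, h, -h),
          lat = cc$lat[i] + c(-h, -h, h, h))
  })
}

# shared checks for block aggregation
aggregation_factor <- function(fine_grid, grid) {
  f <- grid$cell_size / fine_grid$cell_size
  if (abs(f - round(f)) > 1e-9)
    stop("coarse cell size is not an integer multiple of the fine resolution")
  f <- as.integer(round(f))
  if (abs(fine_grid$lon_min - grid$lon_min) > 1e-9 ||
      abs(fine_grid$lat_min - grid$lat_min) > 1e-9)
    stop("fine and coarse grids must share an origin")
  if (fine_grid$n_rows != grid$n_rows * f || fine_grid$n_cols != grid$n_cols * f)
    stop("fine grid dimensions do not tile the coarse grid")
  f
}

#' Aggregate a fine raster to the modelling grid by averaging
#'
#' Each coarse cell takes the arithmetic mean of the fine cells it
#' contains; missing fine cells are ignored. This mirrors how
#' high-resolution climate layers are brought to the modelling
#' resolution.
#'
#' @param fine_layer numeric matrix on `fine_grid`.
#' @param fine_grid a [grid_spec()] describing the fine raster; must share
#'   the coarse grid's origin and tile it by an integer factor.
#' @param grid target [grid_spec()].
#' @return numeric matrix on `grid`.
#' @export
aggregate_mean <- function(fine_layer, fine_grid, grid) {
  f <- aggregation_factor(fine_grid, grid)
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    rows <- ((r - 1) * f + 1):(r * f)
    for (c in seq_len(grid$n_cols)) {
      cols <- ((c - 1) * f + 1):(c * f)
      block <- fine_layer[rows, cols]
      if (any(!is.na(block))) out[r, c] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

#' Land-cover class fraction at the modelling resolution
#'
#' The categorical fine raster is turned into a presence/absence indicator
#' for `class_id` and aggregated by averaging, yielding the proportion of
#' the coarse cell covered by that class.
#'
#' @param fine_classes categorical (integer) matrix on `fine_grid`.
#' @param fine_grid a [grid_spec()] for the fine raster.
#' @param class_id the class to extract; must occur in `fine_classes`.
#' @param grid target [grid_spec()].
#' @return numeric matrix on `grid` with values in `[0, 1]`.
#' @export
aggregate_fractions <- function(fine_classes, fine_grid, class_id, grid) {
  if (!class_id %in% fine_classes)
    stop("unknown class_id: ", class_id)
  indicator <- matrix(as.numeric(fine_classes == class_id),
                      nrow(fine_classes), ncol(fine_classes))
  indicator[is.na(fine_classes)] <- NA_real_
  aggregate_mean(indicator, fine_grid, grid)
}
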