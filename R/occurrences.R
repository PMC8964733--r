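#' Occurrence sets at the three filtering levels
#'
#' An `occurrence_set` holds a species' records at one of three levels:
#' `"raw"` (quality/temporal/native-region filtered, deduplicated),
#' `"presence_cells"` (one record per occupied grid cell), or
#' `"thinned"` (presence cells after spatial thinning). It carries the
#' occupied cell ids and per-cell record counts.
#'
#' @param kind one of `"raw"`, `"presence_cells"`, `"thinned"`.
#' @param records data.frame with columns `lon`, `lat`, `year` (cells are
#'   derived from the coordinates).
#' @param grid the [grid_spec()] records live on.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(kind, records, grid) {
  kind <- match.arg(kind, c("raw", "presence_cells", "thinned"))
  cell <- cell_of(grid, records$lon, records$lat)
  if (nrow(records) > 0 && anyNA(cell))
    stop("records outside the grid in an occurrence_set")
  records$cell <- cell
  if (kind != "raw" && anyDuplicated(cell))
    stop("kind '", kind, "' requires at most one record per cell")
  counts <- if (nrow(records) > 0) table(cell) else table(integer())
  structure(list(kind = kind, records = records, grid = grid,
                 cells = as.integer(names(counts)),
                 counts = as.integer(counts)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set:%s> %d records in %d cells\n",
              x$kind, nrow(x$records), length(x$cells)))
  invisible(x)
}

# Accept GBIF-style or plain column names; return lon/lat/year/issue.
normalize_occurrence_columns <- function(table) {
  nm <- names(table)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(table[[cand]])
    NULL
  }
  lon <- pick("decimalLongitude", "lon", "longitude")
  lat <- pick("decimalLatitude", "lat", "latitude")
  if (is.null(lon) || is.null(lat)) stop("no coordinate columns found")
  year <- pick("year")
  if (is.null(year)) year <- rep(NA_integer_, nrow(table))
  issue <- pick("issue", "issues", "flags")
  if (is.null(issue)) issue <- rep("", nrow(table))
  issue[is.na(issue)] <- ""
  data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
             year = suppressWarnings(as.integer(year)),
             issue = as.character(issue), stringsAsFactors = FALSE)
}

#' Filter an occurrence table into the raw data type
#'
#' The filtering pipeline, in order: (1) drop records with missing
#' coordinates, coordinates outside valid lon/lat ranges, or any quality
#' flag in the `issue` column; (2) count records dated within
#' `[year_lo, year_hi]` — if at least `min_recent` such records exist,
#' keep only those (records without a year are dropped too); otherwise
#' keep all years; (3) drop records whose cell is outside the native
#' region; (4) drop exact duplicates on (lon, lat, year) after rounding
#' coordinates to 1e-6 degrees.
#'
#' @param table occurrence data.frame (GBIF-style `decimalLongitude` /
#'   `decimalLatitude` / `year` columns, or plain `lon`/`lat`/`year`; an
#'   optional `issue` column flags geospatial problems with any
#'   non-empty string).
#' @param native a [region_mask()] defining the native region.
#' @param year_lo,year_hi temporal window (defaults 2000, 2020).
#' @param min_recent minimum number of in-window records required to
#'   activate the temporal filter (default 25).
#' @return an [occurrence_set()] of kind `"raw"`.
#' @export
filter_records <- function(table, native, year_lo = 2000, year_hi = 2020,
                           min_recent = 25) {
  stopifnot(inherits(native, "region_mask"))
  grid <- native$grid
  if (nrow(table) == 0)
    return(occurrence_set("raw", data.frame(lon = numeric(), lat = numeric(),
                                            year = integer()), grid))
  tab <- normalize_occurrence_columns(table)
  # (1) quality: coordinates present + in range, no flags
  ok <- !is.na(tab$lon) & !is.na(tab$lat) &
    tab$lon >= -180 & tab$lon <= 180 & tab$lat >= -90 & tab$lat <= 90 &
    tab$issue == ""
  tab <- tab[ok, , drop = FALSE]
  # (2) temporal filter, escaped when too few recent records
  recent <- !is.na(tab$year) & tab$year >= year_lo & tab$year <= year_hi
  if (sum(recent) >= min_recent) tab <- tab[recent, , drop = FALSE]
  # (3) native clipping
  cell <- cell_of(grid, tab$lon, tab$lat)
  keep <- !is.na(cell) & native$member[ifelse(is.na(cell), 1L, cell)]
  tab <- tab[keep, , drop = FALSE]
  # (4) dedup on rounded (lon, lat, year)
  key <- paste(round(tab$lon, 6), round(tab$lat, 6), tab$year, sep = "|")
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  occurrence_set("raw", tab[, c("lon", "lat", "year")], grid)
}

#' Count raw records per grid cell
#'
#' @param raw an [occurrence_set()] of kind `"raw"`.
#' @param grid a [grid_spec()] (defaults to the set's grid).
#' @return integer matrix of per-cell counts (zero where unoccupied).
#' @export
count_per_cell <- function(raw, grid = raw$grid) {
  stopifnot(raw$kind == "raw")
  out <- matrix(0L, grid$n_rows, grid$n_cols)
  if (length(raw$cells) > 0) out[raw$cells] <- raw$counts
  out
}

#' Collapse raw records to presence cells
#'
#' Keeps exactly one record per occupied cell — the cell's first record
#' in input order — so the set of occupied cells is unchanged.
#'
#' @param raw an [occurrence_set()] of kind `"raw"`.
#' @return an [occurrence_set()] of kind `"presence_cells"`.
#' @export
to_presence_cells <- function(raw) {
  stopifnot(raw$kind == "raw")
  keep <- !duplicated(raw$records$cell)
  occurrence_set("presence_cells",
                 raw$records[keep, c("lon", "lat", "year"), drop = FALSE],
                 raw$grid)
}

# pairwise haversine distances in km
haversine_km <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
}

#' Spatially thin presence cells
#'
#' Removes points until all pairwise great-circle distances are at least
#' `min_dist_cells * cell_size * 111.32` km (two 0.5-degree cells give
#' about 111.3 km, anchored to the equatorial cell width). Each of `reps`
#' randomized greedy runs repeatedly deletes a point with the most
#' remaining neighbours inside the exclusion distance (random
#' tie-break); the run retaining the most points wins. Deterministic for
#' a given seed. `min_dist_cells = 0` returns the input unchanged.
#'
#' @param presence_cells an [occurrence_set()] of kind `"presence_cells"`.
#' @param min_dist_cells minimum separation in cell widths (default 2).
#' @param reps number of randomized runs (default 10).
#' @param seed integer seed.
#' @return an [occurrence_set()] of kind `"thinned"`.
#' @export
thin <- function(presence_cells, min_dist_cells = 2, reps = 10, seed = 1) {
  stopifnot(presence_cells$kind == "presence_cells")
  if (reps < 1) stop("reps must be >= 1")
  rec <- presence_cells$records
  if (min_dist_cells == 0 || nrow(rec) <= 1) {
    return(occurrence_set("thinned",
                          rec[, c("lon", "lat", "year"), drop = FALSE],
                          presence_cells$grid))
  }
  thr_km <- min_dist_cells * presence_cells$grid$cell_size * 111.32
  d <- haversine_km(rec$lon, rec$lat)
  conflict <- d < thr_km
  diag(conflict) <- FALSE
  n <- nrow(rec)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(reps)) {
      active <- rep(TRUE, n)
      repeat {
        deg <- colSums(conflict[active, , drop = FALSE]) * active
        if (max(deg) == 0) break
        worst <- which(deg == max(deg))
        active[sample_one(worst)] <- FALSE
      }
      if (is.null(best) || sum(active) > sum(best)) best <- active
    }
  })
  occurrence_set("thinned",
                 rec[best, c("lon", "lat", "year"), drop = FALSE],
                 presence_cells$grid)
}

#' Moran's I of a gridded count field over the native region
#'
#' Global spatial autocorrelation with binary queen-contiguity weights
#' between native cells, `W` the total weight sum and no row
#' standardization: `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`. Native cells with zero counts are included.
#'
#' @param counts numeric matrix of per-cell counts on the mask's grid.
#' @param native a [region_mask()] with at least 2 member cells.
#' @return Moran's I (scalar).
#' @export
morans_index <- function(counts, native) {
  stopifnot(inherits(native, "region_mask"))
  M <- native$member
  if (sum(M) < 2) stop("Moran's I needs at least 2 native cells")
  x <- counts[M]
  if (var(x) == 0) stop("Moran undefined for constant field")
  nr <- nrow(M); nc <- ncol(M)
  Z <- counts - mean(x)
  Z[!M] <- 0
  num <- 0; W <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r_a <- max(1, 1 - dr):min(nr, nr - dr)
    c_a <- max(1, 1 - dc):min(nc, nc - dc)
    r_b <- r_a + dr
    c_b <- c_a + dc
    pair <- M[r_a, c_a, drop = FALSE] & M[r_b, c_b, drop = FALSE]
    num <- num + sum(Z[r_a, c_a, drop = FALSE][pair] *
                       Z[r_b, c_b, drop = FALSE][pair])
    W <- W + sum(pair)
  }
  if (W == 0) stop("no contiguous native cell pairs; Moran undefined")
  (sum(M) / W) * num / sum((x - mean(x))^2)
}
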