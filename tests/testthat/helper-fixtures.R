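# Shared fixture builders. Everything is generated in code at test time.

tiny_grid <- function(n_cols = 10, n_rows = 8, cell_size = 0.5,
                      lon_min = 0, lat_min = 0) {
  grid_spec(lon_min, lat_min, n_cols, n_rows, cell_size)
}

# a full-grid native region
full_mask <- function(grid) {
  region_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
}

# a one-layer stack with a west-east gradient on the grid
gradient_env <- function(grid, name = "BIO1") {
  vals <- matrix(rep(seq_len(grid$n_cols), each = grid$n_rows),
                 grid$n_rows, grid$n_cols)
  env_stack(grid, setNames(list(vals * 1.0), name))
}

# occurrence table rows at given cell ids (cell centers), clean by default
records_at_cells <- function(grid, cells, year = 2010) {
  cc <- cell_centers(grid, cells)
  data.frame(species = "sp",
             decimalLongitude = cc$lon, decimalLatitude = cc$lat,
             year = rep_len(year, length(cells)),
             stringsAsFactors = FALSE)
}

# a small world where every data type is comfortably eligible
eligible_world <- function(seed = 7, n_cols = 40, n_rows = 40) {
  g <- grid_spec(0, 0, n_cols, n_rows, 0.5)
  make_world(g, n_climate = 3, n_landcover = 1, n_blobs = 3, seed = seed)
}
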