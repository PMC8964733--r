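#' Synthetic worlds with known niches
#'
#' The generators in this file build seeded artificial study systems:
#' smooth bioclim-like environmental layers, land-cover fraction layers,
#' blob-shaped native-region masks, presence-only occurrence tables drawn
#' from a known suitability surface (optionally with sampling bias and
#' labelled contaminant records), and expert-style reference ranges
#' obtained by thresholding the true suitability. Every generator is a
#' pure function of its parameters and seed.
#'
#' @name synthetic
NULL

# A smooth standardized field: sum of low-frequency sinusoidal gradients
# plus kernel-smoothed Gaussian noise, standardized to mean 0 / sd 1.
smooth_field <- function(nr, nc, n_waves = 3, noise_weight = 0.35) {
  X <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr) / nr, times = nc), nr, nc)
  field <- matrix(0, nr, nc)
  for (k in seq_len(n_waves)) {
    amp <- runif(1, 0.5, 1)
    fx <- runif(1, -2, 2)
    fy <- runif(1, -2, 2)
    ph <- runif(1, 0, 2 * pi)
    field <- field + amp * sin(2 * pi * (fx * X + fy * Y) + ph)
  }
  noise <- matrix(rnorm(nr * nc), nr, nc)
  k <- rep(1 / 5, 5)
  sm <- t(apply(noise, 1, function(v) stats::filter(v, k, circular = TRUE)))
  sm <- apply(sm, 2, function(v) stats::filter(v, k, circular = TRUE))
  sm <- matrix(as.numeric(sm), nr, nc)
  field <- field + noise_weight * (sm - mean(sm)) / sd(sm)
  (field - mean(field)) / sd(field)
}

#' Generate a synthetic environmental stack
#'
#' Climate layers (`BIO1`, `BIO2`, ...) are smooth standardized fields;
#' land-cover layers (`LC1`, ...) are logistic transforms of smooth
#' fields, constrained to `[0, 1]`. With `correlated_pair = TRUE` the
#' second climate layer is built as a noisy copy of the first so that the
#' stack contains a strongly rank-correlated pair (useful for exercising
#' the collinearity pruning of the variable-selection step).
#'
#' @param grid a [grid_spec()].
#' @param n_climate,n_landcover number of climate / land-cover layers.
#' @param seed integer seed.
#' @param correlated_pair make layers `BIO1` and `BIO2` strongly
#'   rank-correlated (requires `n_climate >= 2`).
#' @return an [env_stack()].
#' @export
make_environment <- function(grid, n_climate = 4, n_landcover = 2, seed = 1,
                             correlated_pair = FALSE) {
  if (n_climate < 0 || n_landcover < 0 || n_climate + n_landcover < 1)
    stop("at least one layer must be requested")
  if (correlated_pair && n_climate < 2)
    stop("correlated_pair requires n_climate >= 2")
  with_seed(seed, {
    nr <- grid$n_rows; nc <- grid$n_cols
    layers <- list()
    for (i in seq_len(n_climate)) {
      layers[[paste0("BIO", i)]] <- smooth_field(nr, nc)
    }
    if (correlated_pair) {
      noisy <- layers$BIO1 + 0.1 * smooth_field(nr, nc)
      layers$BIO2 <- (noisy - mean(noisy)) / sd(noisy)
    }
    fracs <- character()
    for (i in seq_len(n_landcover)) {
      nm <- paste0("LC", i)
      layers[[nm]] <- plogis(1.2 * smooth_field(nr, nc))
      fracs <- c(fracs, nm)
    }
    env_stack(grid, layers, fraction_layers = fracs)
  })
}

#' Generate a blob-shaped native-region mask
#'
#' The mask is the union of `n_blobs` axis-aligned rectangles of cells,
#' standing in for the botanical-country polygons that define native
#' regions in real data. Blob sizes and placements are random unless
#' pinned down through `blob_cells`/`positions`, which tests use to build
#' masks with an exact cell count.
#'
#' @param grid a [grid_spec()].
#' @param n_blobs number of rectangles (>= 1).
#' @param seed integer seed.
#' @param blob_cells optional list of `c(width, height)` in cells, one per
#'   blob; default random sizes in 3..8 cells per side.
#' @param positions optional list of `c(row, col)` lower-left origins.
#' @param min_cells minimum acceptable member-cell count (default 9, the
#'   native-extent eligibility bound; lower it to construct sub-threshold
#'   masks on purpose).
#' @return a [region_mask()].
#' @export
make_native_region <- function(grid, n_blobs = 3, seed = 1, blob_cells = NULL,
                               positions = NULL, min_cells = 9) {
  if (n_blobs < 1) stop("n_blobs must be >= 1")
  with_seed(seed, {
    member <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (b in seq_len(n_blobs)) {
      wh <- if (!is.null(blob_cells)) blob_cells[[b]] else
        c(sample(3:8, 1), sample(3:8, 1))
      w <- wh[1]; h <- wh[2]
      if (w > grid$n_cols || h > grid$n_rows)
        stop("grid too small for requested blobs")
      org <- if (!is.null(positions)) positions[[b]] else
        c(sample.int(grid$n_rows - h + 1, 1), sample.int(grid$n_cols - w + 1, 1))
      member[org[1]:(org[1] + h - 1), org[2]:(org[2] + w - 1)] <- TRUE
    }
    if (sum(member) < min_cells)
      stop("native region smaller than min_cells; enlarge blobs")
    region_mask(grid, member)
  })
}

#' Specify a known species niche
#'
#' Suitability is `plogis(intercept + sum(beta * x) + sum(gamma * x^2))`
#' over the named environmental variables, so it lies strictly in (0, 1).
#' Negative `gamma` values give bell-shaped responses with an interior
#' optimum.
#'
#' @param active character vector of active variable codes.
#' @param beta linear coefficients, one per active variable.
#' @param gamma quadratic coefficients, one per active variable.
#' @param intercept scalar intercept.
#' @return object of class `niche_spec`.
#' @export
niche_spec <- function(active, beta, gamma = rep(0, length(active)),
                       intercept = 0) {
  if (length(active) < 1) stop("at least one active variable required")
  stopifnot(length(beta) == length(active), length(gamma) == length(active))
  structure(list(active = active, beta = beta, gamma = gamma,
                 intercept = intercept),
            class = "niche_spec")
}

#' True suitability surface of a niche on an environmental stack
#'
#' @param env an [env_stack()].
#' @param niche a [niche_spec()].
#' @return numeric matrix of suitabilities in (0, 1).
#' @export
true_suitability <- function(env, niche) {
  eta <- matrix(niche$intercept, env$grid$n_rows, env$grid$n_cols)
  for (i in seq_along(niche$active)) {
    x <- env$layers[[niche$active[i]]]
    if (is.null(x)) stop("niche variable not in stack: ", niche$active[i])
    eta <- eta + niche$beta[i] * x + niche$gamma[i] * x^2
  }
  plogis(eta)
}

# Accessibility-style bias field: distance decay from a few hotspots,
# plus a small baseline so no cell has zero access.
make_bias_layer <- function(grid, n_hotspots = 3) {
  nr <- grid$n_rows; nc <- grid$n_cols
  bias <- matrix(0.05, nr, nc)
  sigma <- max(nr, nc) / 8
  R <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  C <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (h in seq_len(n_hotspots)) {
    hr <- sample.int(nr, 1); hc <- sample.int(nc, 1)
    bias <- bias + exp(-((R - hr)^2 + (C - hc)^2) / (2 * sigma^2))
  }
  bias
}

#' Assemble a complete synthetic world
#'
#' Builds the environment, native region, bias layer and true suitability
#' for one artificial species. By default the niche is bell-shaped in the
#' first `n_active` climate variables (linear coefficient of magnitude
#' 1.5--2.5, negative quadratic term), leaving the remaining layers as
#' nuisance variables.
#'
#' @param grid a [grid_spec()].
#' @param n_climate,n_landcover layer counts passed to
#'   [make_environment()].
#' @param n_blobs blob count for [make_native_region()].
#' @param n_active number of climate variables the niche actually uses.
#' @param niche optional [niche_spec()] overriding the random niche.
#' @param n_hotspots hotspot count for the sampling-bias layer.
#' @param seed integer seed.
#' @param ... further arguments to [make_native_region()].
#' @return object of class `synthetic_world` with elements `env`,
#'   `native`, `niche`, `true_suitability`, `bias_layer`, `seed`.
#' @export
make_world <- function(grid, n_climate = 4, n_landcover = 2, n_blobs = 3,
                       n_active = 2, niche = NULL, n_hotspots = 3, seed = 1,
                       ...) {
  env <- make_environment(grid, n_climate, n_landcover, seed = sub_seed(seed, 1))
  native <- make_native_region(grid, n_blobs, seed = sub_seed(seed, 2), ...)
  world <- with_seed(sub_seed(seed, 3), {
    if (is.null(niche)) {
      active <- paste0("BIO", seq_len(min(n_active, n_climate)))
      niche <- niche_spec(
        active = active,
        beta = runif(length(active), 1.5, 2.5) *
          sample(c(-1, 1), length(active), replace = TRUE),
        gamma = -runif(length(active), 0.5, 1.5),
        intercept = 0)
    }
    bias <- make_bias_layer(grid, n_hotspots)
    list(niche = niche, bias = bias)
  })
  structure(list(env = env, native = native, niche = world$niche,
                 true_suitability = true_suitability(env, world$niche),
                 bias_layer = world$bias, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d, %d env layers, %d native cells, active: %s\n",
              x$seed, length(x$env$layers), sum(x$native$member),
              paste(x$niche$active, collapse = ", ")))
  invisible(x)
}

#' Simulate presence-only occurrence records from a known niche
#'
#' Cells are drawn (with replacement) from the native region with
#' probability proportional to `true_suitability * bias_layer^bias_strength`;
#' each record is jittered uniformly within its cell and dated with a
#' uniform year in `year_range`. A configurable fraction of labelled
#' contaminant records (missing coordinates, pre-2000 years, points
#' outside the native region, exact duplicates) is appended to exercise
#' the occurrence filters; the `contaminant_type` column identifies them
#' and is empty for clean records.
#'
#' @param world a [make_world()] result.
#' @param n_records number of clean records (>= 1).
#' @param year_range integer vector `c(first, last)` year.
#' @param bias_strength exponent on the bias layer (0 = unbiased).
#' @param contaminant_fraction fraction of `n_records` to append as
#'   contaminants (rotating through the four types).
#' @param seed integer seed.
#' @param species species name for the output table.
#' @return data.frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `year`, `contaminant_type`.
#' @export
simulate_species <- function(world, n_records, year_range = c(2000, 2020),
                             bias_strength = 0, contaminant_fraction = 0,
                             seed = 1, species = "Synthetica exempli") {
  if (n_records < 1) stop("n_records must be >= 1")
  grid <- world$env$grid
  native_idx <- mask_cells(world$native)
  w <- world$true_suitability[native_idx] *
    world$bias_layer[native_idx]^bias_strength
  if (all(w <= 0) || all(!is.finite(w))) stop("all-zero sampling weights")
  with_seed(seed, {
    cells <- native_idx[sample.int(length(native_idx), n_records,
                                   replace = TRUE, prob = w)]
    cc <- cell_centers(grid, cells)
    half <- grid$cell_size / 2
    lon <- cc$lon + runif(n_records, -half, half) * 0.999
    lat <- cc$lat + runif(n_records, -half, half) * 0.999
    year <- sample(seq(year_range[1], year_range[2]), n_records, replace = TRUE)
    tab <- data.frame(species = species,
                      decimalLongitude = lon, decimalLatitude = lat,
                      year = year, contaminant_type = "",
                      stringsAsFactors = FALSE)
    n_cont <- round(contaminant_fraction * n_records)
    if (n_cont > 0) {
      types <- rep(c("missing_coords", "old_year", "outside_native",
                     "duplicate"), length.out = n_cont)
      outside_idx <- which(!world$native$member)
      for (ty in types) {
        row <- tab[sample.int(n_records, 1), ]
        if (ty == "missing_coords") {
          row$decimalLongitude <- NA_real_
          row$decimalLatitude <- NA_real_
        } else if (ty == "old_year") {
          row$year <- sample(1980:1999, 1)
        } else if (ty == "outside_native") {
          if (length(outside_idx) == 0) next
          oc <- cell_centers(grid, sample_one(outside_idx))
          row$decimalLongitude <- oc$lon
          row$decimalLatitude <- oc$lat
        } # "duplicate": exact copy of a clean record
        row$contaminant_type <- ty
        tab <- rbind(tab, row)
      }
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Expert-style reference range from the true suitability
#'
#' Member cells are the native cells whose true suitability is at or
#' above the `q`-quantile (inverse-ECDF, so the q -> 0 limit recovers
#' the whole native region) of true suitability over native cells — a
#' synthetic stand-in for an expert-drawn range map.
#'
#' @param world a [make_world()] result.
#' @param quantile_q quantile in (0, 1).
#' @return a [region_mask()], always a subset of the native region.
#' @export
make_reference_range <- function(world, quantile_q = 0.5) {
  if (quantile_q <= 0 || quantile_q >= 1) stop("quantile_q must be in (0, 1)")
  suit <- world$true_suitability
  native <- world$native$member
  thr <- quantile(suit[native], quantile_q, type = 1)
  region_mask(world$env$grid, native & suit >= thr)
}
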