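# Shared fixtures, built in code. Everything is seeded and small.

# A tiny valid grid with a couple of nodata holes.
tiny_grid <- function(nr = 5, nc = 6, seed = 42, cell = 0.5,
                      lon0 = 10, lat0 = 20) {
  m <- withr::with_seed(seed, matrix(stats::rnorm(nr * nc, 10, 3), nr, nc))
  m[1, 2] <- NA
  m[nr, nc] <- NA
  coral_grid(m, lon0, lat0, cell)
}

# Small flat-bottomed bathymetry: constant depth, one land column west.
flat_bathymetry <- function(depth = 1000, nr = 8, nc = 10, cell = 0.1,
                            lon0 = 0, lat0 = 5) {
  z <- matrix(depth, nr, nc)
  z[, 1] <- NA
  bathymetry(coral_grid(z, lon0, lat0, cell))
}

# Inclined-plane bathymetry with depth increasing eastward at `grad` m per
# metre (built from the grid's own metre spacings so the plane is exact).
plane_bathymetry <- function(grad = 0.05, nr = 9, nc = 11, cell = 0.02,
                             lat0 = 1) {
  mdeg <- 6371000 * pi / 180
  lat <- lat0 - (seq_len(nr) - 0.5) * cell
  # use the equator-free small grid near lat ~ 1 deg: dx nearly constant;
  # build the plane in *column index* with the row-specific dx so Horn's
  # x-gradient is exact per row.
  z <- outer(seq_len(nr), seq_len(nc), function(i, j) {
    1000 + grad * (j - 1) * mdeg * cos(lat[i] * pi / 180) * cell
  })
  bathymetry(coral_grid(z, 0, lat0, cell))
}

# The standard synthetic study world used across model-level tests.
fixture_world <- function(seed = 101) {
  simulate_world(synthetic_world_config(seed = seed))
}

fixture_stack <- function(world, idw = idw_config()) {
  layers <- lapply(world$fields, drape_zbins, bathy = world$bathy, config = idw)
  layers$depth <- coral_grid(world$bathy$values, world$bathy$lon_origin,
                             world$bathy$lat_origin, world$bathy$cell_size)
  layer_stack(layers)
}

# Brute-force all-pairs presence-background AUC oracle (ties count 1/2).
auc_oracle <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(p) * length(b))
}

# Per-cell drape oracle: for each sea cell, find the interval containing its
# depth (deeper-than-deepest -> last) and read the resampled slice directly.
drape_oracle <- function(field, bathy, config = idw_config()) {
  gt <- geotransform(bathy)
  resampled <- lapply(field$slices, function(s) {
    resample_nearest(idw_interpolate(s, config), gt)$values
  })
  out <- matrix(NA_real_, gt$n_rows, gt$n_cols)
  n_iv <- nrow(field$intervals)
  for (i in seq_len(gt$n_rows)) {
    for (j in seq_len(gt$n_cols)) {
      d <- bathy$values[i, j]
      if (is.na(d)) next
      k <- NA
      for (s in seq_len(n_iv)) {
        if (d >= field$intervals$top[s] && d < field$intervals$bottom[s]) { k <- s; break }
      }
      if (is.na(k) && d >= field$intervals$bottom[n_iv]) k <- n_iv
      if (!is.na(k)) out[i, j] <- resampled[[k]][i, j]
    }
  }
  out
}

# A random small z-binned field + bathymetry pair for property tests.
random_world_pair <- function(seed) {
  withr::with_seed(seed, {
    nr <- sample(8:14, 1); nc <- sample(10:18, 1)
    cell <- 0.1
    z <- matrix(stats::runif(nr * nc, 10, 3000), nr, nc)
    z[sample(nr * nc, 3)] <- NA
    bathy <- bathymetry(coral_grid(z, 0, 10, cell))
    fgt <- list(n_rows = ceiling(nr / 3), n_cols = ceiling(nc / 3),
                lon_origin = 0, lat_origin = 10, cell_size = 0.3)
    field <- make_zbinned_field("var", c(0, 500, 1500), fgt,
                                base = 5, lat_gradient = 2, lat_ref = 9,
                                depth_scale = 10, depth_efolding = 600,
                                noise_sd = 0.5, seed = seed + 1)
    list(bathy = bathy, field = field)
  })
}
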