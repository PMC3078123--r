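# Synthetic-world generators. These produce inputs with the statistical
# structure the analysis assumes — shelf/slope/abyssal bathymetry with
# seamounts, smooth depth-binned climatology fields with latitudinal
# gradients, presences drawn from a known (planted) niche and noisy bottle
# stations — so every pipeline stage can be exercised, and its ability to
# recover the planted truth measured, without any external datasets.

#' Synthetic world configuration
#'
#' Defaults define the package's standard desk-scale study area: a 60 x 80
#' grid at 0.05 degrees (a 3 x 4 degree mid-latitude window) with a western
#' land margin, a 200 m shelf dropping to a 4000 m abyssal plain, six
#' seamounts and 30 m of depth noise.
#'
#' @param n_rows,n_cols grid size.
#' @param cell_size_deg cell size in degrees.
#' @param lon_origin,lat_origin NW corner of the grid (degrees).
#' @param land_margin_cols columns of land (nodata) at the western edge.
#' @param shelf_depth,abyssal_depth metres (0 < shelf < abyssal).
#' @param shelf_cols,slope_cols columns of shelf and of the shelf-to-abyss
#'   ramp east of the land margin.
#' @param n_seamounts number of Gaussian seamounts on the abyssal plain.
#' @param seamount_height metres of relief at a seamount summit.
#' @param noise_sd standard deviation (m) of additive depth noise.
#' @param seed integer seed; every generated artifact is reproducible per
#'   seed.
#' @return list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_rows = 60, n_cols = 80,
                                   cell_size_deg = 0.05,
                                   lon_origin = 0, lat_origin = 50,
                                   land_margin_cols = 6,
                                   shelf_depth = 200, abyssal_depth = 4000,
                                   shelf_cols = 12, slope_cols = 20,
                                   n_seamounts = 6, seamount_height = 2500,
                                   noise_sd = 30, seed = 1L) {
  stopifnot(shelf_depth > 0, abyssal_depth > shelf_depth, n_seamounts >= 0,
            n_rows >= 3, n_cols > land_margin_cols + shelf_cols + slope_cols)
  structure(
    as.list(environment()),
    class = "synthetic_world_config"
  )
}

#' Generate synthetic bathymetry
#'
#' West-to-east structure: a land margin (nodata), a shallow shelf, a linear
#' shelf-to-abyss ramp, then an abyssal plain studded with Gaussian-bump
#' seamounts at seeded random positions, plus seeded depth noise. Depths are
#' positive down and floored at 5 m so every sea cell stays submerged.
#'
#' @param config a [synthetic_world_config()].
#' @return a `bathymetry`.
#' @export
make_bathymetry <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  withr::with_seed(config$seed, {
    nr <- config$n_rows; nc <- config$n_cols
    profile <- numeric(nc)
    sea0 <- config$land_margin_cols + 1
    shelf_end <- config$land_margin_cols + config$shelf_cols
    slope_end <- shelf_end + config$slope_cols
    profile[sea0:shelf_end] <- config$shelf_depth
    ramp <- seq(config$shelf_depth, config$abyssal_depth,
                length.out = slope_end - shelf_end + 2)[-1]
    profile[(shelf_end + 1):slope_end] <- ramp[-length(ramp)]
    profile[(slope_end + 1):nc] <- config$abyssal_depth
    z <- matrix(rep(profile, each = nr), nr, nc)
    if (config$n_seamounts > 0) {
      for (s in seq_len(config$n_seamounts)) {
        ci <- sample((slope_end + 3):(nc - 2), 1)
        ri <- sample(3:(nr - 2), 1)
        sigma <- stats::runif(1, 2, 6)  # cells
        rr <- matrix(seq_len(nr), nr, nc)
        cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
        bump <- config$seamount_height * exp(-((rr - ri)^2 + (cc - ci)^2) / (2 * sigma^2))
        z <- z - bump
      }
    }
    if (config$noise_sd > 0) z <- z + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    z <- pmax(z, 5)
    z[, seq_len(config$land_margin_cols)] <- NA_real_
    bathymetry(coral_grid(z, config$lon_origin, config$lat_origin,
                          config$cell_size_deg))
  })
}

#' Generate a synthetic z-binned climatology field
#'
#' Each depth slice is a latitudinal linear gradient plus a depth-dependent
#' exponential decay and seeded cell noise:
#' `value = base + lat_gradient * (lat - lat_ref) + depth_scale *
#' exp(-depth / depth_efolding) + N(0, noise_sd)`, evaluated at the slice's
#' level depth. Slices live on their own (typically coarser) geotransform to
#' exercise the interpolation/resampling path of the up-scaling pipeline.
#'
#' @param name variable name.
#' @param depth_levels level depths in metres, increasing.
#' @param geotransform geotransform list for the native slice grids.
#' @param base value at the reference latitude and infinite depth.
#' @param lat_gradient units per degree latitude.
#' @param lat_ref reference latitude (degrees).
#' @param depth_scale amplitude of the depth decay (value units).
#' @param depth_efolding e-folding depth (m) of the decay.
#' @param noise_sd per-cell noise standard deviation.
#' @param seed integer seed.
#' @param single_level_bottom passed to [depth_intervals()].
#' @return a `zbinned_field` (original level depths attached as attribute
#'   `depths_m`).
#' @export
make_zbinned_field <- function(name, depth_levels, geotransform,
                               base = 2, lat_gradient = 0, lat_ref = 48.5,
                               depth_scale = 18, depth_efolding = 800,
                               noise_sd = 0, seed = 1L,
                               single_level_bottom = 11000) {
  if (length(depth_levels) < 1) stop("need at least one depth level")
  gt <- geotransform
  lat <- gt$lat_origin - (seq_len(gt$n_rows) - 0.5) * gt$cell_size
  slices <- withr::with_seed(as.integer(seed), {
    lapply(depth_levels, function(z) {
      v <- base + lat_gradient * (lat - lat_ref) + depth_scale * exp(-z / depth_efolding)
      m <- matrix(v, gt$n_rows, gt$n_cols)
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                        gt$n_rows, gt$n_cols)
      coral_grid(m, gt$lon_origin, gt$lat_origin, gt$cell_size)
    })
  })
  out <- zbinned_field(name, depth_intervals(depth_levels, single_level_bottom), slices)
  attr(out, "depths_m") <- depth_levels
  out
}

#' Planted niche truth
#'
#' A Gaussian-product response: true suitability of a cell is
#' `baseline * prod_v exp(-(x_v - optimum_v)^2 / (2 tolerance_v^2))` over the
#' named variables. Variables not named do not affect suitability.
#'
#' @param optima named numeric vector of response optima.
#' @param tolerances named numeric vector of response widths (> 0), same
#'   names.
#' @param baseline baseline prevalence in (0, 1].
#' @return list of class `niche_truth`.
#' @export
niche_truth <- function(optima, tolerances, baseline = 1) {
  stopifnot(length(optima) == length(tolerances),
            identical(names(optima), names(tolerances)),
            all(tolerances > 0), baseline > 0, baseline <= 1)
  structure(list(optima = optima, tolerances = tolerances, baseline = baseline),
            class = "niche_truth")
}

#' True suitability of covariate vectors under a planted niche
#'
#' @param truth a [niche_truth()].
#' @param covariates tibble/matrix with columns covering the truth's
#'   variables.
#' @return numeric vector of suitabilities in (0, 1].
#' @export
true_suitability <- function(truth, covariates) {
  X <- tibble::as_tibble(as.data.frame(covariates))
  s <- rep(truth$baseline, nrow(X))
  for (v in names(truth$optima)) {
    s <- s * exp(-(X[[v]] - truth$optima[[v]])^2 / (2 * truth$tolerances[[v]]^2))
  }
  s
}

#' Sample presences from a planted niche
#'
#' Computes true suitability on every jointly valid stack cell and samples
#' `n` distinct cells with probability proportional to suitability (without
#' replacement, so the one-presence-per-cell rule holds by construction).
#'
#' @param stack a `layer_stack`.
#' @param truth a [niche_truth()].
#' @param n number of presences.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return a `presence_set`.
#' @export
make_presences <- function(stack, truth, n, seed = 1L, species = "synthetic_coral") {
  cells <- as_tibble.layer_stack(stack)
  if (nrow(cells) < n) stop("fewer valid cells than requested presences")
  s <- true_suitability(truth, cells[, setdiff(names(cells), c("row", "col", "lon", "lat"))])
  idx <- withr::with_seed(as.integer(seed), sample.int(nrow(cells), n, prob = s))
  picked <- cells[idx, ]
  new_presence_set(
    tibble::tibble(species = species, lon = picked$lon, lat = picked$lat,
                   row = picked$row, col = picked$col),
    geotransform(stack$layers[[1]]), species
  )
}

#' Generate synthetic bottle stations
#'
#' Seeded random sea locations (one per sampled cell, jittered inside the
#' cell); each station's depth is its cell's seafloor depth, and its value is
#' the native-field value for the depth interval containing that depth at
#' the station's native cell, plus Gaussian measurement noise.
#'
#' @param field a `zbinned_field`.
#' @param bathy a `bathymetry`.
#' @param n number of stations.
#' @param noise_sd measurement noise standard deviation.
#' @param seed integer seed.
#' @return tibble with `lon`, `lat`, `depth`, `value`.
#' @export
make_stations <- function(field, bathy, n, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(field, "zbinned_field"), inherits(bathy, "bathymetry"), n >= 1)
  sea <- which(sea_mask(bathy))
  if (length(sea) < n) stop("fewer sea cells than requested stations")
  withr::with_seed(as.integer(seed), {
    pick <- sample(sea, n)
    nr <- nrow(bathy$values)
    row <- ((pick - 1) %% nr) + 1
    col <- ((pick - 1) %/% nr) + 1
    cs <- bathy$cell_size
    lon <- lon_centers(bathy)[col] + stats::runif(n, -0.499, 0.499) * cs
    lat <- lat_centers(bathy)[row] + stats::runif(n, -0.499, 0.499) * cs
    depth <- bathy$values[cbind(row, col)]
    iv <- findInterval(depth, c(field$intervals$top, Inf), rightmost.closed = FALSE)
    iv <- pmin(pmax(iv, 1L), nrow(field$intervals))
    idx <- cell_index(field$slices[[1]], lon, lat)
    value <- vapply(seq_len(n), function(i) {
      field$slices[[iv[i]]]$values[idx$row[i], idx$col[i]]
    }, numeric(1))
    if (noise_sd > 0) value <- value + stats::rnorm(n, 0, noise_sd)
    tibble::tibble(lon = lon, lat = lat, depth = depth, value = value)
  })
}

#' Generate the complete synthetic study fixture
#'
#' One call produces everything a full pipeline run needs: bathymetry, three
#' z-binned fields (temperature with a strong depth decay and latitudinal
#' gradient, salinity and dissolved oxygen with weaker structure), the
#' planted temperature niche (optimum 8, tolerance 2 — the envelope typical
#' of framework-forming cold-water corals), presences drawn from it, and
#' noisy validation stations for temperature.
#'
#' @param config a [synthetic_world_config()].
#' @param n_presences presences to sample.
#' @param n_stations validation stations to sample.
#' @param station_noise_sd measurement noise of station values.
#' @param field_cell_size_deg native cell size of the z-binned fields
#'   (coarser than the bathymetry to exercise resampling).
#' @param depth_levels level depths of the z-binned fields.
#' @return list with `config`, `bathy`, `fields` (list of `zbinned_field`),
#'   `truth`, and the seeds used, of class `synthetic_world`. Presences and
#'   stations are *not* drawn here; see [make_presences()]/[make_stations()]
#'   — [run_all()] wires the full set together.
#' @export
simulate_world <- function(config = synthetic_world_config(),
                           field_cell_size_deg = 0.25,
                           depth_levels = c(0, 100, 300, 700, 1500, 3000, 5000)) {
  config$seed <- as.integer(as.numeric(config$seed) %% 2000000000)
  bathy <- make_bathymetry(config)
  ext_lon <- config$n_cols * config$cell_size_deg
  ext_lat <- config$n_rows * config$cell_size_deg
  fgt <- list(
    n_rows = as.integer(ceiling(ext_lat / field_cell_size_deg)),
    n_cols = as.integer(ceiling(ext_lon / field_cell_size_deg)),
    lon_origin = config$lon_origin, lat_origin = config$lat_origin,
    cell_size = field_cell_size_deg
  )
  lat_mid <- config$lat_origin - ext_lat / 2
  fields <- list(
    temperature = make_zbinned_field(
      "temperature", depth_levels, fgt,
      base = 2, lat_gradient = -0.8, lat_ref = lat_mid,
      depth_scale = 18, depth_efolding = 700,
      noise_sd = 0.1, seed = config$seed + 11L
    ),
    salinity = make_zbinned_field(
      "salinity", depth_levels, fgt,
      base = 34.7, lat_gradient = 0.15, lat_ref = lat_mid,
      depth_scale = 0.8, depth_efolding = 1200,
      noise_sd = 0.05, seed = config$seed + 12L
    ),
    oxygen = make_zbinned_field(
      "oxygen", depth_levels, fgt,
      base = 5.5, lat_gradient = 0.05, lat_ref = lat_mid,
      depth_scale = -2.5, depth_efolding = 500,
      noise_sd = 0.08, seed = config$seed + 13L
    )
  )
  truth <- niche_truth(optima = c(temperature = 8), tolerances = c(temperature = 2))
  structure(
    list(config = config, bathy = bathy, fields = fields, truth = truth),
    class = "synthetic_world"
  )
}
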