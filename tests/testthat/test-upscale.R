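test_that("IDW reproduces data sites exactly and stays within neighbour bounds", {
  # single valid source cell -> constant field
  m <- matrix(NA_real_, 3, 3); m[2, 2] <- 7
  g <- coral_grid(m, 0, 3, 1)
  out <- idw_interpolate(g, idw_config(intermediate_cell_size_deg = 0.5))
  expect_true(all(out$values == 7))

  # exactness at source cell centers: intermediate grid coincides with source
  src <- tiny_grid(nr = 4, nc = 5, cell = 0.1, lon0 = 0, lat0 = 2)
  out <- idw_interpolate(src, idw_config(intermediate_cell_size_deg = 0.1))
  ok <- !is.na(src$values)
  expect_equal(out$values[ok], src$values[ok])

  # bounded by neighbour values
  rng <- range(src$values, na.rm = TRUE)
  expect_true(all(out$values >= rng[1] - 1e-12 & out$values <= rng[2] + 1e-12))

  expect_error(idw_interpolate(coral_grid(matrix(NA_real_, 2, 2), 0, 1, 0.5)),
               "no valid cells")
})

test_that("IDW midpoint between two equal-distance sources averages their values", {
  # two cells, values 2 and 4, centers 1 deg apart on one row
  m <- matrix(NA_real_, 1, 4)
  m[1, 1] <- 2; m[1, 3] <- 4
  g <- coral_grid(m, 0, 1, 1)
  # 1-deg intermediate grid puts an output center at lon 1.5, the exact
  # midpoint of the two source centers (0.5 and 2.5): weights are equal
  out <- idw_interpolate(g, idw_config(power = 2, max_neighbors = 2,
                                       intermediate_cell_size_deg = 1))
  expect_equal(lon_centers(out)[2], 1.5)
  expect_equal(out$values[1, 2], 3)
})

test_that("draping selects the slice containing each cell's depth (per-cell oracle)", {
  for (seed in 1:20) {
    wp <- random_world_pair(seed)
    cfg <- idw_config()
    expect_identical(drape_zbins(wp$field, wp$bathy, cfg)$values,
                     drape_oracle(wp$field, wp$bathy, cfg))
  }
})

test_that("draping covers all sea cells, masks land, and extends the deepest bin downward", {
  b <- flat_bathymetry(depth = 6000)  # deeper than the deepest interval
  fgt <- list(n_rows = 2, n_cols = 3, lon_origin = 0, lat_origin = 5, cell_size = 0.4)
  slices <- lapply(c(10, 20, 30), function(v)
    coral_grid(matrix(v, 2, 3), 0, 5, 0.4))
  f <- zbinned_field("v", depth_intervals(c(0, 1000, 5000)), slices)
  out <- drape_zbins(f, b)
  expect_equal(out$values[sea_mask(b)],
               rep(30, sum(sea_mask(b))))  # deepest slice's value
  expect_true(all(is.na(out$values[!sea_mask(b)])))

  # single slice covering everything -> constant over sea
  f1 <- zbinned_field("v", depth_intervals(500, single_level_bottom = 10000),
                      slices[1])
  out1 <- drape_zbins(f1, flat_bathymetry(depth = 800))
  expect_equal(out1$values[!is.na(out1$values)],
               rep(10, sum(!is.na(out1$values))))
})

test_that("draping is cellwise monotone in the slice values", {
  wp <- random_world_pair(31)
  fA <- wp$field
  fB <- zbinned_field(fA$variable, fA$intervals, lapply(fA$slices, function(s)
    coral_grid(s$values - abs(stats::rnorm(length(s$values), 2, 1)),
               s$lon_origin, s$lat_origin, s$cell_size)))
  a <- drape_zbins(fA, wp$bathy)$values
  b <- drape_zbins(fB, wp$bathy)$values
  ok <- !is.na(a) & !is.na(b)
  expect_true(all(a[ok] >= b[ok]))
})

test_that("surface up-scaling equals draping a single all-depth slice", {
  b <- fixture_world(11)$bathy
  src <- tiny_grid(nr = 6, nc = 8, cell = 0.5, lon0 = 0, lat0 = 50, seed = 8)
  src$values[is.na(src$values)] <- 1  # fully valid surface product
  cfg <- idw_config()
  surf <- upscale_surface(src, b, cfg)
  f1 <- zbinned_field("s", depth_intervals(0, single_level_bottom = 1e5), list(src))
  expect_equal(surf$values, drape_zbins(f1, b, cfg)$values)
  expect_true(all(is.na(surf$values[!sea_mask(b)])))
})

test_that("slope is zero on flat seafloor and arctan(g) on an inclined plane", {
  expect_true(all(abs(na.omit(as.vector(terrain_slope(flat_bathymetry())$values))) < 1e-12))
  grad <- 0.05
  s <- terrain_slope(plane_bathymetry(grad))$values
  interior <- s[3:7, 3:9]
  expect_equal(as.vector(interior), rep(atan(grad), length(interior)), tolerance = 1e-3)
  expect_error(terrain_slope(flat_bathymetry(nr = 2, nc = 2)), "3x3")
})

test_that("slope matches a hand evaluation of Horn's stencil at one cell", {
  z <- matrix(c(100, 120, 130,
                110, 150, 160,
                105, 140, 170), 3, 3, byrow = TRUE)
  b <- bathymetry(coral_grid(z, 0, 0.02, 0.01))
  mdeg <- 6371000 * pi / 180
  lat2 <- 0.02 - 1.5 * 0.01
  dx <- mdeg * cos(lat2 * pi / 180) * 0.01
  dy <- mdeg * 0.01
  gx <- ((z[1, 3] + 2 * z[2, 3] + z[3, 3]) - (z[1, 1] + 2 * z[2, 1] + z[3, 1])) / (8 * dx)
  gy <- ((z[3, 1] + 2 * z[3, 2] + z[3, 3]) - (z[1, 1] + 2 * z[1, 2] + z[1, 3])) / (8 * dy)
  expect_equal(terrain_slope(b)$values[2, 2], atan(sqrt(gx^2 + gy^2)))
})

test_that("windowed slope preserves planes and equals slope after an explicit moving average", {
  expect_true(all(abs(na.omit(as.vector(
    windowed_slope(flat_bathymetry(), 20)$values))) < 1e-12))

  grad <- 0.03
  b <- plane_bathymetry(grad, nr = 13, nc = 15)
  ws <- windowed_slope(b, 5)$values
  # interior cells whose smoothing window is complete
  expect_equal(as.vector(ws[5:9, 5:11]), rep(atan(grad), 35), tolerance = 1e-3)

  # two-step oracle: explicit moving average then slope
  wb <- fixture_world(5)$bathy
  kx_ky <- coralniche:::window_radii_cells(wb, 20)
  sm <- coralniche:::window_mean(wb$values, kx_ky$kx, kx_ky$ky)
  oracle <- terrain_slope(bathymetry(coral_grid(sm, wb$lon_origin, wb$lat_origin,
                                                wb$cell_size)))$values
  expect_equal(windowed_slope(wb, 20)$values, oracle)

  expect_warning(tiny_ws <- windowed_slope(b, 1e-4), "falling back")
  expect_equal(tiny_ws$values, terrain_slope(b)$values)
})

test_that("rugosity is 1 on flat seafloor, >= 1 everywhere, and matches a Heron-formula oracle", {
  r <- rugosity(flat_bathymetry(), 5)$values
  expect_equal(na.omit(as.vector(r)), rep(1, sum(!is.na(r))), ignore_attr = TRUE)

  wb <- fixture_world(3)$bathy
  rv <- rugosity(wb, 5)$values
  expect_true(all(rv[!is.na(rv)] >= 1 - 1e-12))

  # single-cell pyramid: center raised h above a flat 3x3 neighbourhood;
  # oracle computes the 8 facet areas from 3-D side lengths via Heron.
  h <- 500
  z <- matrix(1000, 3, 3); z[2, 2] <- 1000 - h
  b <- bathymetry(coral_grid(z, 0, 0.001, 0.001))
  sp <- coralniche:::row_spacings(b)
  dx <- sp$dx[2]; dy <- sp$dy
  corners <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                  c(0, -1), c(-1, -1))
  heron <- function(a, b_, c_) {
    s <- (a + b_ + c_) / 2
    sqrt(s * (s - a) * (s - b_) * (s - c_))
  }
  pt <- function(d) c(d[2] * dx, -d[1] * dy, h)  # neighbour relative to center
  area <- 0
  for (k in 1:8) {
    p1 <- pt(corners[[k]]) / 2           # midpoint towards neighbour k
    p2 <- pt(corners[[if (k == 8) 1 else k + 1]]) / 2
    area <- area + heron(sqrt(sum(p1^2)), sqrt(sum(p2^2)), sqrt(sum((p1 - p2)^2)))
  }
  expect_equal(rugosity(b, 1e-9 + 0.001 * 111000 / 1000)$values[2, 2],
               area / (dx * dy), tolerance = 1e-9)
})

test_that("BPI is zero on flat seafloor, positive on summits, and equals a neighbourhood-mean oracle", {
  expect_true(all(abs(na.omit(as.vector(bpi(flat_bathymetry(), 10)$values))) < 1e-12))

  # isolated seamount summit: shallower than surroundings -> positive
  z <- matrix(3000, 7, 7); z[4, 4] <- 500
  b <- bathymetry(coral_grid(z, 0, 0.07, 0.01))
  expect_gt(bpi(b, 3)$values[4, 4], 0)

  wb <- fixture_world(13)$bathy
  got <- bpi(wb, 10)$values
  kr <- coralniche:::window_radii_cells(wb, 10)
  i <- 20; j <- 40
  r0 <- max(1, i - kr$ky); r1 <- min(nrow(wb$values), i + kr$ky)
  c0 <- max(1, j - kr$kx[i]); c1 <- min(ncol(wb$values), j + kr$kx[i])
  nb <- wb$values[r0:r1, c0:c1]
  oracle <- (sum(nb, na.rm = TRUE) - wb$values[i, j]) / (sum(!is.na(nb)) - 1) -
    wb$values[i, j]
  expect_equal(got[i, j], oracle)
})
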