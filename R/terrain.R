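# Benthic terrain variables derived from bathymetry: slope (Horn's method),
# slope of a smoothed surface at a km-scale window, rugosity
# (surface-area/planar-area, triangulated facets) and bathymetric position
# index. Degree spacings are converted to metres per row (spherical Earth,
# radius 6371 km), so east-west cell widths shrink with latitude.

# Shift a matrix by (dr, dc), padding with NA.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

# Per-row metre spacings of a grid: list(dx = vector by row, dy = scalar).
row_spacings <- function(grid) {
  lat <- lat_centers(grid)
  list(
    dx = METERS_PER_DEGREE * cos(lat * pi / 180) * grid$cell_size,
    dy = METERS_PER_DEGREE * grid$cell_size
  )
}

#' Seafloor slope (radians)
#'
#' Slope of the depth surface from a 3x3 finite-difference gradient with
#' Horn's weights; cells whose 3x3 neighbourhood is incomplete (edges, or
#' adjacent to nodata) are nodata. East-west spacing is computed per row from
#' the cell latitude.
#'
#' @param bathy a `bathymetry` (at least 3x3).
#' @return a `coral_grid` of slope in radians.
#' @export
terrain_slope <- function(bathy) {
  stopifnot(inherits(bathy, "bathymetry"))
  z <- bathy$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid smaller than 3x3")
  sp <- row_spacings(bathy)
  # Neighbours named after compass directions; row 1 is north.
  nw <- shift_mat(z, -1, -1); n_ <- shift_mat(z, -1, 0); ne <- shift_mat(z, -1, 1)
  w_ <- shift_mat(z, 0, -1);                              e_ <- shift_mat(z, 0, 1)
  sw <- shift_mat(z, 1, -1);  s_ <- shift_mat(z, 1, 0);  se <- shift_mat(z, 1, 1)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * sp$dx)  # recycles dx by row
  gy <- ((sw + 2 * s_ + se) - (nw + 2 * n_ + ne)) / (8 * sp$dy)
  slope <- atan(sqrt(gx^2 + gy^2))
  slope[is.na(z)] <- NA_real_
  coral_grid(slope, bathy$lon_origin, bathy$lat_origin, bathy$cell_size, bathy$nodata)
}

# Window radii in whole cells for a km radius: y radius scalar, x radius per
# row (at least 1 cell each).
window_radii_cells <- function(grid, radius_km) {
  sp <- row_spacings(grid)
  list(
    kx = pmax(1L, as.integer(round(radius_km * 1000 / sp$dx))),
    ky = max(1L, as.integer(round(radius_km * 1000 / sp$dy)))
  )
}

# Moving-average of depth over a square window of per-row x-radius kx and
# y-radius ky (cells), ignoring NA neighbours; NA where the center is NA.
window_mean <- function(z, kx, ky, exclude_center = FALSE) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    r0 <- max(1, i - ky); r1 <- min(nr, i + ky)
    k <- kx[i]
    for (j in seq_len(nc)) {
      if (is.na(z[i, j])) next
      c0 <- max(1, j - k); c1 <- min(nc, j + k)
      block <- z[r0:r1, c0:c1]
      s <- sum(block, na.rm = TRUE)
      n <- sum(!is.na(block))
      if (exclude_center) { s <- s - z[i, j]; n <- n - 1 }
      if (n > 0) out[i, j] <- s / n
    }
  }
  out
}

#' Slope at a km-scale moving window
#'
#' Slope of the depth surface after smoothing with a moving average whose
#' radius is given in kilometres and converted to whole cells per row from
#' the latitude-dependent metres-per-degree (minimum one cell). A window
#' smaller than one cell falls back to [terrain_slope()] with a warning.
#'
#' @param bathy a `bathymetry`.
#' @param radius_km window radius in kilometres (the field convention uses 5,
#'   20, 30 and 100 km).
#' @return a `coral_grid` of slope in radians.
#' @export
windowed_slope <- function(bathy, radius_km) {
  stopifnot(inherits(bathy, "bathymetry"), radius_km > 0)
  sp <- row_spacings(bathy)
  if (radius_km * 1000 < min(sp$dx) / 2 && radius_km * 1000 < sp$dy / 2) {
    warning("window smaller than one cell; falling back to terrain_slope()")
    return(terrain_slope(bathy))
  }
  kr <- window_radii_cells(bathy, radius_km)
  sm <- window_mean(bathy$values, kr$kx, kr$ky)
  smooth_bathy <- bathymetry(coral_grid(sm, bathy$lon_origin, bathy$lat_origin,
                                        bathy$cell_size, bathy$nodata))
  terrain_slope(smooth_bathy)
}

# Jenness-style per-cell surface area: eight 3-D triangles joining the cell
# center to midpoints towards its eight neighbours; NA when the 3x3
# neighbourhood is incomplete. Uses a local planar frame per cell row.
cell_surface_area <- function(bathy) {
  z <- bathy$values
  sp <- row_spacings(bathy)
  dirs <- list(
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  )  # N, NE, E, SE, S, SW, W, NW (circular)
  nr <- nrow(z); nc <- ncol(z)
  # Midpoint offset components for each direction, per cell (matrices).
  mx <- vector("list", 8); my <- vector("list", 8); mz <- vector("list", 8)
  for (d in seq_along(dirs)) {
    dr <- dirs[[d]][1]; dc <- dirs[[d]][2]
    zn <- shift_mat(z, dr, dc)
    mx[[d]] <- matrix(rep(dc * sp$dx / 2, nc), nr, nc)
    my[[d]] <- matrix(-dr * sp$dy / 2, nr, nc)
    mz[[d]] <- (zn - z) / 2
  }
  area <- matrix(0, nr, nc)
  for (d in seq_len(8)) {
    e <- if (d == 8) 1 else d + 1
    # cross product of the two midpoint vectors, elementwise over cells
    cx <- my[[d]] * mz[[e]] - mz[[d]] * my[[e]]
    cy <- mz[[d]] * mx[[e]] - mx[[d]] * mz[[e]]
    cz <- mx[[d]] * my[[e]] - my[[d]] * mx[[e]]
    area <- area + 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  area  # NA wherever any neighbour was NA
}

#' Rugosity (surface-area to planar-area ratio)
#'
#' Ratio of triangulated seafloor surface area to planar area within a
#' km-radius window. Per-cell surface areas come from eight 3-D facets
#' joining the cell center to midpoints towards its neighbours; the window
#' ratio sums facet areas over cells with a defined area and divides by the
#' matching planar area. Flat seafloor gives exactly 1; every valid value is
#' >= 1.
#'
#' @param bathy a `bathymetry` (at least 3x3).
#' @param radius_km window radius in kilometres.
#' @return a `coral_grid`.
#' @export
rugosity <- function(bathy, radius_km) {
  stopifnot(inherits(bathy, "bathymetry"), radius_km > 0)
  z <- bathy$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid smaller than 3x3")
  sa <- cell_surface_area(bathy)
  sp <- row_spacings(bathy)
  planar <- matrix(rep(sp$dx * sp$dy, ncol(z)), nrow(z), ncol(z))
  planar[is.na(sa)] <- NA_real_
  kr <- window_radii_cells(bathy, radius_km)
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    r0 <- max(1, i - kr$ky); r1 <- min(nr, i + kr$ky)
    k <- kr$kx[i]
    for (j in seq_len(nc)) {
      if (is.na(sa[i, j])) next
      c0 <- max(1, j - k); c1 <- min(nc, j + k)
      s <- sum(sa[r0:r1, c0:c1], na.rm = TRUE)
      p <- sum(planar[r0:r1, c0:c1], na.rm = TRUE)
      if (p > 0) out[i, j] <- s / p
    }
  }
  coral_grid(out, bathy$lon_origin, bathy$lat_origin, bathy$cell_size, bathy$nodata)
}

#' Bathymetric position index
#'
#' A cell's depth relative to the mean depth of the surrounding window
#' (center excluded): `BPI = mean(neighbourhood depth) - cell depth` with
#' positive-down depths, so crests (shallower than their surroundings) are
#' positive and depressions negative. Flat seafloor gives 0.
#'
#' @param bathy a `bathymetry` (at least 3x3).
#' @param radius_km window radius in kilometres.
#' @return a `coral_grid` (metres).
#' @export
bpi <- function(bathy, radius_km) {
  stopifnot(inherits(bathy, "bathymetry"), radius_km > 0)
  z <- bathy$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid smaller than 3x3")
  kr <- window_radii_cells(bathy, radius_km)
  nb_mean <- window_mean(z, kr$kx, kr$ky, exclude_center = TRUE)
  coral_grid(nb_mean - z, bathy$lon_origin, bathy$lat_origin,
             bathy$cell_size, bathy$nodata)
}
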