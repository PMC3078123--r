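#' Drape a z-binned field over bathymetry
#'
#' The core up-scaling computation. Each depth slice is interpolated to the
#' intermediate resolution ([idw_interpolate()]), resampled onto the
#' bathymetry grid with no further interpolation ([resample_nearest()]), and
#' then assigned ("draped") onto exactly those sea cells whose seafloor depth
#' falls in the slice's half-open interval `[top, bottom)`. The draped slices
#' are merged into one continuous seafloor layer. Sea cells deeper than the
#' deepest interval take the deepest slice's value, reflecting the assumption
#' that conditions below the climatology's maximum depth are stable; land
#' cells are nodata.
#'
#' @param field a `zbinned_field` (contiguous slices on one geotransform).
#' @param bathy a `bathymetry`.
#' @param config an [idw_config()].
#' @return a `coral_grid` on the bathymetry geotransform.
#' @export
drape_zbins <- function(field, bathy, config = idw_config()) {
  stopifnot(inherits(field, "zbinned_field"), inherits(bathy, "bathymetry"))
  gt <- geotransform(bathy)
  depth <- bathy$values
  out <- matrix(NA_real_, gt$n_rows, gt$n_cols)
  n <- nrow(field$intervals)
  for (i in seq_len(n)) {
    slice <- resample_nearest(idw_interpolate(field$slices[[i]], config), gt)
    top <- field$intervals$top[i]
    bottom <- field$intervals$bottom[i]
    sel <- !is.na(depth) & depth >= top & depth < bottom
    if (i == n) sel <- sel | (!is.na(depth) & depth >= bottom)  # deeper-than-deepest rule
    out[sel] <- slice$values[sel]
  }
  coral_grid(out, gt$lon_origin, gt$lat_origin, gt$cell_size, nodata = bathy$nodata)
}

#' Up-scale a surface-only field onto bathymetry
#'
#' Surface products (single z-bin) skip the depth assignment: they are
#' interpolated to the intermediate resolution, resampled onto the bathymetry
#' grid and masked to sea cells.
#'
#' @param source a `coral_grid` (the native-resolution surface field).
#' @param bathy a `bathymetry`.
#' @param config an [idw_config()].
#' @return a `coral_grid` on the bathymetry geotransform, nodata on land.
#' @export
upscale_surface <- function(source, bathy, config = idw_config()) {
  stopifnot(inherits(source, "coral_grid"), inherits(bathy, "bathymetry"))
  gt <- geotransform(bathy)
  res <- resample_nearest(idw_interpolate(source, config), gt)
  res$values[!sea_mask(bathy)] <- NA_real_
  res
}
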