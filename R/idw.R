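#' Inverse-distance-weighting configuration
#'
#' Controls the interpolation step of the up-scaling pipeline: each coarse
#' z-bin (or surface field) is first interpolated onto an intermediate grid
#' (default 0.1 degrees) before being resampled onto the bathymetry.
#'
#' @param power exponent of the inverse distance weights (> 0).
#' @param max_neighbors number of nearest valid source cells used per output
#'   point (>= 1).
#' @param intermediate_cell_size_deg cell size (degrees) of the intermediate
#'   interpolation grid.
#' @return list of class `idw_config`.
#' @export
idw_config <- function(power = 2, max_neighbors = 12,
                       intermediate_cell_size_deg = 0.1) {
  stopifnot(power > 0, max_neighbors >= 1, intermediate_cell_size_deg > 0)
  structure(
    list(
      power = power,
      max_neighbors = as.integer(max_neighbors),
      intermediate_cell_size_deg = intermediate_cell_size_deg
    ),
    class = "idw_config"
  )
}

#' Inverse distance weighted interpolation onto an intermediate grid
#'
#' Interpolates the valid cell centers of `source` onto a grid of
#' `intermediate_cell_size_deg` cells covering the source extent. Each output
#' value is the inverse-distance-power weighted mean of the `max_neighbors`
#' nearest valid source centers (planar degree distances); an output point
#' coinciding with a source center returns that center's value exactly, and
#' every output value lies within the range of the neighbour values used.
#'
#' @param source a `coral_grid` with at least one valid cell.
#' @param config an [idw_config()].
#' @return a `coral_grid` on the intermediate geotransform.
#' @export
idw_interpolate <- function(source, config = idw_config()) {
  stopifnot(inherits(source, "coral_grid"), inherits(config, "idw_config"))
  v <- source$values
  ok <- which(!is.na(v))
  if (length(ok) == 0) stop("idw_interpolate: source has no valid cells")
  nr <- nrow(v)
  src_row <- ((ok - 1) %% nr) + 1
  src_col <- ((ok - 1) %/% nr) + 1
  sx <- lon_centers(source)[src_col]
  sy <- lat_centers(source)[src_row]
  sv <- v[ok]

  cs <- config$intermediate_cell_size_deg
  ext_w <- ncol(v) * source$cell_size
  ext_h <- nr * source$cell_size
  n_cols_out <- max(1L, as.integer(ceiling(ext_w / cs - 1e-9)))
  n_rows_out <- max(1L, as.integer(ceiling(ext_h / cs - 1e-9)))
  gx <- source$lon_origin + (seq_len(n_cols_out) - 0.5) * cs
  gy <- source$lat_origin - (seq_len(n_rows_out) - 0.5) * cs

  k <- min(config$max_neighbors, length(sv))
  out <- matrix(NA_real_, n_rows_out, n_cols_out)
  for (j in seq_len(n_cols_out)) {
    dx2 <- (sx - gx[j])^2
    for (i in seq_len(n_rows_out)) {
      d2 <- dx2 + (sy - gy[i])^2
      nb <- if (length(d2) > k) order(d2)[seq_len(k)] else seq_along(d2)
      dn <- d2[nb]
      if (length(nb) == 1) {
        out[i, j] <- sv[nb]
      } else if (dn[which.min(dn)] < 1e-20) {
        out[i, j] <- sv[nb[which.min(dn)]]
      } else {
        w <- dn^(-config$power / 2)  # d^-power with d2 = d^2
        out[i, j] <- sum(w * sv[nb]) / sum(w)
      }
    }
  }
  coral_grid(out, source$lon_origin, source$lat_origin, cs, nodata = source$nodata)
}
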