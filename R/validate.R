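#' Filter bottle stations by depth
#'
#' Retains stations strictly deeper than `min_depth` (default 50 m), the
#' customary cut-off that removes surface bottles before validating seafloor
#' layers.
#'
#' @param stations tibble with at least `lon`, `lat`, `depth`, `value`.
#' @param min_depth metres; stations with `depth > min_depth` are kept.
#' @return the filtered tibble.
#' @export
filter_stations <- function(stations, min_depth = 50) {
  dplyr::filter(tibble::as_tibble(stations), .data$depth > min_depth)
}

#' Intersect bottle stations with an up-scaled layer
#'
#' Pairs each station with the value of the layer cell containing it
#' (half-open cell footprints), drops stations outside the extent or on
#' nodata cells (counted), and computes the Pearson correlation between
#' station measurements and layer values.
#'
#' @param stations tibble with `lon`, `lat`, `depth`, `value`.
#' @param layer a `coral_grid` (the up-scaled seafloor layer).
#' @return object of class `validation_result` with `n`, `pearson_r`,
#'   `r_squared`, the paired tibble `pairs` and the drop count.
#' @export
intersect_layer <- function(stations, layer) {
  stopifnot(inherits(layer, "coral_grid"))
  stations <- tibble::as_tibble(stations)
  idx <- cell_index(layer, stations$lon, stations$lat)
  lv <- rep(NA_real_, nrow(stations))
  lv[idx$inside] <- layer$values[cbind(idx$row[idx$inside], idx$col[idx$inside])]
  keep <- !is.na(lv)
  pairs <- tibble::tibble(
    lon = stations$lon[keep], lat = stations$lat[keep],
    depth = stations$depth[keep],
    station = stations$value[keep], layer = lv[keep]
  )
  if (nrow(pairs) < 3) stop("fewer than 3 station/layer pairs; correlation undefined")
  r <- stats::cor(pairs$station, pairs$layer)
  structure(
    list(n = nrow(pairs), pearson_r = r, r_squared = r^2,
         pairs = pairs, n_dropped = sum(!keep)),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> n = %d (dropped %d), r = %.4f, r^2 = %.4f\n",
              x$n, x$n_dropped, x$pearson_r, x$r_squared))
  invisible(x)
}

#' @method tidy validation_result
#' @export
tidy.validation_result <- function(x, ...) x$pairs

#' @method glance validation_result
#' @export
glance.validation_result <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r = x$pearson_r, r_squared = x$r_squared,
                 n_dropped = x$n_dropped)
}

#' Binned mean profiles of station and layer values
#'
#' Aggregates station/layer pairs into half-open bins along depth, latitude
#' or longitude (bins start at the axis minimum) and reports per-bin means of
#' both members, the standard diagnostic profile for up-scaled layers (50 m
#' depth bins, 5 degree latitude bins, 10 degree longitude bins).
#'
#' @param pairs tibble from [intersect_layer()] (`$pairs`).
#' @param axis `"depth"`, `"latitude"` or `"longitude"`.
#' @param bin_width bin width in the axis units (m or degrees).
#' @return tibble with `bin_start`, `bin_end`, `n`, `station_mean`,
#'   `layer_mean`; empty bins are omitted.
#' @export
binned_profile <- function(pairs, axis = c("depth", "latitude", "longitude"),
                           bin_width) {
  axis <- match.arg(axis)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (nrow(pairs) == 0) stop("no pairs to bin")
  x <- switch(axis, depth = pairs$depth, latitude = pairs$lat,
              longitude = pairs$lon)
  x0 <- min(x)
  bin <- floor((x - x0) / bin_width + 1e-12)
  tibble::tibble(bin = bin, station = pairs$station, layer = pairs$layer) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      station_mean = mean(.data$station),
      layer_mean = mean(.data$layer),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_start = x0 + .data$bin * bin_width,
      bin_end = x0 + (.data$bin + 1) * bin_width
    ) |>
    dplyr::select("bin_start", "bin_end", "n", "station_mean", "layer_mean")
}

#' Coarse grid of mean layer-station differences
#'
#' Maps the spatial distribution of layer error: each coarse cell (default 5
#' degrees) holds the mean of `layer - station` over the stations it
#' contains; cells with no stations are nodata. Cell edges are snapped to
#' multiples of `cell_deg`.
#'
#' @param pairs tibble from [intersect_layer()] (`$pairs`).
#' @param cell_deg coarse cell size in degrees.
#' @return a `coral_grid`.
#' @export
error_grid <- function(pairs, cell_deg = 5) {
  if (nrow(pairs) == 0) stop("no pairs")
  west <- floor(min(pairs$lon) / cell_deg) * cell_deg
  north <- ceiling(max(pairs$lat) / cell_deg) * cell_deg
  n_cols <- max(1L, as.integer(ceiling((max(pairs$lon) - west) / cell_deg + 1e-12)))
  n_rows <- max(1L, as.integer(ceiling((north - min(pairs$lat)) / cell_deg + 1e-12)))
  gt <- list(n_rows = n_rows, n_cols = n_cols, lon_origin = west,
             lat_origin = north, cell_size = cell_deg)
  idx <- cell_index(gt, pairs$lon, pairs$lat)
  diffs <- pairs$layer - pairs$station
  out <- matrix(NA_real_, n_rows, n_cols)
  agg <- tibble::tibble(row = idx$row, col = idx$col, d = diffs) |>
    dplyr::filter(!is.na(.data$row)) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(mean_d = mean(.data$d), .groups = "drop")
  out[cbind(agg$row, agg$col)] <- agg$mean_d
  coral_grid(out, west, north, cell_deg)
}
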