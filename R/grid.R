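#' Georeferenced grid
#'
#' The universal raster currency of the package: a matrix of values on a
#' regular geographic (WGS84 lat/lon) grid with square cells and cell-center
#' registration. Row 1 is the northernmost row; `lon_origin`/`lat_origin` are
#' the coordinates of the *outer corner* of the first (top-left) cell, i.e. the
#' west edge and north edge of the grid. Missing data are stored as `NA`
#' internally; `nodata` records the sentinel used when the grid is written to
#' disk.
#'
#' @param values numeric matrix (rows = latitude bands north to south).
#' @param lon_origin,lat_origin degrees; outer (NW) corner of the grid.
#' @param cell_size degrees per cell (square cells).
#' @param nodata sentinel written to / read from disk for missing cells.
#' @return An object of class `coral_grid`.
#' @export
coral_grid <- function(values, lon_origin, lat_origin, cell_size,
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  storage.mode(values) <- "double"
  structure(
    list(
      values = values,
      lon_origin = as.numeric(lon_origin),
      lat_origin = as.numeric(lat_origin),
      cell_size = as.numeric(cell_size),
      nodata = as.numeric(nodata)
    ),
    class = "coral_grid"
  )
}

#' @export
print.coral_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<coral_grid> %d x %d cells, %.6g deg/cell\n  NW corner: (%.6g, %.6g); %d valid / %d cells\n",
    nrow(v), ncol(v), x$cell_size, x$lon_origin, x$lat_origin,
    sum(!is.na(v)), length(v)
  ))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  range: [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.coral_grid <- function(x) dim(x$values)

# Geotransform as a plain list; `target` arguments accept either a coral_grid
# or this list.
#' Extract the geotransform of a grid
#'
#' @param grid a `coral_grid` or a geotransform list.
#' @return list with `n_rows`, `n_cols`, `lon_origin`, `lat_origin`, `cell_size`.
#' @export
geotransform <- function(grid) {
  if (inherits(grid, "coral_grid")) {
    list(
      n_rows = nrow(grid$values), n_cols = ncol(grid$values),
      lon_origin = grid$lon_origin, lat_origin = grid$lat_origin,
      cell_size = grid$cell_size
    )
  } else {
    stopifnot(all(c("n_rows", "n_cols", "lon_origin", "lat_origin", "cell_size") %in%
                    names(grid)))
    grid
  }
}

same_geotransform <- function(a, b, tol = 1e-9) {
  a <- geotransform(a); b <- geotransform(b)
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_origin - b$lon_origin) < tol &&
    abs(a$lat_origin - b$lat_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell-center coordinates
#'
#' @param grid a `coral_grid` or geotransform list.
#' @return numeric vectors of cell-center longitudes (by column) or latitudes
#'   (by row, north to south).
#' @export
lon_centers <- function(grid) {
  gt <- geotransform(grid)
  gt$lon_origin + (seq_len(gt$n_cols) - 0.5) * gt$cell_size
}

#' @rdname lon_centers
#' @export
lat_centers <- function(grid) {
  gt <- geotransform(grid)
  gt$lat_origin - (seq_len(gt$n_rows) - 0.5) * gt$cell_size
}

#' Normalize longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @export
normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Locate points on a grid
#'
#' Maps points to the cell whose footprint contains them. Footprints are
#' half-open `[west, east) x [north, south)` so every in-extent point maps to
#' exactly one cell and edge points are assigned deterministically (a point on
#' a shared meridian belongs to the eastern cell's west edge; a point on a
#' shared parallel to the southern cell's north edge).
#'
#' @param grid a `coral_grid` or geotransform list.
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @return A tibble with columns `row`, `col` (NA when the point is outside
#'   the grid extent) and logical `inside`.
#' @export
cell_index <- function(grid, lon, lat) {
  gt <- geotransform(grid)
  col <- floor((lon - gt$lon_origin) / gt$cell_size) + 1
  row <- floor((gt$lat_origin - lat) / gt$cell_size) + 1
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= gt$n_rows & col >= 1 & col <= gt$n_cols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Grid values as a tibble
#'
#' @param x a `coral_grid`.
#' @param ... unused.
#' @return tibble with `row`, `col`, `lon`, `lat`, `value` (valid cells keep
#'   their value; nodata cells carry `NA`).
#' @method as_tibble coral_grid
#' @export
as_tibble.coral_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    lon = rep(lon_centers(x), each = nr),
    lat = rep(lat_centers(x), times = nc),
    value = as.vector(x$values)
  )
}

#' Read a raster from disk
#'
#' Reads an ESRI ASCII grid (`.asc`): a 5-6 line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' whitespace-separated values, north row first. Headers declaring separate
#' x/y cell sizes (`dx`/`dy`) are rejected: the grid model requires square
#' cells.
#'
#' @param path file path.
#' @param format raster format. Only `"ascii_grid"` is supported; GeoTIFF is
#'   not a format this package reads or writes.
#' @return a `coral_grid`.
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported; convert to ESRI ASCII grid (.asc).")
  }
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, n = 8, warn = FALSE)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else {
      break
    }
  }
  if (any(c("dx", "dy") %in% names(hdr))) {
    stop("raster has rectangular cells (dx/dy header); square cells required.")
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, ": need ", paste(req, collapse = ", "))
  }
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, ": missing lower-left origin")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid %s: expected %d values, found %d", path, nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  coral_grid(m, lon_origin = xll, lat_origin = yll + nr * cs,
             cell_size = cs, nodata = nodata)
}

#' Write a raster to disk
#'
#' Values are written with 6 significant digits, so a written grid re-reads to
#' the same values it was written with.
#'
#' @param grid a `coral_grid`.
#' @param path output path.
#' @param format see [read_raster()].
#' @export
write_raster <- function(grid, path, format = c("ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported; use format = \"ascii_grid\".")
  }
  stopifnot(inherits(grid, "coral_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$lon_origin),
    sprintf("yllcorner %.10g", grid$lat_origin - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(r) {
    r[is.na(r)] <- grid$nodata
    paste(formatC(r, digits = 6, format = "g"), collapse = " ")
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Resample a grid onto another geotransform (nearest neighbour)
#'
#' Each output cell takes the value of the source cell containing its center;
#' no interpolation is performed and no value absent from the source can
#' appear in the output. Output centers outside the source extent become
#' nodata.
#'
#' @param source a `coral_grid`.
#' @param target a `coral_grid` or geotransform list defining the output grid.
#' @return a `coral_grid` on the target geotransform.
#' @export
resample_nearest <- function(source, target) {
  stopifnot(inherits(source, "coral_grid"))
  gt <- geotransform(target)
  lon <- gt$lon_origin + (seq_len(gt$n_cols) - 0.5) * gt$cell_size
  lat <- gt$lat_origin - (seq_len(gt$n_rows) - 0.5) * gt$cell_size
  scol <- floor((lon - source$lon_origin) / source$cell_size) + 1
  srow <- floor((source$lat_origin - lat) / source$cell_size) + 1
  scol[scol < 1 | scol > ncol(source$values)] <- NA_integer_
  srow[srow < 1 | srow > nrow(source$values)] <- NA_integer_
  out <- matrix(NA_real_, gt$n_rows, gt$n_cols)
  ok_r <- which(!is.na(srow)); ok_c <- which(!is.na(scol))
  if (length(ok_r) == 0 || length(ok_c) == 0) {
    warning("resample_nearest: source and target extents do not overlap; all-nodata output")
  } else {
    out[ok_r, ok_c] <- source$values[srow[ok_r], scol[ok_c], drop = FALSE]
  }
  coral_grid(out, gt$lon_origin, gt$lat_origin, gt$cell_size, nodata = source$nodata)
}

#' Bathymetry: seafloor depth grid
#'
#' Wraps a grid of seafloor depths in metres, positive down; land cells are
#' nodata. Sources using the elevation convention (negative below sea level)
#' are negated on ingest and cells at or above sea level are masked as land.
#'
#' @param grid a `coral_grid` of depths (positive down) or elevations.
#' @param convention `"depth"` (positive down, default) or `"elevation"`
#'   (negative below sea level, as bathymetric DEMs are usually distributed).
#' @return an object of class `bathymetry` (also a `coral_grid`).
#' @export
bathymetry <- function(grid, convention = c("depth", "elevation")) {
  convention <- match.arg(convention)
  stopifnot(inherits(grid, "coral_grid"))
  v <- grid$values
  if (convention == "elevation") v <- -v
  v[!is.na(v) & v <= 0] <- NA_real_
  out <- coral_grid(v, grid$lon_origin, grid$lat_origin, grid$cell_size, grid$nodata)
  class(out) <- c("bathymetry", class(out))
  out
}

#' Sea mask of a bathymetry
#'
#' @param bathy a `bathymetry`.
#' @return logical matrix, TRUE where the cell is sea (has a depth).
#' @export
sea_mask <- function(bathy) !is.na(bathy$values)

#' Plot a grid with ggplot2
#'
#' @param object a `coral_grid`.
#' @param ... unused.
#' @method autoplot coral_grid
#' @export
autoplot.coral_grid <- function(object, ...) {
  df <- as_tibble.coral_grid(object)
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
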