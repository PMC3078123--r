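#' Depth intervals from standard levels
#'
#' Converts the standard depth levels of a z-binned climatology (e.g. the
#' World-Ocean-Atlas-style 0, 10, 20, ... m levels) into contiguous half-open
#' depth intervals `[top, bottom)`. Boundaries sit at midpoints between
#' consecutive levels; the first interval starts at 0 m and the last extends
#' half the final spacing beyond the deepest level. A single-level product
#' gets one interval `[0, single_level_bottom)`.
#'
#' @param depths numeric vector of level depths (m, positive down), strictly
#'   increasing.
#' @param single_level_bottom bottom (m) assigned when only one level exists.
#' @return tibble with columns `top`, `bottom` (m), one row per level.
#' @export
depth_intervals <- function(depths, single_level_bottom = 11000) {
  if (length(depths) < 1) stop("need at least one depth level")
  if (any(diff(depths) <= 0)) stop("depth levels must be strictly increasing")
  if (any(depths < 0)) stop("depth levels must be non-negative")
  if (length(depths) == 1) {
    return(tibble::tibble(top = 0, bottom = single_level_bottom))
  }
  mids <- (depths[-1] + depths[-length(depths)]) / 2
  top <- c(0, mids)
  bottom <- c(mids, depths[length(depths)] + diff(depths)[length(depths) - 1] / 2)
  tibble::tibble(top = top, bottom = bottom)
}

#' Z-binned field: a stack of depth slices of one variable
#'
#' @param variable variable name.
#' @param intervals tibble with `top`/`bottom` columns (m), sorted,
#'   non-overlapping and contiguous.
#' @param slices list of `coral_grid`, one per interval, all on one
#'   geotransform.
#' @return object of class `zbinned_field`.
#' @export
zbinned_field <- function(variable, intervals, slices) {
  stopifnot(is.character(variable), length(variable) == 1)
  stopifnot(nrow(intervals) == length(slices), length(slices) >= 1)
  if (any(intervals$top >= intervals$bottom)) stop("intervals must have top < bottom")
  if (nrow(intervals) > 1) {
    if (any(abs(intervals$top[-1] - intervals$bottom[-nrow(intervals)]) > 1e-9)) {
      stop("intervals must be contiguous (each bottom equals the next top)")
    }
  }
  gt0 <- geotransform(slices[[1]])
  for (s in slices) {
    if (!same_geotransform(s, gt0)) stop("all slices must share one geotransform")
  }
  structure(
    list(variable = variable, intervals = intervals, slices = slices),
    class = "zbinned_field"
  )
}

#' @export
print.zbinned_field <- function(x, ...) {
  cat(sprintf("<zbinned_field> '%s': %d depth slices, %g-%g m\n",
              x$variable, nrow(x$intervals),
              min(x$intervals$top), max(x$intervals$bottom)))
  invisible(x)
}

#' Read a z-binned field
#'
#' Reads the package's text serialization of a depth-binned climatology: a
#' directory holding `manifest.json` (fields `variable`, `depths_m`, `files`)
#' and one ESRI ASCII grid per depth level. Depth levels are converted to
#' contiguous intervals with [depth_intervals()].
#'
#' @param path directory containing the manifest and slice rasters.
#' @param variable optional name check against the manifest.
#' @param single_level_bottom passed to [depth_intervals()].
#' @return a `zbinned_field`.
#' @export
read_zbinned <- function(path, variable = NULL, single_level_bottom = 11000) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(mf$depths_m)) stop("manifest lacks a depth coordinate (depths_m)")
  depths <- as.numeric(mf$depths_m)
  if (any(diff(depths) <= 0)) stop("depth levels are not sorted increasing")
  if (length(mf$files) != length(depths)) stop("manifest files/depths length mismatch")
  if (!is.null(variable) && !identical(variable, mf$variable)) {
    stop(sprintf("manifest variable is '%s', not '%s'", mf$variable, variable))
  }
  slices <- lapply(file.path(path, mf$files), read_raster)
  zbinned_field(mf$variable, depth_intervals(depths, single_level_bottom), slices)
}

#' Write a z-binned field
#'
#' Inverse of [read_zbinned()]. Level depths are taken as interval midpoints
#' (tops for the first interval start at 0, so the first level is written as
#' the first interval's midpoint only when no `depths_m` attribute is given).
#'
#' @param field a `zbinned_field`.
#' @param path output directory (created if needed).
#' @param depths_m optional original level depths to record in the manifest;
#'   defaults to interval midpoints.
#' @export
write_zbinned <- function(field, path, depths_m = NULL) {
  stopifnot(inherits(field, "zbinned_field"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(field$slices)
  if (is.null(depths_m)) {
    depths_m <- (field$intervals$top + field$intervals$bottom) / 2
  }
  files <- sprintf("%s_%03d.asc", field$variable, seq_len(n))
  for (i in seq_len(n)) write_raster(field$slices[[i]], file.path(path, files[i]))
  jsonlite::write_json(
    list(variable = field$variable, depths_m = depths_m, files = files),
    file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Layer stack: named environmental layers on one geotransform
#'
#' A cell is valid only if it is valid in every member layer; the complete
#' covariate vector at a valid cell is what the niche model consumes.
#'
#' @param layers named list of `coral_grid` objects on one shared
#'   geotransform.
#' @return object of class `layer_stack`.
#' @export
layer_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)),
            all(nzchar(names(layers))))
  gt0 <- geotransform(layers[[1]])
  for (l in layers) {
    stopifnot(inherits(l, "coral_grid"))
    if (!same_geotransform(l, gt0)) stop("all layers must share one geotransform")
  }
  structure(list(layers = layers), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  gt <- geotransform(x$layers[[1]])
  cat(sprintf("<layer_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), gt$n_rows, gt$n_cols,
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  jointly valid cells: %d\n", sum(stack_valid_mask(x))))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' @param stack a `layer_stack`.
#' @return logical matrix, TRUE where every layer is valid.
#' @export
stack_valid_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) m <- m & !is.na(l$values)
  m
}

#' Stack covariates as a tibble
#'
#' @param x a `layer_stack`.
#' @param ... unused.
#' @return tibble of jointly valid cells: `row`, `col`, `lon`, `lat`, then one
#'   column per layer.
#' @method as_tibble layer_stack
#' @export
as_tibble.layer_stack <- function(x, ...) {
  ok <- which(stack_valid_mask(x))
  gt <- geotransform(x$layers[[1]])
  rows <- ((ok - 1) %% gt$n_rows) + 1
  cols <- ((ok - 1) %/% gt$n_rows) + 1
  out <- tibble::tibble(
    row = rows, col = cols,
    lon = lon_centers(gt)[cols],
    lat = lat_centers(gt)[rows]
  )
  for (nm in names(x$layers)) out[[nm]] <- x$layers[[nm]]$values[ok]
  out
}

# Covariate matrix at (row, col) positions; positions must be in-extent.
stack_extract <- function(stack, row, col) {
  gt <- geotransform(stack$layers[[1]])
  idx <- cbind(row, col)
  out <- vapply(stack$layers, function(l) l$values[idx], numeric(length(row)))
  if (length(row) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  out
}
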