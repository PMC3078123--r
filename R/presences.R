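#' Load species presence records
#'
#' Reads a presence CSV with columns `species`, `lon`, `lat`. Longitudes are
#' normalized to \[-180, 180); rows with unparsable coordinates are dropped
#' with a message reporting the count.
#'
#' @param path CSV file path.
#' @return tibble with columns `species`, `lon`, `lat`.
#' @export
load_presences <- function(path) {
  if (!file.exists(path)) stop("presence file does not exist: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("species", "lon", "lat"), names(df))
  if (length(miss) > 0) {
    stop("presence CSV missing columns: ", paste(miss, collapse = ", "))
  }
  df <- dplyr::mutate(
    df,
    lon = suppressWarnings(as.numeric(.data$lon)),
    lat = suppressWarnings(as.numeric(.data$lat))
  )
  bad <- is.na(df$lon) | is.na(df$lat) | abs(df$lat) > 90
  if (any(bad)) {
    message(sum(bad), " record(s) dropped: unparsable or out-of-range coordinates")
  }
  df <- df[!bad, c("species", "lon", "lat")]
  dplyr::mutate(tibble::as_tibble(df), lon = normalize_lon(.data$lon))
}

new_presence_set <- function(records, gt, species_label) {
  structure(
    records,
    geotransform = gt,
    species_label = species_label,
    class = c("presence_set", class(tibble::tibble()))
  )
}

#' Deduplicate and filter presence records against a layer stack
#'
#' Applies the standard cleaning for presence-only modelling on a gridded
#' analysis area: records outside the stack extent are removed, records on
#' cells that are not valid in every layer (land, or any missing covariate)
#' are removed, and within each grid cell only the first record in input
#' order is retained, so multi-record cells contribute a single presence.
#'
#' @param records tibble with `species`, `lon`, `lat` (see
#'   [load_presences()]).
#' @param stack a `layer_stack` defining the analysis area.
#' @return A `presence_set`: a tibble `species`, `lon`, `lat`, `row`, `col`
#'   with at most one row per grid cell, carrying the reference geotransform
#'   as an attribute.
#' @export
dedup_and_filter <- function(records, stack) {
  stopifnot(inherits(stack, "layer_stack"))
  gt <- geotransform(stack$layers[[1]])
  idx <- cell_index(gt, records$lon, records$lat)
  n_in <- nrow(records)
  keep_extent <- idx$inside
  valid <- stack_valid_mask(stack)
  on_valid <- keep_extent
  on_valid[keep_extent] <- valid[cbind(idx$row[keep_extent], idx$col[keep_extent])]
  df <- tibble::tibble(
    species = records$species,
    lon = records$lon, lat = records$lat,
    row = idx$row, col = idx$col
  )[on_valid, ]
  deduped <- dplyr::distinct(df, .data$row, .data$col, .keep_all = TRUE)
  message(sprintf(
    "presences: %d in, %d outside extent, %d on invalid cells, %d duplicate-cell, %d retained",
    n_in, sum(!keep_extent), sum(keep_extent) - sum(on_valid),
    sum(on_valid) - nrow(deduped), nrow(deduped)
  ))
  sp <- unique(deduped$species)
  new_presence_set(deduped, gt, if (length(sp) == 1) sp else "ALL")
}

#' Combine per-species presence sets
#'
#' Pools records of several species and re-deduplicates per cell (first set,
#' first record wins), mirroring the construction of a combined
#' framework-former analysis where multiple species in one cell count once.
#'
#' @param sets list of `presence_set` objects on one reference geotransform.
#' @param stack the `layer_stack` the sets were filtered against.
#' @return a `presence_set` labelled `"ALL"`.
#' @export
combine_species <- function(sets, stack) {
  stopifnot(length(sets) >= 1)
  gt <- attr(sets[[1]], "geotransform")
  for (s in sets) {
    if (!same_geotransform(attr(s, "geotransform"), gt)) {
      stop("presence sets are on different geotransforms")
    }
  }
  pooled <- dplyr::bind_rows(lapply(sets, function(s) tibble::as_tibble(s)))
  deduped <- dplyr::distinct(pooled, .data$row, .data$col, .keep_all = TRUE)
  new_presence_set(deduped, gt, "ALL")
}

#' Export a presence set in samples-with-data (SWD) form
#'
#' Writes (or returns) the SWD table: `species`, `lon`, `lat`, then one
#' column per stack layer sampled at each record's cell.
#'
#' @param set a `presence_set`.
#' @param stack a `layer_stack` on the set's geotransform.
#' @param path optional CSV path; when `NULL` the tibble is returned only.
#' @return the SWD tibble, invisibly when written to `path`.
#' @export
export_swd <- function(set, stack, path = NULL) {
  stopifnot(inherits(set, "presence_set"), inherits(stack, "layer_stack"))
  if (!same_geotransform(attr(set, "geotransform"), geotransform(stack$layers[[1]]))) {
    stop("presence set and stack are on different geotransforms")
  }
  covs <- stack_extract(stack, set$row, set$col)
  out <- dplyr::bind_cols(
    tibble::tibble(species = set$species, lon = set$lon, lat = set$lat),
    tibble::as_tibble(covs)
  )
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}
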