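#' Load occurrence records from CSV
#'
#' Expects columns `longitude` and `latitude` (plus optional `species`,
#' `uncertainty_m`, `source`).  Rows with missing/non-finite coordinates or
#' coordinates outside the valid lon/lat domain are rejected, counted and
#' reported — never dropped silently.
#'
#' @param path CSV file path.
#' @param species optional species name; defaults to the file's `species`
#'   column or the file name.
#' @return An object of class `occurrence_set`: a data frame with columns
#'   `longitude`, `latitude`, `uncertainty_m`, with attributes `species`
#'   and `log` (named counts of rejected rows).
#' @export
load_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no records in ", path)
  need <- c("longitude", "latitude")
  if (!all(need %in% names(raw)))
    stop("missing coordinate columns; found: ",
         paste(names(raw), collapse = ", "))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  ok_parse <- is.finite(lon) & is.finite(lat)
  ok_domain <- ok_parse & lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  log <- c(malformed = sum(!ok_parse),
           out_of_domain = sum(ok_parse & !ok_domain))
  if (any(log > 0))
    message("load_occurrences: rejected ", sum(log), " row(s) (",
            log[["malformed"]], " malformed, ", log[["out_of_domain"]],
            " outside lon/lat domain)")
  keep <- which(ok_domain)
  if (!length(keep)) stop("no records survive coordinate validation in ", path)
  unc <- if ("uncertainty_m" %in% names(raw))
    suppressWarnings(as.numeric(raw$uncertainty_m))[keep] else
      rep(NA_real_, length(keep))
  sp <- species %||% (if ("species" %in% names(raw)) raw$species[keep[1L]]
                      else tools::file_path_sans_ext(basename(path)))
  out <- data.frame(longitude = lon[keep], latitude = lat[keep],
                    uncertainty_m = unc)
  structure(out, species = sp, log = log, class = c("occurrence_set",
                                                    "data.frame"))
}

#' Curate an occurrence set
#'
#' Collapses exact duplicate coordinates (after rounding to 6 decimal
#' places, about 0.1 m), removes records with spatial uncertainty above
#' `max_uncertainty_m`, and removes records outside the bounding box of
#' `bounds`.  Records with unknown uncertainty pass the uncertainty filter
#' (the curated source datasets are pre-screened); their count is logged.
#' The result is independent of input row order.
#'
#' @param occ an [load_occurrences()] set (any data frame with
#'   `longitude`/`latitude` works).
#' @param max_uncertainty_m uncertainty cutoff in metres (default 10 km,
#'   about two grid cells).
#' @param bounds optional [grid_spec()] giving the study bounding box.
#' @return A curated `occurrence_set`; attribute `log` counts removals.
#' @export
filter_occurrences <- function(occ, max_uncertainty_m = 10000, bounds = NULL) {
  stopifnot(max_uncertainty_m > 0)
  df <- as.data.frame(occ)
  n0 <- nrow(df)
  unc <- df$uncertainty_m %||% rep(NA_real_, n0)
  keep <- is.na(unc) | unc <= max_uncertainty_m
  n_unc <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n_oob <- 0L
  if (!is.null(bounds)) {
    inside <- df$longitude >= bounds$lon_min & df$longitude <= bounds$lon_max &
      df$latitude >= bounds$lat_min & df$latitude <= bounds$lat_max
    n_oob <- sum(!inside)
    df <- df[inside, , drop = FALSE]
  }
  key <- paste(round(df$longitude, 6), round(df$latitude, 6))
  ord <- order(key)
  df <- df[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  n_dup <- n0 - n_unc - n_oob - nrow(df)
  rownames(df) <- NULL
  if (nrow(df) == 0L) warning("no occurrence records remain after filtering")
  log <- c(attr(occ, "log"),
           c(high_uncertainty = n_unc, outside_bounds = n_oob,
             duplicates = n_dup,
             unknown_uncertainty_kept = sum(is.na(df$uncertainty_m))))
  structure(df, species = attr(occ, "species"), log = log,
            class = c("occurrence_set", "data.frame"))
}

#' Grid occurrence records to raster cells
#'
#' Records are assigned to half-open cells (`floor((coord - origin)/res)`,
#' lower-left origin; a record exactly on a boundary goes to the
#' higher-index cell).  Multiple records in one cell collapse to a single
#' occupied cell; records on masked or out-of-grid cells are dropped with
#' counts reported.
#'
#' @param occ an occurrence set (data frame with `longitude`/`latitude`).
#' @param grid a [grid_spec()].
#' @param mask optional logical validity matrix congruent with `grid`.
#' @return An object of class `gridded_occurrences`: list with `grid`,
#'   `cells` (sorted occupied cell ids), `n_records`, `n_outside`,
#'   `n_masked`, `n_collapsed`.
#' @export
grid_occurrences <- function(occ, grid, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  df <- as.data.frame(occ)
  loc <- locate_cells(grid, df$longitude, df$latitude)
  n_outside <- sum(is.na(loc$id))
  ids <- loc$id[!is.na(loc$id)]
  n_masked <- 0L
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == c(grid$n_rows, grid$n_cols)))
    on_mask <- mask[ids]
    n_masked <- sum(!on_mask)
    ids <- ids[on_mask]
  }
  cells <- sort(unique(ids))
  structure(list(grid = grid, cells = cells, n_records = nrow(df),
                 n_outside = n_outside, n_masked = n_masked,
                 n_collapsed = length(ids) - length(cells),
                 species = attr(occ, "species")),
            class = "gridded_occurrences")
}

#' @export
print.gridded_occurrences <- function(x, ...) {
  cat(sprintf(
    "gridded_occurrences: %d occupied cells from %d records (%d outside grid, %d masked, %d collapsed)\n",
    length(x$cells), x$n_records, x$n_outside, x$n_masked, x$n_collapsed))
  invisible(x)
}

#' Write occupied cells as CSV
#'
#' @param gocc a [grid_occurrences()] result.
#' @param path output CSV (columns `row`, `col`, `lon`, `lat`).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(gocc, path) {
  cc <- cell_center(gocc$grid, gocc$cells)
  utils::write.csv(cc[, c("row", "col", "lon", "lat")], path,
                   row.names = FALSE)
  invisible(path)
}
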