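#' Occurrence-capture binarization threshold
#'
#' The largest threshold t such that at least a fraction `capture` of the
#' occupied cells have suitability >= t; equivalently the
#' `ceiling(capture * n)`-th largest occurrence suitability.  With the
#' default capture of 0.95 the resulting binary map keeps at least 95% of
#' the occurrence cells suitable by construction.
#'
#' @param suitability suitability values at the occupied cells.
#' @param capture fraction of occurrence cells to capture.
#' @param warn_small warn when fewer than 20 occupied cells make the
#'   quantile unstable.
#' @return The threshold.
#' @export
#' @examples
#' capture_threshold(seq(0.05, 1, by = 0.05)) # 0.10
capture_threshold <- function(suitability, capture = 0.95,
                              warn_small = TRUE) {
  suitability <- suitability[!is.na(suitability)]
  n <- length(suitability)
  if (!n) stop("no occupied cells with suitability values")
  if (warn_small && n < 20L)
    warning("fewer than 20 occupied cells; capture threshold is unstable")
  stopifnot(capture > 0, capture <= 1)
  sort(suitability, decreasing = TRUE)[ceiling(capture * n)]
}

#' Binarize a suitability map
#'
#' A valid cell is suitable iff its cloglog suitability is at or above the
#' threshold; masked (`NA`) cells stay excluded.
#'
#' @param suitability suitability matrix (masked cells `NA`).
#' @param threshold binarization threshold in (0, 1).
#' @param grid the [grid_spec()] of the map.
#' @param label period/scenario label.
#' @return An object of class `binary_map`: list with `grid`, `suitable`
#'   (logical matrix, `NA` on masked cells), `threshold`, `label`.
#' @export
binarize <- function(suitability, threshold, grid, label = "") {
  stopifnot(threshold > 0, threshold < 1,
            all(dim(suitability) == c(grid$n_rows, grid$n_cols)))
  structure(list(grid = grid, suitable = suitability >= threshold,
                 threshold = threshold, label = label),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("binary_map [%s]: %d suitable of %d valid cells (threshold %.3f)\n",
              x$label, sum(x$suitable, na.rm = TRUE),
              sum(!is.na(x$suitable)), x$threshold))
  invisible(x)
}

suitable_cells <- function(bm) which(as.vector(bm$suitable) %in% TRUE)

# total spherical area of a set of cells, km2
area_of_cells <- function(grid, cells) {
  if (!length(cells)) return(0)
  sum(cell_area_km2(row_lat(grid, cell_row(grid, cells)), grid$resolution))
}

#' Habitat loss between present and future binary maps
#'
#' A cell is lost when it is suitable in the present but not in the
#' future.  Losses, range contraction (lost area as a percentage of
#' present suitable area) and the minimum latitude of future suitability
#' are reported overall and per ocean basin (cells west/east of
#' `basin_split_lon`).  Newly suitable (gained) cells are reported
#' separately and excluded from the headline statistics.
#'
#' @param present,future [binarize()]d maps on the same grid.
#' @param basin_split_lon meridian splitting the West and East basins
#'   (degrees; default -40).
#' @return An object of class `loss_accounting`: `lost_cells`,
#'   `gained_cells`, and a data frame `summary` with columns `basin`,
#'   `present_area_km2`, `lost_area_km2`, `contraction_pct`,
#'   `min_suitable_lat`.
#' @export
loss_accounting <- function(present, future, basin_split_lon = -40) {
  stopifnot(inherits(present, "binary_map"), inherits(future, "binary_map"),
            same_grid(present$grid, future$grid))
  grid <- present$grid
  p <- suitable_cells(present)
  if (!length(p)) stop("present map has no suitable cells")
  f <- suitable_cells(future)
  lost <- setdiff(p, f)
  gained <- setdiff(f, p)
  basin_of <- function(cells) {
    lon <- cell_center(grid, cells)$lon
    ifelse(lon < basin_split_lon, "West", "East")
  }
  one_basin <- function(basin) {
    pb <- p[basin_of(p) == basin]
    lb <- lost[basin_of(lost) == basin]
    fb <- f[basin_of(f) == basin]
    pa <- area_of_cells(grid, pb)
    la <- area_of_cells(grid, lb)
    data.frame(basin = basin, present_area_km2 = pa, lost_area_km2 = la,
               contraction_pct = if (pa > 0) 100 * la / pa else NA_real_,
               min_suitable_lat = if (length(fb))
                 min(row_lat(grid, cell_row(grid, fb))) else NA_real_)
  }
  summary <- rbind(one_basin("West"), one_basin("East"),
                   data.frame(basin = "All",
                              present_area_km2 = area_of_cells(grid, p),
                              lost_area_km2 = area_of_cells(grid, lost),
                              contraction_pct = 100 *
                                area_of_cells(grid, lost) /
                                area_of_cells(grid, p),
                              min_suitable_lat = if (length(f))
                                min(row_lat(grid, cell_row(grid, f)))
                              else NA_real_))
  structure(list(grid = grid, lost_cells = lost, gained_cells = gained,
                 present_cells = p, future_cells = f,
                 basin_split_lon = basin_split_lon, summary = summary,
                 scenario = future$label),
            class = "loss_accounting")
}

#' @export
print.loss_accounting <- function(x, ...) {
  cat(sprintf("loss_accounting [%s]: %d cells lost, %d gained\n",
              x$scenario, length(x$lost_cells), length(x$gained_cells)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Recovered-area accounting across the tolerance family
#'
#' Restricts recovery to the cells lost by the base model: for ascending
#' tolerance increases k, `recovered(k)` is the set of lost cells suitable
#' under the k-tolerance future map, the cumulative set is the running
#' union over increases up to k (a cell-wise non-monotone model is
#' permitted but logged), `incremental(k)` is what k adds over k-1, and
#' the unrecovered set is what no tolerance increase in the family
#' recovers.  By construction the identity
#' `lost = sum(incremental) + unrecovered` holds exactly, cell by cell.
#' Percentages are areas relative to the lost area.
#'
#' @param loss a [loss_accounting()] for the baseline model.
#' @param future_maps named list (ascending k, names like `k1`) of
#'   [binarize()]d future maps from the tolerance-shifted models.
#' @param k_values the tolerance increases, parallel to `future_maps`.
#' @return An object of class `recovery_ledger`: data frame `ledger`
#'   (per k: incremental/cumulative cells, areas, percentages),
#'   `unrecovered_cells`, `unrecovered_area_km2`, `unrecovered_pct`,
#'   `first_k` (matrix: 0 = not lost, k = first tolerance recovering the
#'   cell, `NA` = lost but unrecovered or masked), `n_nonmonotone`
#'   (cells that dropped back out at a higher k).
#' @export
recovery_accounting <- function(loss, future_maps,
                                k_values = seq_along(future_maps)) {
  stopifnot(inherits(loss, "loss_accounting"),
            length(future_maps) == length(k_values),
            !is.unsorted(k_values))
  grid <- loss$grid
  lost <- loss$lost_cells
  lost_area <- area_of_cells(grid, lost)
  cum_prev <- integer()
  n_nonmonotone <- 0L
  first_k <- matrix(0, grid$n_rows, grid$n_cols)
  first_k[is.na(future_maps[[1L]]$suitable)] <- NA
  first_k[lost] <- NA # lost, not (yet) recovered
  rows <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    stopifnot(same_grid(grid, future_maps[[i]]$grid))
    rec_i <- intersect(lost, suitable_cells(future_maps[[i]]))
    dropped_back <- setdiff(cum_prev, rec_i)
    n_nonmonotone <- n_nonmonotone + length(dropped_back)
    cum_i <- union(cum_prev, rec_i)
    inc_i <- setdiff(cum_i, cum_prev)
    first_k[inc_i] <- k_values[i]
    rows[[i]] <- data.frame(
      k = k_values[i],
      incremental_cells = length(inc_i),
      cumulative_cells = length(cum_i),
      incremental_area_km2 = area_of_cells(grid, inc_i),
      cumulative_area_km2 = area_of_cells(grid, cum_i))
    cum_prev <- cum_i
  }
  ledger <- do.call(rbind, rows)
  ledger$incremental_pct <- if (lost_area > 0)
    100 * ledger$incremental_area_km2 / lost_area else 0
  ledger$cumulative_pct <- if (lost_area > 0)
    100 * ledger$cumulative_area_km2 / lost_area else 0
  unrec <- setdiff(lost, cum_prev)
  if (n_nonmonotone > 0)
    message("recovery_accounting: ", n_nonmonotone,
            " cell(s) recovered at a lower k dropped out at a higher k ",
            "(model noise); cumulative sets use the running union")
  structure(list(ledger = ledger, lost_cells = lost,
                 lost_area_km2 = lost_area,
                 unrecovered_cells = unrec,
                 unrecovered_area_km2 = area_of_cells(grid, unrec),
                 unrecovered_pct = if (lost_area > 0)
                   100 * area_of_cells(grid, unrec) / lost_area else 0,
                 first_k = first_k, n_nonmonotone = n_nonmonotone,
                 scenario = loss$scenario),
            class = "recovery_ledger")
}

#' @export
print.recovery_ledger <- function(x, ...) {
  cat(sprintf("recovery_ledger [%s]: %.0f km2 lost, %.1f%% unrecovered at max k\n",
              x$scenario, x$lost_area_km2, x$unrecovered_pct))
  print(x$ledger, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.recovery_ledger <- function(x, ...) {
  graphics::plot(x$ledger$k, x$ledger$cumulative_pct, type = "b",
                 ylim = c(0, 100), xlab = "tolerance increase k (degC)",
                 ylab = "cumulative recovered area (% of lost)", ...)
  invisible(x)
}

#' Write a first-recovering-k map as an ASCII grid
#'
#' Byte coding: 0 = not lost, 1-5 = first tolerance increase recovering
#' the cell, 255 = lost but unrecovered; masked cells are nodata.
#'
#' @param ledger a [recovery_accounting()] result.
#' @param grid the map's [grid_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recovery_map <- function(ledger, grid, path) {
  m <- ledger$first_k
  m[ledger$unrecovered_cells] <- 255
  write_ascii_grid(m, grid, path)
}
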