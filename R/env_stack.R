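#' Environmental raster stack
#'
#' Bundles named environmental layers (matrices congruent with one
#' [grid_spec()]) together with a shared validity mask and a period label
#' ("present" or a scenario name).  Cells outside the mask carry `NA` in
#' every layer; present and future stacks used together must expose the
#' same variable names.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of `n_rows x n_cols` numeric matrices
#'   (e.g. `temperature` in deg C, `salinity` in PSS, `phosphate` in
#'   mol m-3).
#' @param mask logical matrix, `TRUE` for valid (sea, within depth) cells;
#'   by default the cells where every layer is non-`NA`.
#' @param period character period/scenario label.
#' @param units optional named character vector of layer units.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, mask = NULL, period = "present",
                      units = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols)
      stop("layer '", nm, "' is not congruent with the grid (",
           grid$n_rows, " x ", grid$n_cols, ")")
  }
  nas <- Reduce(`|`, lapply(layers, is.na))
  if (is.null(mask)) mask <- !nas else {
    stopifnot(is.logical(mask), all(dim(mask) == c(grid$n_rows, grid$n_cols)))
    mask <- mask & !nas
  }
  layers <- lapply(layers, function(l) { l[!mask] <- NA_real_; l })
  structure(list(grid = grid, layers = layers, mask = mask, period = period,
                 units = units),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack [%s]: %d layers on %d x %d grid, %d valid cells\n",
              x$period, length(x$layers), x$grid$n_rows, x$grid$n_cols,
              sum(x$mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_vars <- function(stack) sort(names(stack$layers))

#' Valid cell ids of a stack
#'
#' @param stack an [env_stack()].
#' @return Integer cell ids (column-major) where the mask is `TRUE`.
#' @export
valid_cells <- function(stack) which(as.vector(stack$mask))

#' Extract layer values at cells
#'
#' @param stack an [env_stack()].
#' @param cells integer cell ids.
#' @param vars variables to extract (alphabetical by default).
#' @return Data frame, one column per variable.
#' @export
extract_cells <- function(stack, cells, vars = stack_vars(stack)) {
  out <- lapply(vars, function(v) stack$layers[[v]][cells])
  names(out) <- vars
  as.data.frame(out, check.names = FALSE)
}

#' Subset a stack to named variables
#'
#' @param stack an [env_stack()].
#' @param vars variable names to keep.
#' @return An [env_stack()] with only those layers.
#' @export
keep_vars <- function(stack, vars) {
  stopifnot(all(vars %in% names(stack$layers)))
  env_stack(stack$grid, stack$layers[vars], stack$mask, stack$period,
            stack$units[intersect(names(stack$units), vars)])
}

# ---- ESRI ASCII grid I/O ------------------------------------------------

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by cell
#' values listed north to south.  Values are returned as a matrix in this
#' package's south-up row order.
#'
#' @param path file path.
#' @return `read_ascii_grid()`: a list with `grid` (a [grid_spec()]) and
#'   `values` (matrix, `NA` for nodata).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  res <- vals[["cellsize"]]
  grid <- grid_spec(vals[["xllcorner"]], vals[["xllcorner"]] + nc * res,
                    vals[["yllcorner"]], vals[["yllcorner"]] + nr * res, res)
  x <- scan(path, skip = 6L, quiet = TRUE)
  if (length(x) != nr * nc) stop("ASCII grid body has wrong length in ", path)
  x[x == vals[["nodata_value"]]] <- NA_real_
  m <- matrix(x, nrow = nr, ncol = nc, byrow = TRUE)
  list(grid = grid, values = m[nr:1, , drop = FALSE]) # flip to south-up
}

#' @rdname read_ascii_grid
#' @param grid a [grid_spec()].
#' @param values matrix congruent with `grid` (south-up row order).
#' @param nodata value written for `NA` cells.
#' @return `write_ascii_grid()`: `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(all(dim(values) == c(grid$n_rows, grid$n_cols)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$lon_min),
               sprintf("yllcorner %.10g", grid$lat_min),
               sprintf("cellsize %.10g", grid$resolution),
               sprintf("NODATA_value %g", nodata)), con)
  m <- values[grid$n_rows:1, , drop = FALSE] # north-up for the file
  m[is.na(m)] <- nodata
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an environmental stack from ASCII grid files
#'
#' All files must share the grid geometry exactly; the stack mask is the
#' union of per-layer nodata (a cell missing in any layer is masked in all).
#'
#' @param paths named character vector, variable name -> file path.
#' @param period period/scenario label.
#' @return An [env_stack()].
#' @export
load_stack <- function(paths, period = "present") {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  got <- lapply(paths, read_ascii_grid)
  grid <- got[[1L]]$grid
  bad <- names(paths)[!vapply(got, function(g) same_grid(g$grid, grid), TRUE)]
  if (length(bad))
    stop("layers not congruent with '", names(paths)[1L], "': ",
         paste(bad, collapse = ", "))
  env_stack(grid, lapply(got, `[[`, "values"), period = period)
}

#' Write an environmental stack as ASCII grid files
#'
#' One `<variable>_<period>.asc` file per layer.
#'
#' @param stack an [env_stack()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(v) {
    p <- file.path(dir, paste0(v, "_", stack$period, ".asc"))
    write_ascii_grid(stack$layers[[v]], stack$grid, p)
    p
  }, "")
  invisible(paths)
}

# ---- masking ------------------------------------------------------------

#' Restrict a stack to shallow cells inside study bounds
#'
#' Masks cells deeper than `max_depth_m` (the 200 m boundary is inclusive:
#' a cell at exactly 200 m is retained) or outside the bounding box of
#' `bounds`.
#'
#' @param stack an [env_stack()].
#' @param depth matrix of water depth in metres, congruent with the stack
#'   (`NA` = land).
#' @param max_depth_m depth cutoff in metres.
#' @param bounds optional [grid_spec()] whose bounding box clips the domain.
#' @return A new [env_stack()]; the retained-cell count is reported via
#'   `message()` and a warning is raised if no cells survive.
#' @export
apply_masks <- function(stack, depth, max_depth_m = 200, bounds = NULL) {
  stopifnot(is.matrix(depth),
            all(dim(depth) == c(stack$grid$n_rows, stack$grid$n_cols)))
  mask <- stack$mask & !is.na(depth) & depth <= max_depth_m
  if (!is.null(bounds)) {
    cc <- cell_center(stack$grid)
    inside <- cc$lon >= bounds$lon_min & cc$lon <= bounds$lon_max &
      cc$lat >= bounds$lat_min & cc$lat <= bounds$lat_max
    mask <- mask & matrix(inside[order(cc$id)], stack$grid$n_rows,
                          stack$grid$n_cols)
  }
  out <- env_stack(stack$grid, stack$layers, mask, stack$period, stack$units)
  message("apply_masks: ", sum(out$mask), " of ", n_cells(stack$grid),
          " cells retained")
  if (sum(out$mask) == 0L) warning("no valid cells remain after masking")
  out
}

# ---- correlation pruning ------------------------------------------------

#' Drop highly rank-correlated variables
#'
#' Pairwise Spearman correlations are computed on a seeded subsample of
#' valid cells.  While any unprotected pair exceeds the threshold in
#' absolute value, the member with the larger mean absolute correlation
#' against all remaining variables is dropped (ties broken by dropping the
#' alphabetically later name).  Protected variables are never dropped.
#'
#' @param stack an [env_stack()].
#' @param threshold absolute Spearman correlation above which a pair is
#'   considered collinear.
#' @param protected variable names never dropped (the temperature layer by
#'   default, mirroring its role as the focal predictor).
#' @param sample_n maximum number of valid cells used; the full grid is
#'   used when it has fewer.
#' @param seed seed for the cell subsample.
#' @return A list with `kept`, `dropped` (character vectors) and
#'   `correlations` (the full Spearman matrix).
#' @export
prune_correlated <- function(stack, threshold = 0.8,
                             protected = "temperature",
                             sample_n = 10000, seed = 1) {
  vars <- stack_vars(stack)
  if (length(vars) < 2L) stop("need at least 2 variables")
  missing_prot <- setdiff(protected, vars)
  if (length(missing_prot))
    stop("protected variable(s) absent from stack: ",
         paste(missing_prot, collapse = ", "))
  cells <- valid_cells(stack)
  if (length(cells) < 10L) stop("need at least 10 valid cells")
  if (length(cells) > sample_n)
    cells <- with_seed(seed, sample(cells, sample_n))
  vals <- extract_cells(stack, cells, vars)
  rho <- stats::cor(vals, method = "spearman")
  keep <- vars
  dropped <- character()
  repeat {
    a <- abs(rho[keep, keep, drop = FALSE]); diag(a) <- 0
    offending <- which(a > threshold, arr.ind = TRUE)
    if (!nrow(offending)) break
    involved <- unique(keep[c(offending)])
    candidates <- setdiff(involved, protected)
    if (!length(candidates)) break # only protected pairs exceed threshold
    mean_abs <- vapply(candidates, function(v) mean(a[v, setdiff(keep, v)]),
                       0)
    worst <- candidates[mean_abs == max(mean_abs)]
    drop_var <- sort(worst, decreasing = TRUE)[1L] # tie: alphabetically later
    keep <- setdiff(keep, drop_var)
    dropped <- c(dropped, drop_var)
  }
  list(kept = keep, dropped = dropped, correlations = rho)
}
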