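#' Planted thermal-niche response
#'
#' The ground truth used by the synthetic world: occupancy probability is a
#' Gaussian kernel in temperature centred on `peak_temperature`, times a
#' logistic response in one secondary variable, scaled by
#' `max_occupancy_probability`.
#'
#' @param peak_temperature thermal optimum (deg C).
#' @param thermal_sd Gaussian niche breadth (deg C).
#' @param secondary_variable name of the secondary layer.
#' @param secondary_midpoint,secondary_slope logistic midpoint and slope of
#'   the secondary response.
#' @param max_occupancy_probability occupancy probability at the optimum,
#'   in (0, 1].
#' @return An object of class `truth_response`.
#' @export
truth_response <- function(peak_temperature = 17, thermal_sd = 1.2,
                           secondary_variable = "salinity",
                           secondary_midpoint = 33, secondary_slope = 1.5,
                           max_occupancy_probability = 0.2) {
  stopifnot(thermal_sd > 0,
            max_occupancy_probability >= 0, max_occupancy_probability <= 1)
  structure(list(peak_temperature = peak_temperature, thermal_sd = thermal_sd,
                 secondary_variable = secondary_variable,
                 secondary_midpoint = secondary_midpoint,
                 secondary_slope = secondary_slope,
                 max_occupancy_probability = max_occupancy_probability),
            class = "truth_response")
}

#' True occupancy probability under the planted niche
#'
#' @param env_values named list / data frame of environmental values; must
#'   contain `temperature`, and uses the truth's secondary variable when
#'   present (a missing secondary contributes a factor of 1).
#' @param truth a [truth_response()].
#' @return Occupancy probabilities in `[0, 1]`, vectorized.
#' @export
#' @examples
#' tr <- truth_response(peak_temperature = 15)
#' truth_suitability(list(temperature = 15, salinity = 40), tr)
truth_suitability <- function(env_values, truth) {
  stopifnot(inherits(truth, "truth_response"))
  if (is.null(env_values[["temperature"]]))
    stop("env_values must contain 'temperature'")
  x <- env_values[["temperature"]]
  p <- exp(-0.5 * ((x - truth$peak_temperature) / truth$thermal_sd)^2)
  sec <- env_values[[truth$secondary_variable]]
  if (!is.null(sec))
    p <- p * stats::plogis(truth$secondary_slope *
                             (sec - truth$secondary_midpoint))
  p * truth$max_occupancy_probability
}

#' Generate a seeded synthetic world
#'
#' Builds the present-day environmental stack, per-scenario future stacks,
#' a depth field with a coastal shelf, a land/sea mask, and the planted
#' [truth_response()] — everything downstream stages need, reproducible
#' bit-for-bit from the seed.
#'
#' Layers emulate the structure of a marine climatology stack:
#' * `temperature` (deg C): monotone south-to-north cooling gradient plus
#'   smooth seeded noise (maximum SST analogue);
#' * `salinity` (PSS) and `phosphate` (mol m-3): smooth fields with mild
#'   latitudinal structure;
#' * `degree_days`: a strictly increasing transform of temperature, so its
#'   Spearman correlation with temperature is exactly 1 (exercises the
#'   collinearity pruning);
#' * `turbidity`: pure smoothed noise, uninformative by construction
#'   (exercises the <5% contribution filter).
#'
#' Future stacks differ from the present only in temperature:
#' `present + offset`, optionally scaled linearly with latitude via
#' `options$warming_lat_slope` (per degree latitude, centred mid-grid).
#'
#' @param grid a [grid_spec()]; defaults to the compact [synthetic_grid()].
#' @param scenario_offsets named numeric vector of warming offsets (deg C),
#'   one future stack per entry.
#' @param seed integer seed controlling every random field.
#' @param truth a [truth_response()].
#' @param options list of generator knobs: `t_south` (southern-edge
#'   temperature, deg C), `lat_gradient` (cooling per degree latitude),
#'   `noise_sd` (deg C), `noise_sigma` (smoothing length, cells),
#'   `warming_lat_slope`, `land_quantile` (fraction of cells that are sea).
#' @return A list of class `world_bundle`: `present` (an [env_stack()]),
#'   `future` (named list of stacks), `depth` (matrix, m), `sea` (logical
#'   matrix), `mask` (sea and depth <= 200 m), `truth`, `seed`, `species`.
#' @export
make_world <- function(grid = synthetic_grid(),
                       scenario_offsets = c(warm3 = 3),
                       seed = 1,
                       truth = truth_response(),
                       options = list()) {
  stopifnot(inherits(grid, "grid_spec"), length(scenario_offsets) >= 1,
            !is.null(names(scenario_offsets)),
            any(scenario_offsets >= 0))
  if (grid$n_rows < 2L) stop("degenerate grid: n_rows must be >= 2")
  if (grid$n_cols < 2L) stop("degenerate grid: n_cols must be >= 2")
  o <- utils::modifyList(list(t_south = 26, lat_gradient = 1.8,
                              noise_sd = 0.8, noise_sigma = 6,
                              warming_lat_slope = 0, land_quantile = 0.85,
                              species = "synthetic_kelp"), options)
  nr <- grid$n_rows; nc <- grid$n_cols
  lat <- matrix(row_lat(grid), nr, nc)
  seed <- as.integer(seed)

  temperature <- o$t_south - o$lat_gradient * (lat - grid$lat_min) +
    o$noise_sd * smooth_noise(nr, nc, o$noise_sigma, seed)
  salinity <- 34 + 0.8 * smooth_noise(nr, nc, o$noise_sigma, seed + 1L) +
    0.05 * (lat - grid$lat_min)
  phosphate <- pmax(0.1 + 0.03 * (lat - grid$lat_min) +
                      0.15 * smooth_noise(nr, nc, o$noise_sigma, seed + 2L),
                    0.01)
  degree_days <- 10 * exp(temperature / 8) # strictly increasing in temperature
  turbidity <- smooth_noise(nr, nc, o$noise_sigma, seed + 3L)

  depth <- 500 * stats::plogis(1.2 * smooth_noise(nr, nc, 2 * o$noise_sigma,
                                                  seed + 4L))
  land_field <- smooth_noise(nr, nc, 2 * o$noise_sigma, seed + 5L)
  sea <- land_field <= stats::quantile(land_field, o$land_quantile)
  depth[!sea] <- NA_real_
  mask <- sea & !is.na(depth) & depth <= 200

  layers <- list(temperature = temperature, salinity = salinity,
                 phosphate = phosphate, degree_days = degree_days,
                 turbidity = turbidity)
  units <- c(temperature = "degC", salinity = "PSS",
             phosphate = "mol m-3", degree_days = "degC d",
             turbidity = "NTU")
  present <- env_stack(grid, layers, sea, period = "present", units = units)
  mid_lat <- (grid$lat_min + grid$lat_max) / 2
  future <- lapply(names(scenario_offsets), function(sc) {
    off <- scenario_offsets[[sc]] * (1 + o$warming_lat_slope * (lat - mid_lat))
    fl <- layers
    fl$temperature <- temperature + off
    fl$degree_days <- 10 * exp(fl$temperature / 8)
    env_stack(grid, fl, sea, period = sc, units = units)
  })
  names(future) <- names(scenario_offsets)

  structure(list(present = present, future = future, depth = depth,
                 sea = sea, mask = mask, truth = truth, seed = seed,
                 species = o$species),
            class = "world_bundle")
}

#' @export
print.world_bundle <- function(x, ...) {
  cat(sprintf("world_bundle (seed %d): %d x %d grid, %d modelling cells\n",
              x$seed, x$present$grid$n_rows, x$present$grid$n_cols,
              sum(x$mask)))
  cat("  scenarios:", paste(names(x$future), collapse = ", "), "\n")
  invisible(x)
}

#' Sample occurrence records from a synthetic world
#'
#' Draws Bernoulli(`truth_suitability`) over the world's modelling cells,
#' repeating passes until at least `n_target` distinct cells are occupied
#' (or `max_passes` is hit, which is an error reporting the attainable
#' count).  One record is emitted per occupied cell, at the cell center
#' plus seeded jitter smaller than half a cell.
#'
#' @param world a [make_world()] bundle.
#' @param n_target minimum number of occupied cells.
#' @param seed integer seed.
#' @param max_passes pass cap.
#' @return A data frame with columns `species`, `longitude`, `latitude`,
#'   `uncertainty_m`, carrying the occupied cell ids as attribute `cells`.
#' @export
sample_occurrences <- function(world, n_target, seed = 1, max_passes = 20) {
  stopifnot(inherits(world, "world_bundle"), n_target >= 1)
  grid <- world$present$grid
  cells <- which(as.vector(world$mask))
  env <- extract_cells(world$present, cells)
  p <- truth_suitability(env, world$truth)
  if (max(p) <= 0)
    stop("no cells attainable: planted occupancy probability is 0 everywhere")
  occupied <- with_seed(seed, {
    occ <- integer()
    for (pass in seq_len(max_passes)) {
      hit <- stats::runif(length(p)) < p
      occ <- union(occ, cells[hit])
      if (length(occ) >= n_target) break
    }
    occ
  })
  if (length(occupied) < n_target)
    stop("n_target unreachable within ", max_passes, " passes; attainable: ",
         length(occupied), " occupied cells")
  occupied <- sort(occupied)
  cc <- cell_center(grid, occupied)
  jit <- grid$resolution / 2 * 0.999
  out <- with_seed(seed + 1L, data.frame(
    species = world$species,
    longitude = cc$lon + stats::runif(nrow(cc), -jit, jit),
    latitude = cc$lat + stats::runif(nrow(cc), -jit, jit),
    uncertainty_m = round(stats::runif(nrow(cc), 10, 4000))))
  attr(out, "cells") <- occupied
  out
}

#' Write a synthetic world to disk
#'
#' Layers go out as one ASCII grid per variable per period (plus the depth
#' field), occurrences as CSV.
#'
#' @param world a [make_world()] bundle.
#' @param dir output directory.
#' @param occurrences optional data frame from [sample_occurrences()].
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir, occurrences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(world$present, dir)
  for (f in world$future) write_stack(f, dir)
  write_ascii_grid(world$depth, world$present$grid,
                   file.path(dir, "depth.asc"))
  if (!is.null(occurrences))
    utils::write.csv(occurrences, file.path(dir, "occurrences.csv"),
                     row.names = FALSE)
  invisible(dir)
}
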