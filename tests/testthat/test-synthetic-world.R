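test_that("future stacks are the present plus the stated uniform offset", {
  w <- tiny_world(seed = 5, offsets = c(warm2 = 2, warm4 = 4))
  ok <- w$present$mask
  for (sc in c("warm2", "warm4")) {
    d <- w$future[[sc]]$layers$temperature - w$present$layers$temperature
    expect_equal(unique(round(d[ok], 12)), as.numeric(sub("warm", "", sc)))
    # non-temperature layers are untouched
    expect_identical(w$future[[sc]]$layers$salinity,
                     w$present$layers$salinity)
  }
})

test_that("identical seed and options give a bit-identical bundle", {
  expect_identical(tiny_world(seed = 7), tiny_world(seed = 7))
  w2 <- tiny_world(seed = 8)
  expect_false(identical(tiny_world(seed = 7)$present$layers$temperature,
                         w2$present$layers$temperature))
})

test_that("the monotone-transform layer has Spearman rho exactly 1", {
  w <- tiny_world()
  cells <- valid_cells(w$present)
  expect_equal(cor(w$present$layers$temperature[cells],
                   w$present$layers$degree_days[cells],
                   method = "spearman"), 1)
})

test_that("degenerate grids are rejected naming the offending dimension", {
  expect_error(make_world(grid_spec(0, 10, 40, 40.05, 0.05), c(a = 1)),
               "n_rows")
  expect_error(make_world(grid_spec(0, 0.05, 40, 50, 0.05), c(a = 1)),
               "n_cols")
})

test_that("truth_suitability follows the Gaussian-times-logistic form", {
  tr <- truth_response(peak_temperature = 15, thermal_sd = 2,
                       secondary_midpoint = 30, secondary_slope = 1,
                       max_occupancy_probability = 0.6)
  # kernel maximum at the peak with a saturating secondary
  at_peak <- truth_suitability(list(temperature = 15, salinity = 1e4), tr)
  expect_equal(at_peak, 0.6, tolerance = 1e-12)
  # far tails vanish
  expect_lt(truth_suitability(list(temperature = 15 + 20 * 2,
                                   salinity = 1e4), tr), 1e-20 * 0.6)
  # one thermal sd away: exp(-1/2) of the peak value, secondary fixed
  sal <- 31.7
  v_peak <- truth_suitability(list(temperature = 15, salinity = sal), tr)
  v_sd <- truth_suitability(list(temperature = 17, salinity = sal), tr)
  expect_equal(v_sd, exp(-0.5) * v_peak)
  expect_error(truth_suitability(list(salinity = 30), tr), "temperature")
})

test_that("occurrence sampling respects the planted response", {
  w <- tiny_world()
  # degenerate truth: nothing attainable
  w0 <- w
  w0$truth <- truth_response(max_occupancy_probability = 0)
  expect_error(sample_occurrences(w0, 1), "no cells attainable")

  # forced outcome: exactly one cell has suitability 1, all others ~0
  cells <- which(as.vector(w$mask))
  target <- cells[100]
  w1 <- w
  w1$truth <- truth_response(
    peak_temperature = w$present$layers$temperature[target],
    thermal_sd = 1e-9, secondary_variable = "absent_layer",
    max_occupancy_probability = 1)
  occ1 <- sample_occurrences(w1, 1, seed = 4)
  expect_equal(nrow(occ1), 1L)
  expect_equal(attr(occ1, "cells"), target)

  # records never fall on masked cells and jitter stays within the cell
  occ <- sample_occurrences(w, 250, seed = 3)
  ids <- attr(occ, "cells")
  expect_true(all(w$mask[ids]))
  loc <- locate_cells(w$present$grid, occ$longitude, occ$latitude)
  expect_equal(loc$id, ids)
})

test_that("sampled occurrences center on the planted thermal optimum", {
  w <- tiny_world()
  occ <- sample_occurrences(w, 500, seed = 21)
  temps <- w$present$layers$temperature[attr(occ, "cells")]
  # independent expectation over the grid: E[T | occupied] for one pass
  cells <- which(as.vector(w$mask))
  p <- truth_suitability(extract_cells(w$present, cells), w$truth)
  t_all <- w$present$layers$temperature[cells]
  expected <- sum(t_all * p) / sum(p)
  expect_lt(abs(mean(temps) - w$truth$peak_temperature), 1)
  expect_lt(abs(mean(temps) - expected), 0.3)
})

test_that("occurrence density is proportional to the planted suitability", {
  w <- tiny_world()
  cells <- which(as.vector(w$mask))
  p <- truth_suitability(extract_cells(w$present, cells), w$truth)
  t_all <- w$present$layers$temperature[cells]
  # single Bernoulli pass so occupancy probability is exactly p
  occ <- sample_occurrences(w, 1, seed = 9, max_passes = 1)
  hit <- cells %in% attr(occ, "cells")
  breaks <- quantile(t_all, seq(0, 1, length.out = 7))
  bin <- cut(t_all, breaks, include.lowest = TRUE)
  expected <- tapply(p, bin, sum)
  observed <- tapply(hit, bin, sum)
  keep <- expected > 5
  chi <- suppressWarnings(
    chisq.test(observed[keep], p = expected[keep] / sum(expected[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("a world round-trips through its on-disk form", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  occ <- sample_occurrences(w, 50, seed = 2)
  write_world(w, dir, occ)
  st <- load_stack(c(temperature = file.path(dir, "temperature_present.asc"),
                     salinity = file.path(dir, "salinity_present.asc")))
  expect_equal(st$layers$temperature[w$present$mask],
               w$present$layers$temperature[w$present$mask],
               tolerance = 1e-8)
  occ2 <- load_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ2), nrow(occ))
})
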