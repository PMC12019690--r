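test_that("the capture threshold is the stated order statistic", {
  ladder <- seq(0.05, 1, by = 0.05) # 20 occurrence suitabilities
  expect_equal(capture_threshold(ladder, 0.95), 0.10) # drops only 0.05
  expect_equal(capture_threshold(ladder, 1.0), 0.05)  # the minimum
  expect_equal(capture_threshold(rep(0.4, 30), 0.95), 0.4)
  expect_error(capture_threshold(numeric(0)), "no occupied cells")
  expect_warning(capture_threshold(runif(5)), "unstable")
})

test_that("binarization keeps the promised occurrence fraction", {
  g <- grid_spec(0, 1, 50, 51, resolution = 0.1)
  suit <- matrix(withr::with_seed(2, runif(100)), 10, 10)
  occ_cells <- 1:40
  thr <- capture_threshold(suit[occ_cells], 0.95)
  bm <- binarize(suit, thr, g)
  expect_gte(mean(suit[occ_cells] >= thr), 0.95)
  expect_equal(which(as.vector(bm$suitable)), which(as.vector(suit >= thr)))
  # extreme thresholds
  expect_equal(sum(binarize(suit, 0.999999, g)$suitable), 0)
  expect_equal(sum(binarize(suit, 1e-9, g)$suitable), 100)
  expect_error(binarize(suit, 1.2, g))
})

# a 1-row sea strip: cells A, B, C, D at the same latitude (equal areas)
strip_maps <- function(pres, fut) {
  g <- grid_spec(0, 0.2, 50, 50.05, resolution = 0.05)
  mk <- function(cells) {
    m <- matrix(0.01, 1, 4)
    m[cells] <- 0.99
    binarize(m, 0.5, g)
  }
  list(g = g, present = mk(pres), future = mk(fut))
}

test_that("loss accounting enumerates lost cells and contraction", {
  s <- strip_maps(pres = c(1, 2, 3), fut = 2)
  out <- loss_accounting(s$present, s$future, basin_split_lon = 0.1)
  expect_setequal(out$lost_cells, c(1, 3))
  all_row <- out$summary[out$summary$basin == "All", ]
  expect_equal(all_row$contraction_pct, 2 / 3 * 100, tolerance = 1e-12)
  # future superset of present: nothing lost
  s2 <- strip_maps(pres = 2, fut = c(1, 2, 3))
  out2 <- loss_accounting(s2$present, s2$future)
  expect_length(out2$lost_cells, 0)
  expect_equal(out2$summary$contraction_pct[3], 0)
  expect_setequal(out2$gained_cells, c(1, 3))
})

test_that("minimum suitable latitude is taken over future cells per basin", {
  g <- grid_spec(-80, -20, 35, 75, resolution = 5)
  pres <- matrix(0.9, g$n_rows, g$n_cols)
  fut <- matrix(0.01, g$n_rows, g$n_cols)
  # future-suitable at rows 4 and 6 (lat centers 52.5, 62.5), west of -40
  fut[4, 2] <- 0.9; fut[6, 2] <- 0.9
  out <- loss_accounting(binarize(pres, 0.5, g), binarize(fut, 0.5, g),
                         basin_split_lon = -40)
  s <- out$summary
  expect_equal(s$min_suitable_lat[s$basin == "West"], 52.5)
  expect_true(is.na(s$min_suitable_lat[s$basin == "East"]))
  expect_error(loss_accounting(binarize(fut * 0 + 0.01, 0.5, g),
                               binarize(fut, 0.5, g)),
               "no suitable cells")
})

test_that("recovery accounting splits losses into incremental gains", {
  s <- strip_maps(pres = c(1, 3, 4), fut = 4) # lost = {A, C}
  loss <- loss_accounting(s$present, s$future, basin_split_lon = 0.3)
  mk <- function(cells) {
    m <- matrix(0.01, 1, 4); m[cells] <- 0.99
    binarize(m, 0.5, s$g)
  }
  rec <- recovery_accounting(loss, list(k1 = mk(c(1, 4)),
                                        k2 = mk(c(1, 3, 4))),
                             k_values = 1:2)
  expect_equal(rec$ledger$incremental_pct, c(50, 50))
  expect_equal(rec$ledger$cumulative_pct, c(50, 100))
  expect_length(rec$unrecovered_cells, 0)
  expect_equal(rec$first_k[1], 1)
  expect_equal(rec$first_k[3], 2)
  expect_equal(rec$first_k[2], 0) # never lost

  # no model recovers anything
  rec0 <- recovery_accounting(loss, list(k1 = mk(4)), k_values = 1)
  expect_equal(rec0$ledger$cumulative_pct, 0)
  expect_setequal(rec0$unrecovered_cells, loss$lost_cells)
  expect_equal(rec0$unrecovered_pct, 100)
})

test_that("a cell that drops back out stays recovered via the running union", {
  s <- strip_maps(pres = c(1, 2, 3), fut = 3) # lost = {A, B}
  loss <- loss_accounting(s$present, s$future, basin_split_lon = 0.3)
  mk <- function(cells) {
    m <- matrix(0.01, 1, 4); m[cells] <- 0.99
    binarize(m, 0.5, s$g)
  }
  # k1 recovers A; k2 loses A again but recovers B
  expect_message(
    rec <- recovery_accounting(loss, list(k1 = mk(c(1, 3)),
                                          k2 = mk(c(2, 3)))),
    "running union")
  expect_equal(rec$n_nonmonotone, 1L)
  expect_equal(rec$ledger$cumulative_cells, c(1, 2))
  # identity still exact
  expect_setequal(c(rec$ledger$incremental_cells, 0),
                  c(1, 1, length(rec$unrecovered_cells)))
  expect_true(all(diff(rec$ledger$cumulative_pct) >= 0))
})

test_that("recovery maps encode first-recovering k on disk", {
  s <- strip_maps(pres = c(1, 2, 3), fut = 3)
  loss <- loss_accounting(s$present, s$future, basin_split_lon = 0.3)
  mk <- function(cells) {
    m <- matrix(0.01, 1, 4); m[cells] <- 0.99
    binarize(m, 0.5, s$g)
  }
  rec <- recovery_accounting(loss, list(k1 = mk(c(1, 3)), k2 = mk(c(1, 3))))
  path <- withr::local_tempfile(fileext = ".asc")
  write_recovery_map(rec, s$g, path)
  vals <- read_ascii_grid(path)$values
  expect_equal(vals[1, ], c(1, 255, 0, 0)) # recovered at 1; unrecovered; not lost
})
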