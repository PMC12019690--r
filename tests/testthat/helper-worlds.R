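# shared fixtures, built in code and memoised for the session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a compact world whose temperature range (about 14-20 degC) brackets the
# planted 17 degC optimum on an 80 x 100 grid
tiny_world <- function(seed = 7, offsets = c(warm3 = 3)) {
  make_world(synthetic_grid(n_rows = 80, n_cols = 100), offsets, seed = seed,
             options = list(t_south = 20, lat_gradient = 1.2))
}

tiny_study_parts <- function() cached("tiny_parts", {
  w <- tiny_world()
  occ <- sample_occurrences(w, 250, seed = 3)
  st <- suppressMessages(apply_masks(w$present, w$depth))
  g <- grid_occurrences(occ, st$grid, st$mask)
  pr <- prune_correlated(st)
  st2 <- keep_vars(st, pr$kept)
  folds <- assign_folds(st2$grid, st2$mask, 1, k = 5, seed = 2,
                        presence_cells = g$cells)
  list(world = w, occ = occ, stack = st2, gocc = g, folds = folds,
       pruning = pr)
})

tiny_cv <- function() cached("tiny_cv", {
  p <- tiny_study_parts()
  suppressWarnings(cross_validate(p$gocc, p$stack, p$folds, bg_max = 4000))
})

# a small presence/background pair with a planted thermal optimum, for
# direct maxent-level tests
planted_fit_data <- function(seed = 11, n_pres = 120, n_bg = 1500) {
  withr::with_seed(seed, {
    bg <- data.frame(temperature = runif(n_bg, 8, 26),
                     noise = rnorm(n_bg))
    w <- exp(-0.5 * ((bg$temperature - 16) / 1.5)^2)
    idx <- sample(n_bg, n_pres, replace = TRUE, prob = w)
    list(presence = bg[idx, ], background = bg)
  })
}

# the full-scale synthetic study shared by the acceptance checks
acceptance_study <- function() cached("acceptance_study",
  suppressMessages(suppressWarnings(run_synthetic_study(seed = 1))))
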