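#' Ensemble suitability map
#'
#' Mean cloglog prediction of a list of sub-models over the valid cells of
#' a stack.
#'
#' @param fits list of [fit_maxnet()] models.
#' @param stack an [env_stack()].
#' @return Suitability matrix (masked cells `NA`).
#' @export
predict_map <- function(fits, stack) {
  vcells <- valid_cells(stack)
  env <- extract_cells(stack, vcells)
  vals <- rowMeans(vapply(fits, function(ft) predict(ft, env),
                          numeric(length(vcells))))
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[vcells] <- vals
  out
}

#' Iterative low-contribution variable filter
#'
#' Fits a model at the default hyperparameters, measures
#' [permutation_importance()], and drops every variable contributing less
#' than `threshold` percent (the temperature layer is protected and kept
#' regardless, with a log message).  With survivors the model is refitted
#' and the filter applied once more (at most two rounds).
#'
#' @param stack an [env_stack()] (after correlation pruning).
#' @param occ a [grid_occurrences()] result.
#' @param threshold minimum percent contribution.
#' @param protected variables never dropped.
#' @param classes,multiplier hyperparameters for the filtering fits.
#' @param bg_max,seed background cap and RNG seed.
#' @param n_repeats permutation repeats.
#' @return List with `kept`, `dropped`, and `importance` (one named
#'   vector per round).
#' @export
contribution_filter <- function(stack, occ, threshold = 5,
                                protected = "temperature",
                                classes = feature_class_names,
                                multiplier = 1, bg_max = 10000, seed = 1,
                                n_repeats = 3L) {
  vars <- stack_vars(stack)
  if (length(vars) < 2L) stop("need at least 2 variables")
  stopifnot(all(protected %in% vars))
  vcells <- valid_cells(stack)
  bg_cells <- if (length(vcells) > bg_max)
    sort(with_seed(seed, sample(vcells, bg_max))) else vcells
  presence_cells <- intersect(occ$cells, vcells)
  rounds <- list()
  kept <- vars
  dropped <- character()
  for (round in 1:2) {
    env_p <- extract_cells(stack, presence_cells, kept)
    env_b <- extract_cells(stack, bg_cells, kept)
    fit <- fit_maxnet(env_p, env_b, classes = classes,
                      multiplier = multiplier)
    imp <- permutation_importance(fit, env_p, env_b,
                                  n_repeats = n_repeats, seed = seed + round)
    rounds[[round]] <- imp
    low <- names(imp)[imp < threshold]
    low_protected <- intersect(low, protected)
    if (length(low_protected))
      message("contribution_filter: protected variable(s) below threshold ",
              "but kept: ", paste(low_protected, collapse = ", "))
    drop_now <- setdiff(low, protected)
    if (!length(drop_now)) break
    if (length(setdiff(kept, drop_now)) == 0L) {
      message("contribution_filter: all variables below threshold; ",
              "keeping protected set only")
      drop_now <- setdiff(kept, protected)
    }
    kept <- setdiff(kept, drop_now)
    dropped <- c(dropped, drop_now)
    if (length(kept) < 2L) break
  }
  list(kept = kept, dropped = dropped, importance = rounds)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list.  Defaults are the study conditions: 0.05 degree cells, 200 m
#' depth limit, |Spearman rho| > 0.8 pruning with temperature protected,
#' 5% contribution filter, linear/quadratic/product features at beta
#' multiplier 1, 5 spatial folds, 95% occurrence capture, tolerance
#' increases 1-5 deg C.
#'
#' @param species species label for the synthetic world.
#' @param seed master seed; stage seeds are derived from it.
#' @param grid modelling [grid_spec()].
#' @param scenario_offsets named warming offsets (deg C) defining the
#'   future scenarios of the synthetic world.
#' @param n_occurrences target occupied cells for the synthetic sample.
#' @param world_options options passed to [make_world()].
#' @param truth the planted [truth_response()].
#' @param max_uncertainty_m occurrence spatial-uncertainty cutoff.
#' @param max_depth_m depth mask limit.
#' @param correlation_threshold Spearman pruning threshold.
#' @param contribution_threshold percent contribution filter.
#' @param protected never-dropped variables.
#' @param candidates hyperparameter candidates
#'   (see [default_candidates()]).
#' @param k_folds number of spatial folds.
#' @param block_candidates candidate block sizes in degrees.
#' @param capture occurrence-capture fraction for binarization.
#' @param k_list tolerance increases to simulate.
#' @param increase_rate logistic steepness of the tolerance transform.
#' @param calibration `"full"` or `"fast"` (see [calibrate_Tinc()]).
#' @param basin_split_lon basin split meridian.
#' @param bg_max background cell cap.
#' @param outdir optional output directory for rasters, tables, manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(species = "synthetic_kelp", seed = 1,
                       grid = synthetic_grid(),
                       scenario_offsets = c(warm1 = 1, warm3 = 3, warm5 = 5),
                       n_occurrences = 500,
                       world_options = list(),
                       truth = truth_response(),
                       max_uncertainty_m = 10000,
                       max_depth_m = 200,
                       correlation_threshold = 0.8,
                       contribution_threshold = 5,
                       protected = "temperature",
                       candidates = default_candidates(),
                       k_folds = 5L,
                       block_candidates = c(0.5, 1, 2, 4),
                       capture = 0.95,
                       k_list = 1:5,
                       increase_rate = 2,
                       calibration = "full",
                       basin_split_lon = NULL,
                       bg_max = 10000,
                       outdir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$basin_split_lon))
    cfg$basin_split_lon <- (grid$lon_min + grid$lon_max) / 2
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-world generation (or the supplied world),
#' depth/land masking, occurrence curation and gridding, Spearman
#' correlation pruning, the <threshold% contribution filter, block-size
#' choice and fold assignment, cross-validated hyperparameter selection
#' and the base ensemble, occurrence-capture binarization of present and
#' scenario projections, the calibrated tolerance family, and the
#' lost/recovered-area ledgers.  With `config$outdir` set, rasters
#' (ASCII grids), tables (CSV/JSON) and a run manifest are written.
#'
#' @param config a [run_config()].
#' @param world optional pre-built [make_world()] bundle.
#' @param occurrences optional occurrence data frame (else sampled from
#'   the world).
#' @return An object of class `pipeline_run` collecting every stage
#'   result; see the elements `cv`, `losses`, `recoveries`.
#' @export
run_pipeline <- function(config, world = NULL, occurrences = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  stage <- function(...) message("[pipeline] ", ...)

  stage("synthetic world")
  if (is.null(world))
    world <- make_world(config$grid, config$scenario_offsets, seed = seed,
                        truth = config$truth,
                        options = utils::modifyList(
                          list(species = config$species),
                          config$world_options))
  grid <- world$present$grid
  if (is.null(occurrences))
    occurrences <- sample_occurrences(world, config$n_occurrences,
                                      seed = seed + 100L)

  stage("masks (depth <= ", config$max_depth_m, " m)")
  present <- apply_masks(world$present, world$depth, config$max_depth_m)
  scenarios <- lapply(world$future, function(s)
    env_stack(grid, s$layers, present$mask, s$period, s$units))

  stage("occurrence curation and gridding")
  occ_f <- filter_occurrences(occurrences, config$max_uncertainty_m,
                              bounds = grid)
  gocc <- grid_occurrences(occ_f, grid, mask = present$mask)

  stage("correlation pruning (|rho| > ", config$correlation_threshold, ")")
  pruning <- prune_correlated(present, config$correlation_threshold,
                              config$protected, seed = seed + 200L)
  stack1 <- keep_vars(present, pruning$kept)

  stage("contribution filter (< ", config$contribution_threshold, "%)")
  contrib <- contribution_filter(stack1, gocc,
                                 threshold = config$contribution_threshold,
                                 protected = config$protected,
                                 bg_max = config$bg_max, seed = seed + 300L)
  stack2 <- keep_vars(stack1, contrib$kept)
  scenarios2 <- lapply(scenarios, keep_vars, vars = contrib$kept)

  stage("spatial folds")
  block_size <- choose_block_size(stack2$layers$temperature, grid,
                                  config$block_candidates,
                                  mask = stack2$mask, seed = seed + 400L)
  folds <- assign_folds(grid, stack2$mask, block_size, k = config$k_folds,
                        seed = seed + 500L, presence_cells = gocc$cells)

  stage("cross-validated base ensemble")
  cv <- cross_validate(gocc, stack2, folds, config$candidates,
                       bg_max = config$bg_max, seed = seed + 600L,
                       capture = config$capture)

  stage("binarization and base-model loss accounting")
  present_bin <- binarize(cv$suitability, cv$threshold, grid, "present")
  base_future <- lapply(scenarios2, function(sc)
    binarize(predict_map(cv$fits, sc), cv$threshold, grid, sc$period))
  losses <- lapply(base_future, function(bm)
    loss_accounting(present_bin, bm, config$basin_split_lon))

  stage("tolerance family (k in {", paste(config$k_list, collapse = ","),
        "}, ", config$calibration, " calibration)")
  family <- train_shifted_family(cv, stack2, scenarios2,
                                 k_list = config$k_list,
                                 increase_rate = config$increase_rate,
                                 calibration = config$calibration)

  stage("recovery accounting")
  ok_k <- !vapply(family, inherits, TRUE, what = "error")
  recoveries <- lapply(names(scenarios2), function(sc) {
    maps <- lapply(family[ok_k], function(fk)
      binarize(fk$future[[sc]], fk$threshold, grid, sc))
    recovery_accounting(losses[[sc]], maps,
                        k_values = config$k_list[ok_k])
  })
  names(recoveries) <- names(scenarios2)

  run <- structure(list(config = config, world = world,
                        occurrences = occurrences, occ_filtered = occ_f,
                        gridded = gocc, pruning = pruning,
                        contributions = contrib, block_size = block_size,
                        folds = folds, cv = cv,
                        present_map = present_bin, base_future = base_future,
                        losses = losses, family = family,
                        recoveries = recoveries),
                   class = "pipeline_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", x$config$species, "seed", x$config$seed, "\n")
  print(x$cv)
  for (sc in names(x$losses)) {
    cat("scenario", sc, ": contraction ",
        sprintf("%.1f%%", x$losses[[sc]]$summary$contraction_pct[3L]),
        ", recovered at max k ",
        sprintf("%.1f%%",
                max(x$recoveries[[sc]]$ledger$cumulative_pct)), "\n")
  }
  invisible(x)
}

# write rasters, tables and the manifest for a finished run
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- run$world$present$grid
  write_ascii_grid(run$cv$suitability, grid,
                   file.path(outdir, "suitability_present.asc"))
  write_ascii_grid(run$present_map$suitable + 0, grid,
                   file.path(outdir, "binary_present.asc"))
  utils::write.csv(run$cv$metrics, file.path(outdir, "cv_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$cv$selection, file.path(outdir, "cv_selection.csv"),
                   row.names = FALSE)
  ledgers <- do.call(rbind, lapply(names(run$recoveries), function(sc) {
    l <- run$recoveries[[sc]]$ledger
    l$scenario <- sc
    l
  }))
  utils::write.csv(ledgers, file.path(outdir, "recovery_ledger.csv"),
                   row.names = FALSE)
  loss_tbl <- do.call(rbind, lapply(names(run$losses), function(sc) {
    s <- run$losses[[sc]]$summary
    s$scenario <- sc
    s
  }))
  utils::write.csv(loss_tbl, file.path(outdir, "loss_summary.csv"),
                   row.names = FALSE)
  for (sc in names(run$recoveries))
    write_recovery_map(run$recoveries[[sc]], grid,
                       file.path(outdir, paste0("recovery_", sc, ".asc")))
  manifest <- list(
    package = "thermoshift",
    version = as.character(utils::packageVersion("thermoshift")),
    r_version = R.version.string,
    seed = run$config$seed,
    species = run$config$species,
    grid = unclass(run$config$grid),
    scenario_offsets = as.list(run$config$scenario_offsets),
    k_list = run$config$k_list,
    capture = run$config$capture,
    correlation_threshold = run$config$correlation_threshold,
    contribution_threshold = run$config$contribution_threshold,
    increase_rate = run$config$increase_rate,
    calibration = run$config$calibration,
    variables_kept = run$contributions$kept,
    block_size_deg = as.numeric(run$block_size),
    chosen_candidate = run$cv$candidate,
    threshold = run$cv$threshold,
    transforms = lapply(Filter(function(f) !inherits(f, "error"),
                               run$family),
                        function(f) unclass(f$transform)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' One-call synthetic study
#'
#' Runs the whole pipeline on the default synthetic world (compact grid,
#' planted thermal peak at 17 deg C, about 500 occurrence cells) and
#' returns the headline quantities: the fitted suitability peak, the
#' cross-validation skill, variable contributions, and the loss/recovery
#' ledger of each scenario.  This is the entry point the acceptance
#' checks and the worked examples use.
#'
#' @param seed master seed.
#' @param ... overrides passed to [run_config()].
#' @return A list with `peak`, `mean_auc_test`, `mean_auc_train`,
#'   `mean_tss`, `importance` (percent per variable, final round),
#'   `pruned`, `dropped_contribution`, `threshold`, `n_presence_cells`,
#'   `losses` and `recoveries` (per scenario summaries), and `run` (the
#'   full [run_pipeline()] object).
#' @export
run_synthetic_study <- function(seed = 1, ...) {
  cfg <- run_config(seed = seed, ...)
  run <- run_pipeline(cfg)
  imp <- run$contributions$importance
  list(peak = suitability_peak(response_curve(run$cv$pooled_fit)),
       mean_auc_test = mean(run$cv$metrics$auc_test),
       mean_auc_train = mean(run$cv$metrics$auc_train),
       mean_tss = mean(run$cv$metrics$tss_test),
       importance = imp[[length(imp)]],
       first_round_importance = imp[[1L]],
       pruned = run$pruning$dropped,
       dropped_contribution = run$contributions$dropped,
       threshold = run$cv$threshold,
       n_presence_cells = length(run$cv$presence_cells),
       losses = lapply(run$losses, `[[`, "summary"),
       recoveries = lapply(run$recoveries, `[[`, "ledger"),
       run = run)
}
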