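#' Rank-based AUC (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half.
#'
#' @param positive,negative numeric score vectors (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.4), c(0.5, 0.1)) # 0.75
auc <- function(positive, negative) {
  if (!length(positive) || !length(negative))
    stop("both score sets must be non-empty")
  np <- length(positive); nn <- length(negative)
  r <- rank(c(positive, negative))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' True Skill Statistic
#'
#' Sensitivity + specificity - 1 for binary predictions against
#' presence/background-as-absence labels.
#'
#' @param predicted logical (or 0/1) predicted-suitable vector.
#' @param actual logical presence labels (background treated as absence).
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  if (!any(actual) || all(actual))
    stop("need both presences and absences to compute TSS")
  sens <- mean(predicted[actual])
  spec <- mean(!predicted[!actual])
  sens + spec - 1
}

#' Choose a spatial block size from the temperature correlogram
#'
#' Computes a Moran-type empirical correlogram of the layer on a seeded
#' sample of valid cells (correlation of cell pairs binned by distance in
#' degrees) and returns the smallest candidate block size at least as
#' large as the distance where autocorrelation first drops below 0.1.  If
#' no candidate is large enough, the largest is returned with a warning.
#' A single candidate is returned as-is.
#'
#' @param layer matrix of values (typically the temperature layer).
#' @param grid a [grid_spec()].
#' @param candidates candidate block sizes in degrees.
#' @param mask optional validity matrix.
#' @param seed RNG seed for the cell sample.
#' @param n_sample cells sampled for the correlogram.
#' @param bin_width correlogram distance-bin width in degrees.
#' @return Chosen block size (degrees), with the correlogram attached as
#'   attribute `correlogram`.
#' @export
choose_block_size <- function(layer, grid, candidates, mask = NULL,
                              seed = 1, n_sample = 2000, bin_width = NULL) {
  stopifnot(length(candidates) >= 1)
  ok <- !is.na(layer)
  if (!is.null(mask)) ok <- ok & mask
  cells <- which(as.vector(ok))
  if (length(cells) < 100L) stop("fewer than 100 valid cells")
  if (length(candidates) == 1L) return(candidates)
  candidates <- sort(candidates)
  if (length(cells) > n_sample)
    cells <- with_seed(seed, sample(cells, n_sample))
  cc <- cell_center(grid, cells)
  x <- layer[cells]
  xc <- x - mean(x)
  v <- mean(xc^2)
  d <- as.matrix(stats::dist(cbind(cc$lon, cc$lat)))
  cp <- tcrossprod(xc)
  ut <- upper.tri(d)
  dd <- d[ut]; pp <- cp[ut]
  if (is.null(bin_width)) bin_width <- max(2 * grid$resolution,
                                           max(candidates) / 10)
  dmax <- min(max(dd), 2 * max(candidates) + bin_width)
  bins <- cut(dd, breaks = seq(0, dmax + bin_width, by = bin_width),
              include.lowest = TRUE)
  r <- tapply(pp, bins, mean) / v
  mids <- seq(bin_width / 2, by = bin_width, length.out = nlevels(bins))
  valid_bin <- !is.na(r)
  r <- r[valid_bin]; mids <- mids[valid_bin]
  below <- which(r < 0.1)
  range_d <- if (length(below)) mids[below[1L]] else Inf
  ok_cand <- candidates[candidates >= range_d]
  out <- if (length(ok_cand)) ok_cand[1L] else {
    warning(sprintf(
      "no candidate reaches the autocorrelation range (%.2f deg); using the largest",
      range_d))
    candidates[length(candidates)]
  }
  attr(out, "correlogram") <- data.frame(distance = mids, correlation = r)
  out
}

#' Assign spatial blocks to cross-validation folds
#'
#' Lays a regular checkerboard of square blocks over the grid, shuffles
#' the blocks with the seed, and deals them round-robin to `k` folds, so
#' every block lies wholly inside one fold and the folds cover the whole
#' modelling region.  When `presence_cells` are supplied, the seed is
#' incremented (and logged) until every fold contains at least one
#' presence cell.
#'
#' @param grid a [grid_spec()].
#' @param mask logical validity matrix.
#' @param block_size_deg block edge length in degrees
#'   (>= `grid$resolution`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param presence_cells optional occupied cell ids that every fold must
#'   sample.
#' @param max_tries re-seed attempts before giving up.
#' @return An object of class `block_folds`: list with `grid`,
#'   `block_size_deg`, `cells` (valid cell ids), `block` and `fold`
#'   (parallel integer vectors), `k`, `seed_used`.
#' @export
assign_folds <- function(grid, mask, block_size_deg, k = 5L, seed = 1,
                         presence_cells = NULL, max_tries = 25L) {
  if (k < 2L) stop("k must be at least 2")
  if (block_size_deg < grid$resolution)
    stop("block size must be at least one grid cell")
  cells <- which(as.vector(mask))
  if (!length(cells)) stop("mask has no valid cells")
  bc <- max(1L, as.integer(round(block_size_deg / grid$resolution)))
  row <- cell_row(grid, cells); col <- cell_col(grid, cells)
  n_bc <- (grid$n_cols - 1L) %/% bc + 1L
  block <- ((row - 1L) %/% bc) * n_bc + ((col - 1L) %/% bc) + 1L
  ublocks <- sort(unique(block))
  if (length(ublocks) < k)
    stop("only ", length(ublocks), " block(s) at this block size; cannot fill ",
         k, " folds")
  for (try in seq_len(max_tries)) {
    seed_try <- as.integer(seed) + try - 1L
    perm <- with_seed(seed_try, sample(ublocks))
    fold_of_block <- integer(max(ublocks))
    fold_of_block[perm] <- ((seq_along(perm) - 1L) %% k) + 1L
    fold <- fold_of_block[block]
    if (!is.null(presence_cells)) {
      pf <- fold[match(presence_cells, cells)]
      if (length(unique(stats::na.omit(pf))) < k) {
        message("assign_folds: fold without presences at seed ", seed_try,
                "; re-assigning")
        next
      }
    }
    return(structure(list(grid = grid, block_size_deg = block_size_deg,
                          cells = cells, block = block, fold = fold,
                          k = as.integer(k), seed_used = seed_try),
                     class = "block_folds"))
  }
  stop("could not place at least one presence cell in every fold after ",
       max_tries, " seeds")
}

#' @export
print.block_folds <- function(x, ...) {
  cat(sprintf("block_folds: %d blocks of %g deg over %d cells, %d folds (seed %d)\n",
              length(unique(x$block)), x$block_size_deg, length(x$cells),
              x$k, x$seed_used))
  invisible(x)
}

fold_of <- function(folds, cells) folds$fold[match(cells, folds$cells)]

default_candidates <- function(multipliers = 1) {
  sets <- list(linear = "linear",
               lq = c("linear", "quadratic"),
               lqp = c("linear", "quadratic", "product"))
  out <- list()
  for (mu in multipliers) for (nm in names(sets))
    out[[length(out) + 1L]] <- list(classes = sets[[nm]], multiplier = mu)
  out
}

# candidate selection rule: smallest |train - test| AUC gap (the signed
# gap would reward underfit models whose test AUC exceeds train), then
# highest mean test AUC, then fewest feature classes, then first listed
select_candidate <- function(gap, auc_test, n_classes) {
  ord <- order(abs(gap), -auc_test, n_classes)
  ord[1L]
}

#' Spatially blocked cross-validation of MaxEnt candidates
#'
#' For each hyperparameter candidate (feature classes x beta multiplier),
#' fits 5 sub-models, each trained on the presences and background cells
#' of 4 folds and tested on the held-out fold (background points inherit
#' fold membership from their cells, keeping evaluation spatially honest).
#' The chosen candidate minimizes the mean train-test AUC gap, with ties
#' broken by higher mean test AUC and then fewer feature classes.  The
#' final suitability map is the cell-wise mean of the 5 sub-model cloglog
#' maps; a pooled model on all folds is also fitted for response-curve
#' work.
#'
#' @param occ a [grid_occurrences()] result.
#' @param stack an [env_stack()] (already pruned to the modelling
#'   variables).
#' @param folds an [assign_folds()] result built on the stack's mask.
#' @param candidates list of `list(classes =, multiplier =)` candidates.
#' @param bg_max cap on background cells (seeded subsample above it).
#' @param seed RNG seed for the background subsample.
#' @param capture occurrence-capture fraction used for the per-fold TSS
#'   threshold and the ensemble binarization threshold.
#' @return An object of class `sdm_cv`: `candidate`, `selection` (per
#'   candidate mean metrics), `fits` (5 sub-models of the chosen
#'   candidate), `pooled_fit`, `metrics` (per fold), `suitability`
#'   (matrix), `threshold`, `presence_cells`, `bg_cells`, `folds`.
#' @export
cross_validate <- function(occ, stack, folds, candidates = default_candidates(),
                           bg_max = 10000, seed = 1, capture = 0.95) {
  stopifnot(length(candidates) >= 1, inherits(folds, "block_folds"))
  vcells <- valid_cells(stack)
  presence_cells <- intersect(occ$cells, vcells)
  if (length(presence_cells) < 2 * folds$k)
    stop("too few presence cells (", length(presence_cells), ") for ",
         folds$k, "-fold cross-validation")
  bg_cells <- vcells
  if (length(bg_cells) > bg_max)
    bg_cells <- sort(with_seed(seed, sample(bg_cells, bg_max)))
  env_pres <- extract_cells(stack, presence_cells)
  env_bg <- extract_cells(stack, bg_cells)
  pf <- fold_of(folds, presence_cells)
  bf <- fold_of(folds, bg_cells)
  if (anyNA(pf) || anyNA(bf))
    stop("folds were not built on this stack's mask")
  missing_folds <- setdiff(seq_len(folds$k), unique(pf))
  if (length(missing_folds))
    stop("fold(s) without test presences: ",
         paste(missing_folds, collapse = ", "),
         "; re-assign folds with a new seed")

  eval_candidate <- function(cand) {
    fits <- vector("list", folds$k)
    met <- data.frame(fold = seq_len(folds$k), auc_train = NA_real_,
                      auc_test = NA_real_, tss_test = NA_real_,
                      threshold = NA_real_)
    for (f in seq_len(folds$k)) {
      tr_p <- pf != f; tr_b <- bf != f
      fit <- fit_maxnet(env_pres[tr_p, , drop = FALSE],
                        env_bg[tr_b, , drop = FALSE],
                        classes = cand$classes, multiplier = cand$multiplier)
      sc_p_tr <- predict(fit, env_pres[tr_p, , drop = FALSE])
      sc_b_tr <- predict(fit, env_bg[tr_b, , drop = FALSE])
      sc_p_te <- predict(fit, env_pres[!tr_p, , drop = FALSE])
      sc_b_te <- predict(fit, env_bg[!tr_b, , drop = FALSE])
      thr <- capture_threshold(sc_p_tr, capture, warn_small = FALSE)
      met$auc_train[f] <- auc(sc_p_tr, sc_b_tr)
      met$auc_test[f] <- auc(sc_p_te, sc_b_te)
      met$tss_test[f] <- tss(c(sc_p_te, sc_b_te) >= thr,
                             rep(c(TRUE, FALSE),
                                 c(length(sc_p_te), length(sc_b_te))))
      met$threshold[f] <- thr
      fits[[f]] <- fit
    }
    list(fits = fits, metrics = met)
  }

  runs <- lapply(candidates, eval_candidate)
  selection <- data.frame(
    candidate = vapply(candidates, function(cd)
      paste0(paste(substr(cd$classes, 1, 1), collapse = ""), ".b",
             cd$multiplier), ""),
    n_classes = vapply(candidates, function(cd) length(cd$classes), 0L),
    auc_train = vapply(runs, function(r) mean(r$metrics$auc_train), 0),
    auc_test = vapply(runs, function(r) mean(r$metrics$auc_test), 0),
    tss_test = vapply(runs, function(r) mean(r$metrics$tss_test), 0))
  selection$gap <- selection$auc_train - selection$auc_test
  pick <- select_candidate(selection$gap, selection$auc_test,
                           selection$n_classes)
  chosen <- candidates[[pick]]
  fits <- runs[[pick]]$fits

  env_all <- extract_cells(stack, vcells)
  maps <- vapply(fits, function(ft) predict(ft, env_all),
                 numeric(length(vcells)))
  avg <- rowMeans(maps)
  suit <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  suit[vcells] <- avg
  pooled <- fit_maxnet(env_pres, env_bg, classes = chosen$classes,
                       multiplier = chosen$multiplier)
  thr <- capture_threshold(suit[presence_cells], capture)

  structure(list(candidate = chosen, selection = selection,
                 metrics = runs[[pick]]$metrics, fits = fits,
                 pooled_fit = pooled, suitability = suit, threshold = thr,
                 capture = capture, presence_cells = presence_cells,
                 bg_cells = bg_cells, folds = folds),
            class = "sdm_cv")
}

#' @export
print.sdm_cv <- function(x, ...) {
  cat(sprintf("sdm_cv: chosen {%s} x beta %g\n",
              paste(x$candidate$classes, collapse = ","),
              x$candidate$multiplier))
  cat(sprintf("  mean AUC train %.3f / test %.3f, mean TSS %.3f, threshold %.3f\n",
              mean(x$metrics$auc_train), mean(x$metrics$auc_test),
              mean(x$metrics$tss_test), x$threshold))
  invisible(x)
}
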