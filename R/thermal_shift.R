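#' Logistic tolerance transformation
#'
#' Parameters of the temperature-layer transformation used to simulate an
#' increase of the upper thermal tolerance by `target_increase` degrees:
#' each cell's temperature `x` becomes `x + delta(x)` with
#' `delta(x) = temperature_increase / (1 + exp(-increase_rate * (x -
#' suitability_peak)))`.  The increment is strictly increasing in `x` and
#' bounded in `(0, temperature_increase)`, so the transform preserves
#' temperature ranks (no disjointed response curve), is about zero well
#' below the suitability peak, and approaches the full
#' `temperature_increase` on the warm tail.
#'
#' @param target_increase k, the tolerance increase being simulated
#'   (deg C, integer 1-5).
#' @param temperature_increase asymptotic increment (deg C, >= k; species
#'   and tolerance specific, normally set by [calibrate_Tinc()]).
#' @param increase_rate steepness of the transition (per deg C, held
#'   constant; default 2, i.e. the transition spans about +-2 deg C around
#'   the peak).
#' @param suitability_peak thermal optimum of the base model's response
#'   curve (deg C).
#' @return An object of class `tolerance_transform`.
#' @export
tolerance_transform <- function(target_increase, temperature_increase,
                                increase_rate = 2, suitability_peak) {
  if (target_increase < 1)
    stop("target_increase must be >= 1")
  stopifnot(temperature_increase >= target_increase, increase_rate > 0,
            is.finite(suitability_peak))
  structure(list(target_increase = target_increase,
                 temperature_increase = temperature_increase,
                 increase_rate = increase_rate,
                 suitability_peak = suitability_peak),
            class = "tolerance_transform")
}

#' @export
print.tolerance_transform <- function(x, ...) {
  cat(sprintf(
    "tolerance_transform: k = %g, T_inc = %.3f, rate = %g, peak = %.2f degC\n",
    x$target_increase, x$temperature_increase, x$increase_rate,
    x$suitability_peak))
  invisible(x)
}

#' Temperature increment of the tolerance transform
#'
#' `delta(x) = T_inc / (1 + exp(-r * (x - peak)))`; numerically safe for
#' extreme temperatures (underflows to 0 or saturates at `T_inc`).
#'
#' @param x temperatures (deg C), vector or matrix.
#' @param transform a [tolerance_transform()].
#' @return Increments, same shape as `x`.
#' @export
#' @examples
#' tr <- tolerance_transform(2, 4, increase_rate = 2, suitability_peak = 15)
#' delta(15, tr) # T_inc / 2 = 2
delta <- function(x, transform) {
  stopifnot(inherits(transform, "tolerance_transform"))
  transform$temperature_increase *
    stats::plogis(transform$increase_rate * (x - transform$suitability_peak))
}

#' Apply the tolerance transform to a temperature layer
#'
#' Cell-wise `x + delta(x)`; the mask (`NA` cells) is preserved, the
#' modified layer is everywhere warmer than the original by less than
#' `temperature_increase`, and cell ordering by temperature is preserved.
#'
#' @param layer temperature matrix (deg C).
#' @param transform a [tolerance_transform()].
#' @return Modified layer.
#' @export
transform_layer <- function(layer, transform) {
  layer + delta(layer, transform)
}

# stack with the temperature layer transformed (other layers untouched)
transform_stack <- function(stack, transform, variable = "temperature") {
  stopifnot(variable %in% names(stack$layers))
  layers <- stack$layers
  layers[[variable]] <- transform_layer(layers[[variable]], transform)
  env_stack(stack$grid, layers, stack$mask,
            paste0(stack$period, "+k", transform$target_increase),
            stack$units)
}

# largest variable value where the curve is still at/above the threshold,
# linearly interpolated; attribute "censored" marks a curve that never
# drops below the threshold on its upper tail
upper_crossing <- function(curve, threshold) {
  x <- curve$value; y <- curve$cloglog
  if (max(y) < threshold)
    stop("response curve never reaches the binarization threshold")
  i <- max(which(y >= threshold))
  if (i == length(y))
    return(structure(x[i], censored = TRUE))
  frac <- (y[i] - threshold) / (y[i] - y[i + 1L])
  structure(x[i] + frac * (x[i + 1L] - x[i]), censored = FALSE)
}

#' Calibrate the asymptotic temperature increase
#'
#' Finds the `temperature_increase` for which the tolerance-shifted model's
#' response curve crosses the binarization threshold `k` degrees above the
#' base model's upper crossing.
#'
#' In full mode (a `refit_curve` function is supplied) this is a bisection
#' on `temperature_increase` in `[k, k + 10]`, retraining at each step and
#' accepting when the retrained upper crossing sits `k +- tol` above the
#' base crossing.  In fast mode (no `refit_curve`) the first-order
#' approximation is returned: `k` divided by the fraction of the logistic
#' increment attained at the base upper crossing,
#' `k * (1 + exp(-r * (x_cross - peak)))`.
#'
#' @param base_curve the base model's [response_curve()].
#' @param threshold binarization threshold (cloglog units).
#' @param k target tolerance increase (deg C).
#' @param increase_rate logistic steepness r (per deg C).
#' @param refit_curve optional function `(temperature_increase) -> curve`
#'   that retrains on the transformed layer and returns the new response
#'   curve (or a list `list(curve =, threshold =)` when the retrained
#'   model is binarized at its own occurrence-capture threshold);
#'   supplying it switches on full mode.
#' @param tol acceptance window on the crossing shift (deg C).
#' @return `temperature_increase` with attributes `mode` and (full mode)
#'   `achieved_shift`.
#' @export
calibrate_Tinc <- function(base_curve, threshold, k, increase_rate = 2,
                           refit_curve = NULL, tol = 0.05) {
  stopifnot(k >= 1, threshold > 0, threshold < 1)
  peak <- suitability_peak(base_curve)
  x_base <- upper_crossing(base_curve, threshold)
  if (isTRUE(attr(x_base, "censored")))
    stop("base response curve does not cross the threshold on its upper tail")
  if (is.null(refit_curve)) {
    frac <- stats::plogis(increase_rate * (as.numeric(x_base) - peak))
    out <- k / frac
    message(sprintf("calibrate_Tinc: fast mode, T_inc = %.3f", out))
    return(structure(out, mode = "fast"))
  }
  shift_at <- function(ti) {
    res <- refit_curve(ti)
    if (!is.data.frame(res)) {
      thr_k <- res$threshold %||% threshold
      res <- res$curve
    } else thr_k <- threshold
    as.numeric(upper_crossing(res, thr_k)) - as.numeric(x_base) - k
  }
  lo <- k; hi <- k + 10
  g_lo <- shift_at(lo)
  if (g_lo >= -tol) {
    if (g_lo > tol)
      warning("minimal temperature_increase already overshoots the target shift")
    return(structure(lo, mode = "full", achieved_shift = g_lo + k))
  }
  g_hi <- shift_at(hi)
  if (g_hi < -tol) {
    warning("target shift not reached at temperature_increase = k + 10")
    return(structure(hi, mode = "full", achieved_shift = g_hi + k))
  }
  mid <- hi; g_mid <- g_hi
  for (it in seq_len(25L)) {
    mid <- (lo + hi) / 2
    g_mid <- shift_at(mid)
    if (abs(g_mid) <= tol || (hi - lo) < 0.01) break
    if (g_mid < 0) lo <- mid else hi <- mid
  }
  message(sprintf(
    "calibrate_Tinc: full mode, T_inc = %.3f (achieved shift %.3f degC)",
    mid, g_mid + k))
  structure(mid, mode = "full", achieved_shift = g_mid + k)
}

#' Train the family of tolerance-shifted model ensembles
#'
#' For each target tolerance increase `k`, calibrates the transform
#' against the base (pooled) response curve, transforms the present
#' temperature layer, refits the 5 sub-models with identical folds,
#' hyperparameters and non-temperature layers, and projects every
#' ensemble onto the unmodified present and scenario layers.  Occurrences
#' are never moved — only the training temperature layer changes, which
#' is what lets the fitted upper tail express the added tolerance.
#'
#' @param cv the base [cross_validate()] result.
#' @param stack the present [env_stack()] used for the base fit.
#' @param scenarios named list of future [env_stack()]s (same variables).
#' @param k_list target tolerance increases (deg C, integers >= 1).
#' @param increase_rate logistic steepness r.
#' @param calibration `"full"` (bisection with retraining) or `"fast"`.
#' @return An object of class `tolerance_family`: per k, a list with
#'   `transform`, `fits`, `threshold`, `present` (suitability matrix) and
#'   `future` (named list of matrices); failed k's carry the error
#'   condition instead.  Empty `k_list` gives an empty family.
#' @export
train_shifted_family <- function(cv, stack, scenarios, k_list = 1:5,
                                 increase_rate = 2,
                                 calibration = c("full", "fast")) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(cv, "sdm_cv"), inherits(stack, "env_stack"))
  if (!length(k_list))
    return(structure(list(), class = "tolerance_family"))
  if (any(k_list < 1)) stop("target_increase must be >= 1")
  vars <- stack_vars(stack)
  scenarios <- lapply(scenarios, keep_vars, vars = vars)
  base_curve <- response_curve(cv$pooled_fit)
  peak <- suitability_peak(base_curve)
  vcells <- valid_cells(stack)
  env_bg_raw <- extract_cells(stack, cv$bg_cells)
  env_pres_raw <- extract_cells(stack, cv$presence_cells)
  env_all <- extract_cells(stack, vcells)
  pf <- fold_of(cv$folds, cv$presence_cells)
  bf <- fold_of(cv$folds, cv$bg_cells)

  fit_family_member <- function(k) {
    # retrain a pooled model on the transformed layer and report its curve
    # together with its own occurrence-capture threshold (the threshold the
    # family maps are binarized with), so calibration matches crossings on
    # the scale that actually defines suitability
    refit <- if (calibration == "full") function(ti) {
      tr <- tolerance_transform(k, ti, increase_rate, peak)
      p <- env_pres_raw; b <- env_bg_raw
      p$temperature <- transform_layer(p$temperature, tr)
      b$temperature <- transform_layer(b$temperature, tr)
      fit_k <- fit_maxnet(p, b, classes = cv$candidate$classes,
                          multiplier = cv$candidate$multiplier)
      # present-day suitability of the shifted model at the occurrence cells
      thr_k <- capture_threshold(predict(fit_k, env_pres_raw), cv$capture,
                                 warn_small = FALSE)
      list(curve = response_curve(fit_k), threshold = thr_k)
    }
    t_inc <- calibrate_Tinc(base_curve, cv$threshold, k, increase_rate,
                            refit_curve = refit)
    transform <- tolerance_transform(k, as.numeric(t_inc), increase_rate,
                                     peak)
    p <- env_pres_raw; b <- env_bg_raw
    p$temperature <- transform_layer(p$temperature, transform)
    b$temperature <- transform_layer(b$temperature, transform)
    fits <- lapply(seq_len(cv$folds$k), function(f)
      fit_maxnet(p[pf != f, , drop = FALSE], b[bf != f, , drop = FALSE],
                 classes = cv$candidate$classes,
                 multiplier = cv$candidate$multiplier))
    ens_map <- function(newdata) {
      rowMeans(vapply(fits, function(ft) predict(ft, newdata),
                      numeric(nrow(newdata))))
    }
    present_vals <- ens_map(env_all)
    present <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
    present[vcells] <- present_vals
    threshold <- capture_threshold(present[cv$presence_cells], cv$capture,
                                   warn_small = FALSE)
    future <- lapply(scenarios, function(sc) {
      fut <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
      fut[vcells] <- ens_map(extract_cells(sc, vcells))
      fut
    })
    list(transform = transform, fits = fits, threshold = threshold,
         present = present, future = future, calibration_mode = attr(t_inc, "mode"))
  }

  out <- lapply(k_list, function(k)
    tryCatch(fit_family_member(k), error = identity))
  names(out) <- paste0("k", k_list)
  failed <- vapply(out, inherits, TRUE, what = "error")
  if (any(failed))
    warning("tolerance family failed for k = ",
            paste(k_list[failed], collapse = ", "), "; first error: ",
            conditionMessage(out[[which(failed)[1L]]]))
  structure(out, k_list = k_list, peak = peak,
            calibration = calibration, class = "tolerance_family")
}

#' @export
print.tolerance_family <- function(x, ...) {
  cat(sprintf("tolerance_family: k in {%s}, peak %.2f degC, %s calibration\n",
              paste(attr(x, "k_list"), collapse = ", "),
              attr(x, "peak") %||% NA_real_, attr(x, "calibration") %||% "?"))
  for (nm in names(x)) {
    if (inherits(x[[nm]], "error"))
      cat(sprintf("  %s: FAILED (%s)\n", nm, conditionMessage(x[[nm]])))
    else
      cat(sprintf("  %s: T_inc = %.3f, threshold %.3f\n", nm,
                  x[[nm]]$transform$temperature_increase, x[[nm]]$threshold))
  }
  invisible(x)
}
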