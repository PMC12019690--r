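#' Default MaxEnt regularization schedule
#'
#' The published MaxEnt default per-class regularization values
#' r(class, m): linear, quadratic and product features share the
#' sample-size breakpoints m = 0, 10, 30, 100 with values 1, 1, 0.2, 0.05,
#' interpolated linearly in the number of presences m and held constant
#' beyond the last breakpoint.  The per-feature L1 weight is
#' `lambda_j = multiplier * r(class_j, m) * scale_j / sqrt(m)` where
#' `scale_j` is the feature's standard deviation over the training
#' background.
#'
#' @return Data frame with columns `class`, `m`, `beta`.
#' @export
maxent_reg_schedule <- function() {
  data.frame(class = rep(c("linear", "quadratic", "product"), each = 4L),
             m = rep(c(0, 10, 30, 100), 3L),
             beta = rep(c(1.0, 1.0, 0.2, 0.05), 3L))
}

reg_beta <- function(class, m, schedule = maxent_reg_schedule()) {
  vapply(class, function(cl) {
    sub <- schedule[schedule$class == cl, ]
    if (!nrow(sub)) stop("no regularization schedule for class '", cl, "'")
    stats::approx(sub$m, sub$beta, xout = min(m, max(sub$m)), rule = 2)$y
  }, 0)
}

feature_class_names <- c("linear", "quadratic", "product")

#' Build the MaxEnt feature matrix
#'
#' Expands raw environmental variables into model features: `linear` (each
#' variable), `quadratic` (each variable squared) and `product` (the
#' product of each unordered distinct pair).  Variables are taken in
#' alphabetical order, so the column layout is deterministic.  When
#' `clamps` are supplied (prediction time), raw values are first clamped
#' into the training range, so inputs beyond the training maximum are
#' treated as equal to it.
#'
#' @param data data frame of raw variable values.
#' @param classes subset of `c("linear", "quadratic", "product")`.
#' @param clamps optional named list `variable -> c(min, max)`.
#' @return Numeric matrix with attribute `classes` (per-column feature
#'   class).
#' @export
build_features <- function(data, classes = feature_class_names,
                           clamps = NULL) {
  stopifnot(length(classes) >= 1)
  unknown <- setdiff(classes, feature_class_names)
  if (length(unknown))
    stop("unknown feature class(es): ", paste(unknown, collapse = ", "))
  vars <- if (!is.null(clamps)) sort(names(clamps)) else sort(names(data))
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop("data lacks variable(s): ", paste(missing, collapse = ", "))
  x <- lapply(vars, function(v) as.numeric(data[[v]]))
  names(x) <- vars
  if (!is.null(clamps))
    for (v in vars) x[[v]] <- pmin(pmax(x[[v]], clamps[[v]][1L]),
                                   clamps[[v]][2L])
  cols <- list(); cls <- character()
  if ("linear" %in% classes) {
    for (v in vars) { cols[[v]] <- x[[v]]; cls <- c(cls, "linear") }
  }
  if ("quadratic" %in% classes) {
    for (v in vars) { cols[[paste0(v, "^2")]] <- x[[v]]^2
      cls <- c(cls, "quadratic") }
  }
  if ("product" %in% classes && length(vars) >= 2) {
    pairs <- utils::combn(vars, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      cols[[paste0(a, ":", b)]] <- x[[a]] * x[[b]]
      cls <- c(cls, "product")
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  attr(out, "classes") <- cls
  out
}

# penalized negative log-likelihood in standardized feature space
maxent_objective <- function(b, Gp_means, Gb, lambda) {
  -sum(Gp_means * b) + logsumexp(drop(Gb %*% b)) + sum(lambda * abs(b))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a presence-background MaxEnt model
#'
#' Maximizes the penalized presence log-likelihood of the Gibbs
#' distribution over the background,
#' `mean_presence(f(x) . beta) - log sum_background exp(f(z) . beta)
#'  - sum_j lambda_j |beta_j|`,
#' with `lambda_j = multiplier * r(class_j, m) * scale_j / sqrt(m)`
#' (see [maxent_reg_schedule()]).  The solver is proximal gradient descent
#' with backtracking line search on standardized features; the penalized
#' objective is non-increasing across iterations, and convergence is
#' declared when the objective change is below `tol` or the largest
#' coefficient update is below `1e-6`.  The intercept is implicit in the
#' background normalizer Z, so raw predictions over the training
#' background sum to exactly 1.
#'
#' @param presence,background data frames of raw variable values at
#'   presence and background points (identical column sets).
#' @param classes feature classes, see [build_features()].
#' @param multiplier beta regularization multiplier (the study default
#'   is 1).
#' @param reg_schedule regularization table, see [maxent_reg_schedule()].
#' @param tol objective-change convergence tolerance.
#' @param max_iter iteration cap; exceeding it without convergence is an
#'   error carrying diagnostics.
#' @return An object of class `maxent_fit` with elements `beta` (named
#'   coefficients on the original feature scale), `lambda`, `classes`,
#'   `variables`, `clamps`, `log_z` (log background normalizer), `entropy`
#'   (H of the raw distribution over the background), `bg_var_means`,
#'   `m`, `n_background`, `iterations`, `objective` and `objective_trace`
#'   (the non-increasing per-iteration penalized objective).
#' @export
fit_maxnet <- function(presence, background,
                       classes = feature_class_names,
                       multiplier = 1.0,
                       reg_schedule = maxent_reg_schedule(),
                       tol = 1e-8, max_iter = 20000L) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  if (!setequal(names(presence), names(background)))
    stop("presence and background must share the same variables")
  m <- nrow(presence)
  if (m < 5L) stop("need at least 5 presence points, got ", m)
  if (nrow(background) < 10L * m)
    warning("background has fewer than 10x the presences (",
            nrow(background), " vs ", m, ")")
  vars <- sort(names(presence))
  clamps <- lapply(vars, function(v)
    range(c(presence[[v]], background[[v]]), na.rm = TRUE))
  names(clamps) <- vars

  Fp <- build_features(presence[vars], classes)
  Fb <- build_features(background[vars], classes)
  fcls <- attr(Fb, "classes")
  s <- apply(Fb, 2L, stats::sd)
  keep <- s > 0
  if (!all(keep))
    warning("excluding constant feature(s): ",
            paste(colnames(Fb)[!keep], collapse = ", "))
  if (!any(keep)) stop("all features are constant over the background")
  Fp <- Fp[, keep, drop = FALSE]; Fb <- Fb[, keep, drop = FALSE]
  fcls <- fcls[keep]; s <- s[keep]
  mu <- colMeans(Fb)
  Gp <- sweep(sweep(Fp, 2L, mu), 2L, s, "/")
  Gb <- sweep(sweep(Fb, 2L, mu), 2L, s, "/")
  r_j <- reg_beta(fcls, m, reg_schedule)
  lambda_std <- multiplier * r_j / sqrt(m)

  gp_means <- colMeans(Gp)
  b <- numeric(ncol(Gb))
  smooth_val <- function(b) {
    eta <- drop(Gb %*% b)
    lse <- logsumexp(eta)
    list(value = -sum(gp_means * b) + lse,
         grad = -gp_means + drop(crossprod(Gb, exp(eta - lse))))
  }
  sv <- smooth_val(b)
  obj <- sv$value + sum(lambda_std * abs(b))
  pen_obj <- function(bb, sm) sm$value + sum(lambda_std * abs(bb))
  # FISTA with backtracking; an extrapolated step that would raise the
  # penalized objective is replaced by a plain proximal step from the
  # current iterate (and the momentum restarted), so the objective is
  # non-increasing by construction.
  prox_from <- function(bb, sm) {
    repeat {
      b_new <- soft_threshold(bb - step * sm$grad, step * lambda_std)
      d <- b_new - bb
      sv_new <- smooth_val(b_new)
      if (sv_new$value <= sm$value + sum(sm$grad * d) +
          sum(d^2) / (2 * step) + 1e-12)
        return(list(b = b_new, sv = sv_new))
      step <<- step / 2
      if (step < 1e-12) return(list(b = bb, sv = sm))
    }
  }
  step <- 1
  y <- b; sy <- sv; t_mom <- 1
  trace <- obj
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cand <- prox_from(y, sy)
    obj_cand <- pen_obj(cand$b, cand$sv)
    if (obj_cand > obj) { # restart momentum from the current iterate
      cand <- prox_from(b, sv)
      obj_cand <- pen_obj(cand$b, cand$sv)
      t_mom <- 1
    }
    max_upd <- max(abs(cand$b - b))
    delta_obj <- obj - obj_cand
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- cand$b + ((t_mom - 1) / t_new) * (cand$b - b)
    sy <- smooth_val(y)
    t_mom <- t_new
    b <- cand$b; sv <- cand$sv; obj <- obj_cand
    trace[iter + 1L] <- obj
    step <- step * 1.1
    if (delta_obj < tol || max_upd < 1e-6) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "maxent solver did not converge in %d iterations (objective %.8g, last change %.3g)",
      max_iter, obj, delta_obj))

  beta <- b / s
  names(beta) <- colnames(Fb)
  eta_bg <- drop(Fb %*% beta)
  log_z <- logsumexp(eta_bg)
  raw <- exp(eta_bg - log_z)
  entropy <- -sum(ifelse(raw > 0, raw * log(raw), 0))

  structure(list(beta = beta, lambda = multiplier * r_j * s / sqrt(m),
                 classes = classes, feature_classes = fcls,
                 variables = vars, clamps = clamps,
                 multiplier = multiplier,
                 log_z = log_z, entropy = entropy,
                 bg_var_means = vapply(vars, function(v)
                   mean(background[[v]], na.rm = TRUE), 0),
                 m = m, n_background = nrow(background),
                 iterations = iter, objective = obj,
                 objective_trace = trace),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "maxent_fit: %d presences vs %d background, classes {%s}, multiplier %g\n",
    x$m, x$n_background, paste(substr(x$classes, 1, 1), collapse = ""),
    x$multiplier))
  nz <- sum(abs(x$beta) > 0)
  cat(sprintf("  %d/%d non-zero features, entropy %.4f, %d iterations\n",
              nz, length(x$beta), x$entropy, x$iterations))
  invisible(x)
}

#' Predict habitat suitability from a MaxEnt fit
#'
#' `raw` is the Gibbs density `exp(f(z) . beta) / Z` with Z fixed from the
#' training background (so raw sums to 1 over that background); `cloglog`
#' is `1 - exp(-exp(H) * raw)`, a monotone map of raw into (0, 1).  Raw
#' variable values are clamped into the training range before feature
#' expansion unless `clamp = FALSE`.
#'
#' @param object a [fit_maxnet()] model.
#' @param newdata data frame of raw variable values.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param clamp clamp inputs into training bounds.
#' @param ... unused.
#' @return Numeric vector of suitabilities.
#' @export
predict.maxent_fit <- function(object, newdata, type = c("cloglog", "raw"),
                               clamp = TRUE, ...) {
  type <- match.arg(type)
  feats <- build_features(as.data.frame(newdata), object$classes,
                          clamps = if (clamp) object$clamps else NULL)
  if (!all(names(object$beta) %in% colnames(feats)))
    stop("newdata features do not match the fitted model")
  eta <- drop(feats[, names(object$beta), drop = FALSE] %*% object$beta)
  raw <- exp(eta - object$log_z)
  switch(type, raw = raw,
         cloglog = 1 - exp(-exp(object$entropy) * raw))
}

#' Response curve of a fitted model
#'
#' Varies one variable across its training range while holding all other
#' variables at their background means, and reports the cloglog curve and
#' its argmax (the suitability peak; ties resolve to the lowest value of
#' the variable).
#'
#' @param fit a [fit_maxnet()] model.
#' @param variable variable name (default the temperature layer).
#' @param n_points number of evaluation points.
#' @return A data frame of class `maxent_response` with columns `value`
#'   and `cloglog`, attributes `variable` and `peak`.
#' @export
response_curve <- function(fit, variable = "temperature", n_points = 200L) {
  if (!variable %in% fit$variables)
    stop("variable '", variable, "' is not in the fitted model")
  rng <- fit$clamps[[variable]]
  xs <- seq(rng[1L], rng[2L], length.out = n_points)
  nd <- as.data.frame(as.list(fit$bg_var_means))[rep(1L, n_points), ,
                                                 drop = FALSE]
  nd[[variable]] <- xs
  y <- predict(fit, nd, type = "cloglog")
  structure(data.frame(value = xs, cloglog = y),
            variable = variable, peak = xs[which.max(y)],
            class = c("maxent_response", "data.frame"))
}

#' @export
plot.maxent_response <- function(x, ...) {
  graphics::plot(x$value, x$cloglog, type = "l",
                 xlab = attr(x, "variable"), ylab = "cloglog suitability",
                 ...)
  graphics::abline(v = attr(x, "peak"), lty = 2)
  invisible(x)
}

#' Suitability peak of a response curve
#'
#' @param curve a [response_curve()] result.
#' @return The variable value at the curve maximum.
#' @export
suitability_peak <- function(curve) attr(curve, "peak")

#' Permutation importance of model variables
#'
#' For each raw variable, its values are shuffled across all points
#' (presences and background together), features are rebuilt, and the mean
#' drop in training AUC over `n_repeats` seeded shuffles is recorded.
#' Negative drops are floored at zero and the drops are normalized to
#' percentages summing to 100.
#'
#' @param fit a [fit_maxnet()] model.
#' @param presence,background raw variable data frames used in training.
#' @param n_repeats shuffles per variable.
#' @param seed RNG seed.
#' @return Named numeric vector of percent contributions.
#' @export
permutation_importance <- function(fit, presence, background,
                                   n_repeats = 5L, seed = 1) {
  stopifnot(n_repeats >= 1L)
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  all_pts <- rbind(presence[fit$variables], background[fit$variables])
  is_pres <- rep(c(TRUE, FALSE), c(nrow(presence), nrow(background)))
  score <- predict(fit, all_pts)
  auc0 <- auc(score[is_pres], score[!is_pres])
  drops <- with_seed(seed, vapply(fit$variables, function(v) {
    mean(vapply(seq_len(n_repeats), function(r) {
      perm <- all_pts
      perm[[v]] <- sample(perm[[v]])
      sc <- predict(fit, perm)
      auc0 - auc(sc[is_pres], sc[!is_pres])
    }, 0))
  }, 0))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("all permutation drops are zero; returning uniform contributions")
    drops <- rep(1, length(drops))
    names(drops) <- fit$variables
  }
  100 * drops / sum(drops)
}
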