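# hand-built response curve with a known shape, for calibration tests
fake_curve <- function(peak = 15, width = 3, xs = seq(5, 30, by = 0.05)) {
  structure(data.frame(value = xs,
                       cloglog = 0.9 * exp(-0.5 * ((xs - peak) / width)^2)),
            variable = "temperature", peak = xs[which.max(
              0.9 * exp(-0.5 * ((xs - peak) / width)^2))],
            class = c("maxent_response", "data.frame"))
}

test_that("the logistic increment has its closed-form values", {
  tr <- tolerance_transform(2, 5, increase_rate = 2, suitability_peak = 15)
  expect_equal(delta(15, tr), 2.5)           # midpoint: T_inc / 2
  expect_lt(delta(15 - 100, tr), 1e-6)       # lower asymptote
  tr2 <- tolerance_transform(2, 4, increase_rate = 2, suitability_peak = 15)
  expect_equal(delta(16, tr2), 4 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(delta(16, tr2), 3.5232, tolerance = 1e-4 / 3.5232)
})

test_that("delta is bounded, increasing, and preserves temperature ranks", {
  # realistic sea-surface span; far outside it the logistic saturates to
  # 0 / T_inc at double precision, as documented
  tr <- tolerance_transform(3, 4.2, increase_rate = 2, suitability_peak = 16)
  x <- withr::with_seed(1, sort(runif(500, 4, 28)))
  d <- delta(x, tr)
  expect_true(all(d > 0 & d < 4.2))
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(x + d) > 0)) # no rank inversions
})

test_that("transform_layer shifts cell-wise and preserves the mask", {
  tr <- tolerance_transform(2, 5, increase_rate = 2, suitability_peak = 15)
  m <- matrix(15, 4, 5); m[2, 2] <- NA
  out <- transform_layer(m, tr)
  expect_true(is.na(out[2, 2]))
  expect_equal(out[1, 1], 15 + 2.5)
  w <- tiny_world()
  t0 <- w$present$layers$temperature
  t1 <- transform_layer(t0, tr)
  ok <- !is.na(t0)
  expect_true(all(t1[ok] > t0[ok]))
  expect_lt(max(t1[ok] - t0[ok]), 5)
  expect_equal(order(t0[ok]), order(t1[ok]))
})

test_that("transform parameters are validated", {
  expect_error(tolerance_transform(0, 2, suitability_peak = 15),
               "target_increase must be >= 1")
  expect_error(tolerance_transform(3, 2, suitability_peak = 15))
  expect_error(tolerance_transform(1, 2, increase_rate = -1,
                                   suitability_peak = 15))
})

test_that("fast calibration returns the closed-form first-order value", {
  # threshold chosen so the upper crossing sits exactly at the peak:
  # fraction 1/2 -> T_inc = 2k
  curve <- fake_curve(peak = 15)
  suppressMessages({
    t1 <- calibrate_Tinc(curve, threshold = 0.9 - 1e-9, k = 2,
                         increase_rate = 2)
  })
  expect_equal(as.numeric(t1), 4, tolerance = 1e-2)
  expect_equal(attr(t1, "mode"), "fast")
  # a crossing far above the peak gives a fraction near 1 -> T_inc ~ k
  wide <- fake_curve(peak = 15, width = 5)
  thr <- wide$cloglog[which.min(abs(wide$value - 29))]
  suppressMessages(t2 <- calibrate_Tinc(wide, thr, k = 3, increase_rate = 2))
  expect_equal(as.numeric(t2), 3, tolerance = 1e-3)
  expect_error(calibrate_Tinc(fake_curve(), threshold = 0.95, k = 1),
               "never reaches")
})

test_that("full calibration bisects the retrained crossing to the target", {
  base <- fake_curve(peak = 15)
  thr <- 0.5
  # mock retraining: raising tolerance by T_inc moves the upper tail by
  # 0.8 * T_inc, so the exact answer is k / 0.8
  refit <- function(ti) fake_curve(peak = 15 + 0.8 * ti)
  suppressMessages(
    t_inc <- calibrate_Tinc(base, thr, k = 3, increase_rate = 2,
                            refit_curve = refit))
  expect_equal(attr(t_inc, "mode"), "full")
  expect_equal(as.numeric(t_inc), 3 / 0.8, tolerance = 0.05)
  expect_lt(abs(attr(t_inc, "achieved_shift") - 3), 0.05 + 1e-9)
})

test_that("the family constructor validates its targets", {
  cv <- tiny_cv()
  p <- tiny_study_parts()
  expect_error(train_shifted_family(cv, p$stack, list(), k_list = c(0, 1)),
               "target_increase must be >= 1")
  empty <- train_shifted_family(cv, p$stack, list(), k_list = integer(0))
  expect_s3_class(empty, "tolerance_family")
  expect_length(empty, 0L)
})

test_that("the shifted response curve dominates the base curve above the peak", {
  cv <- tiny_cv()
  p <- tiny_study_parts()
  base <- response_curve(cv$pooled_fit)
  peak <- suitability_peak(base)
  tr <- tolerance_transform(3, 4, increase_rate = 2, suitability_peak = peak)
  env_p <- extract_cells(p$stack, cv$presence_cells)
  env_b <- extract_cells(p$stack, cv$bg_cells)
  env_p$temperature <- transform_layer(env_p$temperature, tr)
  env_b$temperature <- transform_layer(env_b$temperature, tr)
  shifted_fit <- suppressWarnings(fit_maxnet(
    env_p, env_b, classes = cv$candidate$classes,
    multiplier = cv$candidate$multiplier))
  xs <- seq(peak, max(base$value), length.out = 50)
  nd <- as.data.frame(as.list(cv$pooled_fit$bg_var_means))[rep(1, 50), ]
  nd$temperature <- xs
  y_base <- predict(cv$pooled_fit, nd)
  y_shift <- predict(shifted_fit, nd)
  expect_true(all(y_shift >= y_base - 0.02))
})
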