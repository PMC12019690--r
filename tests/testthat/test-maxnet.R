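# penalized objective in original feature space, used as the independent
# reference throughout: -mean(Fp b) + log(sum(exp(Fb b))) + sum(lambda|b|)
penalized_objective <- function(beta, Fp, Fb, lambda) {
  eta <- drop(Fb %*% beta)
  m <- max(eta)
  -mean(drop(Fp %*% beta)) + m + log(sum(exp(eta - m))) +
    sum(lambda * abs(beta))
}

test_that("feature expansion has the documented layout and size", {
  d <- data.frame(b = 1:3, a = c(2, 4, 6))
  expect_equal(colnames(build_features(d, "linear")), c("a", "b"))
  f <- build_features(data.frame(a = 1, b = 2, c = 3),
                      c("linear", "quadratic", "product"))
  expect_equal(ncol(f), 9L)
  expect_equal(colnames(f), c("a", "b", "c", "a^2", "b^2", "c^2",
                              "a:b", "a:c", "b:c"))
  expect_equal(attr(f, "classes"),
               rep(c("linear", "quadratic", "product"), each = 3))
  expect_error(build_features(d, "hinge"), "unknown feature class")
})

test_that("prediction clamps inputs into the training range", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background, classes = "linear")
  hi <- max(c(pd$presence$temperature, pd$background$temperature))
  nd_max <- data.frame(temperature = hi, noise = 0)
  nd_beyond <- data.frame(temperature = hi + 50, noise = 0)
  expect_equal(predict(fit, nd_beyond), predict(fit, nd_max))
})

test_that("a flat likelihood yields all-zero coefficients", {
  withr::with_seed(2, {
    bg <- data.frame(x = rnorm(20), y = runif(20))
  })
  fit <- suppressWarnings(fit_maxnet(bg, bg,
                                     classes = c("linear", "quadratic")))
  expect_true(all(abs(fit$beta) < 1e-6))
  # with zero coefficients raw is uniform over the background
  expect_equal(predict(fit, bg, type = "raw"), rep(1 / 20, 20),
               tolerance = 1e-4)
})

test_that("presences concentrated at high values force a positive slope", {
  withr::with_seed(3, {
    bg <- data.frame(x = runif(200))
    pres <- data.frame(x = runif(40, 0.7, 1))
  })
  fit <- suppressWarnings(fit_maxnet(pres, bg, classes = "linear"))
  expect_gt(fit$beta[["x"]], 0)
})

test_that("an overwhelming multiplier shrinks every coefficient to zero", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background, multiplier = 1e6)
  expect_true(all(fit$beta == 0))
})

test_that("raw predictions normalize over the training background", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background)
  raw <- predict(fit, pd$background, type = "raw")
  expect_lt(abs(sum(raw) - 1), 1e-10)
  expect_gte(fit$entropy, 0)
  # cloglog is a strictly increasing transform of raw
  cll <- predict(fit, pd$background, type = "cloglog")
  ord <- order(raw)
  expect_true(all(diff(cll[ord]) >= 0))
  expect_true(all(cll > 0 & cll < 1))
})

test_that("raw is invariant to adding a constant to a feature column", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background, classes = "linear")
  Fb <- build_features(pd$background, "linear")[, names(fit$beta)]
  eta <- drop(Fb %*% fit$beta)
  raw0 <- exp(eta - thermoshift:::logsumexp(eta))
  eta_shift <- drop((Fb + 100) %*% fit$beta) # every column shifted
  raw1 <- exp(eta_shift - thermoshift:::logsumexp(eta_shift))
  expect_equal(raw1, raw0)
})

test_that("constant features are excluded with a warning", {
  withr::with_seed(4, {
    bg <- data.frame(x = rnorm(120), flat = 1)
    pres <- data.frame(x = rnorm(10, 1), flat = 1)
  })
  expect_warning(fit <- fit_maxnet(pres, bg, classes = "linear"),
                 "constant feature")
  expect_equal(names(fit$beta), "x")
})

test_that("the penalized objective never increases across iterations", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("the solver matches a generic optimizer on small instances", {
  for (seed in 1:3) {
    inst <- withr::with_seed(seed, {
      bg <- data.frame(x = rnorm(40), z = runif(40))
      pres <- bg[sample(40, 12, prob = plogis(2 * bg$x)), ]
      list(pres = pres, bg = bg)
    })
    fit <- suppressWarnings(fit_maxnet(inst$pres, inst$bg,
                                       classes = "linear"))
    Fp <- build_features(inst$pres, "linear")
    Fb <- build_features(inst$bg, "linear")
    lam <- fit$lambda
    ours <- penalized_objective(fit$beta, Fp, Fb, lam)
    ref <- optim(rep(0, ncol(Fb)), penalized_objective, Fp = Fp, Fb = Fb,
                 lambda = lam, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    expect_lt(abs(ours - ref$value), 1e-4)
  }
})

test_that("response curves locate interior optima from the fitted quadratic", {
  pd <- planted_fit_data()
  d1 <- pd$presence["temperature"]; d0 <- pd$background["temperature"]
  fit <- fit_maxnet(d1, d0, classes = c("linear", "quadratic"))
  rc <- response_curve(fit, "temperature", n_points = 400)
  expect_equal(nrow(rc), 400L)
  b1 <- fit$beta[["temperature"]]; b2 <- fit$beta[["temperature^2"]]
  expect_lt(b2, 0)
  vertex <- -b1 / (2 * b2)
  spacing <- diff(rc$value[1:2])
  expect_lt(abs(suitability_peak(rc) - vertex), spacing)
  # near the planted optimum of 16 degC
  expect_lt(abs(suitability_peak(rc) - 16), 1)

  # a purely increasing exponent peaks at the range maximum
  fit_lin <- suppressWarnings(fit_maxnet(
    data.frame(temperature = runif(30, 20, 26)), d0, classes = "linear"))
  rc_lin <- response_curve(fit_lin, "temperature")
  expect_equal(suitability_peak(rc_lin), max(rc_lin$value))
  expect_error(response_curve(fit, "salinity"), "not in the fitted model")
})

test_that("permutation importance isolates the informative variable", {
  pd <- planted_fit_data()
  fit <- fit_maxnet(pd$presence, pd$background,
                    classes = c("linear", "quadratic"))
  imp <- permutation_importance(fit, pd$presence, pd$background, seed = 5)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_gt(imp[["temperature"]], 95)
  expect_lt(imp[["noise"]], 5)
})

test_that("exchangeable variable copies split the contribution evenly", {
  pd <- planted_fit_data()
  pres <- data.frame(t1 = pd$presence$temperature,
                     t2 = pd$presence$temperature)
  bg <- data.frame(t1 = pd$background$temperature,
                   t2 = pd$background$temperature)
  fit <- fit_maxnet(pres, bg, classes = c("linear", "quadratic"))
  imp <- permutation_importance(fit, pres, bg, n_repeats = 10, seed = 6)
  expect_lt(abs(imp[["t1"]] - 50), 3)
})
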