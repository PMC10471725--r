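test_that("the data-space Jacobian solves H DPsi = -M and handles edge cases", {
  # scalar-mean model with d data points: H = 2d, M = -2 * 1' -> DPsi = 1/d
  d <- 4
  H <- matrix(2 * d, 1, 1)
  M <- matrix(-2, 1, d)
  DPsi <- computeDPsi(H, M)
  expect_equal(unname(DPsi[1, ]), rep(1 / d, d))
  expect_equal(max(abs(H %*% DPsi + M)), 0, tolerance = 1e-12)

  # M = 0 -> DPsi = 0
  expect_equal(computeDPsi(H, matrix(0, 1, 3)), matrix(0, 1, 3),
               ignore_attr = TRUE)

  # linear model: DPsi = (X'X)^{-1} X'
  X <- randomDesign(6, 3)
  H <- 2 * crossprod(X)
  M <- -2 * t(X)
  expect_rel_equal(computeDPsi(H, M), solve(crossprod(X), t(X)), 1e-9)

  # singular Hessian names the near-null direction
  Hs <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(computeDPsi(Hs, matrix(0, 2, 2)), "unidentifiab")
})

test_that("continuation state assembles FD pieces consistently within the simulation budget", {
  m <- rampModel() # y_i = t_i * theta: exact linear model in disguise
  th <- paramVector(c(k = 2), lower = 0, upper = 10)
  tt <- c(1, 2, 3)
  d <- calibrationData(tt, c(2.2, 3.9, 6.1))
  counterReset(m)
  st <- continuationState(m, th, d)
  # closed form: X = t, DPsi = X' / (X'X)
  expect_rel_equal(st$dpsi, matrix(tt / sum(tt^2), 1), 1e-6)
  # linear-system invariant
  expect_lt(max(abs(st$hessian %*% st$dpsi + st$mixed_partial)), 1e-6)
  # full build within 2p(p+2) model simulations (single condition)
  p <- 1
  expect_lte(st$eval_counts$n_sim, 2 * p * (p + 2))
  expect_lte(st$eval_counts$n_obj, 2 * p * (p + 1))
})

test_that("the predictor is exact for observables affine in the parameters", {
  X <- randomDesign(6, 3, seed = 21)
  m <- linearModel(X)
  phi <- as.numeric(X %*% c(1, -2, 0.5)) + c(0.1, -0.2, 0.05, 0, 0.3, -0.1)
  d <- calibrationData(seq_len(6), phi)
  theta0 <- paramVector(m$mle(phi), names = c("t1", "t2", "t3"))
  st <- continuationState(m, theta0, d)
  set.seed(31)
  for (rep in 1:5) {
    dphi <- stats::rnorm(6, 0, 0.5)
    pred <- predictMLE(st, dphi)
    exact <- m$mle(phi + dphi)
    expect_rel_equal(pred$values, exact, 1e-6)
  }
  # zero perturbation returns theta* unchanged
  expect_equal(predictMLE(st, rep(0, 6))$values, theta0$values)
})

test_that("predictions respect the mean-shift closed form and clip to bounds", {
  m <- meanModel()
  th <- paramVector(c(mu = 2), lower = 0, upper = 3)
  d <- calibrationData(1:3, c(1, 2, 3))
  st <- continuationState(m, th, d)
  pred <- predictMLE(st, c(0.3, 0, 0))
  expect_equal(unname(pred$values), 2.1, tolerance = 1e-8) # mean shifts by 0.1
  th2 <- paramVector(c(mu = 2), lower = 0, upper = 2.05)
  st2 <- continuationState(m, th2, d)
  expect_warning(pred2 <- predictMLE(st2, c(0.9, 0, 0)), "clipped")
  expect_equal(unname(pred2$values), 2.05)
})

test_that("the corrector never worsens the start and reaches stationarity on smooth problems", {
  X <- randomDesign(5, 2, seed = 41)
  m <- linearModel(X)
  phi <- as.numeric(X %*% c(2, -1)) + c(0.1, 0, -0.1, 0.2, 0)
  d <- calibrationData(seq_len(5), phi)
  start <- paramVector(c(a = 0.5, b = 0.5), lower = -10, upper = 10)
  fit <- correctMLE(m, d, start)
  expect_rel_equal(fit$theta$values, m$mle(phi), 1e-6)
  expect_lte(fit$objective, objectiveValue(m, start, d) + 1e-12)
  expect_true(fit$converged)
  expect_gt(fit$n_obj, 0)

  # starting at the optimum returns it essentially unchanged
  fit2 <- correctMLE(m, d, fit$theta)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-9)
})

test_that("continuation along identical data sets is stationary; linear paths are exact", {
  X <- randomDesign(5, 2, seed = 51)
  m <- linearModel(X)
  phi0 <- as.numeric(X %*% c(1, 1))
  d0 <- calibrationData(seq_len(5), phi0)
  th0 <- paramVector(m$mle(phi0), names = c("a", "b"))

  # identical data sets -> identical states
  same <- continuationPath(m, th0, d0, list(d0, d0), mode = "predict_only")
  expect_equal(same[[1]]$predicted$values, th0$values, tolerance = 1e-8)
  expect_equal(same[[2]]$predicted$values, th0$values, tolerance = 1e-8)

  # arbitrary sequence: predictions equal the exact MLE at every step
  set.seed(61)
  datasets <- lapply(1:3, function(j) {
    setDataValues(d0, phi0 + stats::rnorm(5, 0, 0.3))
  })
  steps <- continuationPath(m, th0, d0, datasets, mode = "predict_and_correct")
  for (j in seq_along(steps)) {
    exact <- m$mle(datasets[[j]]$value)
    expect_rel_equal(steps[[j]]$predicted$values, exact, 1e-6)
    expect_rel_equal(steps[[j]]$theta$values, exact, 1e-6)
  }
  # evaluation counters are cumulative and nondecreasing
  expect_true(all(diff(vapply(steps, function(s) s$n_obj, numeric(1))) >= 0))

  # mismatched designs are rejected
  dbad <- calibrationData(seq_len(5), phi0, sigma = 2)
  expect_error(continuationPath(m, th0, d0, list(dbad)), "share")
})

test_that("a pinned parameter produces a zero Jacobian row and consistent predictions", {
  # two-parameter mean-like model where b is pinned at its bound
  m <- modelSpec(name = "two", analytic = function(times, theta, condition) {
    rep(theta[["a"]] + theta[["b"]], length(times))
  })
  th <- paramVector(c(a = 1, b = 2), lower = c(-10, 2), upper = c(10, 10))
  d <- calibrationData(1:3, c(3.1, 2.9, 3.0))
  st <- continuationState(m, th, d)
  expect_true(st$active["b"])
  expect_equal(unname(st$dpsi["b", ]), rep(0, 3))
  # free row behaves like the scalar mean model: 1/d per point
  expect_equal(unname(st$dpsi["a", ]), rep(1 / 3, 3), tolerance = 1e-6)
})
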