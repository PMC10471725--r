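test_that("viral dynamics preserve nonnegativity and the burst-size identity", {
  m <- viralModel()
  th <- viralReferenceParams()
  tt <- seq(0.5, 58, by = 2.5)

  # trajectories stay (numerically) nonnegative from nonnegative initials
  init <- c(T = 300, I = 0, V = 100)
  rhs <- function(t, s, p) list(m$rhs(t, s, th$values, "control"))
  sol <- deSolve::ode(init, c(0, tt), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_gt(min(sol[, -1]), -1e-8 * max(sol[, -1]))

  # V = 0, I = 0: dT/dt = lambda - d T, other derivatives vanish
  dx <- m$rhs(0, c(T = 100, I = 0, V = 0), th$values, "control")
  expect_equal(dx[1], 80 - 0.15 * 100)
  expect_equal(dx[2:3], c(0, 0))

  # (beta, d, delta, c, N, lambda) and the p = delta*N parameterization
  # give identical virion production
  p_prod <- th$values[["delta"]] * th$values[["N"]]
  expect_equal(p_prod, 495)
  m2 <- modelSpec(
    name = "viral-p",
    rhs = function(t, state, theta, condition) {
      c(
        theta[["lambda"]] - theta[["beta"]] * state[1] * state[3] - theta[["d"]] * state[1],
        theta[["beta"]] * state[1] * state[3] - theta[["delta"]] * state[2],
        theta[["p"]] * state[2] - theta[["c"]] * state[3]
      )
    },
    initial_state = function(theta, condition) init,
    observable = function(states, theta) log10(states[, 3])
  )
  th2 <- paramVector(c(beta = 2e-5, d = 0.15, delta = 0.55, c = 5.5,
                       p = p_prod, lambda = 80))
  y1 <- simulateObservables(m, th, tt)
  y2 <- simulateObservables(m2, th2, tt)
  expect_equal(y1, y2, tolerance = 1e-8)
})

test_that("infection grows from a small inoculum when R0 exceeds one", {
  th <- viralReferenceParams()
  v <- th$values
  R0 <- v[["lambda"]] * v[["beta"]] * v[["N"]] / (v[["d"]] * v[["c"]])
  expect_equal(R0, 80 * 2e-5 * 900 / (0.15 * 5.5), tolerance = 1e-12)
  expect_gt(R0, 1)
  # simulation confirms growth: seed a tiny inoculum at the uninfected
  # equilibrium T = lambda/d and watch V rise
  m <- viralModel(init = c(T = 80 / 0.15, I = 0, V = 1e-3))
  y <- simulateObservables(m, th, c(1, 10, 20))
  expect_gt(y[3], y[1])
})

test_that("phenotype-switching growth shuts off at carrying capacity and responds to treatment", {
  m <- nsclcModel(K = 4800)
  th <- nsclcSyntheticParams()

  # logistic factor vanishes at A + B = K: both growth terms are pure death
  dx <- m$rhs(0, c(A = 4000, B = 800), th$values, "control")
  expect_equal(dx[1], -th$values[["d_A"]] * 4000)
  expect_equal(dx[2], -th$values[["d_A"]] * 800)

  # control and treated trajectories agree before treatment start (day 3)
  tt_pre <- c(0.5, 1.5, 2.5, 2.9)
  y_ctrl <- simulateObservables(m, th, tt_pre, "control")
  y_trt <- simulateObservables(m, th, tt_pre, "treated")
  expect_equal(y_ctrl, y_trt, tolerance = 1e-9)

  # treated population decreases immediately after day 3
  y_post <- simulateObservables(m, th, c(3.05, 3.3, 3.6, 4), "treated")
  expect_true(all(diff(y_post) < 0))
  y3 <- simulateObservables(m, th, c(2.99, 3.2), "treated")
  expect_lt(y3[2], y3[1])

  # control stays below carrying capacity over the fitted window
  y_ctrl_full <- simulateObservables(m, th, seq(0.5, 7, by = 0.5), "control")
  expect_lt(max(y_ctrl_full), 4800 * (1 + 1e-6))
})

test_that("linear models expose exact normal-equations oracles", {
  # column of ones: MLE is the sample mean
  m1 <- linearModel(matrix(1, 3, 1))
  expect_equal(m1$mle(c(1, 2, 3)), 2)
  # identity design: MLE = phi, DPsi = identity
  mI <- linearModel(diag(3))
  expect_equal(mI$mle(c(4, 5, 6)), c(4, 5, 6))
  expect_equal(mI$dpsi_exact(), diag(3), ignore_attr = TRUE)
  # arbitrary design matches a direct solve
  X <- randomDesign(5, 2, seed = 81)
  m <- linearModel(X)
  phi <- stats::rnorm(5)
  expect_equal(m$mle(phi), as.numeric(solve(crossprod(X), crossprod(X, phi))),
               tolerance = 1e-10)
  expect_error(linearModel(cbind(1:4, 2 * (1:4))), "rank")
})

test_that("the model registry resolves names", {
  expect_equal(getModel("viral")$name, "viral")
  expect_equal(getModel("nsclc")$name, "nsclc")
  expect_equal(getModel("linear", X = diag(2))$name, "linear")
  expect_error(getModel("nope"), "unknown model")
})
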