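# Shared fixtures: tiny closed-form models used across the suite.

# dx/dt = 0, x(0) = theta1, observable = state: y_i = theta1 for all i.
constantModel <- function() {
  modelSpec(
    name = "constant",
    rhs = function(t, state, theta, condition) 0,
    initial_state = function(theta, condition) c(x = theta[["theta1"]]),
    observable = function(states, theta) states[, 1]
  )
}

# Scalar-mean model: y_i(theta) = theta for every data row (closed form).
meanModel <- function() {
  modelSpec(
    name = "mean",
    analytic = function(times, theta, condition) rep(theta[[1]], length(times))
  )
}

# y(t; theta) = t * theta (closed form, linear in theta).
rampModel <- function() {
  modelSpec(
    name = "ramp",
    analytic = function(times, theta, condition) times * theta[[1]]
  )
}

# Scalar quadratic observable y = theta^2 at a single "time".
squareModel <- function() {
  modelSpec(
    name = "square",
    analytic = function(times, theta, condition) rep(theta[[1]]^2, length(times))
  )
}

# Random full-rank design for the linear model, fixed by seed.
randomDesign <- function(d = 6, p = 3, seed = 11) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(seed, matrix(stats::rnorm(d * p), d, p))
}

# Precise viral model + small fixtures for the heavier tests.
preciseViral <- function() viralModel(rtol = 1e-12, atol = 1e-14)

expect_rel_equal <- function(actual, expected, tol) {
  scale <- pmax(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(actual - expected) / scale), tol)
}

# The viral study setup is expensive (baseline fit + refined Jacobian);
# compute it once per test run and share it across acceptance blocks.
.viral_cache <- new.env(parent = emptyenv())
viralSetupCached <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.viral_cache[[key]])) {
    .viral_cache[[key]] <- suppressWarnings(viralStudySetup(seed = seed))
  }
  .viral_cache[[key]]
}
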