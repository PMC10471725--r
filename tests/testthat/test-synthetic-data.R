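test_that("generators are pure functions of their seed", {
  m <- viralModel()
  th <- viralReferenceParams()
  a <- generateViralBaseline(m, th, seed = 9)
  b <- generateViralBaseline(m, th, seed = 9)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, generateViralBaseline(m, th, seed = 10)$value))

  d0 <- calibrationData(1:5, c(2, 3, 4, 5, 6))
  expect_identical(perturbAbsolute(d0, 0.1, 3)$value,
                   perturbAbsolute(d0, 0.1, 3)$value)
  expect_identical(perturbLog(d0, 0.8, 3)$value, perturbLog(d0, 0.8, 3)$value)
  expect_identical(perturbNormScaled(d0, 2, seed = 3)$value,
                   perturbNormScaled(d0, 2, seed = 3)$value)
  # the generators restore the caller's RNG state
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123); invisible(generateViralBaseline(m, th, seed = 5))
  expect_identical(stats::rnorm(1), before)
})

test_that("the viral baseline adds log10 noise of the configured variance", {
  m <- viralModel()
  th <- viralReferenceParams()
  tt <- c(0.4, 1, 8, 14, 20, 36, 46, 58)
  y <- simulateObservables(m, th, tt)
  # zero variance reproduces the noiseless log10 viral load
  d0 <- generateViralBaseline(m, th, sigma2 = 0, seed = 1)
  expect_equal(d0$value, y, tolerance = 1e-12)
  # Monte-Carlo: pooled variance of the added noise across replicates
  eps <- unlist(lapply(1:1250, function(s) {
    generateViralBaseline(m, th, seed = s)$value - y
  }))
  expect_lt(abs(stats::var(eps) - 0.15), 0.05 * 0.15)
})

test_that("absolute half-normal perturbations shift monotonically with h_step", {
  d0 <- calibrationData(1:6, c(1, 2, 3, 4, 5, 6))
  up <- perturbAbsolute(d0, 0.1, seed = 2)
  expect_true(all(up$value >= d0$value)) # |eps| >= 0
  dn <- perturbAbsolute(d0, -0.1, seed = 2)
  expect_true(all(dn$value <= d0$value))
  expect_identical(perturbAbsolute(d0, 0, seed = 2)$value, d0$value)
  # mean shift approximates h_step * sqrt(2/pi)
  big <- calibrationData(seq_len(1e4), rep(1, 1e4))
  shift <- mean(perturbAbsolute(big, 0.1, seed = 4)$value - 1)
  expect_lt(abs(shift - 0.1 * sqrt(2 / pi)), 0.003)
})

test_that("log perturbations preserve positivity and have the configured spread", {
  d0 <- calibrationData(1:4, c(0.5, 2, 8, 32))
  expect_identical(perturbLog(d0, 0, seed = 5)$value, d0$value)
  for (s in 1:20) expect_true(all(perturbLog(d0, 0.8, seed = s)$value > 0))
  big <- calibrationData(seq_len(1e4), rep(10, 1e4))
  lr <- log(perturbLog(big, 0.8, seed = 6)$value) - log(10)
  expect_lt(abs(stats::sd(lr) - 0.8), 0.02)
})

test_that("norm-scaled perturbations hit their target distance exactly and honor constraints", {
  d0 <- calibrationData(c(0, 2, 4, 6, 4, 6), c(900, 1600, 2500, 3400, 1300, 900),
                        condition = c(rep("control", 4), rep("treated", 2)))
  cons <- rbind(c(5, 3), c(6, 4))
  l0 <- log10(d0$value)
  for (j in c(1, 5, 10)) {
    pj <- perturbNormScaled(d0, j, h_step = 0.07, seed = 100 + j,
                             constraints = cons)
    achieved <- sqrt(sum((log10(pj$value) - l0)^2)) / sqrt(sum(l0^2))
    expect_equal(achieved, 0.05 + j * 0.07, tolerance = 1e-12)
    expect_true(all(pj$value[cons[, 1]] <= pj$value[cons[, 2]]))
  }
  # constraints hold across many seeds
  for (s in 1:25) {
    pj <- perturbNormScaled(d0, 3, seed = s, constraints = cons)
    expect_true(all(pj$value[cons[, 1]] <= pj$value[cons[, 2]]))
  }
  # degenerate target factor: h_step chosen so the factor is zero
  p0 <- perturbNormScaled(d0, 1, h_step = -0.05, seed = 1)
  expect_equal(p0$value, d0$value, tolerance = 1e-12)
})

test_that("constraint enforcement leaves unconstrained rows' draws untouched", {
  d0 <- calibrationData(c(0, 2, 4, 6, 4, 6), c(900, 1600, 2500, 3400, 1300, 900),
                        condition = c(rep("control", 4), rep("treated", 2)))
  cons <- rbind(c(5, 3), c(6, 4))
  free_rows <- c(1, 2)
  with_c <- vapply(1:400, function(s) {
    log10(perturbNormScaled(d0, 3, seed = s, constraints = cons)$value[free_rows])
  }, numeric(2))
  without_c <- vapply(1:400, function(s) {
    log10(perturbNormScaled(d0, 3, seed = s)$value[free_rows])
  }, numeric(2))
  # two-sample location comparison on the free rows
  for (r in 1:2) {
    pv <- stats::wilcox.test(with_c[r, ], without_c[r, ])$p.value
    expect_gt(pv, 1e-4)
  }
})

test_that("switching baselines respect the treated-below-control ordering", {
  m <- nsclcModel()
  th <- nsclcSyntheticParams()
  for (s in 1:5) {
    b <- generateSwitchingBaseline(m, th, seed = s)
    expect_equal(nrow(b), 6)
    cons <- attr(b, "constraints")
    expect_true(all(b$value[cons[, 1]] <= b$value[cons[, 2]]))
  }
})
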