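test_that("per-point sensitivity is the absolute column sum with earliest-index ties", {
  D <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(unname(dataPointSensitivity(D)), c(1, 2))
  expect_equal(unname(dataPointSensitivity(D, 1)), 1)
  expect_error(dataPointSensitivity(D, 5), "out of range")

  D2 <- matrix(c(1, 3, -2, 4), 2, 2) # columns (1,3) and (-2,4)
  expect_equal(unname(dataPointSensitivity(D2, 2)), 6)

  mip <- mostInformativePoint(D)
  expect_equal(mip$index, 2)
  expect_equal(mip$value, 2)
  expect_equal(dpsiNorm(D), 2)

  # ties break to the earliest data point
  expect_equal(mostInformativePoint(matrix(1, 2, 3))$index, 1)
  # a zero column is never selected over a nonzero one
  D3 <- cbind(c(0, 0), c(0.5, 0.1))
  expect_equal(mostInformativePoint(D3)$index, 2)
})

test_that("per-point sensitivity is invariant to residual sign and permutes with rows", {
  D <- matrix(c(1, -2, 3, 4, -5, 6), 2, 3)
  expect_equal(dataPointSensitivity(-D), dataPointSensitivity(D))
  perm <- c(3, 1, 2)
  expect_equal(unname(dataPointSensitivity(D[, perm])),
               unname(dataPointSensitivity(D)[perm]))
})

test_that("BIC is consistent for within-model comparisons", {
  expect_equal(bic(2.5, 4, 6), bic(2.5, 4, 6))
  # delta BIC depends only on the objective difference at equal p, d
  expect_equal(bic(3, 4, 6) - bic(2, 4, 6), 2 * (3 - 2))
  expect_gt(bic(3, 4, 6), bic(2, 4, 6))
})

test_that("appending an exact simulated measurement leaves the objective unchanged", {
  m <- preciseViral()
  th <- viralReferenceParams()
  tt <- c(0.4, 1, 8, 14, 20)
  y <- simulateObservables(m, th, tt)
  d <- calibrationData(tt, y + c(0.1, -0.1, 0.2, 0, -0.2))
  g0 <- objectiveValue(m, th, d)
  aug <- appendSimulatedMeasurement(m, th, d, time = 10, condition = "control",
                                    delta_phi = 0)
  expect_equal(nrow(aug), nrow(d) + 1)
  expect_lt(abs(objectiveValue(m, th, aug) - g0), 1e-8)
  # appended row sits in time order
  expect_true(all(diff(aug$time[aug$condition == "control"]) > 0))
})

test_that("candidate ranking reports antisymmetric first-order shifts and sane ordering", {
  m <- nsclcModel()
  th <- nsclcSyntheticParams()
  spec <- objectiveSpec("log10_sum_of_squares")
  base <- generateSwitchingBaseline(m, th, seed = 3)
  fit <- fitMLE(m, base, th, spec)
  st <- continuationState(m, fit$theta, base, spec)
  dphi <- 0.3 * simulateObservables(m, fit$theta, 3.1, "treated")
  rk <- rankCandidateMeasurements(m, st, times = c(3.2, 5), condition = "treated",
                                  delta_phi = dphi, target_parameter = "d_A_max")
  expect_equal(nrow(rk), 4) # two candidates x two signs
  expect_setequal(rk$rank, 1:4)
  for (tt in unique(rk$time)) {
    up <- rk$pct_shift_d_A_max[rk$time == tt & rk$sign == "+"]
    dn <- rk$pct_shift_d_A_max[rk$time == tt & rk$sign == "-"]
    expect_lt(up * dn, 0) # opposite first-order response
  }
  # empty candidate list -> empty ranking
  rk0 <- rankCandidateMeasurements(m, st, numeric(0), "treated", delta_phi = dphi)
  expect_equal(nrow(rk0), 0)
})

test_that("robustness comparison is order-invariant and flat for linear models", {
  X <- randomDesign(6, 2, seed = 71)
  m <- linearModel(X)
  phi <- as.numeric(X %*% c(1, 2)) + 0.05
  d <- calibrationData(seq_len(6), phi)
  th1 <- paramVector(m$mle(phi), names = c("a", "b"))
  th2 <- th1 # identical candidates -> equal norms, ratio 1
  cmp <- compareMinimaRobustness(m, d, list(th1, th2))
  expect_equal(cmp$dpsi_norm[1], cmp$dpsi_norm[2], tolerance = 1e-9)
  expect_equal(cmp$norm_ratio, c(1, 1), tolerance = 1e-9)

  # order invariance with distinct (non-stationary, hence warned) points
  th3 <- paramVector(c(a = 0.8, b = 2.1))
  cmp_a <- suppressWarnings(compareMinimaRobustness(m, d, list(th1, th3)))
  cmp_b <- suppressWarnings(compareMinimaRobustness(m, d, list(th3, th1)))
  expect_equal(cmp_a$dpsi_norm, rev(cmp_b$dpsi_norm), tolerance = 1e-9)
  # linear model: DPsi is data-independent, so norms agree across points
  expect_equal(cmp_a$dpsi_norm[1], cmp_a$dpsi_norm[2], tolerance = 1e-9)
})

test_that("sensitivity reports expose the norm, argmax and per-parameter shifts", {
  m <- meanModel()
  th <- paramVector(c(mu = 2))
  d <- calibrationData(1:4, c(1.9, 2.2, 1.8, 2.1))
  st <- continuationState(m, th, d)
  rep_ <- sensitivityReport(st)
  expect_equal(rep_$dpsi_norm, dpsiNorm(st$dpsi))
  expect_equal(unname(rep_$per_point_sensitivity[rep_$most_informative_index]),
               rep_$dpsi_norm)
  expect_equal(dim(rep_$per_parameter_shift), dim(st$dpsi))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSensitivityCSV(rep_, path)
  tab <- utils::read.csv(path, row.names = 1)
  expect_equal(nrow(tab), 2) # one parameter + column-sum row
})
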