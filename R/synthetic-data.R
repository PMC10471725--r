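#' Seeded synthetic calibration data for the viral dynamics model
#'
#' Simulates the viral model at `theta`, takes the log10 viral load at the
#' requested times, and adds i.i.d. Gaussian noise of variance `sigma2` on
#' the log10 scale. The returned table carries the noisy log10 values with
#' unit noise scales, matching the unweighted log-scale objective used for
#' this model.
#'
#' @param model a [viralModel()] (or any model whose observable is already
#'   on the data scale).
#' @param theta a [paramVector()] of true parameters.
#' @param times measurement times (days); default the sparse 8-point
#'   schedule `0.4, 1, 8, 14, 20, 36, 46, 58`.
#' @param sigma2 noise variance on the log10 scale (default 0.15).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return a [calibrationData()] of log10 viral loads.
#' @export
generateViralBaseline <- function(model, theta,
                                  times = c(0.4, 1, 8, 14, 20, 36, 46, 58),
                                  sigma2 = 0.15, seed = 1L) {
  stopifnot(sigma2 >= 0)
  y <- simulateObservables(model, theta, times, "control")
  eps <- withSeed(seed, stats::rnorm(length(times), 0, sqrt(sigma2)))
  calibrationData(times, y + eps, sigma = 1, condition = "control")
}

## Evaluate expr under a local RNG state; restores the caller's state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Half-normal absolute perturbation of a data set
#'
#' `phi_i' = phi_i + h_step * |eps_i|` with `eps_i` standard normal: every
#' value is shifted in the direction of `h_step`'s sign, by an average of
#' `|h_step| * sqrt(2/pi)`. Emulates measurements drifting systematically
#' as a sample grows.
#'
#' @param data a [calibrationData()] table.
#' @param h_step signed step size (the study uses `+-0.1, +-0.2`).
#' @param seed integer seed.
#' @return a perturbed [calibrationData()] with the same design.
#' @export
perturbAbsolute <- function(data, h_step, seed = 1L) {
  eps <- withSeed(seed, stats::rnorm(nrow(data)))
  setDataValues(data, data$value + h_step * abs(eps))
}

#' Multiplicative log-space perturbation
#'
#' `log phi_i' = log phi_i + scale * eps_i` with standard-normal `eps_i`
#' (natural log), so the output stays strictly positive for positive
#' input.
#'
#' @param data a [calibrationData()] table with positive values.
#' @param scale log-space noise scale (default 0.8).
#' @param seed integer seed.
#' @return a perturbed [calibrationData()].
#' @export
perturbLog <- function(data, scale = 0.8, seed = 1L) {
  if (any(data$value <= 0)) stop("log perturbation requires positive values")
  eps <- withSeed(seed, stats::rnorm(nrow(data)))
  setDataValues(data, data$value * exp(scale * eps))
}

#' Norm-scaled log10 perturbation sequence with ordering constraints
#'
#' Draws a standard-normal direction in log10 space and rescales it so that
#' `||log10 phi^j - log10 phi^0||_2 = (0.05 + j * h_step) * ||log10 phi^0||_2`
#' holds exactly, giving a sequence of data sets at controlled, growing
#' distance from the baseline. Optional ordering constraints (row `i` must
#' not exceed row `j`, e.g. treated measurements bounded by their control
#' counterparts) are enforced by redrawing the offending components and
#' rescaling until satisfied, so the norm equality survives enforcement.
#'
#' The default `h_step = 0.65/55` places the tenth perturbation at ~17% of
#' the baseline log-norm. An `h_step = 0.07` preset instead makes step 10
#' reach 75% of the baseline log-norm; with half a dozen data points that
#' corresponds to several-hundred-fold changes of individual values, far
#' outside any regime where refitting (let alone continuation) is
#' meaningful, so the milder increment is the default.
#'
#' @param data baseline [calibrationData()] with strictly positive values.
#' @param j perturbation index (1-based); the distance factor is
#'   `0.05 + j * h_step`.
#' @param h_step per-step distance increment.
#' @param seed integer seed.
#' @param constraints optional two-column matrix (or list of length-2
#'   vectors) of row-index pairs `(lo, hi)` enforcing
#'   `value[lo] <= value[hi]`.
#' @param max_retries redraw budget for constraint enforcement.
#' @return a perturbed [calibrationData()].
#' @export
perturbNormScaled <- function(data, j, h_step = 0.65 / 55, seed = 1L,
                              constraints = NULL, max_retries = 1000L) {
  if (any(data$value <= 0)) stop("norm-scaled perturbation requires positive values")
  if (!is.null(constraints) && is.list(constraints)) {
    constraints <- do.call(rbind, constraints)
  }
  l0 <- log10(data$value)
  target <- (0.05 + j * h_step) * sqrt(sum(l0^2))
  d <- length(l0)
  vals <- withSeed(seed, {
    z <- stats::rnorm(d)
    for (try in seq_len(max_retries)) {
      delta <- if (target == 0 || sqrt(sum(z^2)) == 0) rep(0, d) else
        z * target / sqrt(sum(z^2))
      cand <- 10^(l0 + delta)
      bad <- integer(0)
      if (!is.null(constraints)) {
        viol <- cand[constraints[, 1]] > cand[constraints[, 2]]
        bad <- unique(as.integer(constraints[viol, ]))
      }
      if (!length(bad)) break
      z[bad] <- stats::rnorm(length(bad))
      cand <- NULL
    }
    if (is.null(cand)) stop("constraint enforcement failed after ",
                            max_retries, " redraws")
    cand
  })
  setDataValues(data, vals)
}

#' Append a simulated measurement to a calibration table
#'
#' Adds the model's own prediction `y(time; theta*) + delta_phi` as a new
#' row under the given condition, inserted so that times stay strictly
#' increasing within the condition. With `delta_phi = 0` the appended point
#' matches the model exactly, so the objective value at `theta*` (and hence
#' the MLE) is unchanged — the premise of simulated-measurement
#' experimental design.
#'
#' @param model a [modelSpec()].
#' @param theta the current MLE [paramVector()].
#' @param data a [calibrationData()] table.
#' @param time measurement time of the new point.
#' @param condition condition label of the new point.
#' @param delta_phi signed perturbation added to the simulated value
#'   (raw observable units).
#' @param sigma noise scale for the new row (default 1).
#' @return a [calibrationData()] with one extra row; the index of the new
#'   row is attached as attribute `"appended_row"`.
#' @export
appendSimulatedMeasurement <- function(model, theta, data, time, condition,
                                       delta_phi = 0, sigma = 1) {
  validateCalibrationData(data)
  y_s <- simulateObservables(model, theta, time, condition)
  new_row <- data.frame(
    time = time, value = y_s + delta_phi, sigma = sigma,
    condition = condition, stringsAsFactors = FALSE
  )
  df <- rbind(as.data.frame(data), new_row)
  ## stable sort: by condition first-appearance order, then time
  cond_order <- match(df$condition, unique(data$condition), nomatch = length(unique(data$condition)) + 1L)
  ord <- order(cond_order, df$time)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("calibration_data", "data.frame")
  validateCalibrationData(df)
  attr(df, "appended_row") <- which(df$time == time & df$condition == condition &
                                      df$value == new_row$value)[1]
  df
}
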