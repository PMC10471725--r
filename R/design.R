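#' Per-data-point sensitivity of the MLE
#'
#' The absolute column sum `sum_n |DPsi[n, k]|` measures how strongly the
#' full MLE responds to a unit perturbation of the `k`-th data value: it is
#' the first-order bound on the total parameter shift per unit data shift.
#' A zero column means the fit is completely insensitive to that
#' measurement.
#'
#' @param dpsi `p x d` data-space Jacobian (or a `continuation_state`).
#' @param k data-row index in `1..d`; omit for all rows.
#' @return numeric vector (or scalar when `k` given) of non-negative
#'   sensitivities.
#' @export
dataPointSensitivity <- function(dpsi, k = NULL) {
  dpsi <- asDPsiMatrix(dpsi)
  s <- colSums(abs(dpsi))
  if (is.null(k)) return(s)
  if (any(k < 1) || any(k > ncol(dpsi))) {
    stop("data-row index out of range 1..", ncol(dpsi))
  }
  s[k]
}

asDPsiMatrix <- function(x) {
  if (inherits(x, "continuation_state")) x <- x$dpsi
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 1)
  x
}

#' Induced 1-norm of the data-space Jacobian
#'
#' `||DPsi||_1 = max_k sum_n |DPsi[n, k]|`: the worst-case MLE sensitivity
#' over data points. Smaller values mean a fit more robust to data
#' perturbations.
#'
#' @inheritParams dataPointSensitivity
#' @return non-negative scalar.
#' @export
dpsiNorm <- function(dpsi) {
  max(dataPointSensitivity(dpsi))
}

#' Most informative data point
#'
#' The data row whose perturbation moves the MLE the most, i.e. the argmax
#' of [dataPointSensitivity()]; its value equals [dpsiNorm()]. Ties are
#' broken by the smallest index (earliest measurement).
#'
#' @inheritParams dataPointSensitivity
#' @return list with `index` and `value`.
#' @export
mostInformativePoint <- function(dpsi) {
  s <- dataPointSensitivity(dpsi)
  idx <- which.max(s) # which.max returns the first maximum: earliest index
  list(index = unname(idx), value = unname(s[idx]))
}

#' Sensitivity report for a fitted state
#'
#' Summarises the data-space Jacobian of a [continuationState()] as
#' experimental-design quantities: per-data-point sensitivities, the matrix
#' 1-norm, the most informative point, and the predicted per-parameter
#' shift for a unit (or specified) perturbation of each data point.
#'
#' @param state a [continuationState()].
#' @param delta_phi scalar perturbation size applied per data point for the
#'   per-parameter shift matrix (default 1, i.e. the raw Jacobian).
#' @return a `sensitivity_report`: list with `per_point_sensitivity`,
#'   `dpsi_norm`, `most_informative_index`, `per_parameter_shift` (`p x d`),
#'   and `labels`.
#' @export
sensitivityReport <- function(state, delta_phi = 1) {
  dpsi <- asDPsiMatrix(state)
  s <- dataPointSensitivity(dpsi)
  mip <- mostInformativePoint(dpsi)
  structure(
    list(
      per_point_sensitivity = s,
      dpsi_norm = mip$value,
      most_informative_index = mip$index,
      per_parameter_shift = dpsi * delta_phi,
      labels = colnames(dpsi)
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ||DPsi||_1 =", format(x$dpsi_norm, digits = 4),
      "at data row", x$most_informative_index, "\n")
  print(round(x$per_point_sensitivity, 6))
  invisible(x)
}

#' Write a sensitivity report as CSV
#'
#' Rows are parameters plus a final `column-sum` row; columns are data rows
#' labelled `time@condition`.
#'
#' @param report a [sensitivityReport()].
#' @param path output file path.
#' @export
writeSensitivityCSV <- function(report, path) {
  m <- rbind(report$per_parameter_shift,
             `column-sum` = report$per_point_sensitivity)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Rank candidate measurements by their informativeness
#'
#' Implements simulated-measurement experimental design: for each candidate
#' time point, append the model's own prediction `y(t; theta*)` to the data
#' (which by construction changes neither the MLE nor the objective),
#' rebuild the data-space Jacobian on the augmented design at the unchanged
#' MLE, and score the candidate by the predicted parameter shift a fixed
#' perturbation `+/- delta_phi` of the appended value would cause. Ranking
#' is by the absolute percent shift of `target_parameter` when given,
#' otherwise by the augmented `||DPsi||_1`; ties break toward earlier
#' times, then `+` perturbations, then input order.
#'
#' @param model a [modelSpec()].
#' @param state a [continuationState()] at the current MLE.
#' @param times numeric vector of candidate measurement times.
#' @param condition condition label the candidates are measured under.
#' @param delta_phi fixed perturbation magnitude, in raw observable units.
#' @param target_parameter optional parameter name to rank by.
#' @param fd an [fdConfig()].
#' @return a `data.frame` with one row per (candidate, sign): columns
#'   `time`, `condition`, `sign`, `simulated_value`, `augmented_norm`, one
#'   `pct_shift_<name>` column per parameter (percent relative change of
#'   the predicted MLE), and `rank`.
#' @export
rankCandidateMeasurements <- function(model, state, times,
                                      condition = "control", delta_phi,
                                      target_parameter = NULL,
                                      fd = fdConfig()) {
  stopifnot(inherits(state, "continuation_state"), length(times) >= 0)
  theta <- state$theta_star
  spec <- state$spec
  if (!is.null(target_parameter) &&
      !target_parameter %in% base::names(theta$values)) {
    stop("unknown target parameter '", target_parameter, "'")
  }
  rows <- list()
  for (tt in times) {
    aug <- appendSimulatedMeasurement(model, theta, state$data, tt, condition, 0)
    k <- attr(aug, "appended_row")
    y_s <- aug$value[k]
    if (spec$kind == "log10_sum_of_squares" && y_s - delta_phi <= 0) {
      stop("perturbation delta_phi = ", delta_phi,
           " exceeds the simulated value ", format(y_s), " at time ", tt,
           "; log10 residual undefined")
    }
    st_aug <- continuationState(model, theta, aug, spec, state$fd)
    for (sgn in c(+1, -1)) {
      dphi <- rep(0, nrow(aug))
      # perturbation enters on the objective's residual scale
      dphi[k] <- residualScale(y_s + sgn * delta_phi, spec) -
        residualScale(y_s, spec)
      shift <- as.numeric(st_aug$dpsi %*% dphi)
      pct <- 100 * shift / theta$values
      row <- data.frame(
        time = tt, condition = condition, sign = ifelse(sgn > 0, "+", "-"),
        simulated_value = y_s, augmented_norm = dpsiNorm(st_aug$dpsi)
      )
      for (nm in base::names(theta$values)) {
        row[[paste0("pct_shift_", nm)]] <- pct[match(nm, base::names(theta$values))]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), condition = character(0), sign = character(0),
               simulated_value = numeric(0), augmented_norm = numeric(0))
  if (nrow(out)) {
    score <- if (is.null(target_parameter)) out$augmented_norm else
      abs(out[[paste0("pct_shift_", target_parameter)]])
    ord <- order(-score, out$time, out$sign != "+", seq_len(nrow(out)))
    out$rank <- integer(nrow(out))
    out$rank[ord] <- seq_len(nrow(out))
  } else {
    out$rank <- integer(0)
  }
  out
}

#' Robustness comparison of competing local minima
#'
#' When several local minima fit the data comparably (similar objective and
#' BIC), the data-space Jacobian discriminates between them: a smaller
#' `||DPsi||_1` means the fitted parameters are less sensitive to
#' perturbations of the calibration data, and that fit is the more robust,
#' preferable one.
#'
#' @param model a [modelSpec()].
#' @param data a [calibrationData()] table.
#' @param thetas list of [paramVector()] candidates, each expected to be a
#'   stationary point of the objective on `data` (a warning is issued
#'   otherwise).
#' @param spec an [objectiveSpec()].
#' @param fd an [fdConfig()].
#' @param grad_tol scale-relative gradient sup-norm above which the
#'   stationarity warning fires.
#' @return a `data.frame` with one row per candidate: `objective`,
#'   `dpsi_norm`, `norm_ratio` (relative to the smallest finite norm), and
#'   `singular` (TRUE when the Hessian was numerically singular there; such
#'   candidates report `NA` norms but do not abort the others).
#' @export
compareMinimaRobustness <- function(model, data, thetas,
                                    spec = objectiveSpec(), fd = fdConfig(),
                                    grad_tol = 1e-3) {
  stopifnot(is.list(thetas), length(thetas) >= 1)
  norms <- rep(NA_real_, length(thetas))
  objs <- rep(NA_real_, length(thetas))
  singular <- rep(FALSE, length(thetas))
  for (i in seq_along(thetas)) {
    th <- thetas[[i]]
    objs[i] <- objectiveValue(model, th, data, spec)
    gn <- max(abs(scaledGradient(model, th, data, spec, fd)))
    if (gn > grad_tol * max(1, objs[i])) {
      warning("candidate ", i, " is not stationary (scaled gradient ",
              format(gn, digits = 3), "); its DPsi norm is only indicative")
    }
    st <- try(continuationState(model, th, data, spec, fd), silent = TRUE)
    if (inherits(st, "try-error")) {
      singular[i] <- TRUE
    } else {
      norms[i] <- dpsiNorm(st$dpsi)
    }
  }
  ref <- if (all(is.na(norms))) NA_real_ else min(norms, na.rm = TRUE)
  data.frame(
    candidate = seq_along(thetas),
    objective = objs,
    dpsi_norm = norms,
    norm_ratio = norms / ref,
    singular = singular
  )
}

#' Bayesian information criterion for a Gaussian sum-of-squares fit
#'
#' `BIC = -2 log L + p log d` with the Gaussian likelihood underlying the
#' weighted sum-of-squares objective, whose additive constants are dropped
#' (they cancel in any within-model comparison, the only use supported
#' here): `BIC = 2 G(theta*, phi) + p log d` up to a constant shared by all
#' fits of the same model to the same design.
#'
#' @param objective objective value `G` at the MLE.
#' @param p number of fitted parameters.
#' @param d number of data points.
#' @return BIC value (comparable only across fits sharing the design).
#' @export
bic <- function(objective, p, d) {
  stopifnot(d >= 1, p >= 0)
  2 * objective + p * log(d)
}
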