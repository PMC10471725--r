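#' Objective specification
#'
#' The fitting objective is the weighted sum of squared residuals,
#' `G(theta, phi) = sum_i (g(y_i(theta)) - g(phi_i))^2 / sigma_i^2`,
#' i.e. the Gaussian negative log-likelihood with its additive constants
#' dropped. The residual transform `g` is the identity for
#' `"weighted_sum_of_squares"` and `log10` for `"log10_sum_of_squares"`
#' (observations compared on the decadic log scale, standard for cell counts
#' and viral loads).
#'
#' All derivative machinery (gradients, Hessians, the mixed partial and the
#' data-space Jacobian) operates on this smooth sum-of-squares form. A
#' root-sum-of-squares display value is available via `sqrt()` on the returned
#' objective if desired, but it is never differentiated: the square root is
#' non-smooth at a perfect fit and a monotone transform does not move the
#' minimiser.
#'
#' @param kind `"weighted_sum_of_squares"` or `"log10_sum_of_squares"`.
#' @return an `objective_spec` object.
#' @export
objectiveSpec <- function(kind = c("weighted_sum_of_squares", "log10_sum_of_squares")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, constant_terms_dropped = TRUE),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat("<objective_spec>", x$kind, "(constants dropped)\n")
  invisible(x)
}

## Transform raw observable/data values onto the residual scale of the objective.
residualScale <- function(values, spec) {
  if (spec$kind == "log10_sum_of_squares") {
    if (any(values <= 0)) stop("log10 objective requires strictly positive values")
    log10(values)
  } else {
    values
  }
}

#' Weighted residual vector
#'
#' Residuals `(g(y_i) - g(phi_i)) / sigma_i` on the objective's residual
#' scale; the objective is their sum of squares.
#'
#' @inheritParams objectiveValue
#' @return numeric vector of length `nrow(data)`.
#' @export
residualVector <- function(model, theta, data, spec = objectiveSpec()) {
  y <- fittedValues(model, theta, data)
  (residualScale(y, spec) - residualScale(data$value, spec)) / data$sigma
}

#' Objective function value
#'
#' Evaluates the weighted sum-of-squares objective `G(theta, phi)` for the
#' model at the given parameters and calibration data. One call costs one
#' model simulation per condition in the data and increments the
#' objective-evaluation counter by one.
#'
#' @param model a [modelSpec()].
#' @param theta a [paramVector()].
#' @param data a [calibrationData()] table.
#' @param spec an [objectiveSpec()].
#' @return a single non-negative number; zero iff all residuals vanish.
#' @export
objectiveValue <- function(model, theta, data, spec = objectiveSpec()) {
  r <- residualVector(model, theta, data, spec)
  bumpObj(model, 1L)
  sum(r^2)
}

#' Scale-relative finite-difference gradient of the objective
#'
#' Central-difference gradient of `G` with respect to the *relative* change
#' of each parameter: component `n` is `dG/dtheta_n * max(|theta_n|, floor)`.
#' Parameters of a dynamical model commonly span many orders of magnitude
#' (e.g. an infection rate of 2e-5 next to a burst size of 900), so the raw
#' gradient components are not comparable; the scale-relative gradient is the
#' natural stationarity diagnostic and is what the corrector's convergence is
#' checked against.
#'
#' @inheritParams objectiveValue
#' @param fd an [fdConfig()]; its relative step is used for the differencing.
#' @return named numeric vector of length `p`.
#' @export
scaledGradient <- function(model, theta, data, spec = objectiveSpec(),
                           fd = fdConfig()) {
  p <- length(theta$values)
  g <- numeric(p)
  ## The gradient check uses a 10x smaller step than the curvature
  ## stencils: near an optimum the gradient is close to zero, so the
  ## h^2-truncation from third derivatives would otherwise dominate the
  ## estimate in strongly curved coordinates.
  fd_g <- fd
  fd_g$relative_step <- fd$relative_step / 10
  for (n in seq_len(p)) {
    st <- fdStep(theta, n, fd_g)
    up <- perturbParam(theta, n, +st)
    dn <- perturbParam(theta, n, -st)
    gn <- (objectiveValue(model, up, data, spec) -
             objectiveValue(model, dn, data, spec)) / (2 * st)
    g[n] <- gn * max(abs(theta$values[n]), fd$absolute_step_floor)
  }
  base::names(g) <- base::names(theta$values)
  g
}
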