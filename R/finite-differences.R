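#' Finite-difference configuration
#'
#' Step-size policy for all finite-difference derivatives. The per-parameter
#' step is `max(relative_step * |theta_n|, absolute_step_floor)`: relative so
#' that parameters spanning orders of magnitude are perturbed proportionally,
#' with an absolute floor so parameters at zero still move. The defaults
#' (1e-4 relative, 1e-12 floor) balance truncation error against integrator
#' noise, which is why the model integration tolerances default to 1e-10
#' relative — the integrator error must sit well below the FD increment.
#'
#' @param relative_step positive relative step (default 1e-4).
#' @param absolute_step_floor positive absolute floor (default 1e-12).
#' @param hessian_diagonal_scheme `"central"` (default, second-order accurate)
#'   or `"forward"` for the pure second derivatives.
#' @param richardson extrapolate the Hessian from step sizes `h` and `2h`
#'   (`(4 H(h) - H(2h)) / 3`), cancelling the leading `h^2` truncation term
#'   at twice the evaluation cost. Off by default; recommended whenever the
#'   observed information is badly conditioned, because the inverse in the
#'   data-space Jacobian amplifies Hessian truncation error along soft
#'   (weakly identified) directions.
#' @return an `fd_config` object. Deterministic: no randomness anywhere.
#' @export
fdConfig <- function(relative_step = 1e-4, absolute_step_floor = 1e-12,
                     hessian_diagonal_scheme = c("central", "forward"),
                     richardson = FALSE) {
  stopifnot(relative_step > 0, absolute_step_floor > 0)
  structure(
    list(
      relative_step = relative_step,
      absolute_step_floor = absolute_step_floor,
      hessian_diagonal_scheme = match.arg(hessian_diagonal_scheme),
      richardson = isTRUE(richardson)
    ),
    class = "fd_config"
  )
}

## Step for parameter n. Clipped so theta +- step stays inside the bounds
## when there is room; a parameter sitting on one bound keeps the unclipped
## step and the probe is allowed to exit the box (the box constrains the
## fit, not the model's domain — built-in bounds sit strictly inside it).
## A parameter pinned by coinciding bounds cannot be differenced at all.
fdStep <- function(theta, n, fd) {
  if (theta$upper[n] <= theta$lower[n]) {
    stop("finite-difference step for parameter '", base::names(theta$values)[n],
         "' clipped to zero: parameter pinned at both bounds")
  }
  st <- max(fd$relative_step * abs(theta$values[n]), fd$absolute_step_floor)
  room <- min(theta$upper[n] - theta$values[n], theta$values[n] - theta$lower[n])
  if (room >= st) return(unname(st))
  if (room >= fd$absolute_step_floor) return(unname(room))
  unname(st)
}

## FD probe point: values shifted, bounds stretched to contain the probe so
## that validation of downstream simulation calls still passes.
perturbParam <- function(theta, n, delta) {
  v <- theta$values
  v[n] <- v[n] + delta
  theta$values <- v
  theta$lower <- pmin(theta$lower, v)
  theta$upper <- pmax(theta$upper, v)
  theta
}

#' Sensitivity matrix of the observables
#'
#' Central-difference local sensitivities `S[n, i] = d y_i / d theta_n` of
#' every observable with respect to every parameter, on the residual scale of
#' the objective (so for a log10 objective the sensitivities are those of
#' `log10 y_i`). Costs exactly `2p` model simulations per condition in the
#' data.
#'
#' @param model a [modelSpec()].
#' @param theta a [paramVector()].
#' @param data a [calibrationData()] table providing the design points.
#' @param spec an [objectiveSpec()] fixing the residual scale.
#' @param fd an [fdConfig()].
#' @return `p x d` numeric matrix with parameter names as row names and
#'   `time@condition` labels as column names.
#' @export
sensitivityMatrix <- function(model, theta, data, spec = objectiveSpec(),
                              fd = fdConfig()) {
  validateCalibrationData(data)
  p <- length(theta$values)
  d <- nrow(data)
  S <- matrix(0, p, d, dimnames = list(base::names(theta$values), dataRowLabels(data)))
  for (n in seq_len(p)) {
    st <- fdStep(theta, n, fd)
    yp <- residualScale(fittedValues(model, perturbParam(theta, n, +st), data), spec)
    ym <- residualScale(fittedValues(model, perturbParam(theta, n, -st), data), spec)
    S[n, ] <- (yp - ym) / (2 * st)
  }
  S
}

#' Mixed second partial of the objective with respect to parameters and data
#'
#' For the weighted sum-of-squares objective the mixed partial is available in
#' closed form from the sensitivity matrix: `M[n, i] = -2 S[n, i] / sigma_i^2`
#' (with unit noise scales this is exactly `-2 dy_i/dtheta_n`). `M` maps data
#' perturbations into gradient perturbations and is the right-hand side of the
#' linear system defining the data-space Jacobian.
#'
#' @param S sensitivity matrix from [sensitivityMatrix()] (`p x d`).
#' @param sigma numeric vector of noise scales, length `d`.
#' @return `p x d` numeric matrix.
#' @export
mixedPartial <- function(S, sigma = 1) {
  stopifnot(is.matrix(S))
  sigma <- rep_len(as.numeric(sigma), ncol(S))
  if (any(sigma <= 0)) stop("noise scales must be strictly positive")
  sweep(S, 2, sigma^2, "/") * (-2)
}

#' Finite-difference Hessian of the objective
#'
#' Observed-information matrix `H = D^2_theta G` at `theta`, assembled from
#' objective evaluations only: the diagonal by a three-point second
#' difference (central by default, forward optional) and each off-diagonal
#' pair by the four-point mixed stencil
#' `[G(++) - G(+-) - G(-+) + G(--)] / (4 h_i h_j)`,
#' computed once per unordered pair and mirrored, then symmetrised as
#' `(H + t(H))/2`. Both stencils are exact on quadratics up to rounding. The
#' total cost is at most `2p(p+1)` objective evaluations.
#'
#' @inheritParams sensitivityMatrix
#' @return `p x p` symmetric numeric matrix with parameter names on both
#'   dimensions. A non-finite objective at any stencil point raises an error
#'   identifying the offending stencil displacement.
#' @export
hessianFD <- function(model, theta, data, spec = objectiveSpec(),
                      fd = fdConfig()) {
  if (fd$richardson) {
    fd_h <- fd; fd_h$richardson <- FALSE
    fd_2h <- fd_h; fd_2h$relative_step <- 2 * fd$relative_step
    fd_2h$absolute_step_floor <- 2 * fd$absolute_step_floor
    return((4 * hessianFD(model, theta, data, spec, fd_h) -
              hessianFD(model, theta, data, spec, fd_2h)) / 3)
  }
  p <- length(theta$values)
  nm <- base::names(theta$values)
  H <- matrix(0, p, p, dimnames = list(nm, nm))
  steps <- vapply(seq_len(p), function(n) fdStep(theta, n, fd), numeric(1))

  gEval <- function(dvec, tag) {
    th <- theta
    th$values <- theta$values + dvec
    th$lower <- pmin(th$lower, th$values)
    th$upper <- pmax(th$upper, th$values)
    val <- objectiveValue(model, th, data, spec)
    if (!is.finite(val)) {
      stop("non-finite objective at Hessian stencil point ", tag)
    }
    val
  }

  g0 <- gEval(rep(0, p), "center")
  for (n in seq_len(p)) {
    h <- steps[n]
    e <- replace(rep(0, p), n, h)
    if (fd$hessian_diagonal_scheme == "central") {
      H[n, n] <- (gEval(e, paste0("+", nm[n])) - 2 * g0 +
                    gEval(-e, paste0("-", nm[n]))) / h^2
    } else {
      H[n, n] <- (gEval(2 * e, paste0("+2", nm[n])) -
                    2 * gEval(e, paste0("+", nm[n])) + g0) / h^2
    }
  }
  if (p > 1) {
    for (i in seq_len(p - 1)) {
      for (j in seq((i + 1), p)) {
        hi <- steps[i]; hj <- steps[j]
        ei <- replace(rep(0, p), i, hi)
        ej <- replace(rep(0, p), j, hj)
        val <- (gEval(ei + ej, paste0("++", nm[i], ",", nm[j])) -
                  gEval(ei - ej, paste0("+-", nm[i], ",", nm[j])) -
                  gEval(-ei + ej, paste0("-+", nm[i], ",", nm[j])) +
                  gEval(-ei - ej, paste0("--", nm[i], ",", nm[j]))) /
          (4 * hi * hj)
        H[i, j] <- H[j, i] <- val
      }
    }
  }
  asym <- max(abs(H - t(H)))
  if (asym > 1e-3 * max(abs(H))) {
    warning("Hessian asymmetry ", format(asym),
            " exceeds 1e-3 * ||H||; FD step may be too large")
  }
  (H + t(H)) / 2
}
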