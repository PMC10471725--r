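#' Target-cell-limited viral dynamics model
#'
#' Standard three-compartment model of within-host viral infection: target
#' cells `T` are produced at rate `lambda` and cleared at rate `d`, become
#' infected at rate `beta` per virion, infected cells `I` are cleared at
#' rate `delta` and each releases `N` virions upon lysis (virion production
#' `p = delta * N`), and free virus `V` is cleared at rate `c`:
#' \deqn{T' = \lambda - \beta T V - d T,\quad
#'       I' = \beta T V - \delta I,\quad
#'       V' = \delta N I - c V.}
#' The observable is the decadic log viral load `log10 V(t)`, the standard
#' clinical readout, so calibration data for this model live on the log10
#' scale and the plain weighted sum-of-squares objective applies.
#'
#' Initial conditions are treated as fixed and known — the regime in which
#' all six parameters `(beta, d, delta, c, N, lambda)` are identifiable —
#' and are supplied explicitly rather than hard-coded.
#'
#' @param init named numeric vector `c(T = , I = , V = )` of initial
#'   concentrations (cells, cells, virions per unit volume).
#' @param rtol,atol integration tolerances.
#' @return a [modelSpec()] for states `(T, I, V)`.
#' @seealso [viralReferenceParams()] for the reference parameter vector.
#' @export
viralModel <- function(init = c(T = 300, I = 0, V = 100),
                       rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(c("T", "I", "V") %in% base::names(init)), all(init >= 0))
  modelSpec(
    name = "viral",
    rhs = function(t, state, theta, condition) {
      T <- state[[1]]; I <- state[[2]]; V <- state[[3]]
      c(
        theta[["lambda"]] - theta[["beta"]] * T * V - theta[["d"]] * T,
        theta[["beta"]] * T * V - theta[["delta"]] * I,
        theta[["delta"]] * theta[["N"]] * I - theta[["c"]] * V
      )
    },
    initial_state = function(theta, condition) init[c("T", "I", "V")],
    observable = function(states, theta) log10(states[, 3]),
    rtol = rtol, atol = atol
  )
}

#' Reference parameters for the viral dynamics model
#'
#' The identifiability-study reference point
#' `(beta, d, delta, c, N, lambda) = (2e-5, 0.15, 0.55, 5.5, 900, 80)`
#' (rates per day, burst size in virions per cell, production in cells per
#' day), with broad positive box bounds around it. At this point the basic
#' reproduction number `R0 = beta * N * (lambda/d) / c ~ 1.75 > 1`, so
#' infection grows from a small inoculum.
#'
#' @return a [paramVector()] of the six viral parameters.
#' @export
viralReferenceParams <- function() {
  paramVector(
    c(beta = 2e-5, d = 0.15, delta = 0.55, c = 5.5, N = 900, lambda = 80),
    lower = c(1e-7, 0.01, 0.05, 0.5, 50, 1),
    upper = c(1e-3, 1.5, 5.5, 55, 9000, 800)
  )
}

#' Synthetic phenotype-switching tumour growth model
#'
#' A two-phenotype model of non-small cell lung cancer growth under
#' treatment, tracking drug-sensitive cells `A` and drug-tolerant cells `B`
#' as ODEs. Both phenotypes grow logistically toward a shared carrying
#' capacity `K`; the tolerant phenotype additionally requires cooperation
#' (an Allee effect): its growth rate carries the factor
#' `f(B) = B^n_allee / (B^n_allee + a_allee^n_allee) <= 1`, small when tolerant cells
#' are rare. Sensitive cells die at rate `d_A` off treatment; from
#' `treatment_start` (day 3) onward in the `"treated"` condition the drug
#' raises their death rate to `d_A_max`. Tolerant cells die at the constant
#' rate `d_B`, tied to `d_A` in the fitted vector
#' `(r_A, r_B, d_A = d_B, d_A_max)`:
#' \deqn{A' = [r_A (1 - N/K) - d_A(t)] A,\quad
#'       B' = [r_B (1 - N/K) f(B) - d_B] B,\quad N = A + B.}
#' The observable is the total population `N(t)`; cell-count data are
#' compared on the log10 scale, so the `"log10_sum_of_squares"` objective
#' is the intended pairing.
#'
#' This is a deliberately synthetic reduction: the structural ingredients
#' (two phenotypes, logistic growth, Allee cooperation of the tolerant
#' clone, a death-rate switch at day 3, observable `A + B`) follow the
#' published phenotype-switching model class, but the Allee function, its
#' constants, carrying capacity and initial split are this package's own
#' choices, documented in [nsclcSyntheticParams()] and the methods
#' vignette.
#'
#' @param init named numeric vector `c(A = , B = )` of initial cell counts.
#' @param K carrying capacity (cells).
#' @param a_allee Allee half-saturation (cells): tolerant-cell cooperation
#'   is half-effective at `B = a_allee`.
#' @param n_allee Hill exponent of the Allee factor.
#' @param treatment_start treatment onset time in the treated condition
#'   (days).
#' @param rtol,atol integration tolerances.
#' @return a [modelSpec()] for states `(A, B)` with conditions `"control"`
#'   and `"treated"`; the treated integration restarts at
#'   `treatment_start` where the death rate is discontinuous.
#' @export
nsclcModel <- function(init = c(A = 800, B = 200), K = 4800,
                       a_allee = 150, n_allee = 2, treatment_start = 3,
                       rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(init >= 0), K > 0, a_allee > 0, n_allee > 0)
  modelSpec(
    name = "nsclc",
    rhs = function(t, state, theta, condition) {
      A <- state[[1]]; B <- state[[2]]
      Ntot <- A + B
      dA <- if (identical(condition, "treated") && t >= treatment_start) {
        theta[["d_A_max"]]
      } else {
        theta[["d_A"]]
      }
      f <- B^n_allee / (B^n_allee + a_allee^n_allee)
      logistic <- 1 - Ntot / K
      c(
        (theta[["r_A"]] * logistic - dA) * A,
        (theta[["r_B"]] * logistic * f - theta[["d_A"]]) * B # d_B tied to d_A
      )
    },
    initial_state = function(theta, condition) init[c("A", "B")],
    observable = function(states, theta) states[, 1] + states[, 2],
    breaks = function(condition) {
      if (identical(condition, "treated")) treatment_start else numeric(0)
    },
    rtol = rtol, atol = atol
  )
}

#' Synthetic reference parameters for the phenotype-switching model
#'
#' Ground-truth parameter values used by the synthetic tumour-growth
#' experiments: growth rates `r_A = 0.48`, `r_B = 0.35` per day, shared
#' baseline death rate `d_A = d_B = 0.10` per day, and on-treatment
#' sensitive-cell death rate `d_A_max = 0.60` per day. Chosen so the
#' control culture grows toward carrying capacity over a week while the
#' treated culture declines immediately after treatment onset at day 3 —
#' the qualitative regime the design analysis probes.
#'
#' @return a [paramVector()] of `(r_A, r_B, d_A, d_A_max)`.
#' @export
nsclcSyntheticParams <- function() {
  paramVector(
    c(r_A = 0.48, r_B = 0.35, d_A = 0.10, d_A_max = 0.60),
    lower = c(0.01, 0.01, 0.001, 0.01),
    upper = c(5, 5, 2, 5)
  )
}

#' Closed-form linear test model
#'
#' Observables affine in the parameters, `y = X theta`, for which the MLE,
#' its data-space Jacobian and the whole continuation are available in
#' closed form: with unit noise scales the MLE is the least-squares
#' solution and `DPsi = (X' X)^{-1} X'` independent of the data, so the
#' first-order predictor is exact. Used as the analytic oracle throughout
#' the test suite.
#'
#' @param X design matrix with full column rank (`d x p`).
#' @param sigma noise scales, recycled to `d` rows.
#' @return a [modelSpec()] whose "times" are the row indices `1..d`, with
#'   extra closed-form fields `$X`, `$mle(phi)` and `$dpsi_exact()`
#'   (weighted normal equations).
#' @export
linearModel <- function(X, sigma = 1) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  sigma <- rep_len(as.numeric(sigma), nrow(X))
  W <- diag(1 / sigma^2, nrow(X))
  m <- modelSpec(
    name = "linear",
    analytic = function(times, theta, condition) {
      idx <- match(times, seq_len(nrow(X)))
      if (anyNA(idx)) stop("linear model times must be row indices 1..", nrow(X))
      as.numeric(X[idx, , drop = FALSE] %*% theta)
    }
  )
  m$X <- X
  m$mle <- function(phi) {
    as.numeric(solve(crossprod(X, W %*% X), crossprod(X, W %*% phi)))
  }
  m$dpsi_exact <- function() {
    solve(crossprod(X, W %*% X), t(X) %*% W)
  }
  m
}

#' Model registry
#'
#' Look up a built-in model constructor by name; custom models are built
#' directly with [modelSpec()].
#'
#' @param name one of `"viral"`, `"nsclc"`, `"linear"`.
#' @param ... passed to the constructor.
#' @return a [modelSpec()].
#' @export
getModel <- function(name, ...) {
  switch(name,
    viral = viralModel(...),
    nsclc = nsclcModel(...),
    linear = linearModel(...),
    stop("unknown model '", name, "'; available: viral, nsclc, linear")
  )
}
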