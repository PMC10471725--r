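#' Data-space Jacobian of the MLE
#'
#' At a maximum likelihood estimate `theta*` for data `phi`, the stationarity
#' condition `D_theta G(theta*, phi) = 0` defines `theta*` implicitly as a
#' function `Psi(phi)` of the data. By the implicit function theorem its
#' Jacobian is `DPsi = -H^{-1} M`, with `H` the observed information
#' (parameter Hessian of `G`) and `M` the mixed parameter-data partial. The
#' Jacobian is computed by solving the linear system `H DPsi = -M`; the
#' inverse is never formed.
#'
#' A near-singular `H` signals practical unidentifiability: a direction in
#' parameter space the data barely constrain. When the condition number of
#' `H` exceeds `cond_threshold` the computation stops with an error naming
#' the parameters dominating the near-null eigendirection.
#'
#' @param H `p x p` symmetric Hessian (observed information).
#' @param M `p x d` mixed partial from [mixedPartial()].
#' @param cond_threshold condition-number limit (default 1e10).
#' @return `p x d` numeric matrix `DPsi`; rows = parameters, columns = data
#'   rows. Column `k` is the derivative of the MLE with respect to the
#'   `k`-th data value (on the objective's residual scale).
#' @export
computeDPsi <- function(H, M, cond_threshold = 1e10) {
  stopifnot(is.matrix(H), is.matrix(M), nrow(H) == ncol(H), nrow(M) == nrow(H))
  Hs <- (H + t(H)) / 2
  ## Jacobi equilibration: parameters of a dynamical model can differ by many
  ## orders of magnitude, which inflates cond(H) through units alone. The
  ## identifiability test is done on the scale-free equilibrated matrix.
  dscale <- sqrt(pmax(abs(diag(Hs)), .Machine$double.xmin))
  He <- Hs / tcrossprod(dscale)
  ev <- eigen(He, symmetric = TRUE)
  mags <- abs(ev$values)
  if (min(mags) == 0 || max(mags) / min(mags) > cond_threshold) {
    v <- ev$vectors[, which.min(mags)]
    nm <- rownames(H)
    if (is.null(nm)) nm <- paste0("theta", seq_len(nrow(H)))
    top <- order(abs(v), decreasing = TRUE)[seq_len(min(3, length(v)))]
    stop(
      "Hessian is numerically singular (equilibrated cond = ",
      format(max(mags) / min(mags), digits = 3),
      "): practical unidentifiability along direction dominated by ",
      paste0(nm[top], " (", format(v[top], digits = 2), ")", collapse = ", ")
    )
  }
  ## solve the equilibrated system, never forming an inverse
  DPsi <- solve(He, -(M / dscale)) / dscale
  dimnames(DPsi) <- list(rownames(H), colnames(M))
  DPsi
}

#' Continuation state at a fitted MLE
#'
#' Assembles everything the predictor needs at a known MLE: the observed
#' information `H`, the mixed partial `M`, and the data-space Jacobian
#' `DPsi`, together with the evaluation counts spent building them. A full
#' build costs `2p` model simulations (sensitivities) plus at most
#' `2p(p+1)` objective evaluations (Hessian), i.e. at most `2p(p+2)` model
#' simulations per condition in total.
#'
#' @param model a [modelSpec()].
#' @param theta a [paramVector()] holding the MLE.
#' @param data the [calibrationData()] the MLE was fitted to.
#' @param spec an [objectiveSpec()].
#' @param fd an [fdConfig()].
#' @param hessian optional precomputed `p x p` Hessian to recycle (e.g. from
#'   an optimiser); default is a dedicated finite-difference Hessian for
#'   determinism.
#' @param cond_threshold passed to [computeDPsi()].
#' @return a `continuation_state` object: list with `theta_star`, `data`,
#'   `spec`, `hessian`, `mixed_partial`, `dpsi`, `eval_counts`.
#' @export
continuationState <- function(model, theta, data, spec = objectiveSpec(),
                              fd = fdConfig(), hessian = NULL,
                              cond_threshold = 1e10) {
  validateCalibrationData(data)
  before <- counterReport(model)
  S <- sensitivityMatrix(model, theta, data, spec, fd)
  M <- mixedPartial(S, data$sigma)
  H <- if (is.null(hessian)) hessianFD(model, theta, data, spec, fd) else hessian
  ## Active-set handling: a parameter sitting exactly on a bound is a
  ## constrained optimum coordinate (common under practical
  ## unidentifiability, where the likelihood is monotone along a soft
  ## direction until the admissible region ends). Such parameters are held
  ## fixed: the implicit-function construction applies on the free
  ## subspace, and the pinned rows of DPsi are zero. With no active bound
  ## this reduces exactly to the unconstrained equations.
  active <- atBound(theta)
  free <- !active
  if (!any(free)) stop("all parameters are pinned at bounds; no continuation possible")
  DPsi <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  DPsi[free, ] <- computeDPsi(H[free, free, drop = FALSE],
                              M[free, , drop = FALSE], cond_threshold)
  after <- counterReport(model)
  structure(
    list(
      theta_star = theta, data = data, spec = spec, fd = fd,
      hessian = H, mixed_partial = M, dpsi = DPsi, active = active,
      eval_counts = list(
        n_sim = after$n_sim - before$n_sim,
        n_obj = after$n_obj - before$n_obj
      )
    ),
    class = "continuation_state"
  )
}

## Parameters lying exactly on a (finite) box bound, up to rounding.
atBound <- function(theta) {
  tol <- 4 * .Machine$double.eps * pmax(abs(theta$values), 1)
  (is.finite(theta$lower) & theta$values - theta$lower <= tol) |
    (is.finite(theta$upper) & theta$upper - theta$values <= tol)
}

#' @export
print.continuation_state <- function(x, ...) {
  cat("<continuation_state> p =", nrow(x$dpsi), "parameters, d =",
      ncol(x$dpsi), "data rows\n")
  cat("  theta* :", paste0(base::names(x$theta_star$values), "=",
                           format(x$theta_star$values, digits = 4),
                           collapse = ", "), "\n")
  cat("  ||DPsi||_1 =", format(dpsiNorm(x$dpsi), digits = 4),
      "; build cost:", x$eval_counts$n_sim, "simulations,",
      x$eval_counts$n_obj, "objective evaluations\n")
  invisible(x)
}

#' Predictor: first-order MLE update for perturbed data
#'
#' First-order Taylor (implicit-function-theorem) prediction
#' `Psi(phi + dphi) = theta* + DPsi dphi` of the MLE for perturbed data.
#' Requires no model simulation. `delta_phi` lives on the objective's
#' residual scale (raw data units for a plain weighted objective, decadic
#' log units for a log10 objective). Components pushed outside the
#' admissible box are clipped back with a warning.
#'
#' @param state a [continuationState()].
#' @param delta_phi numeric vector of data perturbations, length `d`.
#' @return a [paramVector()] with the predicted MLE values.
#' @export
predictMLE <- function(state, delta_phi) {
  stopifnot(inherits(state, "continuation_state"))
  delta_phi <- as.numeric(delta_phi)
  if (length(delta_phi) != ncol(state$dpsi)) {
    stop("delta_phi must have one entry per data row (d = ", ncol(state$dpsi), ")")
  }
  theta <- state$theta_star
  raw <- theta$values + as.numeric(state$dpsi %*% delta_phi)
  cl <- clipToBounds(theta, raw)
  if (cl$any_clipped) {
    warning("predicted MLE left the admissible region; clipped to bounds")
  }
  setParamValues(theta, cl$values)
}

## delta on the residual scale between two calibration tables sharing a design
residualDelta <- function(data_new, data_old, spec) {
  residualScale(data_new$value, spec) - residualScale(data_old$value, spec)
}

#' Corrector: local refinement of a predicted MLE
#'
#' Bounded Levenberg-Marquardt refinement (via `minpack.lm::nls.lm`) of the
#' weighted residual vector, started from `start`. Intended as the corrector
#' of a predictor-corrector continuation: cheap when started at a good
#' prediction. The returned objective never exceeds the objective at the
#' start (the start is kept if the optimiser fails to improve on it), and
#' convergence is assessed by the scale-relative gradient sup-norm.
#'
#' @param model a [modelSpec()].
#' @param data the (new) [calibrationData()].
#' @param start a [paramVector()] starting point inside its bounds.
#' @param spec an [objectiveSpec()].
#' @param control list passed to [minpack.lm::nls.lm.control()]; defaults to
#'   tight tolerances (`ftol = ptol = 1e-12`, up to 400 iterations).
#' @param gtol stationarity tolerance on the scale-relative gradient
#'   sup-norm (free components only; a parameter resting on a bound is a
#'   constrained-optimum coordinate, not a convergence failure).
#' @param polish run a log-scale quasi-Newton polish (L-BFGS-B) when plain
#'   LM stalls before reaching `gtol`; recommended for strongly
#'   anisotropic problems.
#' @param fd an [fdConfig()] used for the gradient check.
#' @return list with elements `theta` ([paramVector()]), `objective`,
#'   `n_obj` (objective evaluations consumed), `converged` (logical), and
#'   `grad_norm` (scale-relative gradient sup-norm at the returned point).
#' @export
correctMLE <- function(model, data, start, spec = objectiveSpec(),
                       control = list(), gtol = 1e-5, fd = fdConfig(),
                       polish = TRUE) {
  validateParamVector(start)
  validateCalibrationData(data)
  before <- counterReport(model)$n_obj
  g_start <- objectiveValue(model, start, data, spec)

  resid_fn <- function(par) {
    bumpObj(model, 1L)
    r <- tryCatch({
      th <- setParamValues(start, par)
      y <- fittedValues(model, th, data)
      suppressWarnings(
        (residualScale(y, spec) - residualScale(data$value, spec)) / data$sigma
      )
    }, error = function(e) NULL)
    # infeasible trial point (integration failure, nonpositive observable
    # under a log objective): steer the optimiser away with a huge residual
    if (is.null(r) || !all(is.finite(r))) r <- rep(1e8, nrow(data))
    r
  }
  ## epsfcn declares the relative precision of the residuals to the FD
  ## Jacobian: ODE-integrated residuals are good to ~1e-9 at the default
  ## tolerances, not machine precision, so the internal FD step must be
  ## ~sqrt(1e-9), else the Jacobian is noise-dominated near the optimum.
  ctrl <- utils::modifyList(
    list(ftol = 1e-12, ptol = 1e-12, gtol = 0, maxiter = 400, epsfcn = 1e-9),
    control
  )
  runLM <- function(theta, g_fit) {
    ## restart LM until it stops improving: along nearly flat likelihood
    ## valleys a single run can halt on a small trust region before the
    ## free directions are fully converged
    for (round in 1:3) {
      fit <- try(minpack.lm::nls.lm(
        par = theta$values, lower = theta$lower, upper = theta$upper,
        fn = resid_fn, control = do.call(minpack.lm::nls.lm.control, ctrl)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) break
      cand <- clipToBounds(start, as.numeric(fit$par))$values
      th_new <- setParamValues(start, cand)
      g_new <- objectiveValue(model, th_new, data, spec)
      if (g_new <= g_fit) { # never move to a point worse than the incumbent
        improved <- g_fit - g_new > max(1e-12, 1e-10 * g_fit)
        theta <- th_new
        g_fit <- g_new
        if (!improved) break
      } else break
    }
    list(theta = theta, g = g_fit)
  }

  freeGrad <- function(theta) {
    g_all <- scaledGradient(model, theta, data, spec, fd)
    max(abs(g_all[!atBound(theta)]), 0)
  }

  res <- runLM(start, g_start)
  theta <- res$theta
  g_fit <- res$g
  gn <- freeGrad(theta)

  if (polish && gn > gtol) {
    ## Quasi-Newton polish on the log-parameter scale: trust-region LM can
    ## crawl along strongly anisotropic likelihood valleys, while L-BFGS-B
    ## in log coordinates tracks them well. Only triggered when LM has not
    ## reached stationarity; requires strictly positive lower bounds,
    ## otherwise the raw scale with parameter scaling is used.
    uselog <- all(start$lower > 0)
    tf <- if (uselog) log else identity
    itf <- if (uselog) exp else identity
    fn <- function(q) {
      v <- pmin(pmax(itf(q), start$lower), start$upper)
      tryCatch({
        val <- objectiveValue(model, setParamValues(start, v), data, spec)
        if (is.finite(val)) val else 1e10
      }, error = function(e) 1e10)
    }
    o <- try(stats::optim(
      tf(theta$values), fn, method = "L-BFGS-B",
      lower = tf(start$lower), upper = tf(start$upper),
      control = list(
        maxit = 500, factr = 10, pgtol = 0,
        ndeps = rep(1e-6, length(start$values)),
        parscale = if (uselog) rep(1, length(start$values)) else
          pmax(abs(theta$values), 1e-8)
      )
    ), silent = TRUE)
    if (!inherits(o, "try-error") && is.finite(o$value) && o$value <= g_fit) {
      th_new <- setParamValues(start, pmin(pmax(itf(o$par), start$lower),
                                           start$upper))
      res <- runLM(th_new, o$value) # harvest final quadratic convergence
      if (res$g <= g_fit) {
        theta <- res$theta
        g_fit <- res$g
      }
    }
    gn <- freeGrad(theta)
  }
  list(
    theta = theta,
    objective = g_fit,
    n_obj = counterReport(model)$n_obj - before,
    converged = gn <= gtol,
    grad_norm = gn
  )
}

#' Continuation along a sequence of data sets
#'
#' Steps the MLE along a sequence of calibration tables
#' `phi^1, ..., phi^J` that share times, noise scales and conditions and
#' differ only in their observed values. Step `j` predicts
#' `Psi(phi^j) = theta*(phi^{j-1}) + DPsi(phi^{j-1}) (phi^j - phi^{j-1})`
#' from the state at the previous data set; in `"predict_and_correct"` mode
#' each prediction is refined by [correctMLE()] before the next step (so the
#' Jacobian is rebuilt at a genuine stationary point), while
#' `"predict_only"` carries the raw predictions forward.
#'
#' @param model a [modelSpec()].
#' @param theta0 a [paramVector()]: the MLE for `data0`.
#' @param data0 the initial [calibrationData()].
#' @param datasets list of calibration tables (the perturbed sequence).
#' @param spec an [objectiveSpec()].
#' @param fd an [fdConfig()].
#' @param mode `"predict_and_correct"` (default) or `"predict_only"`.
#' @param ... passed to [correctMLE()].
#' @return list of per-step records: `data`, `predicted` (param vector),
#'   `objective_predicted`, and in corrected mode `theta` (refit MLE),
#'   `objective`, `n_obj_correct`; plus cumulative counter snapshots
#'   `n_sim`, `n_obj`.
#' @export
continuationPath <- function(model, theta0, data0, datasets,
                             spec = objectiveSpec(), fd = fdConfig(),
                             mode = c("predict_and_correct", "predict_only"),
                             ...) {
  mode <- match.arg(mode)
  for (dd in datasets) {
    if (!identical(dd$time, data0$time) || !identical(dd$condition, data0$condition) ||
        !identical(dd$sigma, data0$sigma)) {
      stop("all data sets in a continuation path must share times, sigma and conditions")
    }
  }
  steps <- vector("list", length(datasets))
  theta_prev <- theta0
  data_prev <- data0
  for (j in seq_along(datasets)) {
    data_j <- datasets[[j]]
    state <- continuationState(model, theta_prev, data_prev, spec, fd)
    pred <- predictMLE(state, residualDelta(data_j, data_prev, spec))
    g_pred <- objectiveValue(model, pred, data_j, spec)
    rec <- list(
      data = data_j, predicted = pred, objective_predicted = g_pred,
      state = state
    )
    if (mode == "predict_and_correct") {
      corr <- correctMLE(model, data_j, pred, spec, fd = fd, ...)
      rec$theta <- corr$theta
      rec$objective <- corr$objective
      rec$n_obj_correct <- corr$n_obj
      theta_prev <- corr$theta
    } else {
      theta_prev <- pred
    }
    cnt <- counterReport(model)
    rec$n_sim <- cnt$n_sim
    rec$n_obj <- cnt$n_obj
    steps[[j]] <- rec
    data_prev <- data_j
  }
  steps
}

#' Newton refinement of a stationary point
#'
#' Drives a fitted optimum to derivative-grade stationarity. Optimiser
#' stopping rules localise the optimum well in strongly curved directions
#' but can leave a residual displacement along soft (weakly identified)
#' directions; because the data-space Jacobian is exact only at a
#' stationary point, that displacement biases its soft-direction entries.
#' This routine polishes the point with full Newton steps on the free
#' subspace, using a Richardson-extrapolated central gradient
#' (`(4 g(h) - g(2h))/3`) and the Richardson Hessian, until the
#' scale-relative gradient sup-norm drops below `gtol`.
#'
#' Intended as a post-processing step before [continuationState()] when
#' Jacobian accuracy matters, and for the refit endpoints of
#' derivative-oracle checks. Parameters resting on bounds stay fixed.
#'
#' @param model a [modelSpec()].
#' @param data a [calibrationData()] table.
#' @param theta a [paramVector()] already close to a (possibly
#'   constrained) optimum, e.g. from [correctMLE()].
#' @param spec an [objectiveSpec()].
#' @param fd an [fdConfig()]; the gradient uses a fifth of its relative
#'   step, the Hessian its Richardson refinement.
#' @param max_iter maximum Newton iterations (default 4).
#' @param gtol target scale-relative gradient sup-norm (default 1e-8).
#' @param max_rel_step trust bound on the relative parameter move per
#'   iteration.
#' @return the refined [paramVector()].
#' @export
refineStationary <- function(model, data, theta, spec = objectiveSpec(),
                             fd = fdConfig(), max_iter = 4L, gtol = 1e-8,
                             max_rel_step = 0.2) {
  fd_rich <- fd
  fd_rich$richardson <- TRUE
  relstep <- fd$relative_step / 5
  scaleOf <- function(v) pmax(abs(v), fd$absolute_step_floor)

  richGrad <- function(th) {
    p <- length(th$values)
    gh <- numeric(p)
    g2h <- numeric(p)
    for (n in seq_len(p)) {
      st <- max(relstep * abs(th$values[n]), fd$absolute_step_floor)
      gh[n] <- (objectiveValue(model, perturbParam(th, n, st), data, spec) -
                  objectiveValue(model, perturbParam(th, n, -st), data, spec)) /
        (2 * st)
      g2h[n] <- (objectiveValue(model, perturbParam(th, n, 2 * st), data, spec) -
                   objectiveValue(model, perturbParam(th, n, -2 * st), data, spec)) /
        (4 * st)
    }
    (4 * gh - g2h) / 3
  }

  H <- NULL
  for (it in seq_len(max_iter)) {
    free <- !atBound(theta)
    if (!any(free)) break
    g <- richGrad(theta)
    if (max(abs((g * scaleOf(theta$values))[free])) < gtol) break
    if (is.null(H) || it <= 2) { # curvature varies slowly near the optimum
      H <- hessianFD(model, theta, data, spec, fd_rich)
    }
    Hf <- H[free, free, drop = FALSE]
    sc <- sqrt(pmax(abs(diag(Hf)), .Machine$double.xmin))
    step <- -solve(Hf / tcrossprod(sc), g[free] / sc) / sc
    relmove <- max(abs(step) / scaleOf(theta$values[free]))
    if (relmove > max_rel_step) step <- step * (max_rel_step / relmove)
    cand <- theta$values
    cand[free] <- cand[free] + step
    cand <- pmin(pmax(cand, theta$lower), theta$upper)
    th_new <- setParamValues(theta, cand)
    ok <- tryCatch(
      is.finite(objectiveValue(model, th_new, data, spec)),
      error = function(e) FALSE
    )
    if (!ok) break
    theta <- th_new
  }
  theta
}
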