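#' Synthetic baseline for the phenotype-switching growth experiments
#'
#' Simulates the tumour-growth model at `theta` on the standard design —
#' control cultures measured at days 0, 2, 4, 6 and treated cultures at
#' days 4, 6 (treatment from day 3) — and applies multiplicative log10
#' noise of standard deviation `sigma_log10`. Because treatment kills
#' cells, the treated day-4 and day-6 counts must not exceed their control
#' counterparts; noise draws violating this ordering are redrawn.
#'
#' @param model an [nsclcModel()].
#' @param theta true [paramVector()].
#' @param sigma_log10 log10-scale noise SD (default 0.05, ~12% count
#'   error).
#' @param seed integer seed.
#' @return a [calibrationData()] of cell counts (6 rows); the ordering
#'   constraint row pairs are attached as attribute `"constraints"`.
#' @export
generateSwitchingBaseline <- function(model, theta, sigma_log10 = 0.05,
                                      seed = 1L) {
  times <- c(0, 2, 4, 6, 4, 6)
  conds <- c(rep("control", 4), rep("treated", 2))
  y <- simulateObservables(model, theta, times, conds)
  cons <- switchingConstraints()
  vals <- withSeed(seed, {
    repeat {
      cand <- 10^(log10(y) + stats::rnorm(length(y), 0, sigma_log10))
      if (all(cand[cons[, 1]] <= cand[cons[, 2]])) break
    }
    cand
  })
  out <- calibrationData(times, vals, sigma = 1, condition = conds)
  attr(out, "constraints") <- cons
  out
}

#' @rdname generateSwitchingBaseline
#' @details `switchingConstraints()` returns the row-index pairs
#'   `(treated, control)` measured on the same day, as a two-column matrix
#'   `(lo, hi)` meaning `value[lo] <= value[hi]`: rows 5 <= 3 and 6 <= 4.
#' @export
switchingConstraints <- function() {
  rbind(c(5L, 3L), c(6L, 4L))
}

#' Fit an MLE by bounded least squares
#'
#' Thin wrapper over [correctMLE()] for the initial fit: starts from
#' `start` and returns the fitted [paramVector()] with the objective and
#' evaluation count.
#'
#' @inheritParams correctMLE
#' @return as [correctMLE()].
#' @export
fitMLE <- function(model, data, start, spec = objectiveSpec(), ...) {
  correctMLE(model, data, start, spec, ...)
}

#' Shared setup for the viral continuation experiments
#'
#' Builds the viral model at high integration precision (rtol 1e-12), draws
#' the seeded noisy baseline (log10 noise variance 0.15 on the sparse
#' 8-point schedule), fits the initial MLE from the reference parameters,
#' and assembles the continuation state at that MLE. The Hessian of this
#' state is Richardson-refined: the viral information matrix is badly
#' conditioned, and the plain-stencil truncation error would otherwise be
#' amplified along its soft directions (see [fdConfig()]).
#'
#' @param seed integer seed for the baseline noise.
#' @param richardson use the Richardson-refined Hessian for the state.
#' @return list with `model`, `spec`, `theta_true`, `baseline`, `fit`
#'   (see [correctMLE()]) and `state` (a [continuationState()]).
#' @export
viralStudySetup <- function(seed = 1L, richardson = TRUE) {
  model <- viralModel(rtol = 1e-12, atol = 1e-14)
  spec <- objectiveSpec("weighted_sum_of_squares")
  theta_true <- viralReferenceParams()
  baseline <- generateViralBaseline(model, theta_true, sigma2 = 0.15,
                                    seed = seed)
  fit <- correctMLE(model, baseline, theta_true, spec,
                    control = list(epsfcn = 1e-12))
  # the Jacobian is exact only at a stationary point: polish the optimum
  # to derivative-grade stationarity before differentiating
  fit$theta <- refineStationary(model, baseline, fit$theta, spec)
  # Hessian base step 3e-4: with the Richardson refinement the h^2
  # truncation is already cancelled, and the larger step keeps the
  # objective-evaluation noise (measured ~1e-10 at these integrator
  # tolerances) from being amplified through the badly conditioned
  # information matrix into the Jacobian's soft-direction entries
  state <- continuationState(model, fit$theta, baseline, spec,
                             fd = fdConfig(relative_step = 3e-4,
                                           richardson = richardson))
  list(model = model, spec = spec, theta_true = theta_true,
       baseline = baseline, fit = fit, state = state)
}

#' First-order consistency of the predictor
#'
#' Empirical check of the quadratic remainder of the Taylor predictor: for
#' a fixed random direction `dphi` and scales `s`, the distance between
#' the predicted MLE at `phi + s dphi` and the refit MLE must shrink like
#' `s^2`, i.e. the log-log slope of error against scale should approach 2
#' (anything well above 1 rules out a first-order defect). Distances are
#' measured relative to the baseline MLE so parameters of different units
#' contribute comparably.
#'
#' @param setup result of [viralStudySetup()].
#' @param scales perturbation scales (default `1, 1/2, 1/4`).
#' @param dphi_sd per-point SD of the random direction (log10 units).
#'   The default, about an eighth of the measurement noise SD, keeps the
#'   largest scale inside the asymptotic regime of the Taylor remainder
#'   while the smallest-scale error stays orders of magnitude above the
#'   refit reproducibility floor.
#' @param seed seed for the direction draw.
#' @return list with `slope`, `errors` (one per scale), and `scales`.
#' @export
viralFirstOrderSlope <- function(setup, scales = c(1, 0.5, 0.25),
                                 dphi_sd = 0.05, seed = 1L) {
  dphi <- withSeed(seed + 7777L, stats::rnorm(nrow(setup$baseline), 0, dphi_sd))
  ref <- pmax(abs(setup$fit$theta$values), 1e-12)
  errors <- vapply(scales, function(s) {
    data_s <- setDataValues(setup$baseline, setup$baseline$value + s * dphi)
    pred <- predictMLE(setup$state, s * dphi)
    refit <- correctMLE(setup$model, data_s, pred, setup$spec,
                        control = list(epsfcn = 1e-12), polish = FALSE)
    th_ref <- refineStationary(setup$model, data_s, refit$theta, setup$spec)
    sqrt(sum(((pred$values - th_ref$values) / ref)^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errors) ~ log(scales)))[[2]]
  list(slope = slope, errors = errors, scales = scales)
}

#' Refit-derivative oracle for the data-space Jacobian
#'
#' Brute-force verification of the Jacobian: column `k` of `DPsi` is
#' compared against the central difference of full refits at
#' `phi +/- eps e_k`. Components with oracle magnitude above
#' `threshold * ||column||` are compared relatively; parameters pinned at
#' bounds are held fixed by both routes.
#'
#' @param setup result of [viralStudySetup()].
#' @param eps data perturbation for the refit differences.
#' @param threshold relative magnitude floor for the comparison.
#' @param columns data-row indices to check (default all).
#' @return list with `max_rel_err`, `per_column` (worst relative error per
#'   checked column), and `n_compared`.
#' @export
viralRefitOracle <- function(setup, eps = 0.01, threshold = 1e-3,
                             columns = NULL) {
  d0 <- setup$baseline
  if (is.null(columns)) columns <- seq_len(nrow(d0))
  per_column <- numeric(0)
  n_comp <- 0L
  for (k in columns) {
    up <- d0; up$value[k] <- up$value[k] + eps
    dn <- d0; dn$value[k] <- dn$value[k] - eps
    f_up <- correctMLE(setup$model, up, setup$fit$theta, setup$spec,
                       control = list(epsfcn = 1e-12), polish = FALSE)
    f_dn <- correctMLE(setup$model, dn, setup$fit$theta, setup$spec,
                       control = list(epsfcn = 1e-12), polish = FALSE)
    th_up <- refineStationary(setup$model, up, f_up$theta, setup$spec)
    th_dn <- refineStationary(setup$model, dn, f_dn$theta, setup$spec)
    oracle <- (th_up$values - th_dn$values) / (2 * eps)
    sel <- abs(oracle) > threshold * sqrt(sum(oracle^2))
    rel <- abs(setup$state$dpsi[, k] - oracle)[sel] / abs(oracle)[sel]
    per_column[as.character(k)] <- max(rel)
    n_comp <- n_comp + sum(sel)
  }
  list(max_rel_err = max(per_column), per_column = per_column,
       n_compared = n_comp)
}

#' Viral perturbation study: predictor vs refit
#'
#' End-to-end replication of the viral-dynamics continuation experiment at
#' desk scale. Starting from the fitted baseline MLE, each half-normal
#' perturbation step `h_step in {0.1, -0.1, 0.2, -0.2}` is handled twice:
#' by the first-order continuation prediction (no further optimisation)
#' and by a full refit started from the baseline MLE (the naive route).
#' Reported per set: both objective values, the BIC gap between the
#' predicted-parameter fit and the refit, and the objective-evaluation
#' count of the naive refit. The continuation state used here is the
#' plain-stencil build, whose cost is bounded by `2p(p+2)` model
#' simulations; that count is reported as `predictor_cost`.
#'
#' @param setup result of [viralStudySetup()].
#' @param h_steps signed perturbation steps.
#' @param seed seed for the perturbation draws.
#' @return list with `predictor_cost` (list `n_sim`, `n_obj`), and `sets`:
#'   one record per perturbation with `h_step`, `data`, `predicted`,
#'   `objective_predicted`, `refit`, `objective_refit`, `n_obj_refit`,
#'   `delta_bic`.
#' @export
runViralPerturbationStudy <- function(setup,
                                      h_steps = c(0.1, -0.1, 0.2, -0.2),
                                      seed = 1L) {
  model <- setup$model
  spec <- setup$spec
  baseline <- setup$baseline
  theta0 <- setup$fit$theta
  # dedicated plain-stencil state: its build cost is the predictor cost
  counterReset(model)
  state0 <- continuationState(model, theta0, baseline, spec, fdConfig())
  predictor_cost <- state0$eval_counts
  p <- length(theta0$values)
  d <- nrow(baseline)

  sets <- vector("list", length(h_steps))
  for (i in seq_along(h_steps)) {
    pert <- perturbAbsolute(baseline, h_steps[i], seed = seed + 100L * i)
    pred <- predictMLE(state0, residualDelta(pert, baseline, spec))
    g_pred <- objectiveValue(model, pred, pert, spec)
    refit <- correctMLE(model, pert, theta0, spec,
                        control = list(epsfcn = 1e-12)) # naive start
    sets[[i]] <- list(
      h_step = h_steps[i], data = pert,
      predicted = pred, objective_predicted = g_pred,
      refit = refit$theta, objective_refit = refit$objective,
      n_obj_refit = refit$n_obj,
      delta_bic = bic(g_pred, p, d) - bic(refit$objective, p, d)
    )
  }
  list(predictor_cost = predictor_cost, sets = sets)
}

#' Iterated continuation for the phenotype-switching model
#'
#' Replication of the norm-scaled perturbation continuation at desk scale:
#' generates a synthetic growth baseline, fits the initial MLE, draws one
#' Gaussian direction in log10 space and rescales it to the growing
#' distances `(0.05 + j * h_step) * ||log10 phi^0||` for `j = 1..n_steps`
#' (ordering constraints enforced), and steps the predictor-corrector
#' continuation along the resulting sequence. Because the sequence shares
#' one noise direction, consecutive data sets differ by a small coherent
#' step, the regime in which an iterated first-order continuation is
#' meaningful. At each step `j` three objective values on the new data are
#' recorded: the naive value at the previous MLE, the value at the
#' first-order prediction, and the refit minimum — the triple whose
#' ordering `refit <= predicted < naive` is the generic outcome of the
#' method.
#'
#' @param seed integer seed.
#' @param n_steps number of perturbation steps (default 10).
#' @param h_step norm increment per step (see [perturbNormScaled()]).
#' @param theta_true true [paramVector()] (default
#'   [nsclcSyntheticParams()]).
#' @return list with `model`, `baseline`, `fit0`, and `steps`: per step
#'   `j`, `objective_naive`, `objective_predicted`, `objective_refit`,
#'   `n_obj_predict` (Jacobian build cost), `n_obj_correct`.
#' @export
runSwitchingContinuation <- function(seed = 1L, n_steps = 10L,
                                     h_step = 0.65 / 55,
                                     theta_true = nsclcSyntheticParams()) {
  model <- nsclcModel()
  spec <- objectiveSpec("log10_sum_of_squares")
  baseline <- generateSwitchingBaseline(model, theta_true, seed = seed)
  cons <- attr(baseline, "constraints")
  fit0 <- fitMLE(model, baseline, theta_true, spec)

  theta_prev <- fit0$theta
  data_prev <- baseline
  steps <- vector("list", n_steps)
  for (j in seq_len(n_steps)) {
    data_j <- perturbNormScaled(baseline, j, h_step, seed = seed,
                                constraints = cons)
    g_naive <- objectiveValue(model, theta_prev, data_j, spec)
    before <- counterReport(model)$n_obj
    state <- continuationState(model, theta_prev, data_prev, spec)
    pred <- predictMLE(state, residualDelta(data_j, data_prev, spec))
    n_obj_predict <- counterReport(model)$n_obj - before
    g_pred <- objectiveValue(model, pred, data_j, spec)
    corr <- correctMLE(model, data_j, pred, spec)
    steps[[j]] <- list(
      j = j, data = data_j,
      objective_naive = g_naive, objective_predicted = g_pred,
      objective_refit = corr$objective,
      predicted = pred, theta = corr$theta,
      n_obj_predict = n_obj_predict, n_obj_correct = corr$n_obj
    )
    theta_prev <- corr$theta
    data_prev <- data_j
  }
  list(model = model, baseline = baseline, fit0 = fit0, steps = steps)
}
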