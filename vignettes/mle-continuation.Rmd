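---
title: "Continuation of maximum likelihood estimators in calibration-data space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuation of maximum likelihood estimators in calibration-data space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlecont)
```

## The problem

Calibrating a dynamical model means solving
$$\theta^*(\phi) = \arg\min_{\theta \in \Omega} G(\theta, \phi), \qquad
G(\theta,\phi) = \sum_{i=1}^d \frac{\left(g(y_i(\theta)) - g(\phi_i)\right)^2}{\sigma_i^2},$$
where $y_i(\theta)$ are model observables at the measurement times,
$\phi$ is the calibration data, $\sigma_i$ are fixed, known noise scales,
and $g$ is the identity or $\log_{10}$ depending on the scale on which
residuals are naturally Gaussian. $G$ is the Gaussian negative
log-likelihood with its $\theta$-independent constants dropped.

Calibration data rarely stay fixed: measurements accumulate during a
study, epidemic curves are revised, assays are re-run. Every revision
moves the maximum likelihood estimate (MLE), and refitting from scratch
costs many model integrations. This package treats the MLE as an implicit
function $\Psi(\phi)$ of the data, defined by the stationarity condition
$D_\theta G(\Psi(\phi), \phi) = 0$, and computes its Jacobian by the
implicit function theorem:
$$D\Psi(\phi) = -\left[D^2_\theta G\right]^{-1} D^2_{\theta,\phi} G .$$

`DPsi` is a $p \times d$ matrix: entry $(n, k)$ is the first-order
response of fitted parameter $n$ to a change in data value $k$. It powers
two workflows:

* **Prediction.** $\Psi(\phi + \Delta\phi) \approx \theta^* + D\Psi\,
  \Delta\phi$ predicts the MLE for revised data at *zero* additional model
  integrations (`predictMLE()`), with an optional bounded least-squares
  corrector (`correctMLE()`) and an iterated path over a sequence of data
  sets (`continuationPath()`).
* **Experimental design.** The absolute column sums of `DPsi` say which
  measurement the fit is most sensitive to (`dataPointSensitivity()`,
  `mostInformativePoint()`); appending the model's own prediction at a
  candidate time and rebuilding `DPsi` ranks future measurements by how
  much they would inform a target parameter
  (`rankCandidateMeasurements()`); and $\|D\Psi\|_1$ compares the
  robustness of competing local minima with indistinguishable BIC
  (`compareMinimaRobustness()`).

## How the Jacobian is built

All derivatives come from finite differences of the objective and the
observables, so any model that can be integrated can be analysed.

* **Sensitivities.** $\partial y_i / \partial \theta_n$ by central
  differences: exactly $2p$ model integrations per experimental condition
  (`sensitivityMatrix()`). The mixed partial is then closed-form:
  $M_{n,i} = -2\,S_{n,i}/\sigma_i^2$ (`mixedPartial()`).
* **Observed information.** $H = D^2_\theta G$ from objective values
  only: three-point central second differences on the diagonal (a forward
  variant is available) and the four-point mixed stencil
  $[G(++) - G(+-) - G(-+) + G(--)]/(4 h_i h_j)$ off the diagonal, each
  unordered pair evaluated once and mirrored, then symmetrised. At most
  $2p(p+1)$ objective evaluations (`hessianFD()`).
* **The linear solve.** `computeDPsi()` solves $H\,D\Psi = -M$; the
  inverse is never formed. The system is Jacobi-equilibrated first
  (divide row/column $n$ by $\sqrt{|H_{nn}|}$): dynamical-model parameters
  span many orders of magnitude (an infection rate of $2\times 10^{-5}$
  next to a burst size of 900), and without equilibration the condition
  number measures units, not identifiability.

### Step sizes

The FD step for parameter $n$ is
$\max(\texttt{relative\_step}\cdot|\theta_n|,\ \texttt{absolute\_step\_floor})$
with defaults $10^{-4}$ and $10^{-12}$ (`fdConfig()`). The floor exists
only so a parameter sitting at zero still moves; it must stay far below
`relative_step` times the smallest parameter magnitude, otherwise small
parameters get percent-scale steps whose truncation error dominates the
derivative. The stationarity diagnostic (`scaledGradient()`) uses a
ten-times smaller step than the curvature stencils, because near an
optimum the gradient is nearly zero and the $h^2$ term from third
derivatives would otherwise dominate it. These choices require the
integrator error to sit well below the FD increments: the built-in models
default to `rtol = 1e-10`, and the high-precision variants used in the
package's own studies to `rtol = 1e-12`.

### Ill-conditioned information and Richardson refinement

When $H$ is badly conditioned — the signature of practical
unidentifiability — the inverse amplifies the $O(h^2)$ truncation error
of the stencils along the soft directions. For the viral example below,
the plain-stencil `DPsi` deviates from a brute-force refit derivative by
tens of percent in exactly those components, while the refit derivative
itself is stable under changes of its own step. `fdConfig(richardson =
TRUE)` therefore offers a Richardson-extrapolated Hessian,
$(4H(h) - H(2h))/3$, which cancels the $h^2$ term at twice the
evaluation cost. Once truncation is cancelled, the *base step* trades
only evaluation noise against the remaining $h^4$ terms, and for an
ill-conditioned $H$ it pays to enlarge it: at the viral study's measured
objective resolution ($\sim 10^{-10}$, the scatter of $G$ across
integrator tolerances and an independent stiff integrator) a base step of
$3\times 10^{-4}$ keeps the noise amplified through the
$\kappa \sim 10^5$ equilibrated conditioning below a few percent of
every Jacobian entry, verified against the refit oracle across seeds.
The plain scheme at $10^{-4}$ stays the package default so that the
$2p(p+2)$ simulation budget of a standard Jacobian build is preserved;
the accuracy-critical viral analyses (`viralStudySetup()`) switch the
refinement on.

Two further stationarity subtleties matter at this conditioning. First,
the Jacobian formula is exact only at a stationary point, and an
optimiser's stopping rule leaves a residual displacement along soft
directions that biases the soft Jacobian entries; `refineStationary()`
(full Newton on the free subspace with Richardson gradient and Hessian)
removes it, and the study setup applies it before differentiating.
Second, the same applies to the *refits* that a derivative oracle is
built from: without the stationarity polish their central differences
drift linearly in the probe step, a pure artefact of termination rules.

### Optima on the boundary: active-set continuation

Under strong practical unidentifiability the likelihood can be monotone
along a soft parameter combination all the way to the edge of the
admissible box $\Omega$, so a fully converged fit legitimately ends with
one or more parameters *on* a bound. The implicit-function construction
assumes an interior stationary point, so `continuationState()` treats
exactly-at-bound parameters as fixed: their `DPsi` rows are zero and the
linear solve runs on the free block. The corrector's convergence flag
likewise tests stationarity only on free components. In the generic
interior case none of this machinery engages and the unconstrained
equations are recovered verbatim. A boundary optimum whose gradient pulls
*inward* is not an optimum at all; `compareMinimaRobustness()` warns
when given such a point.

### The corrector

`correctMLE()` is a bounded Levenberg–Marquardt refinement of the
weighted residual vector (`minpack.lm::nls.lm`, restarted until it stops
improving), with two safeguards. First, the internal FD Jacobian is told
the true residual precision (`epsfcn`), which for ODE-integrated
residuals is the integration tolerance, not machine epsilon. Second, when
LM stalls before reaching the gradient tolerance — its trust region can
collapse while crawling along a strongly anisotropic valley — a
quasi-Newton polish (L-BFGS-B) runs in log-parameter coordinates, where
the valley geometry is far better behaved, followed by a final LM
harvest. The returned objective never exceeds the objective at the start,
which is what makes the predicted-vs-refit comparisons in the studies
below well defined. Trial points where the model cannot be integrated (or
a log-scale observable is nonpositive) return a large constant residual
so the optimiser backs away instead of aborting.

## The built-in models

**Viral dynamics** (`viralModel()`): target cells $T$, infected cells
$I$, free virus $V$;
$T' = \lambda - \beta T V - dT$, $I' = \beta T V - \delta I$,
$V' = \delta N I - c V$; observable $\log_{10} V(t)$. The reference
parameters (`viralReferenceParams()`) give a basic reproduction number
$R_0 = \beta N (\lambda/d)/c \approx 1.75$. Initial conditions are fixed
and known — the regime in which all six parameters are structurally
identifiable. The defaults $(T_0, I_0, V_0) = (300, 0, 100)$ were chosen
once, by maximising the smallest parameter-relative eigenvalue of the
observed information at the reference parameters over a grid of candidate
inocula: an acute-infection start excites the early virion-clearance
phase, the growth phase and the approach to the set point, which is as
much as the sparse 8-point schedule (days 0.4–58) can see. Even at this
optimum the design is *practically unidentifiable* at the study's noise
level (log10 variance 0.15): fitted MLEs generically carry one parameter
on a bound, which is precisely the regime the active-set machinery and
the robustness comparison are for.

**Phenotype switching** (`nsclcModel()`): drug-sensitive cells $A$ and
drug-tolerant cells $B$ growing logistically toward a shared carrying
capacity, the tolerant clone additionally throttled by a cooperative
(Allee) factor $f(B) = B^2/(B^2 + a^2) \le 1$; sensitive-cell death
switches from $d_A$ to $d_A^{max}$ at day 3 of the treated condition;
observable is the total count $N(t) = A + B$, compared on the log10
scale. This is an intentionally *synthetic* reduction of the
phenotype-switching model class: the structural ingredients (two
phenotypes, logistic growth, tolerant-clone cooperation, a treatment
switch at day 3, observable $A + B$, fitted vector
$(r_A, r_B, d_A{=}d_B, d_A^{max})$) are standard, but the specific Allee
form, its constants, the carrying capacity and the initial split are this
package's own choices (`nsclcSyntheticParams()`), so quantitative results
on this model characterise the synthetic regime, not any published cell
line. A design scan over these knobs shows the fixed 6-point design
(control days 0, 2, 4, 6; treated days 4, 6) cannot practically identify
all four parameters at realistic noise — baseline fits typically pin the
weakly informed $r_B$ and $d_A$ — which the continuation carries as
active constraints.

**Linear test model** (`linearModel()`): $y = X\theta$, for which the
MLE, $D\Psi = (X^\top X)^{-1} X^\top$ and the entire continuation are
closed-form. The predictor is *exact* here for every perturbation size,
which is the sharpest available oracle and anchors the test suite.

## The synthetic-data generators

All experiments run on seeded, generated data; no external files are
needed. Each generator is a pure function of its arguments and a seed,
and restores the caller's RNG state.

* `generateViralBaseline()`: noiseless $\log_{10} V(t_i)$ plus Gaussian
  noise of variance 0.15 at times $\{0.4, 1, 8, 14, 20, 36, 46, 58\}$ d.
* `perturbAbsolute()`: $\phi_i + h\,|\varepsilon_i|$ — a systematic drift
  whose sign is $h$'s, mean shift $|h|\sqrt{2/\pi}$.
* `perturbLog()`: multiplicative log-normal perturbation,
  $\phi_i e^{0.8\varepsilon_i}$ by default.
* `perturbNormScaled()`: rescales a Gaussian direction in $\log_{10}$
  space so that $\lVert\log_{10}\phi^j - \log_{10}\phi^0\rVert_2 =
  (0.05 + j\,h_{step})\lVert\log_{10}\phi^0\rVert_2$ *exactly*, then
  enforces ordering constraints (treated counts below their same-day
  controls) by redrawing only the offending components and rescaling, so
  the norm equality survives enforcement. The default increment is
  $h_{step} = 0.65/55$, which puts step 10 at roughly 17% of the baseline
  log-norm; a preset reaching 75% exists but corresponds to
  several-hundred-fold changes of individual counts, far outside any
  regime where refitting — let alone first-order continuation — is
  meaningful, so it is not the default. For the iterated continuation
  study one draw is rescaled across $j$ (pass the same seed), so
  consecutive data sets differ by a small coherent step; passing
  different seeds per $j$ gives independent perturbations instead.
* `appendSimulatedMeasurement()`: appends the model's own prediction at a
  new time, optionally offset by $\pm\Delta\phi$. With zero offset the
  objective at the MLE is untouched, which is what licenses using
  appended simulated points for design questions.
* `generateSwitchingBaseline()`: the 6-point tumour-growth design with
  12% (0.05 log10) count noise and the ordering constraints enforced.

What these generators deliberately do **not** emulate: measurement-level
censoring (below-detection viral loads), non-Gaussian or correlated
errors, batch effects, or model misspecification — the synthetic data are
always generated by the same model class that is fitted. Passing studies
on them therefore validate the continuation calculus, not the biology of
any particular system.

## The package's own studies

Three study drivers reproduce the method's characteristic experiments at
desk scale (a few minutes each on one CPU); the acceptance script under
`scripts/` runs them end to end.

1. `viralFirstOrderSlope()`: the predictor's error against a full refit
   must shrink quadratically in the perturbation scale; the log–log slope
   over scales $1, \tfrac12, \tfrac14$ is the reported diagnostic.
2. `viralRefitOracle()`: every column of `DPsi` against the central
   difference of full refits at $\phi \pm 0.01 e_k$.
3. `runViralPerturbationStudy()`: four half-normal data drifts
   ($h = \pm 0.1, \pm 0.2$); for each, the BIC of the predicted fit
   against the refit BIC, plus the evaluation-count comparison (a plain
   Jacobian build, at most $2p(p+2)$ simulations, against the naive
   refit's objective evaluations).
4. `runSwitchingContinuation()`: ten norm-scaled perturbation steps; at
   each step the objective at the naive carry-over, at the prediction,
   and at the refit — the refit $\le$ prediction $<$ naive ordering is
   the expected generic outcome.

Problem sizes in these drivers (8 and 6 data points, 6 and 4 parameters,
10 continuation steps, $10^4$ Monte-Carlo draws in the generator checks)
match the studies they replicate; they are deliberate choices, small
enough to re-run interactively while large enough that every pathway —
prediction, correction, active sets, constraint enforcement — is
exercised.

## Known limitations

* The analysis is local twice over: in parameter space (a pre-identified
  optimum) and in data space (first-order Taylor). Large data revisions
  need the corrector.
* Fixed, known noise scales; estimating $\sigma$ alongside $\theta$ is
  out of scope.
* The candidate-measurement ranking searches a user-supplied list of
  times, not the continuum, and evaluates one appended point at a time.
* FD derivatives inherit integrator noise; for new models with very
  different scales, check `scaledGradient()` at a known optimum before
  trusting `DPsi`, and prefer `richardson = TRUE` whenever the
  equilibrated condition number of `H` is large.
* Censored observations and non-Gaussian likelihoods are not supported;
  the objective is (possibly log-scale) weighted least squares.
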