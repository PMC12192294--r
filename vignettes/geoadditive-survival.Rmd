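---
title: "Geoadditive survival analysis by the Poisson-offset reduction"
author: "geocox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geoadditive survival analysis by the Poisson-offset reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`geocox` targets censored age-at-event outcomes from geographically
referenced household surveys. Each record carries an observed duration
`t_i = min(T_i, C_i)` (age at the event, or current age if it has not yet
occurred), an event indicator, categorical covariates, a survey weight
equal to the inverse of the selection probability, and the coordinates of
the respondent's enumeration area (all members of a cluster share one
point). The hazard is modelled as

$$\lambda_i(t) = \lambda_0(t)\,\exp\{\mathbf{x}_i'\beta + S(\mathbf{s}_i)\},$$

with an unspecified baseline `lambda_0`, log-linear covariate effects, and
a bivariate smooth `S` of location that absorbs unmeasured spatially
structured drivers. Hazard ratios between subjects are constant over time
(proportional hazards), and the log hazard is additive in its components.

### The Poisson-offset reduction

The counting process evaluated at the end of follow-up satisfies
$E(N_i \mid \mathbf{x}_i, \mathbf{s}_i) =
\exp\{\mathbf{x}_i'\beta + S(\mathbf{s}_i)\}\Lambda_i$, where
$N_i = \delta_i$ is the event indicator and $\Lambda_i$ the cumulative
baseline hazard at the observed duration. Plugging in the Breslow estimate
from a standard Cox fit turns the survival problem into a Poisson
regression of $\delta_i$ with the known offset $\log\hat\Lambda_i$ and no
intercept (the baseline hazard already carries it). `fit_cox()` maximizes
the survey-weighted Breslow partial likelihood by Newton–Raphson
(convergence when the largest score component is below 1e-8 or the
relative log-likelihood change below 1e-10), `breslow_cumhaz()` computes
$\hat\Lambda_0$, and `to_poisson_frame()` assembles the Poisson data,
dropping (with a logged count) any record censored before the first event
time, whose cumulative hazard is zero and whose offset would be $-\infty$.

Breslow — not Efron — tie handling is used throughout, deliberately: the
Breslow baseline is exactly what the reduction plugs in as the offset, so
the two stages stay mutually consistent. With ages recorded in whole years
ties are heavy and this choice is material.

### The low-rank kriging smooth

`S` is expanded as
$S(\mathbf{s}) = \mathbf{s}'\beta_s + \sum_{k=1}^{K} u_k z_k(\mathbf{s})$:
raw (mean-centered) longitude and latitude enter the fixed effects, and
the $z_k$ form the low-rank kriging basis
$Z = C(\mathbf{s}, \kappa)\,C(\kappa, \kappa)^{-1/2}$, where $C$ evaluates
an isotropic generalized covariance $g_\tau$ at data-to-knot and
knot-to-knot distances. Six families are supported, all normalized to
$g_\tau(0) = 1$ with $\tau$ a length scale: exponential $e^{-h/\tau}$,
Gaussian $e^{-h^2/\tau^2}$, Matérn at smoothness 3/2
$(1 + h/\tau)e^{-h/\tau}$, spherical
$(1 - 1.5h/\tau + 0.5h^3/\tau^3)\,1[h<\tau]$, circular
$(2/\pi)(\arccos\vartheta - \vartheta\sqrt{1-\vartheta^2})$ with
$\vartheta = \min(h/\tau, 1)$, and inverse quadratic $1/(1 + h^2/\tau^2)$.
The circular and inverse-quadratic forms are the standard normalizations
of their families. The inverse square root is taken by symmetric
eigendecomposition with eigenvalues floored at $10^{-10}\lambda_{max}$
(floored directions contribute zero), which keeps the basis finite even
when the knot covariance is numerically singular, as the Gaussian family
is at very long range.

Knots number $K = \max\{20, \min(\lfloor n/4\rfloor, 150)\}$ (capped at
the number of distinct locations) and are placed by a greedy max–min
("coffee-house") pass over the candidate locations followed by pairwise
swap improvement of the minimum inter-knot distance until no single swap
improves it — deterministic given its seed.

Distances are planar Euclidean in coordinate units. For a low-latitude
study area raw degrees are an adequate planar approximation; users at high
latitudes should project coordinates (e.g. a local equirectangular
scaling) before calling the package, since no projection is applied
internally.

### PQL estimation

Treating $u \sim N(0, \sigma_u^2 I)$ makes the working model a Poisson
GLMM, fitted by Breslow–Clayton penalized quasi-likelihood: iterate the
Gaussian working response $y^* = \eta - o + (N - \mu)/\mu$, solve the
weighted ridge-penalized least squares for $(\beta, u)$ with observation
weights $w_i\mu_i$, and update
$\sigma_u^2 \leftarrow \hat u'\hat u / (K - \mathrm{tr}(A^{-1}_{uu})/\sigma_u^2)$,
until the relative change in $(\beta, u, \sigma_u^2)$ falls below 1e-6
(200 iterations maximum; a variance pinned at its 1e-10 floor degrades
gracefully to the fixed-effects fit with a warning). Survey weights are
normalized to mean 1 first, so the variance component is not distorted by
the weights' arbitrary scale and rescaling all weights leaves the fit
unchanged. Effective degrees of freedom are the working-model hat-matrix
trace, and the final coefficient system is rebuilt at the converged
$\sigma_u^2$ so the reported edf and covariance are internally consistent.

**Coefficient covariance.** The collapsed Poisson working information
treats the offsets as known and overstates precision: in simulation its
standard errors ran about 18% below the empirical sampling spread.
Because the Poisson-offset estimates coincide with the (penalized)
partial-likelihood maximizer, the package instead takes Wald covariances
from the penalized partial-likelihood observed information, which reduces
exactly to the Cox covariance when the smooth is absent and restores
nominal interval coverage (0.95–0.97 empirically at n = 400). Intervals
are normal-theory on the log scale; design-based (sandwich) variances are
out of scope, so under strongly variable weights intervals remain
model-based and mildly anticonservative.

### Choosing the range and the family

For a candidate $\tau$ the basis is rebuilt and the PQL fit rerun; the
profile criterion is the corrected AIC,
$\mathrm{AICc} = -2\ell + 2\,\mathrm{edf} +
2\,\mathrm{edf}(\mathrm{edf}+1)/(n - \mathrm{edf} - 1)$, with $\ell$ the
weighted Poisson log-likelihood. An obvious alternative — profiling the
working-model restricted likelihood — was implemented first and rejected:
the PQL working data (response and weights) themselves change with
$\tau$, so restricted-likelihood values are not comparable across
candidate ranges; empirically that profile was near-monotone with a
spurious small-range mode that interpolates noise, while the AICc profile
is unimodal with its minimum at the generating length scale. AICc also
keeps range profiling coherent with family selection. The search brackets
the optimum on a 7-point log-spaced grid over $[d_{min}, d_{max}]$ (the
extreme pairwise distances between distinct locations) and refines by
golden section to a tolerance of $10^{-3} d_{max}$, warm-starting
$\sigma_u^2$ between passes; a profile flat within tolerance falls back to
the fixed choice $\tau = d_{max}$. `select_covariance()` profiles each
family and ranks by AICc with BIC as the (package's own) tiebreak; the
corrected AIC is preferred because the plain AIC under-penalizes the
smooth's effective dimension.

The range is only weakly identified when the spatial signal is modest:
long range with a large variance component can mimic a moderate range
with a moderate variance at nearly equal AICc, so $\hat\tau$ scatters.
Simulation shows reliable factor-of-two recovery of the generating length
scale once the field's amplitude is clearly above the covariate effects
(about ±1.5 on the log hazard at n ≈ 1000); the package's tests probe that
regime, and at weaker signal one should read $\hat\tau$ as a smoothing
choice rather than a physical parameter. The fitted surface is much more
stable than $\hat\tau$ itself.

### The mapped surface

`predict_log_hr()` evaluates the total spatial effect — centered-coordinate
linear terms plus the smooth — on a regular lattice (default 100×100 over
the data's bounding box with a convex-hull mask) and mean-centers it over
the unmasked points. Only spatial contrasts are identified, since any
constant is absorbed by the baseline hazard; centering makes that
explicit. A switch maps the smooth alone. Masking is boundary-inclusive:
the package's even-odd point-in-polygon test counts lattice points lying
exactly on the mask edge as inside.

## The synthetic cohort

The generator stands in for restricted survey microdata and reproduces
the features that matter downstream: cluster-shared coordinates sampled
uniformly over a (masked) domain; covariates drawn per-person from stated
level probabilities with log-hazard effects; a smooth spatial field (sums
of Gaussian bumps, mean-centered over a reference grid); a latent debut
age $T = a_0 + b\,(E/e^{x'\beta + S(s)})^{1/k}$ with $E$ unit exponential
— a Weibull baseline under a proportional-hazards shift, with hazard
support starting at $a_0 = 8$ years so simulated ages stay biologically
plausible; an interview age uniform on 15–25 years acting as the
censoring time; optional flooring of observed durations to whole years
(on by default, deliberately inducing the heavy ties of age-reported
data; flooring never flips an event into a censoring); and cluster-level
inverse-probability weights rescaled to mean 1.

The default baseline was calibrated in closed form before any fitting:
requiring median debut at 16 years and 18.9% of debuts before age 15 at a
null linear predictor gives shape $k = 9$ and scale
$b = 8/\log(2)^{1/9} \approx 8.333$ (solving $(7/b)^k = -\log 0.81$ and
$(8/b)^k = \log 2$). Default covariate effects (a 20%-prevalence binary
exposure at hazard ratio 1.5, a 78%-prevalence protective flag at 0.9,
two null covariates) were chosen so the population mean log-hazard shift
is approximately zero, leaving that calibration intact; the default
two-bump field (±0.4, width 0.18, mean-centered) does the same.

What the generator does **not** emulate: multi-stage selection mechanics
beyond cluster weights, item nonresponse, recall error in reported ages,
within-cluster covariate correlation, and anisotropic or nonstationary
spatial structure. Tests passing on synthetic data therefore validate the
estimators' internal correctness and calibration, not robustness to those
real-data complications.

### Discretized ages and attenuation

Flooring event ages to whole years pools events so heavily (event-to-risk
ratios up to ~0.5 under the steep baseline) that the Breslow partial
likelihood itself attenuates log-hazard ratios by roughly 0.1–0.15 per
component — a property of discretized data (Efron ties barely differ),
not of the estimator: with continuous ages the same fits are unbiased.
The replicate studies of estimator calibration (effect recovery, interval
coverage, log-rank size) therefore run the generator with rounding off,
while ties remain on everywhere else — the descriptive statistics, the
Poisson–Cox equivalence (which holds exactly under ties), determinism,
and the end-to-end pipeline. The recovery study also uses equal weights:
it isolates estimator calibration, and model-based Wald intervals cannot
absorb the design variance injected by random weights (sandwich variances
being out of scope); the weighted path is validated by its own invariance
and oracle tests.

## Numerical choices and degenerate inputs

- Newton–Raphson for the Cox stage starts at zero with step halving;
  rank-deficient designs and constant covariates are rejected by name.
- The PQL system is solved by Cholesky with a relative jitter retry;
  divergence (non-finite predictor) aborts with the iteration count.
- Records censored before the first event time are dropped with a count;
  an all-dropped frame is an error.
- `estimate_tau` requires at least two distinct locations; all-identical
  coordinates are a degeneracy error.
- Knot selection requires at least K distinct candidates (duplicates
  collapsed first) and returns them all when forced (candidates = K).
- Mean-centering tie-break: reference levels default to the first sorted
  level of each covariate unless stated explicitly.
- All numeric CSV output is written at 12 significant digits, making
  same-seed re-runs byte-identical.

## Stratified models and the pipeline

`run_study()` executes the full sequence — descriptives, Cox stage,
Poisson frame, knots, per-family range profiling and AICc comparison,
final fits, hazard-ratio tables, surfaces, manifest — overall and once
per stratum (e.g. female/male), each stratum with its own Cox-offset
stage, knots, and (by default) its own profiled range, while reusing the
overall winning family; both behaviors are switchable. Stage seeds derive
deterministically from one master seed and the stage name. Stratified
fits depend only on their own records, so permuting another stratum's
rows leaves them bit-identical.

## Problem sizes used by the tests

The suite validates the hand-computable oracles exactly and the
statistical properties at sizes chosen to finish in minutes: Poisson–Cox
agreement and effect recovery on 200 cohorts of n = 400; log-rank size on
2000 null cohorts of n = 100; surface recovery on one n = 2000 cohort
against a 50×50 truth grid; range recovery on 6 cohorts of n ≈ 1000 at
the strong-signal amplitude; family selection on 3 cohorts of n = 700;
end-to-end determinism on two full runs of an n = 400 configuration with
two candidate families. `scripts/acceptance.R` re-runs the same studies
from scratch under a caller-supplied seed.

## Known limitations

- Isotropic covariances only; anisotropy and location measurement error
  (coordinates are shared at the cluster level) are not modelled.
- Model-based variances; no design-based (sandwich) or replicate-weight
  uncertainty, and no uncertainty band on the mapped surface.
- The Poisson reduction assumes equidispersion given the random effects
  and proportional hazards; neither is tested internally.
- The range parameter is a smoothing choice at realistic signal strength;
  compare families and ranges by AICc rather than interpreting
  $\hat\tau$ physically.
- Left truncation, competing risks, and time-varying covariates are out
  of scope.
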