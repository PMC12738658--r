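# cilinfer

Parameter inference for dynamical models whose output is **intrinsically
variable** — chaotic ODE systems, Turing reaction–diffusion patterns, and a
nonlocal model of tumour-colony growth. It is aimed at modellers in
mathematical biology who need to calibrate a mechanistic model when repeated
runs at identical parameters produce different trajectories or patterns, so
that pointwise least-squares or Gaussian likelihoods break down.

## The method

Instead of comparing states pointwise, model output is summarised by a
**generalised correlation-integral vector**: the empirical CDF of pairwise
distances at fixed radii $R_1 < \dots < R_M$,

$$y_k(\theta) = \frac{1}{N^2} \#\bigl\{(i,j) : \lVert s_i - \tilde s_j\rVert < R_k\bigr\}$$

for a pair of trajectories (or, for pattern models, the eCDF of distances
$d^i = \rho(s^1_i, s^2_i)$ between independently simulated patterns). Across
replicated simulations $y(\theta_0)$ is approximately Gaussian
$N(\mu, \Sigma)$, and the **correlation-integral likelihood (CIL)** cost

$$f(\theta) = \bigl(y(\theta) - \mu\bigr)^{\top} \Sigma^{-1} \bigl(y(\theta) - \mu\bigr),
\qquad f(\theta_0) \approx \chi^2(M),$$

is a stochastic negative log-likelihood usable inside MCMC. A synthetic
variant (**SCIL**) handles severely limited data — down to a single observed
pattern — by estimating $\mu(\theta), \Sigma(\theta)$ from repeated
simulations at each candidate parameter.

The package couples these costs, and a classical Gaussian posterior for the
colony model ($V(\theta) = \tfrac12\lvert D - \mathcal M(\theta)\rvert^2_\Gamma
+ \tfrac12\lvert\theta - m\rvert^2_\Sigma$), to:

* **Metropolis, Metropolis–Hastings, adaptive Metropolis** samplers with
  chain diagnostics (acceptance rate, autocorrelation-based ESS, credible
  intervals);
* **gradient-flow samplers** — unadjusted Langevin (Euler–Maruyama of
  $dX = -\nabla V\,dt + \sqrt2\,dB$) and Stein variational gradient descent —
  plus a 1-D Chang–Cooper **Fokker–Planck** solver and Kullback–Leibler
  diagnostics that serve as reference oracles.

Forward models included: Lorenz-63 (pluggable registry), the Schnakenberg
Turing system on 1-D/2-D grids (compiled semi-implicit stepper), and the
radially reduced nonlocal logistic colony model with its 95%-mass radius
observable and multiplicative lognormal measurement error. All data are
synthetic and generated by the package itself, with explicit seeds
everywhere.

## Worked example

Calibration of the CIL cost for the Turing model — build reference
statistics at the true parameters, then score candidate parameters:

```r
library(cilinfer)

theta0 <- schnakenberg_params()
turing <- cil_model(function(theta, n, seed) {
  simulate_turing_ensemble(n, theta = theta,
                           grid = list(nx = 64, length = 40), seed = seed)
}, kind = "pattern")

stats <- estimate_statistics_sim(turing, theta0, n_rep = 120, N = 10,
                                 M = 8, seed = 1)
print(stats)
#> <cil_statistics> pattern mode, M = 8 bins, 120 realisations (N = 10), ridge 1e-08

f_true <- cil_cost_at_parameter(theta0, stats, turing, seed = 2)
theta_bad <- theta0; theta_bad["Dv"] <- 160
f_bad <- cil_cost_at_parameter(theta_bad, stats, turing, seed = 2)
#> cost at true theta: 6.01 (chi-squared(8) mean is 8)
#> cost at Dv x4:      211.33 (99th percentile is 20.1)

costs <- sapply(1:100, function(i)
  cil_cost_at_parameter(theta0, stats, turing, seed = 100 + i))
chi2_calibration(costs, 8)
#> mean cost / M = 1.148, KS p-value vs chi-squared(8) = 0.03
```

At the true parameters the cost sits where a $\chi^2(8)$ draw should
(mean/M near 1; at this small reference size, 120 realisations, the mean
is visibly inflated — the acceptance runs use 400 realisations of larger
subsets on a longer domain); a fourfold-wrong
diffusion ratio is rejected by two orders of magnitude. `-0.5 * f` plugs
straight into `metropolis()` or `adaptive_metropolis()` as a log target,
and `run_pipeline()` wires simulate → likelihood → sample → diagnose from a
YAML config (see `validate_config()`); a thin command-line front end ships
in `inst/cli/cil.R`.

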