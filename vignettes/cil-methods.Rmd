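---
title: "Correlation-integral likelihoods and samplers: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-integral likelihoods and samplers: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Many biological models do not map a parameter vector to a single predicted
curve. A chaotic system started twice from imperceptibly different initial
states produces two trajectories that disagree pointwise while tracing the
same attractor; a Turing reaction–diffusion model produces a different
stationary pattern for every realisation of its initial noise; an
individual-based simulation differs between runs at identical settings.
Least-squares or Gaussian-likelihood fits, which compare model output to
data point by point, are useless in this regime: at the *true* parameters
the pointwise residuals are as large as anywhere else.

`cilinfer` implements a likelihood for exactly this situation. The idea is
to compare *distributions of pairwise distances* rather than states. Two
model outputs at the same parameters look different but are statistically
exchangeable; the empirical cumulative distribution function (eCDF) of
distances between them is a stable, low-dimensional fingerprint of the
attractor or pattern family.

# The correlation-integral likelihood

Fix bin radii $0 < R_1 < \dots < R_M$. For two trajectories
$S = \{s_1,\dots,s_N\}$ and $\tilde S = \{\tilde s_1,\dots,\tilde s_N\}$
the generalised correlation-integral vector has components

$$y_k = \frac{1}{N^2}\,\#\{(i,j) : \|s_i - \tilde s_j\| < R_k\},
  \qquad k = 1,\dots,M,$$

the empirical probability that a cross-pair of states is closer than
$R_k$. For pattern-forming models the same construction is applied to the
scalar distances $d^i = \rho(s^1, s^2)$ between independently simulated
patterns, with $y_k = n^{-1}\#\{i : d^i < R_k\}$. (Strict inequality
throughout; ties at a bin edge count as outside.) As the number of
distances grows, $y$ tends to a multivariate Gaussian
$N(\mu(\theta_0), \Sigma(\theta_0))$; estimating $\mu$ and $\Sigma$ from
replicated simulations (or a partition of a large dataset) turns

$$f(\theta) = (y(\theta) - \mu)^\top \Sigma^{-1} (y(\theta) - \mu)$$

into a stochastic cost whose value at the true parameter is approximately
$\chi^2(M)$. The package exposes this as `cil_cost()` /
`cil_cost_at_parameter()`; `-f/2` plugs into any of the samplers as a log
target.

## Estimating the Gaussian statistics: two routes

`estimate_statistics()` implements the data-facing route: partition
$N_{\text{data}} = n_{\text{ens}} \times N$ items into $n_{\text{ens}}$
subsets and use all $n_{\text{ens}}(n_{\text{ens}}-1)/2$ subset pairs, one
eCDF realisation each. This is the right tool when one fixed experimental
dataset is all there is. It has a quantifiable drawback: pairs sharing a
subset are positively correlated, so the sample covariance of the
realisations underestimates the true covariance, and the cost at the true
parameter is inflated above its $\chi^2(M)$ reference (we measure a mean
ratio of roughly 1.3 at $n_{\text{ens}} = 16$, $N = 10$, $M = 10$ for the
Turing model below; the effect grows as $n_{\text{ens}}$ shrinks).

`estimate_statistics_sim()` implements the simulation route: when the model
can be run freely, draw $n_{\text{rep}}$ *independent* pairs of $N$-item
subsets and use one realisation per pair. The realisations are i.i.d., the
covariance estimate is unbiased, and the only residual inflation is the
classical finite-sample inverse-covariance factor
$(m-1)/(m-M-2)$ for $m$ realisations. The calibration experiments in the
test suite use this route with $m = 400$, $N = 30$, $M = 10$ on a 128-cell
Schnakenberg model, giving a cost distribution that passes a
Kolmogorov–Smirnov test against $\chi^2(10)$ at level 0.01 with
mean$/M$ within $[0.9, 1.1]$.

## Bins

The paper-facing construction takes the bin radii as given. The package
places them at equally spaced quantiles of pooled training distances
(`select_radii()`), which spreads the information across the distance
distribution and keeps every bin component non-degenerate. Duplicate
quantiles (heavily tied distances) are collapsed with a warning; fewer than
`M` distinct distances is an error. Default $M = 10$.

## SCIL: the single-snapshot variant

With very limited data — down to one observed pattern — the roles of data
and simulation are interchanged: at each candidate $\theta$ the statistics
are estimated from repeated simulations, and the data supply a single eCDF
realisation. `scil_cost()` builds all synthetic realisations *and* the data
vector against one fixed simulated reference subset of $N$ items: each
realisation pairs $n_{\text{data}}$ fresh independent simulations against
the reference, the data vector pairs the observed items against the same
reference. Conditional on the reference the synthetic realisations are
exactly i.i.d. copies of the data vector's null distribution, which is what
keeps the cost $\chi^2(M)$-consistent even at $n_{\text{data}} = 1$. (An
earlier design that resampled overlapping subsets from one simulation pool
— mimicking the partition estimator — was measurably miscalibrated for
single snapshots, mean$/M \approx 1.2$–$1.4$, and was discarded.)

A genuine limitation surfaced here: with one snapshot the eCDF carries only
$N$ distances, all sharing the single observed pattern, so the Gaussian
approximation needs the *pattern distribution itself* to be rich. On a
short 1-D domain (64 cells, length 40) the Schnakenberg model admits only a
handful of no-flux modes; patterns fall into a few discrete classes, the
single-snapshot eCDF is strongly non-Gaussian, and no estimator setting
recovers a $\chi^2$ shape. On a length-80, 128-cell domain the unstable
mode band is ~3x wider, the pattern family is far richer, and calibration
holds (KS p-values 0.2–0.8 across seed batches). The single-snapshot
calibration experiments therefore run on the longer domain; this is a
property of the method worth knowing before applying it to data with little
intrinsic variability.

# Forward models

**Chaotic systems.** A pluggable registry (`register_chaotic_system()`),
with Lorenz-63 at classical parameters
($\sigma = 10, \rho = 28, \beta = 8/3$) as default — canonical, cheap, and
with known equilibria $(\pm\sqrt{\beta(\rho-1)}, \pm\sqrt{\beta(\rho-1)},
\rho - 1)$ used as fixed-point tests. Integration by `deSolve::ode`
(default `lsoda`, rtol $10^{-8}$, atol $10^{-10}$). Intrinsic variability
enters only through `perturb_initial_state()`; the integrator itself is
deterministic and bit-reproducible.

**Turing patterns.** The two-component Schnakenberg model
$u_t = D_u\Delta u + \gamma(a - u + u^2 v)$,
$v_t = D_v\Delta v + \gamma(b - u^2 v)$, no-flux boundaries, defaults
$a = 0.1$, $b = 0.9$, $\gamma = 1$, $D_u = 1$, $D_v = 40$ — a standard
Turing benchmark whose linearisation gives an analytic dispersion relation
(`turing_growth_rate()`), used to test that the dominant Fourier mode of
simulated patterns matches the fastest-growing admissible wavenumber. The
integrator is a fixed-step semi-implicit scheme (implicit diffusion via
constant-coefficient tridiagonal solves, explicit reaction, Lie splitting
in 2-D), written in C++. A calibration run needs thousands of pattern
simulations; an adaptive method-of-lines integrator is the right default
for the other models but would make these experiments needlessly slow. The
homogeneous steady state is an exact fixed point of the discrete scheme, so
`ic_amplitude = 0` reproduces it to round-off. Default time step 0.1
(reaction-limited; the implicit diffusion step is unconditionally stable),
stationarity declared when the max-norm relative change per unit time drops
below $10^{-6}$; non-stationary output is flagged, not rejected.

**Nonlocal colony growth.** The volumetric tumour-cell density obeys
$\partial_t n = \alpha\,(k * n)(1 - n)$ with $k$ the normalised indicator
of a ball of radius $\sigma_k$ and initial colony a ball of radius
$\sigma_s$ (radial density $p(r, 0) = 4\pi r^2$ on $[0, \sigma_s]$). For
radially symmetric $k$ and $n$ the 3-D convolution collapses to
$(k*n)(r) = \frac{2\pi}{r}\int_0^\infty s\,n(s) \int_{|r-s|}^{r+s} t K(t)
\,dt\,ds$, precomputed as a dense kernel matrix on a cell-centred radial
grid — no 3-D grid is ever built. Method of lines in time
(`deSolve`, default `lsoda`). The observable is the radius enclosing 95% of
total mass, computed by trapezoidal cumulative mass and linear
interpolation between nodes (the infimum in the defining expression is
grid-ambiguous; interpolation removes the grid bias). On the initial ball
the closed form $(0.95)^{1/3}\sigma_s$ is available and is checked to
0.5%. Because both the kernel and the initial state are indicators, grid
convergence is non-monotone in the refinement (the kink positions move
relative to cell edges); the tests assert shrinking differences under
fourfold refinement rather than a clean Richardson order.

Measurements carry multiplicative lognormal noise,
$r_o^i = r(t_i)\exp(\tilde Z_i)$, $\tilde Z_i \sim N(0, \sigma_o^2)$ —
deviations scale with the measured radius, and observed radii stay
positive. The likelihood keeps its $\sigma_o$-dependent normalising term
because $\sigma_o$ is estimated alongside the dynamics parameters. All
four parameters $(\alpha, \sigma_k^2, \sigma_s^2, \sigma_o^2)$ are handled
on the log scale, with wide Gaussian priors there (sd 2 around plausible
magnitudes; the original study's priors are not stated, so the defaults
are deliberately uninformative).

# Samplers

**Metropolis family.** `metropolis()` (isotropic Gaussian random walk),
`metropolis_hastings()` (user proposal with the standard Hastings
correction — the correction formula is not printed in the source material,
so the textbook form is used), and `adaptive_metropolis()` with proposal
covariance $s_d\,\mathrm{cov}(\theta_{1:j}) + s_d\,\epsilon I$,
$s_d = 2.38^2/d$, updated by an $O(d^2)$ Welford recursion (checked against
batch recomputation to $10^{-8}$). For stochastic CIL targets the current
state's cost is cached by default; a `refresh` flag re-evaluates it each
step. Both behaviours are available because the refresh policy genuinely
changes the sampler's stationary behaviour for noisy targets and no
prescription exists; the default (freeze) matches how a stochastic cost is
normally used inside MCMC.

**Gradient-flow samplers.** The unadjusted Langevin algorithm discretises
$dX = -\nabla V\,dt + \sqrt{2}\,dB$ by Euler–Maruyama. On
$V = \theta^2/2$ the chain is AR(1) with stationary variance exactly
$1/(1 - h/2)$ — the tests verify this closed form for
$h \in \{0.2, 0.1, 0.05\}$ and its convergence to 1. Stein variational
gradient descent evolves particles by
$\dot\theta_i = -\frac1N\sum_j \nabla K(\theta_i - \theta_j)
- \frac1N \sum_j K(\theta_i - \theta_j)\nabla V(\theta_j)$ (explicit Euler,
default $dt = 0.1$), with a Gaussian RBF kernel and median-heuristic
bandwidth $\ell^2 = \mathrm{med}^2 / (2\log(N+1))$ recomputed each step.
SVGD is deterministic after initialisation; one particle reduces exactly to
scaled gradient descent; SVGD ensembles under-estimate the target variance
at moderate $N$, so the convergence assertion is on the mean. Gradient-flow
samplers are wired to smooth analytic potentials only — CIL costs are
stochastic and nowhere differentiable in practice, so coupling them to
$\nabla V$ is out of scope by design.

**Fokker–Planck reference solver.** A 1-D conservative finite-volume
scheme with exponential-fitting (Chang–Cooper/Scharfetter–Gummel) fluxes:
zero flux at an interface forces the density ratio $e^{-\Delta V}$, so
$e^{-V}/Z$ is an *exact* discrete stationary state, and column sums of the
generator vanish, so mass is conserved to round-off. Implicit Euler in time
(unconditionally stable; a cached QR factorisation is solved each step —
applying a precomputed dense inverse was found to leak mass at
$\sim 10^{-8}$ per step). The relative entropy
$D_{KL}(\varrho_t\|\varrho_\infty)$ is monitored by `kl_decay_monitor()`
and is monotone non-increasing along the discrete flow — the Lyapunov
property of the continuous gradient flow survives discretisation. The
solver doubles as an oracle: Langevin particle histograms at $T = 5$ agree
with the PDE density within total-variation 0.1 at $N = 10^3$ particles,
and the Gaussian variance follows the Ornstein–Uhlenbeck law
$\sigma^2(t) = 1 + (\sigma_0^2 - 1)e^{-2t}$ to grid accuracy. Domains
should hold $\gtrsim 8$ standard deviations of the target *and* of the
initial density: no-flux boundaries silently truncate whatever mass sits
outside.

# Synthetic data and what the tests do (and do not) show

The package generates all of its own data. The generator defaults define
the study conditions:

* **Colony**: $\theta^* = (\alpha, \sigma_k, \sigma_s, \sigma_o) =
  (0.3, 0.15, 0.25, 0.05)$, radii observed at $t = 0, 2, \dots, 20$
  (11 time points, 5% lognormal noise) — a growth-curve geometry of the
  kind spheroid diameter series provide, with the radius roughly tripling
  over the window.
* **Turing CIL calibration**: 128-cell 1-D grid of length 80
  ($\approx 14$ pattern wavelengths, a wide band of unstable modes),
  initial noise amplitude 0.01, $N = 30$ patterns per subset, $m = 400$
  independent pair realisations, $M = 10$ bins, 200 replicate costs. The
  subset size matters: the $\chi^2(M)$ reference is asymptotic in the
  number of distances per eCDF, and on short domains (few admissible
  modes, quasi-discrete pattern classes) or at small $N$ the cost
  distribution visibly departs from it.
* **SCIL single snapshot**: 128-cell 1-D grid of length 80, $N = 20$,
  $n_{\text{rep}} = 120$, $M = 5$, 60 replicate costs.
* **Posterior coverage**: 20 independent synthetic datasets, adaptive
  Metropolis chains of 1500 steps (burn-in 30%), coverage counted per
  parameter component.

Problem sizes are deliberately desk-scale: simulations are 1-D, chains are
short, and replicate counts are in the low hundreds. Passing tests
certify the *mechanics and calibration* of the method under its own
assumptions — an inverse-crime setting in which data are generated by the
same discretisation that evaluates the likelihood. They do not certify
behaviour on real data, where model misspecification, measurement artefacts
and non-stationarity enter; nor do 1-D pattern experiments speak to the
cost of 2-D inference (the 2-D simulator is provided and tested for
correctness, but the calibration experiments would be ~10x slower there).

# Numerical choices, degenerate inputs, tie-breaks

* Covariance regularisation: $\Sigma + \lambda\,\mathrm{tr}(\Sigma)/M\,I$,
  $\lambda = 10^{-8}$ escalated tenfold until the Cholesky factorisation
  succeeds; a realisation count at or below $M$ additionally warns that the
  ridge is load-bearing.
* Strict `<` in all eCDF counts; equal bin radii collapse with a warning;
  constant distance samples are an error, not a silent single bin.
* Forward-model failures during sampling map to $V = +\infty$ (zero
  posterior mass) with a warning — a sampler must survive proposals in
  non-physical corners rather than abort.
* Effective sample size uses the initial-positive-sequence truncation of
  the autocorrelation sum; constant chains are flagged and given ESS 1.
* All stochastic entry points take explicit integer seeds, and all
  randomness flows through a locally scoped RNG (`withr::with_seed`), so no
  call disturbs the caller's RNG state and every artifact is reproducible
  from its manifest.

# Known limitations

* The $\chi^2(M)$ reference is asymptotic in the number of distances per
  eCDF; serial dependence along chaotic trajectories and the finite pattern
  count both inflate the cost's tail slightly. The acceptance experiments
  quantify how close the implemented estimators get (mean$/M$ within 10%).
* The partition-based covariance estimator is biased at small
  $n_{\text{ens}}$ (see above); inference built on it remains usable — the
  cost surface is merely rescaled — but its absolute values should not be
  read as $\chi^2(M)$ quantiles.
* SCIL with a single snapshot requires a rich pattern distribution; on
  domains supporting only a few modes its null distribution departs from
  $\chi^2(M)$ no matter how the statistics are estimated.
* The SVGD implementation targets smooth potentials in low dimension; no
  convergence-rate claims are made, and variance under-estimation at small
  particle counts is inherited from the method.
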