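---
title: "MPFRAP recovery models under shear flow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPFRAP recovery models under shear flow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfrap)
```

## The measurement and the models

Multiphoton FRAP (MPFRAP) bleaches fluorophores in a femtolitre-scale
two-photon focal volume and records the fluorescence recovery as unbleached
molecules move back in. The focal volume is a 3D Gaussian with 1/e^2 radial
radius $\omega_r$ and axial radius $\omega_z$; its aspect enters the models
only through $R = \omega_z^2/\omega_r^2$. For an NA-0.8 water-immersion
objective the package defaults are $\omega_r = 0.404$ um, $\omega_z = 2.27$
um, $R \approx 31.6$.

Recovery is described by a closed-form alternating series in the bleach
depth $\beta$ and up to three characteristic times:

* $\tau_D = \omega_r^2 / 8D$ — diffusion;
* $\tau_v = \omega_r / v_0$ — uniform flow along x at the focal-volume
  centre;
* $\tau_\gamma = 1/\gamma$ — laminar shear, $v_x = v_0 + \gamma z$, with the
  gradient along the optical axis.

The three fitting models form a strict reduction chain. `model_shear_flow()`
covers diffusion + flow + shear; setting $\tau_\gamma = \infty$ reduces it
algebraically to `model_diffusion_convection()`, and additionally
$\tau_v = \infty$ to `model_diffusion()`. The package evaluates each model as
its own series and the test suite checks the chain pointwise to 1e-12
relative, which protects against transcription errors in any one of them.

All model values at $t = 0$ equal `initial_fraction(beta)`
$= \sum_n \frac{(-\beta)^n}{n!}(1+n)^{-3/2}$, and tend to 1 as
$t \to \infty$. Fluorescence is carried in arbitrary units with the
prebleach level $F_0$ explicit: the absolute photophysical calibration
constants (action cross sections, collection efficiency, monitor intensity)
are normalized to 1 throughout, and both bleaching and monitoring are
two-photon processes ($b = m = 2$).

The dimensionless coordinates of all accuracy maps are the scaled velocity
$v_s = \tau_D/\tau_v$ and scaled shear rate $\gamma_s = \tau_D/\tau_\gamma$:
the relative contribution of flow and shear to the recovery. The combined
half-recovery scale obeys $1/\tau_{1/2} = 1/\tau_D + 1/\tau_v +
1/\tau_\gamma$.

### Numerical choices in the series

* Terms are summed adaptively with a relative stop at $10^{-12}$ and a hard
  cap of 60 terms. The alternating series converges rapidly for the
  physically relevant $\beta \lesssim 2$; the cap keeps the partial sums
  finite for pathological inputs. Bleach depths above 12 are rejected: there
  the cancellation in the capped sum can no longer be resolved in double
  precision.
* A fixed 10-term truncation is used in exactly one place — inverting the
  $t = 0$ fraction for the bleach-depth seed — because that is how the
  seeding recipe is defined. The 10-term polynomial is monotone decreasing
  only up to $\beta \approx 5.0$, which bounds the invertible range of
  `seed_beta()`.
* Infinite $\tau_v$ and $\tau_\gamma$ are first-class values; internal
  arithmetic uses reciprocal rates, so the reductions and the combined
  half-time are exact, not approximations at a large cutoff.
* The flow exponent is clamped at $-745$ before exponentiation: large-$t$
  tails underflow cleanly to zero rather than erroring.

## The Monte Carlo simulator

`simulate_recovery()` generates synthetic recovery curves by simulating the
*bleached* molecules (simulating the unbleached reservoir would require an
unbounded domain). The steps:

1. **Time step.** $\Delta t = \tau_{1/2}/1000$, using the combined
   half-recovery time, so the step stays small relative to the fastest
   recovery mechanism even at high flow or shear. The lattice spacing
   follows the 3D diffusion law, $L = \sqrt{6 D \Delta t}$.
2. **Initialization.** A regular lattice with spacing $L$ spans
   $\pm 2\omega_r$ in x, y and $\pm 2\omega_z$ in z. Candidates at the nodes
   are accepted with the bleach probability
   $p_{bl} = 1 - \exp[-\beta\, e^{-4(x^2+y^2)/\omega_r^2 - 4z^2/\omega_z^2}]$
   until exactly `n_molecules` (default 20,000) have been accepted. Sweeps
   are processed in randomized node order (realized by uniform node
   sampling), so truncating the last sweep introduces no spatial bias.
   Node occupancy is unconstrained.
3. **Walk.** Each step every molecule moves $\pm L$ along one of the six
   axis directions, then receives the deterministic shear-flow displacement
   $(v_0 + \gamma z_{new})\Delta t$ along x, with $z_{new}$ its z-coordinate
   after the random step. No boundary conditions: molecules leave the
   initialization region freely.
4. **Fluorescence.** The missing fluorescence of the bleached ensemble is
   the summed two-photon monitor profile,
   $F_{bl}(t) = \sum_i e^{-4(x_i^2+y_i^2)/\omega_r^2 - 4z_i^2/\omega_z^2}$,
   and the recovery is $F(t) = F_0 - F_{bl}(t)$. The prebleach level is
   deduced from the initial ensemble via
   $F_0 = F_{bl}(0) / (1 - \mathrm{initial\_fraction}(\beta))$, which makes
   the recorded $F(0)/F_0$ exactly the model's $t = 0$ value.
5. **Noise.** Each point is multiplied by an independent factor of mean 1
   and relative SD `noise_fraction` (default 3%), constructed as
   $\mathrm{Poisson}(\lambda)/\lambda$ with
   $\lambda = \mathrm{round}(1/f^2) = 1111$ at $f = 0.03$. A Poisson variate
   with mean 1 cannot have a width of 0.03, so this is the natural
   Poisson-family construction with the stated mean and width.

The walk and the fluorescence recording run in compiled code driven by R's
own RNG stream, so a `sim_config(rng_seed=)` reproduces a curve bit for bit.

**Choices the source procedure leaves open.** The total simulated duration
is not prescribed; the default is 10 half-recovery times (10,000 steps),
after which recovery exceeds ~99% in all regimes we map, while keeping one
curve at 20,000 molecules to a few seconds of compute. Fluorescence is
recorded at every step by default, in the harnesses included: with 3%
multiplicative noise, a ten-fold coarser recording leaves the
four-parameter shear-flow fit underdetermined (fitted-D scatter grows by
an order of magnitude at moderate scaled shear), so coarser recording is a
configuration option, not a default. Recording density and duration are
echoed into the curve metadata.

**What the simulator does not emulate:** bleaching during monitoring,
triplet-state photophysics, detector dead time, anisotropic or hindered
diffusion, and any flow profile beyond the linear shear $v_x = v_0 +
\gamma z$. Agreement of fits on simulated data therefore demonstrates
correctness of the estimation pipeline under the model's own assumptions,
not robustness to real-tissue artifacts.

## Seeding and fitting

Fits minimize $\sum_k [F_k - F_0\, m(t_k)]^2$ with a Levenberg-Marquardt
optimizer (`minpack.lm::nls.lm`), with $F_0$ fixed at its measured (or
deduced) value, residuals unweighted, and a numerically differenced
Jacobian. Relative tolerances are $10^{-10}$ and the iteration cap is the
optimizer's ceiling of 1024.

Seed values follow the published recipe:

* $\beta$: invert the 10-term $t=0$ fraction against the first post-bleach
  data point (optionally an average of the first k points).
* $\tau_D$: the half-recovery time $\tau_H$ of the curve, located by the
  closest-data-point rule (earliest point under ties). An optional moving
  average can pre-filter noisy curves; the raw rule is the default.
* $\tau_v$: from the half-recovery constant of the flow-dominated limit in
  $x' = (t/\tau_v)^2$ coordinates. Independent evaluation gives
  $x'_{1/2} = 0.3635$ at $\beta = 0.6$, consistent with the published
  rounded constant 0.3625. Because $x'$ is a *squared* time ratio, the
  substitution implies $\tau_v^{seed} = \tau_H/\sqrt{x'_{1/2}}$; the printed
  recipe divides by $x'_{1/2}$ itself. Both modes are provided
  (`seed_tau_v(mode=)`); the mathematically consistent square-root mode is
  the default. Since these are optimizer seeds, the choice moves the start
  point by less than a factor of two and does not change converged fits in
  the accurate region.
* $\tau_\gamma$: the printed constant is 0.145
  ($\tau_\gamma^{seed} = \tau_H/0.145$). Root-finding on the
  shear-dominated limit gives a half-recovery point of 0.374 in
  $(t/\tau_\gamma)^2$ coordinates (or 11.8 if the substitution absorbs
  $R$) — neither reproduces 0.145, and the substitution behind that
  constant is not documented. The package therefore defaults to the
  paper-literal constant and offers a `"derived"` mode that computes the
  constant by root-finding at the fitted $\beta$ and the actual $R$,
  recording in the result which mode was used.

Free parameters are fitted on their natural scale, with positivity
enforced by tiny positive floors ($10^{-6}$ for $\beta$, $10^{-12}$ s for
the times) in the bounded trust-region variant of the optimizer. A log
reparametrization was evaluated and discarded: on noisy curves whose
likelihood is nearly flat in one parameter direction (high flow or shear),
the log scale lets the optimizer traverse decades in a few steps and
strands distinctly more replicates in extreme-parameter local minima —
profiled at representative grid cells, it produced occasional
fitted-diffusion collapses to zero or runaway overestimates that the
natural scale avoids, while both scales agree wherever the fit is well
conditioned. A parameter may be fixed instead of bounded, e.g. $\tau_v$
and $\tau_\gamma$ when flow and shear are measured independently. Two
safeguards make bounded fits robust on high-shear curves, where the
recipe's $\tau_D$ seed (the half-recovery time) can lie decades below the
bounded box: a seed that violates its bounds starts at the geometric
midpoint of the box instead of its edge, and a fit that terminates on a
bound is retried once from the mid-box start, keeping the lower-SSR
solution. Both were adopted after profiling showed edge-terminated fits
with distinctly worse residuals than the interior minimum — an optimizer
stall, not a feature of the data. `beta` always carries a wide ceiling at 12, the series
stability bound, far above physical bleach depths. Non-convergence is
reported (`converged = FALSE`), never thrown.

## The evaluation harness

`run_sweep()` maps accuracy over a $(v_s, \gamma_s)$ grid: each replicate
reconstructs $(v_0, \gamma)$ from the scaled coordinates at `D_in` (default
60 um^2/s, a typical FITC-BSA value), simulates a noisy curve, fits every
requested model to the *same* curve, and records
$D_{fit} = \omega_r^2/8\hat\tau_D$. The accuracy metric is
$[\ln(D_{fit}/D_{in})]^2$ — symmetric in the ratio, zero at truth, ~5.3 at a
factor of ten either way. Per-replicate seeds are drawn from a deterministic
table derived from the base seed, so any cell of a sweep is reproducible in
isolation (`rerun_sweep_cell()`) and the sweep is order-independent under
parallel execution.

`table1_scenarios()` packages the three a-priori-knowledge regimes at a
single grid point: all four parameters free and unbounded; all four bounded
to a factor of ten around truth; and $\tau_v$, $\tau_\gamma$ fixed at truth.
The same replicate curves are reused across regimes.

In scaled coordinates the simulation is exactly scale-invariant: changing
`D_in` at fixed $(v_s, \gamma_s)$ rescales time and the lattice but leaves
the dimensionless trajectory distribution unchanged, which is why
`collapse_by_scaling()` can require ratio curves at different `D_in` to
overlay within statistical error.

### Problem sizes used by the shipped tests

The published accuracy maps rest on 34,560 simulations (27 x 64 grid, 20
replicates); that is not a sensible regression-test size. The package's own
verification uses the full per-curve conditions (20,000 molecules, 3%
noise) but reduced designs: the two tabulated scenario points at 20
replicates each; regional spot checks of the accuracy contours at
representative cells with 10 replicates; six-point simulator-vs-model
oracle comparisons on noiseless curves; and a three-decade
scaling-collapse check at reduced replication. Unit tests use smaller
ensembles (hundreds to thousands of molecules), scaling the Monte Carlo
error budget as $1/\sqrt{n}$.

## Known limitations

* Where flow or shear strongly dominates, the diffusion signal is a
  percent-level perturbation of the recovery and $D_{fit}$ is intrinsically
  noisy; bounded fits can terminate on a bound, and unbounded ones can
  collapse or run away. This interacts with the simulated duration: at 10
  combined half-recovery times, a curve at $v_s = 10$ spans only
  $0.9\,\tau_D$, truncating the late diffusive tail that identifies $D$, so
  the reliable region of the unbounded shear-flow fit measured at this
  desk-scale duration is narrower (roughly $v_s \lesssim$ a few,
  $\gamma_s \lesssim$ a few) than what cluster-scale simulations with
  longer curves can support. Fixing $\tau_v$ and $\tau_\gamma$, or bounding
  the parameters, restores accuracy at far more extreme coordinates (the
  tabulated scenarios at $\gamma_s \approx 19$ and $40$). The harness
  reports all of this honestly — it is the red region of the accuracy maps
  and the large scenario SEMs.
* The lattice walk's displacement distribution is exact only in its first
  two moments per step; agreement with the closed-form models is at the
  Monte Carlo error level (~1% of $F/F_0$ at 20,000 molecules), not exact.
* No uncertainty quantification beyond residual norms and across-replicate
  SEMs; no multistart/global optimization.
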