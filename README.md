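# mpfrap

Multiphoton fluorescence recovery after photobleaching (MPFRAP) extracts
diffusion coefficients of fluorescently tagged molecules from the
fluorescence recovery that follows a brief, focused two-photon bleach
pulse. Classical fitting models assume pure diffusion, or diffusion plus
uniform flow. In capillaries, microfluidic channels and most flowing
biological media, however, the flow is laminar *shear* flow — the x-velocity
varies linearly along the optical axis, `vx = v0 + gamma * z` — and models
that ignore the shear term return systematically wrong diffusion
coefficients once the scaled shear rate is appreciable.

This package implements, for users of point-bleach MPFRAP:

* the three closed-form recovery models for a 3D Gaussian two-photon focal
  volume — **diffusion**, **diffusion–convection**, and
  **diffusion + shear flow** — as alternating series in the bleach depth
  `beta` and the characteristic times `tau_D = omega_r^2/8D`,
  `tau_v = omega_r/v0`, `tau_gamma = 1/gamma`;
* a **lattice Monte Carlo simulator** of bleached-molecule transport
  (rejection-sampled initial ensemble, six-direction random walk with a
  shear-biased x-displacement, missing-fluorescence bookkeeping,
  Poisson-derived multiplicative noise) that generates realistic recovery
  curves with known ground truth;
* a **seeded Levenberg–Marquardt fitting pipeline** (positivity-constrained
  parameters, optional bounds or fixed parameters, published seeding
  recipe) that extracts `D = omega_r^2 / (8 tau_D)` from a recovery curve;
* an **evaluation harness** mapping fit accuracy over the dimensionless
  scaled-velocity / scaled-shear plane (`vs = tau_D/tau_v`,
  `gs = tau_D/tau_gamma`) with the symmetric accuracy metric
  `[ln(D_fit/D_in)]^2`, plus the a-priori-knowledge scenario table.

## Worked example

Simulate a noisy recovery curve at scaled shear `gs = 1` and refit it with
the shear-flow model:

```r
library(mpfrap)

fv <- focal_volume()                       # NA-0.8: omega_r 0.404, omega_z 2.27 um
tp <- transport_from_scaled(fv, D = 60, vs = 0, gs = 1)
cfg <- sim_config(tp, fv = fv, beta = 0.6, n_molecules = 20000, rng_seed = 1)
curve <- simulate_recovery(cfg)
curve
#> MPFRAP recovery curve: 10001 points, t in [0, 0.0017] s, F0 = 36737

fit_curve(curve, fit_options("shear_flow"), fv)
#> MPFRAP shear_flow fit: D_hat = 35.24 um^2/s (tau_D = 0.0005789 s, beta = 0.5885)
#>   tau_v = 0.001334 s
#>   tau_gamma = 0.0002999 s
#>   residual norm 1.149e+10 after 32 iterations; converged: TRUE

fit_curve(curve, fit_options("diffusion"), fv)
#> MPFRAP diffusion fit: D_hat = 247 um^2/s (tau_D = 8.26e-05 s, beta = 0.7529)
#>   residual norm 1.188e+10 after 7 iterations; converged: TRUE
```

The input shear rate is recovered well: the fitted `tau_gamma = 3.0e-4 s`
matches the simulated `1/gamma = tau_D/gs = 3.4e-4 s`. The fitted diffusion
coefficient of the shear-flow model (`35.2` vs the input `60 um^2/s`) shows
the genuine single-replicate spread of a three-transport-parameter fit on a
3%-noise curve at equal shear and diffusion rates — across seeds it
scatters between roughly 30 and 80, centred near the truth, which is why
the evaluation harness averages 20 replicates per condition. The
diffusion-only fit on the same curve is not scattered but systematically
wrong (`247`, a factor 4.1): with no shear term, all shear-driven recovery
is booked as diffusion. Fluorescence is in arbitrary units, so `F0` and the
residual norms have no absolute meaning.

Accuracy over a grid, and the knowledge-regime table at one point:

```r
sw <- run_sweep(sweep_spec(vs_grid = c(0, 0.5), gs_grid = c(0.1, 1, 10),
                           reps = 20, base_seed = 1))
sw$summary   # mean D_fit/D_in, SEM, accuracy metric per model and cell

table1_scenarios(vs = 0.0016, gs = 19.31, reps = 20, base_seed = 1)
```

A thin command-line interface wraps the same functions:

```sh
exec/mpfrap simulate --D 60 --gs 1 --seed 1 --out curve.csv
exec/mpfrap fit --curve curve.csv --model shear_flow --out fit.json
exec/mpfrap metric --dfit 600 --din 60
```

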