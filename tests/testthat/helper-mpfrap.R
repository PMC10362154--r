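# Shared fixtures for the test suite. Simulations used in unit tests are
# deliberately small (hundreds to thousands of molecules, coarse recording);
# the acceptance tests run the full study conditions.

na08 <- focal_volume()  # omega_r = 0.404 um, omega_z = 2.27 um (NA 0.8)

# independent partial-sum oracle for the t = 0 recovery fraction
oracle_initial_fraction <- function(beta, N = 200) {
  n <- 0:N
  sum((-beta)^n / factorial(n) * (1 + n)^(-1.5))
}

# small noiseless simulated curve for fitting tests
small_sim_curve <- function(vs = 0, gs = 0, n_molecules = 5000L,
                            noise = 0, seed = 1L, record_every = 20L,
                            D = 60, beta = 0.6) {
  tp <- transport_from_scaled(na08, D, vs, gs)
  cfg <- sim_config(tp, fv = na08, beta = beta, n_molecules = n_molecules,
                    noise_fraction = noise, record_every = record_every,
                    rng_seed = seed)
  simulate_recovery(cfg)
}

# dense noiseless curve evaluated from a closed-form model
model_curve <- function(model, vs = 0, gs = 0, D = 60, beta = 0.6,
                        F0 = 1000, n_points = 500, half_times = 10) {
  tp <- transport_from_scaled(na08, D, vs, gs)
  ct <- characteristic_times(na08, tp)
  t <- seq(0, half_times * ct$tau_half, length.out = n_points)
  f <- switch(model,
    diffusion = model_diffusion(t, beta, ct$tau_D, na08$R),
    diffusion_convection =
      model_diffusion_convection(t, beta, ct$tau_D, ct$tau_v, na08$R),
    shear_flow = model_shear_flow(t, beta, ct$tau_D, ct$tau_v,
                                  ct$tau_gamma, na08$R))
  list(curve = recovery_curve(t, F0 * f, F0,
                              meta = list(omega_r = na08$omega_r,
                                          omega_z = na08$omega_z)),
       ct = ct, tp = tp)
}
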