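test_that("focal volume from optics matches the diffraction formulas", {
  fv <- focal_volume_from_optics(0.780, 0.8, 1.33)
  expect_equal(fv$omega_r, 2.6 * 0.780 / (2 * pi * 0.8), tolerance = 1e-12)
  expect_equal(fv$omega_z, 8.8 * 1.33 * 0.780 / (2 * pi * 0.8^2),
               tolerance = 1e-12)
  expect_equal(fv$omega_r, 0.4036, tolerance = 2e-3)
  expect_equal(fv$omega_z, 2.268, tolerance = 2e-3)
  expect_equal(fv$R, fv$omega_z^2 / fv$omega_r^2, tolerance = 1e-12)

  # doubling NA halves omega_r and quarters omega_z
  fv2 <- focal_volume_from_optics(0.780, 1.2, 1.33)
  fv1 <- focal_volume_from_optics(0.780, 0.6, 1.33)
  expect_equal(fv2$omega_r / fv1$omega_r, 0.5, tolerance = 1e-12)
  expect_equal(fv2$omega_z / fv1$omega_z, 0.25, tolerance = 1e-12)

  expect_error(focal_volume_from_optics(0, 0.8), "wavelength")
  expect_error(focal_volume_from_optics(0.78, 1.5, 1.33), "na")
  expect_error(focal_volume(-1, 2), "omega_r")
})

test_that("characteristic times obey the reciprocal combination rule", {
  fv <- focal_volume(0.404, 2.27)
  ct <- characteristic_times(fv, transport_params(D = 60))
  expect_equal(ct$tau_D, 0.404^2 / 480, tolerance = 1e-12)
  expect_equal(ct$tau_D, 3.400e-4, tolerance = 1e-3)
  expect_identical(ct$tau_v, Inf)
  expect_identical(ct$tau_gamma, Inf)
  expect_equal(ct$tau_half, ct$tau_D, tolerance = 1e-12)

  # vs = 1 (equal diffusive and convective rates) halves the combined time
  v0 <- fv$omega_r / ct$tau_D
  ct2 <- characteristic_times(fv, transport_params(D = 60, v0 = v0))
  expect_equal(ct2$tau_v, ct2$tau_D, tolerance = 1e-12)
  expect_equal(ct2$tau_half, ct2$tau_D / 2, tolerance = 1e-12)

  ct3 <- characteristic_times(fv, transport_params(D = 60,
                                                   gamma = 19.31 / ct$tau_D))
  expect_equal(ct3$tau_gamma, ct$tau_D / 19.31, tolerance = 1e-12)
})

test_that("scaled coordinates round-trip through the inverse map", {
  fv <- focal_volume(0.404, 2.27)
  sc0 <- scaled_coordinates(fv, transport_params(D = 60))
  expect_identical(sc0$vs, 0)
  sc <- scaled_coordinates(fv, transport_params(D = 60, gamma = 1000))
  expect_equal(sc$gs, 1000 * 0.404^2 / 480, tolerance = 1e-12)

  tp <- transport_from_scaled(fv, D = 60, vs = 0.2031, gs = 40.1028)
  sc2 <- scaled_coordinates(fv, tp)
  expect_equal(sc2$vs, 0.2031, tolerance = 1e-12)
  expect_equal(sc2$gs, 40.1028, tolerance = 1e-12)
})

test_that("bleach probability has the Gaussian-squared profile", {
  fv <- focal_volume(0.404, 2.27)
  expect_equal(bleach_probability(0, 0, 0, 0.6, fv), 1 - exp(-0.6),
               tolerance = 1e-12)
  expect_equal(bleach_probability(100, 0, 0, 0.6, fv), 0, tolerance = 1e-12)
  expect_identical(bleach_probability(0.3, -0.1, 0.5, 0, fv), 0)
  # radial and axial symmetry, bounded by the on-axis maximum
  p <- bleach_probability(c(0.2, -0.2, 0), c(0, 0, 0.2), c(0.5, -0.5, 0.5),
                          0.6, fv)
  expect_equal(p[1], p[2], tolerance = 1e-15)
  expect_equal(p[1], p[3], tolerance = 1e-15)
  expect_true(all(p <= 1 - exp(-0.6)))
})

test_that("initial fraction matches the independent partial-sum oracle", {
  expect_identical(initial_fraction(0), 1)
  expect_equal(initial_fraction(0.6), oracle_initial_fraction(0.6),
               tolerance = 1e-10)
  expect_equal(initial_fraction(0.6), 0.8184511, tolerance = 1e-6)
  betas <- seq(0.1, 2, by = 0.1)
  vals <- vapply(betas, initial_fraction, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(initial_fraction(50), "truncation-safe")
})

test_that("recovery models are normalized and reduce along the model chain", {
  fv <- focal_volume(0.404, 2.27)
  ct <- characteristic_times(fv, transport_params(60, 300, 1000))
  t <- c(0, 10^seq(-5, 0, length.out = 40))

  m19 <- model_shear_flow(t, 0.6, ct$tau_D, ct$tau_v, ct$tau_gamma, fv$R)
  expect_true(all(m19 > 0 & m19 <= 1))
  expect_equal(m19[1], initial_fraction(0.6), tolerance = 1e-12)
  expect_equal(model_shear_flow(1e6 * ct$tau_D, 0.6, ct$tau_D, ct$tau_v,
                                ct$tau_gamma, fv$R), 1, tolerance = 1e-4)

  # tau_gamma -> Inf reduces to diffusion-convection, additionally
  # tau_v -> Inf to pure diffusion (separately coded series)
  m5 <- model_diffusion_convection(t, 0.6, ct$tau_D, ct$tau_v, fv$R)
  m19_nog <- model_shear_flow(t, 0.6, ct$tau_D, ct$tau_v, Inf, fv$R)
  expect_equal(m19_nog, m5, tolerance = 1e-12)
  m4 <- model_diffusion(t, 0.6, ct$tau_D, fv$R)
  m19_diff <- model_shear_flow(t, 0.6, ct$tau_D, Inf, Inf, fv$R)
  expect_equal(m19_diff, m4, tolerance = 1e-12)
  m5_nov <- model_diffusion_convection(t, 0.6, ct$tau_D, Inf, fv$R)
  expect_equal(m5_nov, m4, tolerance = 1e-12)

  # beta = 0: no bleach, flat unity recovery
  expect_equal(model_diffusion(t, 0, ct$tau_D, fv$R), rep(1, length(t)),
               tolerance = 1e-15)

  # all models agree at t = 0 with the initial fraction
  expect_equal(m4[1], initial_fraction(0.6), tolerance = 1e-12)
  expect_equal(m5[1], initial_fraction(0.6), tolerance = 1e-12)
})

test_that("series truncation is converged at the default order", {
  fv <- focal_volume(0.404, 2.27)
  ct <- characteristic_times(fv, transport_params(60, 100, 500))
  t <- 10^seq(-5, 0, length.out = 20)
  for (beta in c(0.3, 0.6, 1)) {
    adaptive <- model_shear_flow(t, beta, ct$tau_D, ct$tau_v, ct$tau_gamma, fv$R)
    forced <- model_shear_flow(t, beta, ct$tau_D, ct$tau_v, ct$tau_gamma,
                               fv$R, n_terms = 60L)
    expect_lt(max(abs(adaptive - forced)), 1e-10)
  }
})

test_that("flow and shear accelerate recovery monotonically", {
  fv <- focal_volume(0.404, 2.27)
  tau_D <- 0.404^2 / 480
  t <- tau_D * c(0.3, 1, 3)

  # decreasing tau_v (faster flow) speeds recovery at fixed t
  tau_vs <- tau_D * c(10, 3, 1, 0.3)
  for (ti in t) {
    vals <- vapply(tau_vs, function(tv)
      model_diffusion_convection(ti, 0.6, tau_D, tv, fv$R), numeric(1))
    expect_true(all(diff(vals) > 0))
  }

  # half-recovery time of the shear model is non-increasing in gamma
  half_time <- function(gamma) {
    ct <- characteristic_times(fv, transport_params(60, 0, gamma))
    f0 <- initial_fraction(0.6)
    uniroot(function(tt) model_shear_flow(tt, 0.6, ct$tau_D, ct$tau_v,
                                          ct$tau_gamma, fv$R) - (f0 + 1) / 2,
            c(1e-9, 1), tol = 1e-12)$root
  }
  ht <- vapply(c(0, 500, 2000, 10000), half_time, numeric(1))
  expect_true(all(diff(ht) < 0))
})

test_that("flow-dominated limit has the documented half-recovery constant", {
  expect_equal(model_flow_dominated(0, 0.6), initial_fraction(0.6),
               tolerance = 1e-12)
  expect_equal(model_flow_dominated(1e6, 0.6), 1, tolerance = 1e-10)
  xp <- seq(0, 2, length.out = 50)
  expect_true(all(diff(model_flow_dominated(xp, 0.6)) > 0))

  # bisection oracle for the half-recovery point in x' coordinates
  f0 <- oracle_initial_fraction(0.6)
  half <- (f0 + 1) / 2
  lo <- 0.01; hi <- 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (model_flow_dominated(mid, 0.6) < half) lo <- mid else hi <- mid
  }
  expect_equal(flow_half_xprime(0.6), (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(flow_half_xprime(0.6), 0.3635, tolerance = 1e-3)
})

test_that("shear-dominated limit is increasing with a root-findable midpoint", {
  R <- 2.27^2 / 0.404^2
  expect_equal(model_shear_dominated(0, 0.6, R), initial_fraction(0.6),
               tolerance = 1e-12)
  expect_equal(model_shear_dominated(1e6, 0.6, R), 1, tolerance = 1e-4)
  u <- seq(0, 3, length.out = 50)
  expect_true(all(diff(model_shear_dominated(u, 0.6, R)) > 0))

  x_half <- shear_half_const(0.6, R)
  half <- (oracle_initial_fraction(0.6) + 1) / 2
  expect_equal(model_shear_dominated(sqrt(x_half), 0.6, R), half,
               tolerance = 1e-9)
})
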