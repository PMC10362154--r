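test_that("lattice spacing follows the 3D diffusion law", {
  expect_equal(lattice_spacing(60, 1e-6), sqrt(3.6e-4), tolerance = 1e-12)
  # quadrupling dt doubles the step
  expect_equal(lattice_spacing(60, 4e-6) / lattice_spacing(60, 1e-6), 2,
               tolerance = 1e-12)
  expect_error(lattice_spacing(0, 1e-6), "'D'")
})

test_that("initial ensemble samples the bleach probability field", {
  tp <- transport_params(D = 60)
  cfg <- sim_config(tp, fv = na08, beta = 0.6, n_molecules = 4000L,
                    noise_fraction = 0, rng_seed = 101)
  set.seed(cfg$rng_seed)
  e <- populate_bleached(cfg)
  expect_identical(nrow(e), 4000L)
  expect_identical(colnames(e), c("x", "y", "z"))
  expect_true(all(abs(e[, "x"]) <= 2 * na08$omega_r + 1e-9))
  expect_true(all(abs(e[, "z"]) <= 2 * na08$omega_z + 1e-9))

  # independent oracle: continuous rejection sampling from the same density
  set.seed(777)
  zs <- numeric(0)
  while (length(zs) < 4000) {
    x <- runif(50000, -2 * na08$omega_r, 2 * na08$omega_r)
    y <- runif(50000, -2 * na08$omega_r, 2 * na08$omega_r)
    z <- runif(50000, -2 * na08$omega_z, 2 * na08$omega_z)
    keep <- runif(50000) < bleach_probability(x, y, z, 0.6, na08)
    zs <- c(zs, z[keep])
  }
  ks <- suppressWarnings(stats::ks.test(e[, "z"], zs[1:4000]))
  expect_gt(ks$p.value, 0.001)
})

test_that("random walk reproduces the diffusion law and drift bias", {
  n <- 20000L
  D <- 60
  dt <- 1e-6
  L <- lattice_spacing(D, dt)
  e0 <- matrix(0, n, 3)

  # pure diffusion: MSD after k steps = 6 D k dt within sampling error
  set.seed(5)
  e <- e0
  k <- 100L
  tp0 <- transport_params(D = D)
  for (i in seq_len(k)) e <- step_ensemble(e, L, tp0, dt)
  msd <- rowSums(e^2)
  se <- sd(msd) / sqrt(n)
  expect_lt(abs(mean(msd) - 6 * D * k * dt), 3 * se)
  # per-axis means ~ 0
  expect_lt(abs(mean(e[, 1])), 3 * L * sqrt(k / 3) / sqrt(n))

  # uniform flow: deterministic mean drift v0 * k * dt
  set.seed(6)
  e <- e0
  tpv <- transport_params(D = D, v0 = 500)
  for (i in seq_len(20)) e <- step_ensemble(e, L, tpv, dt)
  expect_lt(abs(mean(e[, 1]) - 500 * 20 * dt), 3 * L * sqrt(20 / 3) / sqrt(n))

  # shear antisymmetry: symmetric initial z gives ~zero net x drift,
  # but molecules above/below the mid-plane drift in opposite directions
  set.seed(7)
  ez <- cbind(0 * (1:n), 0 * (1:n), rep(c(-1, 1), length.out = n))
  tpg <- transport_params(D = D, gamma = 5000)
  e1 <- step_ensemble(ez, L, tpg, dt)
  drift <- e1[, 1] - 5000 * e1[, 3] * dt
  expect_true(all(abs(drift) <= L + 1e-12))  # only the lattice step remains
  expect_lt(abs(mean(e1[, 1])), 3 * (L + 5000 * dt) / sqrt(n))

  # molecule count conserved
  expect_identical(nrow(e1), n)
})

test_that("missing fluorescence sums the two-photon monitor profile", {
  e1 <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(missing_fluorescence(e1, na08), 1, tolerance = 1e-15)
  efar <- matrix(c(5 * na08$omega_r, 0, 0), 1, 3)
  expect_lt(missing_fluorescence(efar, na08), 1e-40)
  e2 <- rbind(c(0, 0, 0), c(na08$omega_r, 0, 0))
  expect_equal(missing_fluorescence(e2, na08), 1 + exp(-4), tolerance = 1e-12)
})

test_that("prebleach level is deduced from the initial missing fluorescence", {
  expect_equal(deduce_F0(100, 0.6), 100 / (1 - oracle_initial_fraction(0.6)),
               tolerance = 1e-9)
  expect_equal(deduce_F0(100, 0.6), 550.8, tolerance = 1e-3)
  # F0 always exceeds the missing fluorescence, and deeper bleaches
  # account for more of the prebleach signal
  expect_gt(deduce_F0(100, 0.3), 100)
  expect_gt(deduce_F0(100, 0.3), deduce_F0(100, 3))
  expect_error(deduce_F0(100, 0), "indeterminate")
})

test_that("multiplicative noise has the configured relative width and unit mean", {
  flat <- recovery_curve(seq(0, 1, length.out = 1e5),
                         rep(100, 1e5), 100)
  expect_identical(apply_noise(flat, 0), flat)
  set.seed(42)
  noisy <- apply_noise(flat, 0.03)
  factors <- noisy$F / 100
  expect_equal(sd(factors), 0.03, tolerance = 0.04)
  expect_equal(mean(factors), 1, tolerance = 3 * 0.03 / sqrt(1e5))
})

test_that("simulated recovery is deterministic and matches the closed form", {
  c1 <- small_sim_curve(vs = 0, gs = 0, seed = 9)
  c2 <- small_sim_curve(vs = 0, gs = 0, seed = 9)
  expect_identical(c1, c2)
  c3 <- small_sim_curve(vs = 0, gs = 0, seed = 10)
  expect_false(identical(c1$F, c3$F))

  # F(0)/F0 equals the initial fraction exactly by the F0 construction
  expect_equal(c1$F[1] / c1$F0, initial_fraction(0.6), tolerance = 1e-12)

  # noiseless curve tracks the diffusion model; at 5000 molecules the
  # Monte Carlo error budget is 3% * sqrt(20000/5000)
  ct <- characteristic_times(na08, transport_params(D = 60))
  mod <- model_diffusion(c1$times, 0.6, ct$tau_D, na08$R)
  expect_lt(max(abs(c1$F / c1$F0 - mod) / mod), 0.06)

  # with shear: gs = 1
  c4 <- small_sim_curve(vs = 0, gs = 1, seed = 11)
  ct4 <- characteristic_times(na08, transport_from_scaled(na08, 60, 0, 1))
  mod4 <- model_shear_flow(c4$times, 0.6, ct4$tau_D, ct4$tau_v,
                           ct4$tau_gamma, na08$R)
  expect_lt(max(abs(c4$F / c4$F0 - mod4) / mod4), 0.06)

  # metadata carries the provenance needed for replay
  expect_identical(c4$meta$seed, 11L)
  expect_equal(c4$meta$gs, 1, tolerance = 1e-12)
})

test_that("curve files round-trip bit-exactly through the text format", {
  curve <- small_sim_curve(vs = 0.5, gs = 0, n_molecules = 500L,
                           noise = 0.03, seed = 3, record_every = 100L)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_recovery_curve(curve, p1)
  back <- read_recovery_curve(p1)
  write_recovery_curve(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$times, curve$times, tolerance = 0)
  expect_equal(back$F, curve$F, tolerance = 0)
  expect_equal(back$F0, curve$F0, tolerance = 0)

  expect_error(read_recovery_curve(tempfile()), "no such file")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("# F0=10", "time_s,fluorescence", "0,1,garbage,"), bad)
  expect_error(read_recovery_curve(bad), "malformed|columns")
})
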