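# Lattice Monte Carlo simulator of MPFRAP recovery curves: bleached-molecule
# ensembles undergoing diffusion, uniform flow, and linear shear.

#' Simulation configuration
#'
#' Bundles the focal volume, transport parameters, bleach depth and numerical
#' settings of one Monte Carlo recovery simulation. The defaults are the
#' study conditions used throughout the accuracy sweeps: 20,000 bleached
#' molecules, a time step of 1/1000 of the combined half-recovery time
#' (`1/tau_half = 1/tau_D + 1/tau_v + 1/tau_gamma`), an initialization
#' lattice spanning `-2 omega_r .. 2 omega_r` in x and y and
#' `-2 omega_z .. 2 omega_z` in z, 3% multiplicative Poisson-derived noise,
#' and a total simulated duration of 10 half-recovery times.
#'
#' @param tp A [transport_params()].
#' @param fv A [focal_volume()]; default the NA-0.8 volume.
#' @param beta Bleach depth parameter (default 0.6).
#' @param n_molecules Number of bleached molecules (default 20000).
#' @param steps_per_half_time Steps per combined half-recovery time
#'   (default 1000; the time step is `tau_half / steps_per_half_time`).
#' @param total_half_times Simulated duration in units of `tau_half`
#'   (default 10).
#' @param lattice_extent_r,lattice_extent_z Half-extent of the initialization
#'   lattice in multiples of `omega_r` (x, y) and `omega_z` (z); default 2.
#' @param noise_fraction Relative multiplicative noise (default 0.03; 0 for
#'   noiseless curves).
#' @param record_every Record the fluorescence every this many steps
#'   (default 1).
#' @param rng_seed Integer seed driving initialization, walk and noise;
#'   `NULL` leaves the RNG state untouched.
#' @return Object of class `sim_config`. Derived fields `times` (a
#'   [characteristic_times()]), `dt`, `n_steps` and the lattice spacing `L`
#'   are precomputed.
#' @export
#' @examples
#' cfg <- sim_config(transport_params(D = 60), n_molecules = 1000, rng_seed = 1)
#' cfg$dt
sim_config <- function(tp, fv = focal_volume(), beta = 0.6,
                       n_molecules = 20000L, steps_per_half_time = 1000L,
                       total_half_times = 10, lattice_extent_r = 2,
                       lattice_extent_z = 2, noise_fraction = 0.03,
                       record_every = 1L, rng_seed = NULL) {
  stopifnot(inherits(tp, "transport_params"), inherits(fv, "focal_volume"))
  .check_beta(beta)
  if (n_molecules < 1) stop("'n_molecules' must be positive", call. = FALSE)
  if (steps_per_half_time < 1) stop("'steps_per_half_time' must be positive", call. = FALSE)
  if (total_half_times <= 0) stop("'total_half_times' must be positive", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 0.5)
    stop("'noise_fraction' must lie in [0, 0.5]", call. = FALSE)
  if (record_every < 1) stop("'record_every' must be >= 1", call. = FALSE)
  ct <- characteristic_times(fv, tp)
  dt <- ct$tau_half / steps_per_half_time
  structure(
    list(fv = fv, tp = tp, beta = beta,
         n_molecules = as.integer(n_molecules),
         steps_per_half_time = as.integer(steps_per_half_time),
         total_half_times = total_half_times,
         lattice_extent_r = lattice_extent_r,
         lattice_extent_z = lattice_extent_z,
         noise_fraction = noise_fraction,
         record_every = as.integer(record_every),
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
         times = ct, dt = dt,
         n_steps = as.integer(round(total_half_times * steps_per_half_time)),
         L = lattice_spacing(tp$D, dt)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  sc <- scaled_coordinates(x$fv, x$tp)
  cat(sprintf(paste0("MPFRAP simulation config: %d molecules, beta = %.3g, ",
                     "vs = %.4g, gs = %.4g\n  dt = %.4g s (%d steps), ",
                     "L = %.4g um, noise = %.3g\n"),
              x$n_molecules, x$beta, sc$vs, sc$gs, x$dt, x$n_steps, x$L,
              x$noise_fraction))
  invisible(x)
}

#' Lattice spacing from the 3D diffusion law
#'
#' `L = sqrt(6 D dt)`, so a walk of steps of length `L` along one of six
#' directions reproduces `<r^2> = 6 D t`.
#'
#' @param D Diffusion coefficient (um^2/s, > 0).
#' @param dt Time step (s, > 0).
#' @return Step length in micrometres.
#' @export
lattice_spacing <- function(D, dt) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  sqrt(6 * D * dt)
}

#' Initial bleached-molecule ensemble
#'
#' Populates the initialization lattice (regular grid with spacing `L` over
#' the configured extents) with bleached molecules by rejection sampling
#' against the bleach probability field: a candidate at a node survives when
#' a uniform random number falls below [bleach_probability()]. Full-lattice
#' sweeps are processed in randomized node order and truncated at exactly
#' `n_molecules` acceptances, so the accepted density is proportional to the
#' bleach probability. There is no limit on occupancy per node.
#'
#' @param cfg A [sim_config()]. If `cfg$rng_seed` is set the caller
#'   ([simulate_recovery()]) is expected to have seeded the RNG.
#' @return Numeric matrix with `n_molecules` rows and columns `x`, `y`, `z`
#'   (micrometres).
#' @export
populate_bleached <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fv <- cfg$fv
  L <- cfg$L
  kr <- max(1L, floor(cfg$lattice_extent_r * fv$omega_r / L))
  kz <- max(1L, floor(cfg$lattice_extent_z * fv$omega_z / L))
  n_nodes_axis_r <- 2 * kr + 1
  n_nodes_axis_z <- 2 * kz + 1
  n_target <- cfg$n_molecules

  # Randomized sweep order over an enormous lattice is realized by drawing
  # node indices uniformly; duplicate candidates across sweeps are allowed.
  acc <- vector("list", 0L)
  n_acc <- 0L
  n_tried <- 0
  max_tried <- 5e8
  batch <- max(65536L, 4L * n_target)
  while (n_acc < n_target) {
    if (n_tried >= max_tried)
      stop(paste("bleach acceptance too low to populate the ensemble;",
                 "increase beta or shrink the lattice extents"), call. = FALSE)
    x <- (sample.int(n_nodes_axis_r, batch, replace = TRUE) - kr - 1L) * L
    y <- (sample.int(n_nodes_axis_r, batch, replace = TRUE) - kr - 1L) * L
    z <- (sample.int(n_nodes_axis_z, batch, replace = TRUE) - kz - 1L) * L
    keep <- runif(batch) < bleach_probability(x, y, z, cfg$beta, fv)
    n_tried <- n_tried + batch
    if (any(keep)) {
      acc[[length(acc) + 1L]] <- cbind(x = x[keep], y = y[keep], z = z[keep])
      n_acc <- n_acc + sum(keep)
    }
    if (n_acc > 0 && n_acc < n_target) {
      rate <- n_acc / n_tried
      batch <- as.integer(min(2e7, max(65536, 1.3 * (n_target - n_acc) / rate)))
    }
  }
  out <- do.call(rbind, acc)[seq_len(n_target), , drop = FALSE]
  out
}

#' Advance the ensemble by one lattice step
#'
#' Each molecule moves `+-L` along exactly one axis (uniform over the six
#' directions) and is then displaced along x by `(v0 + gamma * z_new) * dt`,
#' where `z_new` is its z-coordinate after the random step. The molecule
#' count is conserved; no boundary conditions are applied.
#'
#' @param e Ensemble matrix (columns `x`, `y`, `z`).
#' @param L Lattice step length (um).
#' @param tp A [transport_params()].
#' @param dt Time step (s).
#' @return The updated ensemble matrix.
#' @export
step_ensemble <- function(e, L, tp, dt) {
  stopifnot(is.matrix(e), ncol(e) == 3, inherits(tp, "transport_params"))
  .walk_record_cpp(e, 1L, L, tp$v0, tp$gamma, dt, 0L,
                   1, 1)$pos
}

#' Missing fluorescence of the bleached ensemble
#'
#' The two-photon monitor signal the bleached molecules would have emitted:
#' `sum_i exp(-4 (x_i^2 + y_i^2) / omega_r^2 - 4 z_i^2 / omega_z^2)`
#' (normalization constants set to 1; fluorescence is in arbitrary units).
#'
#' @param e Ensemble matrix (columns `x`, `y`, `z`).
#' @param fv A [focal_volume()].
#' @return Summed missing fluorescence (arbitrary units).
#' @export
missing_fluorescence <- function(e, fv) {
  stopifnot(is.matrix(e), ncol(e) == 3, inherits(fv, "focal_volume"))
  sum(exp(-4 * (e[, 1]^2 + e[, 2]^2) / fv$omega_r^2 -
            4 * e[, 3]^2 / fv$omega_z^2))
}

#' Prebleach fluorescence from the initial missing fluorescence
#'
#' Because only bleached molecules are simulated, the prebleach level is
#' deduced from the missing fluorescence at t = 0:
#' `F0 = Fbl(0) / (1 - initial_fraction(beta))`.
#'
#' @param Fbl_at_0 Missing fluorescence at t = 0 (arbitrary units, > 0).
#' @param beta Bleach depth parameter (> 0; at `beta = 0` nothing is bleached
#'   and the prebleach level is indeterminate).
#' @return Prebleach fluorescence `F0 > Fbl_at_0`.
#' @export
deduce_F0 <- function(Fbl_at_0, beta) {
  .check_beta(beta)
  if (beta == 0)
    stop("'beta' must be positive: with no bleaching F0 is indeterminate",
         call. = FALSE)
  if (Fbl_at_0 <= 0) stop("'Fbl_at_0' must be positive", call. = FALSE)
  Fbl_at_0 / (1 - initial_fraction(beta))
}

#' Recovery curve container
#'
#' A time-stamped fluorescence recovery: strictly increasing times starting
#' at the first post-bleach point `t = 0`, non-negative fluorescence in
#' arbitrary units, the prebleach level `F0`, and provenance metadata.
#'
#' @param times Times since the bleach (s), strictly increasing.
#' @param F Fluorescence (arbitrary units, >= 0), same length as `times`.
#' @param F0 Prebleach fluorescence (> 0).
#' @param meta Named list of provenance (seed, truth parameters, config echo).
#' @return Object of class `recovery_curve`.
#' @export
recovery_curve <- function(times, F, F0, meta = list()) {
  if (length(times) != length(F))
    stop("'times' and 'F' must have the same length", call. = FALSE)
  if (length(times) && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.numeric(F0) || length(F0) != 1L || !is.finite(F0) || F0 <= 0)
    stop("'F0' must be a single positive number", call. = FALSE)
  if (any(F < 0)) stop("fluorescence values must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times), F = as.numeric(F),
                 F0 = F0, meta = meta),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("MPFRAP recovery curve: %d points, t in [%.4g, %.4g] s, F0 = %.6g\n",
              length(x$times), min(x$times), max(x$times), x$F0))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Multiplicative Poisson-derived noise
#'
#' Multiplies each fluorescence value by an independent factor with mean 1
#' and relative standard deviation `noise_fraction`, constructed as
#' `Poisson(lambda) / lambda` with `lambda = round(1 / noise_fraction^2)`
#' (so 3% noise uses `lambda = 1111`). `noise_fraction = 0` is the identity.
#'
#' @param curve A [recovery_curve()].
#' @param noise_fraction Relative noise in `[0, 0.5]`.
#' @return The noisy curve.
#' @export
apply_noise <- function(curve, noise_fraction) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (noise_fraction < 0 || noise_fraction > 0.5)
    stop("'noise_fraction' must lie in [0, 0.5]", call. = FALSE)
  if (noise_fraction == 0) return(curve)
  lambda <- round(1 / noise_fraction^2)
  curve$F <- curve$F * rpois(length(curve$F), lambda) / lambda
  curve
}

#' Simulate one MPFRAP recovery curve
#'
#' Runs the full Monte Carlo pipeline: populate the bleached ensemble by
#' rejection sampling, deduce the prebleach level `F0` from the initial
#' missing fluorescence, advance the shear-biased random walk for
#' `total_half_times * steps_per_half_time` steps recording the missing
#' fluorescence every `record_every` steps, form
#' `F(t) = F0 - Fbl(t)`, and apply multiplicative noise. Deterministic for a
#' given `rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [recovery_curve()] whose metadata records the seed, truth
#'   transport parameters, focal volume and numerical settings. By the `F0`
#'   construction the recorded `F(0)/F0` equals
#'   `initial_fraction(beta)` exactly (before noise).
#' @export
#' @examples
#' cfg <- sim_config(transport_params(D = 60), n_molecules = 500,
#'                   record_every = 100L, noise_fraction = 0, rng_seed = 1)
#' curve <- simulate_recovery(cfg)
#' curve$F[1] / curve$F0 # = initial_fraction(0.6)
simulate_recovery <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  e <- populate_bleached(cfg)
  Fbl0 <- missing_fluorescence(e, cfg$fv)
  F0 <- deduce_F0(Fbl0, cfg$beta)
  res <- .walk_record_cpp(e, cfg$n_steps, cfg$L, cfg$tp$v0, cfg$tp$gamma,
                          cfg$dt, cfg$record_every,
                          cfg$fv$omega_r, cfg$fv$omega_z)
  times <- c(0, cfg$dt * seq(cfg$record_every, cfg$n_steps,
                             by = cfg$record_every))
  F <- F0 - c(Fbl0, res$fbl)
  F[F < 0] <- 0
  sc <- scaled_coordinates(cfg$fv, cfg$tp)
  meta <- list(seed = if (is.null(cfg$rng_seed)) NA_integer_ else cfg$rng_seed,
               D = cfg$tp$D, v0 = cfg$tp$v0, gamma = cfg$tp$gamma,
               vs = sc$vs, gs = sc$gs, beta = cfg$beta,
               omega_r = cfg$fv$omega_r, omega_z = cfg$fv$omega_z,
               n_molecules = cfg$n_molecules, dt = cfg$dt,
               n_steps = cfg$n_steps, record_every = cfg$record_every,
               noise_fraction = cfg$noise_fraction)
  curve <- recovery_curve(times, F, F0, meta)
  apply_noise(curve, cfg$noise_fraction)
}
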