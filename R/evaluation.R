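# Accuracy mapping of the three recovery models over scaled-velocity /
# scaled-shear parameter space, and the a-priori-knowledge scenarios.

#' Symmetric fit-accuracy metric
#'
#' `[ln(D_fit / D_in)]^2`: zero for a perfect fit, ~5.3 for a fitted
#' coefficient ten times too large or ten times too small. Symmetric under
#' ratio inversion, so underestimates and overestimates are displayed alike.
#'
#' @param D_fit Fitted diffusion coefficient(s) (> 0).
#' @param D_in Input (true) diffusion coefficient(s) (> 0).
#' @return The metric value(s).
#' @export
#' @examples
#' accuracy_metric(600, 60) # ~5.3
#' accuracy_metric(6, 60)   # same
accuracy_metric <- function(D_fit, D_in) {
  if (any(!is.finite(D_fit)) || any(!is.finite(D_in)) ||
      any(D_fit <= 0) || any(D_in <= 0))
    stop("'D_fit' and 'D_in' must be positive and finite", call. = FALSE)
  log(D_fit / D_in)^2
}

#' Sweep specification
#'
#' Defines a grid of scaled velocities and scaled shear rates, the number of
#' replicate simulations per grid point, the simulated conditions, and the
#' models to fit. Defaults are the study conditions: `D_in = 60` um^2/s,
#' `beta = 0.6`, the NA-0.8 focal volume, 3% noise, 20,000 molecules, 20
#' repetitions, fluorescence recorded at every step.
#'
#' @param vs_grid Scaled velocities (non-empty, >= 0).
#' @param gs_grid Scaled shear rates (non-empty, >= 0).
#' @param reps Replicates per grid point (>= 1; default 20).
#' @param D_in Input diffusion coefficient (um^2/s).
#' @param beta Bleach depth parameter.
#' @param fv A [focal_volume()].
#' @param models Subset of `c("diffusion", "diffusion_convection",
#'   "shear_flow")`; every model is fitted to the same simulated curves.
#' @param base_seed Base RNG seed; per-replicate seeds are derived
#'   deterministically from it so any cell can be reproduced in isolation.
#' @param n_molecules,record_every,noise_fraction,steps_per_half_time,total_half_times
#'   Simulation settings passed to [sim_config()].
#' @param jobs Parallel worker count for [run_sweep()] (forked workers;
#'   results are reduction-order independent).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(vs_grid, gs_grid, reps = 20L, D_in = 60, beta = 0.6,
                       fv = focal_volume(),
                       models = c("diffusion", "diffusion_convection",
                                  "shear_flow"),
                       base_seed = 1L, n_molecules = 20000L,
                       record_every = 1L, noise_fraction = 0.03,
                       steps_per_half_time = 1000L, total_half_times = 10,
                       jobs = 1L) {
  if (!length(vs_grid) || !length(gs_grid))
    stop("'vs_grid' and 'gs_grid' must be non-empty", call. = FALSE)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  structure(list(vs_grid = vs_grid, gs_grid = gs_grid,
                 reps = as.integer(reps), D_in = D_in, beta = beta, fv = fv,
                 models = models, base_seed = as.integer(base_seed),
                 n_molecules = as.integer(n_molecules),
                 record_every = as.integer(record_every),
                 noise_fraction = noise_fraction,
                 steps_per_half_time = as.integer(steps_per_half_time),
                 total_half_times = total_half_times,
                 jobs = as.integer(jobs)),
            class = "sweep_spec")
}

# Deterministic per-replicate seed table: cell index runs over
# expand.grid(vs, gs) row-wise, replicate index within cell.
.sweep_seeds <- function(spec) {
  n_cells <- length(spec$vs_grid) * length(spec$gs_grid)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$base_seed)
  matrix(sample.int(2147483646L, n_cells * spec$reps),
         nrow = n_cells, ncol = spec$reps)
}

.sweep_cells <- function(spec) {
  expand.grid(vs = spec$vs_grid, gs = spec$gs_grid,
              KEEP.OUT.ATTRS = FALSE)
}

# Simulate the replicate curve for one (cell, rep) and fit the requested
# models; pure function of (spec, cell, rep) via the derived seed table.
.sweep_unit <- function(spec, cell_idx, rep_idx, seeds = NULL) {
  if (is.null(seeds)) seeds <- .sweep_seeds(spec)
  cells <- .sweep_cells(spec)
  vs <- cells$vs[cell_idx]; gs <- cells$gs[cell_idx]
  tp <- transport_from_scaled(spec$fv, spec$D_in, vs, gs)
  cfg <- sim_config(tp, fv = spec$fv, beta = spec$beta,
                    n_molecules = spec$n_molecules,
                    steps_per_half_time = spec$steps_per_half_time,
                    total_half_times = spec$total_half_times,
                    noise_fraction = spec$noise_fraction,
                    record_every = spec$record_every,
                    rng_seed = seeds[cell_idx, rep_idx])
  curve <- simulate_recovery(cfg)
  rows <- lapply(spec$models, function(m) {
    fit <- tryCatch(fit_curve(curve, fit_options(model = m), spec$fv),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(model = m, vs = vs, gs = gs, rep = rep_idx,
                        D_fit = NA_real_, converged = FALSE,
                        metric = NA_real_))
    data.frame(model = m, vs = vs, gs = gs, rep = rep_idx,
               D_fit = fit$D_hat, converged = fit$converged,
               metric = accuracy_metric(fit$D_hat, spec$D_in))
  })
  do.call(rbind, rows)
}

#' Run an accuracy sweep
#'
#' For every `(vs, gs)` grid point and replicate: reconstruct the transport
#' parameters from the scaled coordinates, simulate a noisy recovery curve,
#' fit every requested model to it, and record the fitted diffusion
#' coefficient. Individual fit failures are recorded
#' (`converged = FALSE`, `D_fit = NA`) and never abort the sweep.
#'
#' @param spec A [sweep_spec()].
#' @return Object of class `sweep_result`: `results` (long-format data frame
#'   with columns model, vs, gs, rep, D_fit, converged, metric), `summary`
#'   (per model and grid point: mean/sd of `D_fit/D_in`, SEM, mean metric,
#'   sd of `D_fit`, convergence fraction) and the `spec`.
#' @export
#' @examples
#' \donttest{
#' spec <- sweep_spec(vs_grid = 0, gs_grid = 0.01, reps = 2,
#'                    n_molecules = 1000, record_every = 100,
#'                    models = "diffusion", base_seed = 1)
#' sw <- run_sweep(spec)
#' sw$summary
#' }
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  seeds <- .sweep_seeds(spec)
  cells <- .sweep_cells(spec)
  units <- expand.grid(cell = seq_len(nrow(cells)), rep = seq_len(spec$reps),
                       KEEP.OUT.ATTRS = FALSE)
  worker <- function(i)
    .sweep_unit(spec, units$cell[i], units$rep[i], seeds)
  parts <- if (spec$jobs > 1L) {
    parallel::mclapply(seq_len(nrow(units)), worker, mc.cores = spec$jobs)
  } else {
    lapply(seq_len(nrow(units)), worker)
  }
  results <- do.call(rbind, parts)
  results <- results[order(results$model, results$vs, results$gs, results$rep), ]
  rownames(results) <- NULL
  key <- interaction(results$model, results$vs, results$gs, drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(d) {
    ok <- is.finite(d$D_fit)
    ratio <- d$D_fit[ok] / spec$D_in
    data.frame(model = d$model[1], vs = d$vs[1], gs = d$gs[1],
               n = nrow(d),
               mean_ratio = mean(ratio),
               sd_ratio = if (sum(ok) > 1) sd(ratio) else NA_real_,
               sem_ratio = if (sum(ok) > 1) sd(ratio) / sqrt(sum(ok)) else NA_real_,
               mean_D_fit = mean(d$D_fit[ok]),
               sd_D_fit = if (sum(ok) > 1) sd(d$D_fit[ok]) else NA_real_,
               mean_metric = mean(d$metric[ok]),
               conv_frac = mean(d$converged))
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, spec = spec),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("MPFRAP accuracy sweep: %d x %d grid, %d reps, models: %s\n",
              length(x$spec$vs_grid), length(x$spec$gs_grid), x$spec$reps,
              paste(x$spec$models, collapse = ", ")))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Reproduce a single sweep replicate
#'
#' Recomputes the fits of one `(cell, rep)` work unit of a sweep from its
#' deterministically derived seed; the returned `D_fit` values are
#' bit-identical to the corresponding rows of [run_sweep()].
#'
#' @param spec The [sweep_spec()] of the original sweep.
#' @param cell_index Row index into `expand.grid(vs_grid, gs_grid)`.
#' @param rep_index Replicate index.
#' @return Long-format data frame for that replicate (one row per model).
#' @export
rerun_sweep_cell <- function(spec, cell_index, rep_index) {
  stopifnot(inherits(spec, "sweep_spec"))
  .sweep_unit(spec, cell_index, rep_index)
}

#' Scaling collapse of accuracy curves
#'
#' Combines accuracy sweeps run at different input diffusion coefficients
#' (with `vs = 0`) onto the common scaled-shear axis. In scaled coordinates
#' the ratio `D_fit/D_in` as a function of `gs` is independent of `D_in`,
#' so the per-`D_in` curves overlay within statistical error.
#'
#' @param sweeps A list of [run_sweep()] results, each run at a single
#'   `D_in` with `vs_grid = 0` over a common `gs_grid`.
#' @return Overlay data frame with columns model, gs, D_in, mean_ratio,
#'   sem_ratio, n.
#' @export
collapse_by_scaling <- function(sweeps) {
  if (inherits(sweeps, "sweep_result")) sweeps <- list(sweeps)
  stopifnot(length(sweeps) >= 1,
            all(vapply(sweeps, inherits, logical(1), "sweep_result")))
  for (sw in sweeps) {
    if (!length(sw$spec$gs_grid))
      stop("empty shear-rate grid", call. = FALSE)
    if (any(sw$spec$vs_grid != 0))
      stop("scaling collapse requires sweeps run at vs = 0", call. = FALSE)
  }
  out <- do.call(rbind, lapply(sweeps, function(sw) {
    s <- sw$summary
    data.frame(model = s$model, gs = s$gs, D_in = sw$spec$D_in,
               mean_ratio = s$mean_ratio, sem_ratio = s$sem_ratio, n = s$n)
  }))
  rownames(out) <- NULL
  out[order(out$model, out$gs, out$D_in), ]
}

#' A-priori-knowledge fitting scenarios
#'
#' Simulates replicate recovery curves at one `(vs, gs)` point and fits each
#' with the shear-flow model under three knowledge regimes: `"no_bounds"`
#' (all four parameters free, unbounded), `"bounded"` (all four bounded to
#' `[0.1x, 10x]` their true values), and `"known_tau"` (`tau_v` and
#' `tau_gamma` fixed at truth, `beta` and `tau_D` free, unbounded). The same
#' simulated curves are reused across regimes.
#'
#' @param vs,gs Scaled velocity and scaled shear rate of the point.
#' @param reps Replicates (default 20).
#' @param regimes Subset of the three regimes.
#' @param D_in,beta,fv,base_seed,n_molecules,record_every,noise_fraction
#'   Conditions as in [sweep_spec()].
#' @return Object of class `table1_result`: `summary` (per regime: mean
#'   `D_fit`, SEM -- `NA` when `reps = 1` -- and convergence fraction) and
#'   `results` (per-replicate fits). Fit failures are recorded, not raised.
#' @export
table1_scenarios <- function(vs, gs, reps = 20L,
                             regimes = c("no_bounds", "bounded", "known_tau"),
                             D_in = 60, beta = 0.6, fv = focal_volume(),
                             base_seed = 1L, n_molecules = 20000L,
                             record_every = 1L, noise_fraction = 0.03) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  tp <- transport_from_scaled(fv, D_in, vs, gs)
  ct <- characteristic_times(fv, tp)
  truth <- c(beta = beta, tau_D = ct$tau_D, tau_v = ct$tau_v,
             tau_gamma = ct$tau_gamma)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(base_seed)
  seeds <- sample.int(2147483646L, reps)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  opts_for <- function(regime) {
    switch(regime,
      no_bounds = fit_options("shear_flow"),
      bounded = {
        bl <- lapply(truth, function(v) c(0.1 * v, 10 * v))
        # infinite truths (no flow/shear) cannot be bounded; leave them free
        bl <- bl[vapply(bl, function(b) all(is.finite(b)), logical(1))]
        fit_options("shear_flow", bounds = bl)
      },
      known_tau = fit_options("shear_flow",
                              fixed = list(tau_v = ct$tau_v,
                                           tau_gamma = ct$tau_gamma)))
  }

  rows <- vector("list", 0L)
  for (r in seq_len(reps)) {
    cfg <- sim_config(tp, fv = fv, beta = beta, n_molecules = n_molecules,
                      noise_fraction = noise_fraction,
                      record_every = record_every, rng_seed = seeds[r])
    curve <- simulate_recovery(cfg)
    for (regime in regimes) {
      fit <- tryCatch(fit_curve(curve, opts_for(regime), fv),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        regime = regime, rep = r,
        D_fit = if (is.null(fit)) NA_real_ else fit$D_hat,
        converged = if (is.null(fit)) FALSE else fit$converged)
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$regime), function(d) {
    ok <- is.finite(d$D_fit)
    data.frame(regime = d$regime[1], n = nrow(d),
               mean_D_fit = mean(d$D_fit[ok]),
               sem_D_fit = if (sum(ok) > 1)
                 sd(d$D_fit[ok]) / sqrt(sum(ok)) else NA_real_,
               conv_frac = mean(d$converged))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, results = results,
                 vs = vs, gs = gs, D_in = D_in, truth = as.list(truth)),
            class = "table1_result")
}

#' @export
print.table1_result <- function(x, ...) {
  cat(sprintf("A-priori-knowledge scenarios at vs = %.4g, gs = %.4g (D_in = %g um^2/s)\n",
              x$vs, x$gs, x$D_in))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Contour plot of a sweep summary
#'
#' Renders the mean accuracy metric of one model over the `(vs, gs)` grid.
#' Purely cosmetic; requires ggplot2.
#'
#' @param sw A [run_sweep()] result.
#' @param model Which fitted model to display.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sw, model = sw$spec$models[1]) {
  stopifnot(inherits(sw, "sweep_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- sw$summary[sw$summary$model == model, ]
  ggplot2::ggplot(d, ggplot2::aes(x = vs, y = gs, fill = mean_metric)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scaled velocity", y = "scaled shear rate",
                  fill = "[ln(Dfit/Din)]^2", title = model)
}
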