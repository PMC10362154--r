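# Curve and report file handling. The curve format is a diff-able CSV with
# a '#'-prefixed metadata header:
#
#   # mpfrap_curve v1
#   # F0=<value>
#   # <key>=<value> ...
#   time_s,fluorescence
#   0,123.4
#
# Numbers are written with %.17g so the text representation round-trips
# doubles exactly.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a recovery curve to CSV
#'
#' @param curve A [recovery_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recovery_curve()]
#' @export
write_recovery_curve <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  meta <- curve$meta
  lines <- c("# mpfrap_curve v1",
             paste0("# F0=", .fmt_num(curve$F0)))
  for (nm in names(meta)) {
    v <- meta[[nm]]
    v <- if (is.numeric(v)) .fmt_num(v) else as.character(v)
    lines <- c(lines, paste0("# ", nm, "=", v))
  }
  lines <- c(lines, "time_s,fluorescence",
             paste(.fmt_num(curve$times), .fmt_num(curve$F), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a recovery curve from CSV
#'
#' Parses the `# key=value` metadata header (including the required `F0`)
#' and the `time_s,fluorescence` columns written by
#' [write_recovery_curve()]. Reading and re-writing a curve reproduces the
#' file byte for byte.
#'
#' @param path File path.
#' @return A [recovery_curve()].
#' @export
read_recovery_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[hdr])
  meta_lines <- meta_lines[grepl("=", meta_lines)]
  keys <- sub("=.*$", "", meta_lines)
  vals <- sub("^[^=]*=", "", meta_lines)
  meta <- as.list(vals)
  names(meta) <- keys
  num <- suppressWarnings(as.numeric(vals))
  meta[!is.na(num)] <- num[!is.na(num)]
  if (is.null(meta$F0)) stop("curve file has no F0 metadata", call. = FALSE)
  F0 <- meta$F0
  meta$F0 <- NULL
  body <- lines[!hdr]
  if (length(body) < 2L || body[1] != "time_s,fluorescence")
    stop("malformed curve file: expected a 'time_s,fluorescence' table",
         call. = FALSE)
  d <- utils::read.csv(text = body)
  if (anyNA(d$time_s) || anyNA(d$fluorescence))
    stop("malformed curve file: non-numeric data", call. = FALSE)
  recovery_curve(d$time_s, d$fluorescence, F0, meta)
}

#' Write a fit report as JSON
#'
#' Serializes a [fit_curve()] result (parameters, derived diffusion
#' coefficient, seeds, diagnostics, bounds/fixed configuration) to JSON.
#'
#' @param fit A `frap_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "frap_fit"))
  rep <- list(model = fit$model,
              parameters = list(beta = fit$beta_hat,
                                tau_D = fit$tau_D_hat,
                                tau_v = fit$tau_v_hat,
                                tau_gamma = fit$tau_gamma_hat),
              D_hat = fit$D_hat,
              F0 = fit$F0,
              seeds = as.list(fit$seeds),
              fixed = fit$fixed,
              bounds = fit$bounds,
              residual_norm = fit$residual_norm,
              n_iterations = fit$n_iterations,
              converged = fit$converged,
              optimizer_info = fit$info,
              focal_volume = list(omega_r = fit$fv$omega_r,
                                  omega_z = fit$fv$omega_z, R = fit$fv$R))
  rep <- rep[!vapply(rep, is.null, logical(1))]
  # Inf (no flow / no shear) is not representable in JSON numbers
  rep$parameters <- lapply(rep$parameters,
                           function(v) if (is.null(v)) NULL
                           else if (!is.finite(v)) "Inf" else v)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Generate the bundled fixture set
#'
#' Writes small, versioned test inputs into a directory: noiseless curves
#' evaluated from each closed-form model at documented parameters, and one
#' noisy simulated curve per transport regime (diffusion only, uniform flow,
#' shear). Every fixture embeds its truth parameters in the metadata header
#' and regenerates bit-identically from the pinned seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Pinned base seed for the simulated fixtures.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 20230716L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fv <- focal_volume()
  beta <- 0.6
  D <- 60
  F0 <- 1000
  paths <- character(0)

  noiseless <- list(
    diffusion = list(vs = 0, gs = 0),
    diffusion_convection = list(vs = 0.5, gs = 0),
    shear_flow = list(vs = 0.5, gs = 1))
  for (nm in names(noiseless)) {
    p <- noiseless[[nm]]
    tp <- transport_from_scaled(fv, D, p$vs, p$gs)
    ct <- characteristic_times(fv, tp)
    t <- seq(0, 10 * ct$tau_half, length.out = 400)
    Fn <- F0 * switch(nm,
      diffusion = model_diffusion(t, beta, ct$tau_D, fv$R),
      diffusion_convection =
        model_diffusion_convection(t, beta, ct$tau_D, ct$tau_v, fv$R),
      shear_flow = model_shear_flow(t, beta, ct$tau_D, ct$tau_v,
                                    ct$tau_gamma, fv$R))
    curve <- recovery_curve(t, Fn, F0, meta = list(
      kind = paste0("noiseless_", nm), D = D, v0 = tp$v0, gamma = tp$gamma,
      vs = p$vs, gs = p$gs, beta = beta,
      omega_r = fv$omega_r, omega_z = fv$omega_z))
    path <- file.path(out_dir, paste0("noiseless_", nm, ".csv"))
    write_recovery_curve(curve, path)
    paths <- c(paths, path)
  }

  noisy <- list(diffusion = list(vs = 0, gs = 0),
                flow = list(vs = 0.5, gs = 0),
                shear = list(vs = 0, gs = 1))
  for (i in seq_along(noisy)) {
    p <- noisy[[i]]
    tp <- transport_from_scaled(fv, D, p$vs, p$gs)
    cfg <- sim_config(tp, fv = fv, beta = beta, n_molecules = 2000L,
                      record_every = 20L, rng_seed = seed + i)
    curve <- simulate_recovery(cfg)
    curve$meta <- c(list(kind = paste0("simulated_", names(noisy)[i])),
                    curve$meta)
    path <- file.path(out_dir,
                      paste0("simulated_", names(noisy)[i], ".csv"))
    write_recovery_curve(curve, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
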