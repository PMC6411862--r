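#' Define a parameter sweep
#'
#' A sweep is the outer product of viscosities, cargo diameters, unloaded
#' velocities, tether stiffnesses, detachment-profile variants and the
#' diffusion on/off switch, with a fixed ensemble size per cell and one
#' master seed. Cell seeds are derived from the master seed by cell index,
#' so a one-cell sweep reproduces a direct [simulate_ensemble()] call with
#' the same seed.
#'
#' @param eta_water Viscosities, multiples of water.
#' @param d Cargo diameters (nm).
#' @param v0 Unloaded velocities (nm/s).
#' @param kappa Tether stiffnesses (pN/nm).
#' @param variant Detachment-profile variants.
#' @param diffusion Logical: include thermal diffusion of the cargo.
#' @param n_replicates Runs per cell.
#' @param seed Master seed.
#' @param record_stride Per-cell trajectory sampling interval (steps).
#' @param n_boot Bootstrap resamples per cell fit.
#' @param output_dir Directory for per-cell CSVs and the summary, or
#'   `NULL` to keep results in memory only.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(eta_water = 1, d = 500, v0 = 800, kappa = 0.32,
                       variant = "measured", diffusion = TRUE,
                       n_replicates = 1000, seed = 1, record_stride = 100,
                       n_boot = 1000, output_dir = NULL) {
  grid <- expand.grid(eta_water = eta_water, d = d, v0 = v0, kappa = kappa,
                      variant = variant, diffusion = diffusion,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) stop("sweep_spec: empty grid", call. = FALSE)
  if (!all(grid$variant %in% .profile_variants))
    stop("sweep_spec: unknown detachment variant", call. = FALSE)
  structure(list(grid = grid, n_replicates = as.integer(n_replicates),
                 seed = seed, record_stride = as.integer(record_stride),
                 n_boot = n_boot, output_dir = output_dir),
            class = "sweep_spec")
}

# Derive a 31-bit cell seed from the master seed and cell index.
.cell_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647) + 1L
}

#' Run a transport-mode parameter sweep
#'
#' Executes every cell of the sweep grid through the engine and the
#' run-length/velocity/displacement analyses and returns one summary row
#' per cell, sorted by characteristic drag. Cell failures are caught,
#' marked in the `status` column, and do not stop the sweep.
#'
#' Summary columns: condition identifiers, `drag_pN` (characteristic drag
#' `9 pi eta d v` at the measured mean velocity), `eta_d` (viscosity-
#' diameter product), normalized run length with bootstrap SEM, mean
#' velocity with bootstrap SEM, the probability of assisting load among
#' sampled time points, and the displacement-regime statistics.
#'
#' @param spec A [sweep_spec()].
#' @param progress Print one line per completed cell.
#' @return A data.frame of class `sweep_summary` (one row per cell).
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- spec$grid
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    rows[[i]] <- tryCatch(
      .run_sweep_cell(cell, spec, .cell_seed(spec$seed, i)),
      error = function(e) {
        warning(sprintf("sweep cell %d failed: %s", i, conditionMessage(e)),
                call. = FALSE)
        cbind(cell, .empty_cell_row(), status = "failed")
      })
    if (progress)
      message(sprintf("cell %d/%d done (eta %gx, d %g nm, v0 %g nm/s)",
                      i, nrow(grid), cell$eta_water, cell$d, cell$v0))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$drag_pN), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweep_summary", "data.frame")
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(spec$output_dir, "sweep_summary.csv"),
                     row.names = FALSE)
  }
  out
}

.empty_cell_row <- function() {
  data.frame(drag_pN = NA_real_, eta_d = NA_real_,
             run_length_nm = NA_real_, run_length_sem_nm = NA_real_,
             norm_run_length = NA_real_, norm_run_length_sem = NA_real_,
             velocity_nm_s = NA_real_, velocity_sem_nm_s = NA_real_,
             p_assisting = NA_real_, p_hindering = NA_real_, p_free = NA_real_,
             mean_excursion_assisting_nm = NA_real_,
             mean_excursion_hindering_nm = NA_real_,
             n_runs = NA_integer_)
}

.run_sweep_cell <- function(cell, spec, seed) {
  motor <- motor_params(v0 = cell$v0, kappa = cell$kappa)
  fluid <- fluid_cargo(d = cell$d, eta = cell$eta_water * water_viscosity)
  if (!cell$diffusion) fluid$D <- 0
  profile <- detachment_profile(variant = cell$variant, motor = motor)
  cfg <- sim_config(n_replicates = spec$n_replicates, seed = seed,
                    record_stride = spec$record_stride)
  ens <- simulate_ensemble(motor, fluid, profile, cfg)
  rl <- suppressMessages(run_lengths(ens))
  est <- fit_run_length(rl, n_boot = spec$n_boot)
  nrl <- normalized_run_length(est, motor$l0)
  vel <- tryCatch(ensemble_velocity(ens, n_boot = spec$n_boot),
                  error = function(e) list(mean = NA_real_, sem = NA_real_))
  deltas <- pooled_samples(ens, "displacement")
  ds <- displacement_stats(deltas, motor$L0)
  v_for_drag <- if (is.finite(vel$mean)) vel$mean else
    diffusion_free_velocity(fluid$eta, fluid$d, motor)
  cbind(cell, data.frame(
    drag_pN = characteristic_drag(fluid$eta, fluid$d, max(v_for_drag, 0)),
    eta_d = fluid$eta * fluid$d,
    run_length_nm = est$l, run_length_sem_nm = est$sem,
    norm_run_length = nrl$value, norm_run_length_sem = nrl$sem,
    velocity_nm_s = vel$mean, velocity_sem_nm_s = vel$sem,
    p_assisting = ds$p_assisting, p_hindering = ds$p_hindering,
    p_free = ds$p_free,
    mean_excursion_assisting_nm = ds$mean_excursion_assisting,
    mean_excursion_hindering_nm = ds$mean_excursion_hindering,
    n_runs = length(rl)), status = "ok")
}

#' Run an equilibrium-mode sweep
#'
#' Zero-drag displacement sampling over a grid of viscosities, diameters
#' and stiffnesses (the motor is held fixed; detachment disabled). For
#' each cell the displacement-regime statistics, the conditional mean
#' load magnitude, the effective detachment and stepping rates, and the
#' implied normalized run length `(k_eff step / eps_eff) / (v0 / eps0)`
#' are reported.
#'
#' @param eta_water Viscosities, multiples of water.
#' @param d Diameters (nm).
#' @param kappa Stiffnesses (pN/nm); the time step resolves per cell
#'   (1e-6 s above 0.32 pN/nm).
#' @param n_replicates Runs per cell.
#' @param equilibrium_steps Recorded steps per run, or `NULL` (default) to
#'   record a fixed `equilibrium_time` of simulated time at each cell's
#'   own time step. Stiff cells resolve to a 10x finer step; a fixed step
#'   count would observe them for a 10x shorter time, confounding the
#'   stiffness comparison, so equal observation time is the default.
#' @param equilibrium_time Simulated time recorded per run (s) when
#'   `equilibrium_steps` is `NULL`; 0.2 s is 20,000 steps at the default
#'   10-us step.
#' @param seed Master seed.
#' @param motor Base motor parameters (kappa is overridden per cell).
#' @param grid Optional data.frame with columns `eta_water`, `d`, `kappa`
#'   overriding the outer product of the vector arguments (for
#'   non-rectangular designs such as [zero_drag_grid()]).
#' @return Data.frame, one row per cell, plus attribute `samples`: a list
#'   of the pooled displacement vectors per cell.
#' @export
run_equilibrium_sweep <- function(eta_water = 1, d = 500, kappa = 0.32,
                                  n_replicates = 10,
                                  equilibrium_steps = NULL,
                                  equilibrium_time = 0.2, seed = 1,
                                  motor = motor_params(), grid = NULL) {
  if (is.null(grid))
    grid <- expand.grid(eta_water = eta_water, d = d, kappa = kappa)
  if (is.null(grid$kappa)) grid$kappa <- motor$kappa
  if (is.null(grid$eta_water)) grid$eta_water <- 1
  if (is.null(grid$d)) grid$d <- 500
  rows <- vector("list", nrow(grid))
  samples <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    m <- motor
    m$kappa <- cell$kappa
    fl <- fluid_cargo(d = cell$d, eta = cell$eta_water * water_viscosity)
    dt_i <- if (m$kappa > 0.32) 1e-6 else 1e-5
    steps_i <- if (is.null(equilibrium_steps)) round(equilibrium_time / dt_i)
               else equilibrium_steps
    cfg <- sim_config(mode = "equilibrium", n_replicates = n_replicates,
                      equilibrium_steps = steps_i,
                      seed = .cell_seed(seed, i))
    cfg$dt <- dt_i
    eq <- simulate_equilibrium(m, fl, cfg)
    samples[[i]] <- eq$samples
    ds <- displacement_stats(eq$samples, m$L0)
    loads <- tether_load_on_motor(eq$samples, m$kappa, m$L0)
    prof <- detachment_profile(motor = m)
    eps_eff <- effective_detachment_rate(eq$samples, prof, m$kappa, m$L0)
    k_eff <- effective_stepping_rate(eq$samples, m)
    nrl <- (k_eff * m$step_size / eps_eff) / (m$v0 / prof$eps0)
    rows[[i]] <- cbind(cell, data.frame(
      dt = eq$dt,
      p_free = ds$p_free, p_assisting = ds$p_assisting,
      p_hindering = ds$p_hindering,
      mean_excursion_assisting_nm = ds$mean_excursion_assisting,
      mean_excursion_hindering_nm = ds$mean_excursion_hindering,
      p_loaded = ds$p_assisting + ds$p_hindering,
      mean_load_pN = mean(abs(loads[loads != 0])),
      eps_eff = eps_eff, eps_ratio = eps_eff / prof$eps0,
      k_step_eff = k_eff, norm_run_length = nrl))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Condition grid for zero-drag displacement sampling
#'
#' The zero-drag (equilibrium-mode) study design spans wide viscosity and
#' cargo-size ranges at the default stiffness. A run of
#' `equilibrium_steps * dt` seconds can only sample the stationary
#' displacement distribution if the cargo's free-range crossing time
#' `(2 L0)^2 / (2 D)` fits well inside the run; beyond
#' `eta * d ~ 1e4 (x water) nm` a 0.2-s run starting at zero displacement
#' never reaches the tails and the recorded distribution reflects the
#' initial condition, not tethered diffusion. The default grid is
#' therefore the product of viscosities `{1, 3.2, 10, 32, 100}` x water
#' and diameters `{100, 500, 1000}` nm restricted to
#' `eta_water * d <= max_eta_d`.
#'
#' @param eta_water Candidate viscosities (multiples of water).
#' @param d Candidate diameters (nm).
#' @param max_eta_d Equilibration cut on the product (x water * nm).
#' @return Data.frame with columns `eta_water`, `d`.
#' @export
zero_drag_grid <- function(eta_water = c(1, 3.2, 10, 32, 100),
                           d = c(100, 500, 1000), max_eta_d = 1e4) {
  g <- expand.grid(eta_water = eta_water, d = d)
  g <- g[g$eta_water * g$d <= max_eta_d, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Stiffness grid for the zero-drag stiffness sweep
#'
#' Six stiffnesses logarithmically spanning the 100-fold range
#' 0.032--3.2 pN/nm around the kinesin-1 default 0.32 pN/nm.
#'
#' @param n Number of stiffnesses.
#' @param range Two-element range (pN/nm).
#' @return Numeric vector of stiffnesses.
#' @export
stiffness_grid <- function(n = 6, range = c(0.032, 3.2)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Preset sweeps for the study's experiment designs
#'
#' Returns a ready-to-run [sweep_spec()] reproducing a figure-style
#' experiment: `"fig1"` (viscosity sweep at d = 0.5 um, v0 = 0.8 um/s,
#' with and without diffusion), `"fig2_size"` (cargo-size sweep),
#' `"fig2_velocity"` (velocity sweep; the two velocities flanking
#' 0.8 um/s are configurable since only 0.8 is fixed by the study),
#' `"fig5"` (the four detachment-profile variants over a drag grid
#' spanning ~1e-3 to ~10 pN).
#'
#' @param name Preset name.
#' @param n_replicates Runs per cell.
#' @param seed Master seed.
#' @param ... Overrides passed to [sweep_spec()].
#' @return A [sweep_spec()].
#' @export
preset_sweep <- function(name = c("fig1", "fig2_size", "fig2_velocity",
                                  "fig5"),
                         n_replicates = 1000, seed = 1, ...) {
  name <- match.arg(name)
  eta_grid <- c(1, 2.2, 4.6, 10, 22, 46, 100, 220, 460, 1000)
  args <- switch(name,
    fig1 = list(eta_water = eta_grid, d = 500, v0 = 800,
                diffusion = c(TRUE, FALSE)),
    fig2_size = list(eta_water = eta_grid, d = c(100, 200, 500, 1000),
                     v0 = 800),
    fig2_velocity = list(eta_water = eta_grid, d = 500,
                         v0 = c(400, 800, 1600)),
    fig5 = list(eta_water = c(1, 3.2, 10, 32, 100, 320, 1000),
                d = 500, v0 = 800,
                variant = c("measured", "symmetric_hindering",
                            "symmetric_assisting", "reversed")))
  do.call(sweep_spec, utils::modifyList(
    c(args, list(n_replicates = n_replicates, seed = seed)), list(...)))
}
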