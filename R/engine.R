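#' Simulation configuration
#'
#' Controls the Monte Carlo time stepping. In `transport` mode a run starts
#' with the cargo at the motor position and iterates until the motor
#' detaches (or `max_steps` is reached, in which case the record is flagged,
#' not an error). In `equilibrium` mode the motor is held fixed with
#' detachment disabled, and the cargo-motor displacement is sampled; this
#' realizes zero drag regardless of viscosity.
#'
#' The time step defaults to 1e-5 s, switching to 1e-6 s when the tether
#' stiffness exceeds 0.32 pN/nm (stiffer springs need finer resolution of
#' the cargo position). A warning is emitted when `rate * dt` can exceed
#' 0.1 for the stepping rate or the unloaded-neighbourhood detachment rate,
#' since the per-step Bernoulli approximation then degrades.
#'
#' @param dt Time step (s), or `NULL` to resolve from `kappa`.
#' @param n_replicates Ensemble size.
#' @param max_steps Per-run step cap (transport mode).
#' @param seed Master RNG seed, or `NULL` to use the current RNG state.
#' @param mode `"transport"` or `"equilibrium"`.
#' @param equilibrium_steps Recorded steps per equilibrium run.
#' @param record_stride Sampling interval (in steps) for positions/loads in
#'   transport mode; 0 disables trajectory recording. Equilibrium mode
#'   samples every `record_stride` steps (default 1).
#' @param include_binding_wait Prepend an exponential waiting time at rate
#'   `k_on` before each run (does not affect run length).
#' @param burn_in Discarded steps before equilibrium sampling (used by
#'   stationary-distribution oracles; the study conditions use 0).
#' @param init_delta Initial cargo-motor displacement (nm).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = NULL, n_replicates = 1000, max_steps = 1e7,
                       seed = NULL, mode = c("transport", "equilibrium"),
                       equilibrium_steps = 20000, record_stride = NULL,
                       include_binding_wait = FALSE, burn_in = 0,
                       init_delta = 0) {
  mode <- match.arg(mode)
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0))
    stop("sim_config: 'dt' must be positive or NULL", call. = FALSE)
  if (n_replicates < 1) stop("sim_config: 'n_replicates' must be >= 1",
                             call. = FALSE)
  if (is.null(record_stride))
    record_stride <- if (mode == "equilibrium") 1L else 0L
  structure(list(dt = dt, n_replicates = as.integer(n_replicates),
                 max_steps = max_steps, seed = seed, mode = mode,
                 equilibrium_steps = as.integer(equilibrium_steps),
                 record_stride = as.integer(record_stride),
                 include_binding_wait = isTRUE(include_binding_wait),
                 burn_in = burn_in, init_delta = init_delta),
            class = "sim_config")
}

# Resolve dt from the stiffness-dependent default and check the Bernoulli
# approximation at the rates the run will typically visit, plus the
# stability of the explicit tether update.
.resolve_dt <- function(config, motor, profile, fluid = NULL) {
  dt <- config$dt
  if (is.null(dt)) dt <- if (motor$kappa > 0.32) 1e-6 else 1e-5
  k_max <- motor$v0 / motor$step_size
  eps_hi <- detachment_rate(c(-motor$Fs, motor$Fs), profile)
  if (max(k_max, eps_hi) * dt > 0.1)
    warning(sprintf(
      "rate * dt = %.3g exceeds 0.1; per-step Bernoulli approximation is poor",
      max(k_max, eps_hi) * dt), call. = FALSE)
  if (!is.null(fluid) && motor$kappa * dt / fluid$xi > 1)
    warning(sprintf(
      "kappa * dt / xi = %.2f: tether relaxation is under-resolved (unstable beyond 2); reduce dt or raise viscosity",
      motor$kappa * dt / fluid$xi), call. = FALSE)
  dt
}

.variant_code <- function(variant) {
  match(variant, .profile_variants) - 1L
}

#' Advance the coupled motor-cargo state by one time step
#'
#' Reference (R-level) implementation of the per-step update used by the
#' compiled engine, exposed for testing and illustration. The order is:
#' evaluate the tether load from the displacement; detach with probability
#' `eps(F) * dt`; advance the motor one step with probability
#' `k_step(F) * dt`; move the cargo by drift `(-F/xi) * dt` plus a Gaussian
#' diffusion increment `sqrt(2 D dt) * z`. Consumes the same RNG draws in
#' the same order as the compiled loop, so the two produce identical
#' trajectories from identical seeds.
#'
#' @param state List with `motor`, `cargo`, `time` (nm, nm, s).
#' @param motor,fluid,profile Parameter objects.
#' @param dt Time step (s).
#' @return The updated state, with `detached = TRUE` if the motor released
#'   this step (positions then unchanged).
#' @export
advance_one_step <- function(state, motor = motor_params(),
                             fluid = fluid_cargo(),
                             profile = detachment_profile(motor = motor),
                             dt = 1e-5) {
  if (!all(is.finite(c(state$motor, state$cargo))))
    stop("advance_one_step: non-finite state", call. = FALSE)
  F <- tether_load_on_motor(state$cargo - state$motor, motor$kappa, motor$L0)
  state$load <- F
  if (stats::runif(1) < detachment_rate(F, profile) * dt) {
    state$detached <- TRUE
    return(state)
  }
  if (stats::runif(1) < stepping_rate(F, motor) * dt) {
    state$motor <- state$motor + motor$step_size
    state$n_motor_steps <- (state$n_motor_steps %||% 0) + 1
  }
  state$cargo <- state$cargo + (-F / fluid$xi) * dt +
    sqrt(2 * fluid$D * dt) * stats::rnorm(1)
  state$time <- state$time + dt
  state$detached <- FALSE
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one cargo run
#'
#' Runs the transport-mode Monte Carlo loop until the motor detaches or
#' `max_steps` is reached. The run starts with the cargo at the motor
#' position (zero tether extension). With `include_binding_wait`, an
#' exponential waiting time at rate `k_on` is drawn and stored (it models
#' the time to bind the microtubule and does not affect the run length).
#'
#' @param motor,fluid,profile Parameter objects.
#' @param config A [sim_config()]; its `seed`, if non-`NULL`, seeds the run.
#' @return An object of class `trajectory_record`: run length (nm), number
#'   of motor steps, attachment duration (s), termination cause, and, when
#'   `record_stride > 0`, sampled times, motor/cargo positions and loads.
#' @export
simulate_run <- function(motor = motor_params(), fluid = fluid_cargo(),
                         profile = detachment_profile(motor = motor),
                         config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- .resolve_dt(config, motor, profile, fluid)
  wait <- if (config$include_binding_wait) stats::rexp(1, motor$k_on) else 0
  res <- .sim_transport_cpp(dt, config$max_steps, motor$v0, motor$step_size,
                            motor$Fs, motor$kappa, motor$L0, fluid$xi,
                            fluid$D, .variant_code(profile$variant),
                            profile$eps0, profile$Fd_minus, profile$Fd_plus,
                            profile$bridge_slope, profile$bridge_prefactor,
                            config$record_stride, config$init_delta)
  res$seed <- config$seed
  res$dt <- dt
  res$record_stride <- config$record_stride
  res$binding_wait <- wait
  class(res) <- "trajectory_record"
  res
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(
    "Trajectory: run length %.1f nm (%d steps) in %.4g s [%s]\n",
    x$run_length, as.integer(x$n_motor_steps), x$duration, x$termination))
  invisible(x)
}

#' Simulate an ensemble of independent runs
#'
#' Runs `config$n_replicates` independent transport runs. Per-replicate
#' seeds are drawn once from the master seed, so the ensemble is
#' reproducible and each replicate is independent of the order of
#' execution.
#'
#' @inheritParams simulate_run
#' @return An object of class `trajectory_ensemble`: a list of
#'   [simulate_run()] records with the master seed attached.
#' @export
simulate_ensemble <- function(motor = motor_params(), fluid = fluid_cargo(),
                              profile = detachment_profile(motor = motor),
                              config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_replicates
  # diagnose the time step once for the whole ensemble, not per replicate
  .resolve_dt(config, motor, profile, fluid)
  if (!is.null(config$seed)) set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- sub_seeds[i]
    runs[[i]] <- suppressWarnings(simulate_run(motor, fluid, profile, cfg_i))
    runs[[i]]$replicate <- i
  }
  structure(list(runs = runs, master_seed = config$seed,
                 motor = motor, fluid = fluid, profile = profile,
                 config = config),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  rl <- run_lengths(x)
  cat(sprintf("Ensemble of %d runs: mean run length %.0f nm (naive mean)\n",
              length(x$runs), mean(rl)))
  invisible(x)
}

#' Extract run lengths from an ensemble
#'
#' Records that hit the step cap are excluded (with a message) since their
#' run length is censored.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return Numeric vector of run lengths (nm).
#' @export
run_lengths <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  term <- vapply(ensemble$runs, function(r) r$termination, character(1))
  capped <- sum(term == "max_steps")
  if (capped > 0)
    message(capped, " run(s) hit max_steps and were excluded from run lengths")
  vapply(ensemble$runs[term == "detached"],
         function(r) r$run_length, numeric(1))
}

#' Pool sampled loads or displacements from an ensemble
#'
#' @param ensemble A `trajectory_ensemble` simulated with
#'   `record_stride > 0`.
#' @param what `"load"` (pN) or `"displacement"` (cargo minus motor, nm).
#' @return Numeric vector pooled across replicates.
#' @export
pooled_samples <- function(ensemble, what = c("load", "displacement")) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  what <- match.arg(what)
  if (ensemble$config$record_stride <= 0)
    stop("ensemble was simulated without trajectory recording", call. = FALSE)
  if (what == "load")
    unlist(lapply(ensemble$runs, function(r) r$load), use.names = FALSE)
  else
    unlist(lapply(ensemble$runs, function(r) r$cargo - r$motor),
           use.names = FALSE)
}

#' Sample the cargo-motor displacement at zero drag
#'
#' Equilibrium mode: the motor is fixed (velocity zero, realizing zero
#' viscous drag) and detachment is disabled; the cargo diffuses in the
#' flat-bottomed harmonic potential of the tether. Each of
#' `config$n_replicates` runs records `config$equilibrium_steps`
#' displacement samples (every `record_stride` updates, after `burn_in`
#' discarded updates).
#'
#' @inheritParams simulate_run
#' @return Object of class `equilibrium_samples`: `samples` (pooled, nm)
#'   and `per_replicate` (list of vectors).
#' @export
simulate_equilibrium <- function(motor = motor_params(),
                                 fluid = fluid_cargo(),
                                 config = sim_config(mode = "equilibrium")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "equilibrium")
    stop("simulate_equilibrium: config$mode must be 'equilibrium'",
         call. = FALSE)
  dt <- config$dt
  if (is.null(dt)) dt <- if (motor$kappa > 0.32) 1e-6 else 1e-5
  if (!is.null(config$seed)) set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  per <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    set.seed(sub_seeds[i])
    per[[i]] <- .sim_equilibrium_cpp(dt, config$equilibrium_steps,
                                     as.numeric(config$burn_in),
                                     max(1L, config$record_stride),
                                     motor$kappa, motor$L0, fluid$xi,
                                     fluid$D, config$init_delta)
  }
  structure(list(samples = unlist(per, use.names = FALSE),
                 per_replicate = per, dt = dt, motor = motor, fluid = fluid,
                 config = config),
            class = "equilibrium_samples")
}

#' Simulate a force-free diffusing cargo
#'
#' Pure-diffusion control: the cargo diffuses with no tether. Per-step
#' displacement increments are Gaussian with variance `2 D dt`, which is
#' the oracle used to validate the engine's thermal noise.
#'
#' @param fluid A [fluid_cargo()].
#' @param n_steps Number of steps.
#' @param dt Time step (s).
#' @param seed RNG seed, or `NULL`.
#' @return Numeric vector of positions (nm) at each step.
#' @export
simulate_free_diffusion <- function(fluid = fluid_cargo(), n_steps = 1e5,
                                    dt = 1e-5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .sim_equilibrium_cpp(dt, as.numeric(n_steps), 0, 1L, 0, 0, fluid$xi,
                       fluid$D, 0)
}

#' @export
print.equilibrium_samples <- function(x, ...) {
  cat(sprintf(
    "Equilibrium displacements: %d samples from %d run(s), dt = %g s\n",
    length(x$samples), length(x$per_replicate), x$dt))
  invisible(x)
}
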