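test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(n_replicates = 1, max_steps = 2000, seed = 77,
                    record_stride = 10)
  r1 <- simulate_run(config = cfg)
  r2 <- simulate_run(config = cfg)
  expect_identical(r1$cargo, r2$cargo)
  expect_identical(r1$motor, r2$motor)
  expect_identical(r1$duration, r2$duration)
  # ensembles: same master seed reproduces, replicates differ
  cfg2 <- sim_config(n_replicates = 2, max_steps = 5000, seed = 5)
  e1 <- simulate_ensemble(config = cfg2)
  e2 <- simulate_ensemble(config = cfg2)
  expect_identical(vapply(e1$runs, `[[`, 0, "final_cargo"),
                   vapply(e2$runs, `[[`, 0, "final_cargo"))
  expect_false(identical(e1$runs[[1]]$final_cargo, e1$runs[[2]]$final_cargo))
})

test_that("compiled loop reproduces the reference R stepper draw-for-draw", {
  motor <- motor_params()
  fluid <- fluid_cargo()
  profile <- detachment_profile(motor = motor)
  n <- 250
  rec <- simulate_run(motor, fluid, profile,
                      sim_config(n_replicates = 1, max_steps = n, seed = 99,
                                 record_stride = 1))
  set.seed(99)
  st <- list(motor = 0, cargo = 0, time = 0)
  motor_r <- cargo_r <- load_r <- numeric(0)
  for (i in seq_len(n)) {
    motor_r <- c(motor_r, st$motor)
    cargo_r <- c(cargo_r, st$cargo)
    st <- advance_one_step(st, motor, fluid, profile, dt = 1e-5)
    load_r <- c(load_r, st$load)
    if (st$detached) break
  }
  k <- length(motor_r)
  expect_identical(rec$motor[seq_len(k)], motor_r)
  expect_identical(rec$cargo[seq_len(k)], cargo_r)
  expect_identical(rec$load[seq_len(k)], load_r)
})

test_that("run length equals step size times accepted steps, motor never back-steps", {
  ens <- cached_ensemble("water_stride", n = 30, seed = 301,
                         record_stride = 50)
  for (r in ens$runs) {
    expect_identical(r$run_length, r$n_motor_steps * 8)
    expect_identical(r$run_length, r$final_motor)
    expect_true(all(diff(r$motor) >= 0))
  }
})

test_that("force-free cargo diffuses with per-step variance 2 D dt", {
  fl <- fluid_cargo()
  x <- simulate_free_diffusion(fl, n_steps = 1e5, dt = 1e-5, seed = 8)
  inc <- diff(x)
  v_hat <- stats::var(inc)
  v_true <- 2 * fl$D * 1e-5
  se <- v_true * sqrt(2 / (length(inc) - 1))
  expect_lt(abs(v_hat - v_true), 3 * se)
  expect_lt(abs(mean(inc)), 3 * sqrt(v_true / length(inc)))
})

test_that("per-step detachment frequency matches the rate law (clamped load)", {
  # immobilized cargo (enormous friction), initial displacement -65 nm:
  # constant hindering load -8 pN, beyond stall so the motor never steps;
  # attachment times must then be exponential with rate eps(-8 pN)
  motor <- motor_params()
  fluid <- fluid_cargo(eta = 1)           # 1e9 x water: cargo frozen
  profile <- detachment_profile(motor = motor)
  eps <- detachment_rate(-8, profile)
  cfg <- sim_config(n_replicates = 600, seed = 13, init_delta = -65,
                    record_stride = 0)
  ens <- simulate_ensemble(motor, fluid, profile, cfg)
  expect_true(all(vapply(ens$runs, `[[`, 0, "n_motor_steps") == 0))
  durs <- vapply(ens$runs, `[[`, 0, "duration")
  se <- (1 / eps) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 1 / eps), 3 * se)
})

test_that("halving the time step leaves run-length statistics unchanged", {
  fit_at_dt <- function(dt, seed) {
    ens <- simulate_ensemble(config = sim_config(dt = dt, n_replicates = 250,
                                                 seed = seed))
    fit_run_length(run_lengths(ens), n_boot = 100)
  }
  f1 <- fit_at_dt(1e-5, 41)
  f2 <- fit_at_dt(5e-6, 42)
  expect_lt(abs(f1$l - f2$l), 2 * sqrt(f1$sem^2 + f2$sem^2))
})

test_that("unloaded diffusion-free ensemble recovers the unloaded kinetics", {
  # small but well-resolved viscosity: drag ~0.006 pN is negligible
  # against Fd-, while the explicit tether update stays stable
  motor <- motor_params()
  fluid <- fluid_cargo(eta = 0.5 * water_viscosity)
  fluid$D <- 0
  ens <- simulate_ensemble(motor, fluid, detachment_profile(motor = motor),
                           sim_config(n_replicates = 400, seed = 3,
                                      record_stride = 200))
  est <- fit_run_length(suppressMessages(run_lengths(ens)), n_boot = 150)
  expect_lt(abs(est$l - 1500), 3 * est$sem)
  # motor velocity matches the stepping-rate oracle v = k_step * step
  vel <- ensemble_velocity(ens, n_boot = 100, source = "motor")
  expect_lt(abs(vel$mean - 800), 4 * vel$sem)
  # run lengths are consistent with an exponential distribution
  rl <- suppressMessages(run_lengths(ens))
  ks <- suppressWarnings(stats::ks.test(rl, "pexp", 1 / est$l))
  expect_gt(ks$p.value, 0.01)
})

test_that("max_steps caps are flagged and excluded from run lengths", {
  cfg <- sim_config(n_replicates = 5, max_steps = 100, seed = 2)
  ens <- simulate_ensemble(config = cfg)
  term <- vapply(ens$runs, `[[`, "", "termination")
  expect_true(any(term == "max_steps"))
  expect_message(run_lengths(ens), "max_steps")
})

test_that("equilibrium displacements are symmetric and match the Boltzmann oracle", {
  # study protocol (paper time step): symmetry about zero
  eq <- simulate_equilibrium(config = sim_config(mode = "equilibrium",
                                                 n_replicates = 10, seed = 6))
  expect_lt(abs(mean(eq$samples)), 2)
  # continuous-limit oracle at reduced time step with burn-in
  eq2 <- simulate_equilibrium(
    config = sim_config(mode = "equilibrium", dt = 1e-6, n_replicates = 20,
                        equilibrium_steps = 10000, record_stride = 100,
                        burn_in = 1e5, seed = 60))
  ds <- displacement_stats(eq2$samples)
  bt <- boltzmann_tether()
  expect_lt(abs(100 * ds$p_assisting - 100 * bt$p_tail), 1.5)
  expect_lt(abs(100 * ds$p_hindering - 100 * bt$p_tail), 1.5)
  expect_lt(abs(ds$mean_excursion_assisting - bt$mean_excursion), 0.25)
  expect_lt(abs(ds$mean_excursion_hindering - bt$mean_excursion), 0.25)
  # effective detachment rate against the quadrature oracle
  pr <- detachment_profile()
  eps_mc <- effective_detachment_rate(eq2$samples, pr)
  eps_quad <- quad_effective_rate(function(F) detachment_rate(F, pr))
  expect_lt(abs(eps_mc - eps_quad) / eps_quad, 0.04)
})

test_that("equilibrium histogram matches the stationary density (KS, short tether)", {
  # shorter rest length so stride-thinned samples decorrelate quickly and
  # the KS comparison has real power
  motor <- motor_params(L0 = 2)
  eq <- simulate_equilibrium(
    motor = motor,
    config = sim_config(mode = "equilibrium", dt = 1e-7, n_replicates = 5,
                        equilibrium_steps = 10000, record_stride = 1500,
                        burn_in = 2e4, seed = 61))
  bt <- boltzmann_tether(kappa = motor$kappa, L0 = 2)
  ks <- stats::ks.test(eq$samples, bt$cdf)
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("corrupted inputs are rejected", {
  expect_error(sim_config(dt = -1), "dt")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  st <- list(motor = NaN, cargo = 0, time = 0)
  expect_error(advance_one_step(st), "non-finite")
  expect_error(simulate_equilibrium(config = sim_config(mode = "transport")),
               "equilibrium")
})
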