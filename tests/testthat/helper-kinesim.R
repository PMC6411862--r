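# Shared helpers: an ensemble cache (several tests reuse the same study
# conditions) and independent oracles for the equilibrium statistics.

.ens_cache <- new.env(parent = emptyenv())

# Ensemble at a named study condition, computed once per test run.
cached_ensemble <- function(key, eta_water = 1, d = 500, v0 = 800,
                            variant = "measured", diffusion = TRUE,
                            n = 300, seed = 101, record_stride = 0) {
  if (!is.null(.ens_cache[[key]])) return(.ens_cache[[key]])
  motor <- motor_params(v0 = v0)
  fluid <- fluid_cargo(d = d, eta = eta_water * water_viscosity)
  if (!diffusion) fluid$D <- 0
  ens <- simulate_ensemble(
    motor, fluid, detachment_profile(variant = variant, motor = motor),
    sim_config(n_replicates = n, seed = seed, record_stride = record_stride))
  .ens_cache[[key]] <- ens
  ens
}

# Quadrature of the load-detachment (or load-stepping) rate against the
# continuous-limit stationary displacement density: the oracle for the
# sample-weighted effective rates.
quad_effective_rate <- function(rate_fn, kappa = 0.32, L0 = 40, kBT = 4.11) {
  bt <- boltzmann_tether(kappa, L0, kBT)
  f <- function(x) rate_fn(tether_load_on_motor(x, kappa, L0)) * bt$pdf(x)
  stats::integrate(f, -L0 - 60, L0 + 60, subdivisions = 2000,
                   rel.tol = 1e-10)$value
}
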