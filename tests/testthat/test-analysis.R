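test_that("exponential CDF fit recovers known parameters", {
  fx <- generate_fixtures(seed = 2)
  set.seed(10)
  x <- stats::rexp(1000, 1 / 1500)
  est <- fit_run_length(x, n_boot = 200)
  expect_lt(abs(est$l - 1500), 3 * est$sem)
  expect_lt(abs(est$l - 1500) / 1500, 0.1)
  expect_lt(abs(est$A - 1), 0.1)
  expect_gt(est$sem, 0)
  # the 500-sample fixture behaves the same
  est2 <- fit_run_length(fx$run_lengths, n_boot = 100)
  expect_lt(abs(est2$l - 1500) / 1500, 0.12)
})

test_that("run-length fit rejects degenerate input", {
  expect_error(fit_run_length(c(1, 2, 3)), "at least 10")
  expect_error(fit_run_length(rep(500, 50)), "degenerate")
  expect_error(fit_run_length(c(-1, stats::rexp(20, 1))), "non-negative")
})

test_that("run-length fit is scale-equivariant", {
  set.seed(11)
  x <- stats::rexp(400, 1 / 1200)
  l1 <- fit_run_length(x, n_boot = 0)$l
  l2 <- fit_run_length(3.7 * x, n_boot = 0)$l
  expect_equal(l2 / l1, 3.7, tolerance = 1e-6)
})

test_that("bootstrap SEM shrinks like one over root n", {
  set.seed(12)
  x <- stats::rexp(1600, 1 / 1500)
  s_small <- fit_run_length(x[1:200], n_boot = 300)$sem
  s_big <- fit_run_length(x, n_boot = 300)$sem
  ratio <- s_small / s_big          # expect ~ sqrt(1600/200) = 2.83
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 4.5)
})

test_that("trajectory velocity is the least-squares slope with filters", {
  fx <- generate_fixtures(seed = 3, slope = 800, duration = 1, dt = 1e-3)
  rec <- list(time = fx$trajectory$time_s, cargo = fx$trajectory$position_nm,
              motor = fx$trajectory$position_nm, duration = 1)
  v <- trajectory_velocity(rec)
  expect_true(v$accepted)
  expect_equal(v$velocity, 800, tolerance = 1e-9)
  # duration filter
  short <- list(time = seq(0, 0.1, 1e-3), cargo = seq(0, 80, length.out = 101),
                motor = NULL, duration = 0.1)
  expect_false(trajectory_velocity(short)$accepted)
  expect_equal(trajectory_velocity(short)$reason, "duration")
  # displacement filter
  slow <- list(time = seq(0, 1, 1e-3), cargo = seq(0, 50, length.out = 1001),
               motor = NULL, duration = 1)
  expect_false(trajectory_velocity(slow)$accepted)
  expect_equal(trajectory_velocity(slow)$reason, "displacement")
})

test_that("load histogram normalizes and diffusion-free loads are hindering-only", {
  h <- load_histogram(c(-1, -1, -0.5, 0, 0, 0.5), bin_width = 0.25)
  expect_equal(sum(h$frequency), 1)
  ens <- cached_ensemble("nodiff", eta_water = 10, diffusion = FALSE,
                         n = 15, seed = 77, record_stride = 50)
  loads <- pooled_samples(ens, "load")
  expect_true(all(loads <= 0))
  expect_error(load_histogram(numeric(0)), "empty")
})

test_that("displacement statistics classify the diffusion regimes", {
  fx <- generate_fixtures(seed = 4)
  ds <- displacement_stats(fx$displacements, L0 = 40)
  expect_equal(ds$p_free + ds$p_assisting + ds$p_hindering, 1)
  bt <- boltzmann_tether()
  se <- sqrt(bt$p_tail * (1 - bt$p_tail) / length(fx$displacements))
  expect_lt(abs(ds$p_assisting - bt$p_tail), 3 * se)
  expect_lt(abs(ds$p_hindering - bt$p_tail), 3 * se)
  expect_lt(abs(ds$mean_excursion_assisting - bt$mean_excursion), 0.3)
  # all-free input
  ds0 <- displacement_stats(runif(100, -40, 40), L0 = 40)
  expect_equal(ds0$p_assisting, 0)
  expect_equal(ds0$p_hindering, 0)
  expect_equal(ds0$p_free, 1)
})

test_that("effective rates are frequency-weighted and bounded below by eps0", {
  pr <- detachment_profile()
  # free-range samples give exactly the unloaded rate
  expect_identical(effective_detachment_rate(runif(50, -40, 40), pr), pr$eps0)
  # never below eps0
  set.seed(5)
  for (i in 1:10) {
    s <- stats::rnorm(200, sd = 30)
    expect_gte(effective_detachment_rate(s, pr), pr$eps0)
  }
  # Boltzmann fixture agrees with the quadrature oracle
  fx <- generate_fixtures(seed = 6)
  mc <- effective_detachment_rate(fx$displacements, pr)
  quad <- quad_effective_rate(function(F) detachment_rate(F, pr))
  expect_lt(abs(mc - quad) / quad, 0.05)
  expect_equal(quad / pr$eps0, 1.18, tolerance = 0.01)
})

test_that("predicted run length is velocity over detachment rate", {
  expect_equal(predicted_run_length(800, 800 / 1500), 1500)
  expect_equal(predicted_run_length(400, 800 / 1500), 750)
  expect_error(predicted_run_length(800, 0), "positive")
})

test_that("stiffness scaling slope recovers exact power laws", {
  k <- c(0.032, 0.1, 0.32, 1, 3.2)
  expect_equal(stiffness_scaling_slope(k, 2.5 * sqrt(k))$slope, 0.5,
               tolerance = 1e-10)
  # Boltzmann closed form: conditional mean tail load sqrt(2 kappa kBT / pi)
  expect_equal(stiffness_scaling_slope(k, sqrt(2 * k * 4.11 / pi))$slope, 0.5,
               tolerance = 1e-10)
  expect_error(stiffness_scaling_slope(c(1, 2), c(1, 2)), "3")
  expect_error(stiffness_scaling_slope(c(1, 2, 3), c(1, 2, 3)), "10-fold")
})

test_that("normalized run length divides the estimate and its error", {
  est <- list(l = 1140, sem = 49.5)
  nr <- normalized_run_length(est, 1500)
  expect_equal(nr$value, 0.76)
  expect_equal(nr$sem, 0.033)
  expect_equal(normalized_run_length(list(l = 1455, sem = 0), 1500)$value,
               0.97)
  expect_error(normalized_run_length(est, 0), "positive")
})
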