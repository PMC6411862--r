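#' Stationary density of the tethered cargo (continuous limit)
#'
#' In the continuous-time limit the cargo-motor displacement of a motor
#' held at zero velocity is Boltzmann-distributed in the flat-bottomed
#' harmonic tether potential: uniform on `[-L0, L0]` and half-Gaussian
#' (scale `sigma = sqrt(kBT / kappa)`) beyond. These closed forms are the
#' oracles for the equilibrium engine mode.
#'
#' @param kappa Tether stiffness (pN/nm).
#' @param L0 Rest length (nm).
#' @param kBT Thermal energy (pN nm).
#' @return List with `sigma` (nm), `p_tail` (per-side tail mass),
#'   `mean_excursion` (nm beyond `L0`, per side = `sigma * sqrt(2/pi)`),
#'   and functions `pdf(x)`, `cdf(x)`, `quantile(u)`.
#' @export
boltzmann_tether <- function(kappa = 0.32, L0 = 40, kBT = 4.11) {
  sigma <- sqrt(kBT / kappa)
  s <- sigma * sqrt(pi / 2)          # weight of each tail
  Z <- 2 * L0 + 2 * s
  pdf <- function(x) {
    ifelse(abs(x) <= L0, 1 / Z, exp(-(abs(x) - L0)^2 / (2 * sigma^2)) / Z)
  }
  cdf <- function(x) {
    ifelse(x < -L0, (2 * s / Z) * stats::pnorm((x + L0) / sigma),
      ifelse(x <= L0, s / Z + (x + L0) / Z,
             (s + 2 * L0) / Z +
               (2 * s / Z) * (stats::pnorm((x - L0) / sigma) - 0.5)))
  }
  quantile <- function(u) {
    stopifnot(all(u >= 0 & u <= 1))
    p_tail <- s / Z
    out <- numeric(length(u))
    lo <- u < p_tail
    hi <- u > p_tail + 2 * L0 / Z
    mid <- !lo & !hi
    out[lo] <- -L0 + sigma * stats::qnorm(u[lo] * Z / (2 * s))
    out[mid] <- -L0 + (u[mid] * Z - s)
    out[hi] <- L0 + sigma * stats::qnorm(0.5 + (u[hi] * Z - 2 * L0 - s) / (2 * s))
    out
  }
  list(sigma = sigma, p_tail = s / Z,
       mean_excursion = sigma * sqrt(2 / pi),
       pdf = pdf, cdf = cdf, quantile = quantile)
}

#' Deterministic test fixtures
#'
#' Generates the small synthetic datasets used by the analysis unit tests
#' without running the engine: (a) 500 exponential run lengths with known
#' mean, (b) 1e4 displacement samples drawn from the continuous-limit
#' tether density by inverse-CDF, (c) a noiseless linear trajectory.
#' Byte-identical for a given seed.
#'
#' @param seed RNG seed.
#' @param dir If non-`NULL`, the three fixtures are also written there as
#'   CSV files.
#' @param mean_run_length Mean of fixture (a) (nm).
#' @param kappa,L0,kBT Tether constants for fixture (b).
#' @param slope,duration,dt Trajectory slope (nm/s), duration (s) and
#'   sampling interval (s) for fixture (c).
#' @return List with `run_lengths`, `displacements`, `trajectory`
#'   (data.frame `time_s`, `position_nm`).
#' @export
generate_fixtures <- function(seed = 1, dir = NULL, mean_run_length = 1500,
                              kappa = 0.32, L0 = 40, kBT = 4.11,
                              slope = 800, duration = 1, dt = 1e-3) {
  set.seed(seed)
  rl <- stats::rexp(500, rate = 1 / mean_run_length)
  bt <- boltzmann_tether(kappa, L0, kBT)
  disp <- bt$quantile(stats::runif(1e4))
  tt <- seq(0, duration, by = dt)
  traj <- data.frame(time_s = tt, position_nm = slope * tt)
  out <- list(run_lengths = rl, displacements = disp, trajectory = traj)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(run_length_nm = rl),
                     file.path(dir, "run_lengths.csv"), row.names = FALSE)
    utils::write.csv(data.frame(displacement_nm = disp),
                     file.path(dir, "displacements.csv"), row.names = FALSE)
    utils::write.csv(traj, file.path(dir, "trajectory.csv"),
                     row.names = FALSE)
  }
  out
}
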