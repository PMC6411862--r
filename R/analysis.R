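#' Fit an exponential to the run-length distribution
#'
#' Fits the empirical cumulative distribution of run lengths to
#' `1 - A * exp(-x / l)` by unweighted nonlinear least squares on all
#' empirical points, with both the amplitude `A` and the decay constant `l`
#' free. The mean run length is the best-fit `l`; its standard error comes
#' from a nonparametric bootstrap (resampling runs with replacement and
#' refitting; the SEM is the standard deviation of the resampled `l`).
#'
#' @param run_lengths Numeric vector of run lengths (nm), `n >= 10`.
#' @param n_boot Number of bootstrap resamples (0 skips the bootstrap).
#' @return An object of class `run_length_estimate` with fields `l` (nm),
#'   `A`, `sem` (nm), `n`, `n_boot`.
#' @examples
#' set.seed(1)
#' fit_run_length(rexp(500, 1 / 1500), n_boot = 100)
#' @export
fit_run_length <- function(run_lengths, n_boot = 1000) {
  x <- run_lengths[is.finite(run_lengths)]
  if (length(x) < 10)
    stop("fit_run_length: need at least 10 finite run lengths", call. = FALSE)
  if (any(x < 0))
    stop("fit_run_length: run lengths must be non-negative", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("fit_run_length: degenerate sample (no spread)", call. = FALSE)
  l_hat <- .fit_exp_cdf(x)
  sem <- NA_real_
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      xb <- sample(x, replace = TRUE)
      out <- tryCatch(.fit_exp_cdf(xb)["l"], error = function(e) NA_real_)
      out
    }, numeric(1))
    sem <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(l = unname(l_hat["l"]), A = unname(l_hat["A"]),
                 sem = sem, n = length(x), n_boot = n_boot),
            class = "run_length_estimate")
}

# Core CDF fit; returns c(l, A). Levenberg-Marquardt with moment start
# values; errors propagate to the caller as fit failures.
.fit_exp_cdf <- function(x) {
  xs <- sort(x)
  Femp <- seq_along(xs) / length(xs)
  df <- data.frame(x = xs, F = Femp)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ 1 - A * exp(-x / l), data = df,
                      start = list(A = 1, l = max(mean(x), 1e-9)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit_run_length: CDF fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["l"]]) || cf[["l"]] <= 0)
    stop("fit_run_length: fit returned a non-positive decay constant",
         call. = FALSE)
  c(l = cf[["l"]], A = cf[["A"]])
}

#' @export
print.run_length_estimate <- function(x, ...) {
  cat(sprintf("Run length: l = %.1f +/- %.1f nm (A = %.3f, n = %d)\n",
              x$l, x$sem, x$A, x$n))
  invisible(x)
}

#' Normalize a run-length estimate by the unloaded value
#'
#' @param estimate A [fit_run_length()] result.
#' @param l0 Unloaded run length (nm).
#' @return List with `value` (l / l0) and `sem` (sem / l0), both fractions.
#' @export
normalized_run_length <- function(estimate, l0 = 1500) {
  if (!is.finite(l0) || l0 <= 0)
    stop("normalized_run_length: 'l0' must be positive", call. = FALSE)
  list(value = estimate$l / l0, sem = estimate$sem / l0)
}

#' Velocity of a simulated trajectory
#'
#' The trajectory velocity is the least-squares slope of sampled cargo
#' position against time (`source = "motor"` uses the motor positions
#' instead). Trajectories shorter than 0.2 s or moving less than 100 nm
#' are rejected; rejection is reported in the result, not as an error.
#'
#' @param record A `trajectory_record` simulated with `record_stride > 0`.
#' @param min_duration Minimum duration (s).
#' @param min_displacement Minimum total displacement (nm).
#' @param source `"cargo"` (bead-tracking convention) or `"motor"`.
#' @return List with `accepted` (logical), `velocity` (nm/s or `NA`) and
#'   `reason` (`NA` or why the trajectory was rejected).
#' @export
trajectory_velocity <- function(record, min_duration = 0.2,
                                min_displacement = 100,
                                source = c("cargo", "motor")) {
  source <- match.arg(source)
  if (is.null(record$time) || length(record$time) < 2)
    stop("trajectory_velocity: record has no sampled trajectory", call. = FALSE)
  pos <- record[[source]]
  if (record$duration < min_duration)
    return(list(accepted = FALSE, velocity = NA_real_, reason = "duration"))
  if (abs(pos[length(pos)] - pos[1]) < min_displacement)
    return(list(accepted = FALSE, velocity = NA_real_, reason = "displacement"))
  slope <- stats::cov(record$time, pos) / stats::var(record$time)
  list(accepted = TRUE, velocity = slope, reason = NA_character_)
}

#' Mean velocity of an ensemble with bootstrap SEM
#'
#' Applies [trajectory_velocity()] to each run, averages the accepted
#' velocities, and bootstraps the accepted set for the SEM.
#'
#' @param ensemble A `trajectory_ensemble` with recorded trajectories.
#' @param n_boot Bootstrap resamples.
#' @param ... Passed to [trajectory_velocity()].
#' @return List with `mean`, `sem`, `n_accepted`, `n_rejected`.
#' @export
ensemble_velocity <- function(ensemble, n_boot = 1000, ...) {
  vs <- vapply(ensemble$runs,
               function(r) trajectory_velocity(r, ...)$velocity, numeric(1))
  acc <- vs[is.finite(vs)]
  if (!length(acc))
    stop("ensemble_velocity: no trajectory passed the filters", call. = FALSE)
  sem <- if (n_boot > 0)
    stats::sd(vapply(seq_len(n_boot),
                     function(b) mean(sample(acc, replace = TRUE)),
                     numeric(1)))
  else NA_real_
  list(mean = mean(acc), sem = sem,
       n_accepted = length(acc), n_rejected = sum(!is.finite(vs)))
}

#' Histogram of signed loads
#'
#' Normalized frequency of the signed load on the motor, pooled across
#' replicates. Positive loads assist motion.
#'
#' @param loads Numeric vector of signed loads (pN), or a
#'   `trajectory_ensemble` with recorded loads.
#' @param bin_width Bin width (pN).
#' @return Data.frame with `mid` (bin centre, pN) and `frequency`
#'   (fractions summing to 1).
#' @export
load_histogram <- function(loads, bin_width = 0.05) {
  if (inherits(loads, "trajectory_ensemble"))
    loads <- pooled_samples(loads, "load")
  if (!length(loads)) stop("load_histogram: empty input", call. = FALSE)
  lo <- floor(min(loads) / bin_width) * bin_width
  hi <- ceiling(max(loads) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  h <- graphics::hist(loads, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, frequency = h$counts / length(loads))
}

#' Classify cargo-motor displacements by diffusion regime
#'
#' Splits displacement samples into the free-diffusion range
#' (`|delta| <= L0`, no load) and the tethered ranges on each side, and
#' reports per-class probabilities and the mean excursion beyond the rest
#' length among tethered samples.
#'
#' @param samples Displacements, cargo minus motor (nm).
#' @param L0 Rest length (nm).
#' @return Object of class `displacement_stats`: `p_free`, `p_assisting`,
#'   `p_hindering` (fractions summing to 1), `mean_excursion_assisting`,
#'   `mean_excursion_hindering` (nm beyond `L0`; `NaN` if a side is empty).
#' @export
displacement_stats <- function(samples, L0 = 40) {
  if (!length(samples)) stop("displacement_stats: empty input", call. = FALSE)
  assist <- samples > L0
  hinder <- samples < -L0
  n <- length(samples)
  structure(list(
    p_free = sum(!assist & !hinder) / n,
    p_assisting = sum(assist) / n,
    p_hindering = sum(hinder) / n,
    mean_excursion_assisting = mean(samples[assist] - L0),
    mean_excursion_hindering = mean(abs(samples[hinder]) - L0),
    n = n, L0 = L0), class = "displacement_stats")
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat(sprintf(
    "Displacements (n = %d, L0 = %g nm): free %.2f%%, assisting %.2f%% (%.2f nm), hindering %.2f%% (%.2f nm)\n",
    x$n, x$L0, 100 * x$p_free, 100 * x$p_assisting,
    x$mean_excursion_assisting, 100 * x$p_hindering,
    x$mean_excursion_hindering))
  invisible(x)
}

#' Effective detachment rate over a displacement distribution
#'
#' The frequency-weighted detachment rate: each displacement is converted
#' to a load through the tether law, the load-detachment rate is evaluated
#' there, and the rates are averaged. Equal to `eps0` when no sample
#' leaves the free range, and `>= eps0` always (the rate law is minimized
#' at zero load).
#'
#' @param samples Displacements, cargo minus motor (nm).
#' @param profile A [detachment_profile()].
#' @param kappa Tether stiffness (pN/nm).
#' @param L0 Rest length (nm).
#' @return Rate (1/s).
#' @export
effective_detachment_rate <- function(samples,
                                      profile = detachment_profile(),
                                      kappa = 0.32, L0 = 40) {
  if (!length(samples))
    stop("effective_detachment_rate: empty input", call. = FALSE)
  mean(detachment_rate(tether_load_on_motor(samples, kappa, L0), profile))
}

#' Effective stepping rate over a displacement distribution
#'
#' Companion to [effective_detachment_rate()]: the frequency-weighted
#' load-stepping rate, used to form the implied velocity
#' `v = step_size * k_eff` of a motor sampling the given displacement
#' distribution.
#'
#' @inheritParams effective_detachment_rate
#' @param motor A [motor_params()].
#' @return Rate (1/s).
#' @export
effective_stepping_rate <- function(samples, motor = motor_params()) {
  if (!length(samples))
    stop("effective_stepping_rate: empty input", call. = FALSE)
  mean(stepping_rate(tether_load_on_motor(samples, motor$kappa, motor$L0),
                     motor))
}

#' Run length implied by a velocity and detachment rate
#'
#' `l = v / eps`: the mean run length of a motor moving at velocity `v`
#' while detaching at rate `eps`.
#'
#' @param velocity Velocity (nm/s).
#' @param rate Detachment rate (1/s), positive.
#' @return Run length (nm).
#' @examples
#' predicted_run_length(800, 800 / 1500)  # 1500 nm
#' @export
predicted_run_length <- function(velocity, rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("predicted_run_length: 'rate' must be positive", call. = FALSE)
  velocity / rate
}

#' Power-law slope of load magnitude against stiffness
#'
#' Least-squares slope of `log10(mean load magnitude among load-bearing
#' samples)` against `log10(kappa)`. For a cargo equilibrated in the
#' flat-bottomed harmonic tether potential the conditional mean tail load
#' is `sqrt(2 kappa kBT / pi)`, so the expected slope is 1/2
#' (equipartition).
#'
#' @param kappas Stiffness values (pN/nm), at least 3 spanning >= 10-fold.
#' @param mean_loads Mean nonzero-load magnitudes (pN), same length.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
stiffness_scaling_slope <- function(kappas, mean_loads) {
  if (length(kappas) < 3 || length(mean_loads) != length(kappas))
    stop("stiffness_scaling_slope: need >= 3 matched (kappa, load) points",
         call. = FALSE)
  if (max(kappas) / min(kappas) < 10)
    stop("stiffness_scaling_slope: stiffness range must span >= 10-fold",
         call. = FALSE)
  fit <- stats::lm(log10(mean_loads) ~ log10(kappas))
  y <- log10(mean_loads)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2))
}
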