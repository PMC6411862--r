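#' Velocity under self-consistent viscous load (diffusion-free)
#'
#' Without cargo diffusion the only load on the motor is the viscous drag
#' at its own velocity, `|F| = 9 pi eta d v`, applied in the hindering
#' direction. Combining this with the parabolic force-velocity relation
#' `v = v0 (1 - (F/Fs)^2)` gives a quadratic whose physical root is
#' \deqn{v = \frac{v_0}{2}\left(\frac{F_s}{9\pi d\eta v_0}\right)^2
#'   \left(-1 + \sqrt{1 + 4\left(\frac{9\pi\eta d v_0}{F_s}\right)^2}\right).}
#' The `eta -> 0` limit (`v -> v0`) is handled explicitly to avoid the
#' 0/0 form.
#'
#' @param eta Viscosity (pN s/nm^2); vectorized.
#' @param d Cargo diameter (nm).
#' @param motor A [motor_params()] supplying `v0` and `Fs`.
#' @return Velocity (nm/s).
#' @export
diffusion_free_velocity <- function(eta, d, motor = motor_params()) {
  a <- 9 * pi * eta * d * motor$v0 / motor$Fs   # dimensionless drag number
  v <- ifelse(a < 1e-8, motor$v0,
              (motor$v0 / 2) / a^2 * (-1 + sqrt(1 + 4 * a^2)))
  v
}

#' Run length under self-consistent viscous load (diffusion-free)
#'
#' Diffusion-free closed form: `l = (v / eps0) * exp(-9 pi eta d v / Fd-)`
#' with `v` the self-consistent velocity from
#' [diffusion_free_velocity()]. Monotonically decreasing in the product
#' `eta * d`.
#'
#' @inheritParams diffusion_free_velocity
#' @param profile A [detachment_profile()] supplying `eps0` and `Fd_minus`.
#' @return Run length (nm).
#' @examples
#' diffusion_free_run_length(0, 500)                     # 1500 nm
#' diffusion_free_run_length(100 * water_viscosity, 500) # ~1246 nm
#' @export
diffusion_free_run_length <- function(eta, d, motor = motor_params(),
                                      profile = detachment_profile(motor = motor)) {
  v <- diffusion_free_velocity(eta, d, motor)
  drag <- 9 * pi * eta * d * v
  (v / profile$eps0) * exp(-drag / profile$Fd_minus)
}

#' Drag threshold for a given run-length reduction
#'
#' Solves for the characteristic drag `F` at which the diffusion-free run
#' length falls below the unloaded value by `reduction_fraction`:
#' `(1 - (F/Fs)^2) * exp(-F/Fd-) = 1 - reduction_fraction`, with `F`
#' interpreted as the drag at the loaded velocity. Solved by bracketed
#' bisection on `(0, Fs)` to 1e-6 pN.
#'
#' @param reduction_fraction Fractional reduction in `(0, 1)`.
#' @param motor A [motor_params()].
#' @param profile A [detachment_profile()].
#' @param tol Bisection tolerance (pN).
#' @return Drag force (pN).
#' @examples
#' drag_threshold(0.05)  # ~0.34 pN, i.e. 0.3 to one significant figure
#' @export
drag_threshold <- function(reduction_fraction, motor = motor_params(),
                           profile = detachment_profile(motor = motor),
                           tol = 1e-6) {
  if (!is.finite(reduction_fraction) || reduction_fraction <= 0 ||
      reduction_fraction >= 1)
    stop("drag_threshold: 'reduction_fraction' must be in (0, 1)",
         call. = FALSE)
  target <- 1 - reduction_fraction
  g <- function(F) (1 - (F / motor$Fs)^2) * exp(-F / profile$Fd_minus) - target
  lo <- 0
  hi <- motor$Fs * (1 - 1e-12)
  if (g(hi) > 0)
    stop("drag_threshold: no root in (0, Fs)", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
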