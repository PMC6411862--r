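#' Motor kinetic and mechanical constants
#'
#' Bundles the constants describing a single processive motor: its unloaded
#' velocity and run length, lattice step size, stall force, tether stiffness,
#' tether rest length, and microtubule binding rate. Defaults are the
#' kinesin-1 values used throughout the package.
#'
#' Internal units are pN, nm and s throughout the package.
#'
#' @param v0 Unloaded velocity (nm/s).
#' @param l0 Unloaded run length (nm).
#' @param step_size Lattice step size (nm).
#' @param Fs Stall force (pN); hindering load at which stepping stops.
#' @param kappa Tether stiffness (pN/nm).
#' @param L0 Tether rest length (nm); extensions below this transmit no force.
#' @param k_on Microtubule binding rate (1/s).
#' @return An object of class `motor_params`.
#' @examples
#' motor_params()            # kinesin-1 defaults
#' motor_params(v0 = 400)    # slower motor
#' @export
motor_params <- function(v0 = 800, l0 = 1500, step_size = 8, Fs = 7,
                         kappa = 0.32, L0 = 40, k_on = 5) {
  vals <- list(v0 = v0, l0 = l0, step_size = step_size, Fs = Fs,
               kappa = kappa, L0 = L0, k_on = k_on)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("motor_params: fields must be single positive finite numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(vals, class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Motor parameters (pN, nm, s):\n")
  cat(sprintf("  v0 = %g nm/s  l0 = %g nm  step = %g nm  Fs = %g pN\n",
              x$v0, x$l0, x$step_size, x$Fs))
  cat(sprintf("  kappa = %g pN/nm  L0 = %g nm  k_on = %g /s\n",
              x$kappa, x$L0, x$k_on))
  invisible(x)
}

#' Detachment force scale from a characteristic distance
#'
#' The Bell-model detachment force is the thermal energy divided by the
#' characteristic distance between the attached and detached states,
#' `Fd = kBT / delta`.
#'
#' @param delta Characteristic detachment distance (nm).
#' @param kBT Thermal energy (pN nm); 4.11 at room temperature.
#' @return Detachment force (pN).
#' @examples
#' detachment_force(0.60)  # hindering direction: 6.85 pN
#' detachment_force(0.32)  # assisting direction: 12.84 pN
#' @export
detachment_force <- function(delta, kBT = 4.11) {
  if (!is.numeric(delta) || any(!is.finite(delta)) || any(delta <= 0))
    stop("detachment_force: 'delta' must be positive and finite", call. = FALSE)
  if (!is.numeric(kBT) || length(kBT) != 1L || !is.finite(kBT) || kBT <= 0)
    stop("detachment_force: 'kBT' must be a single positive number", call. = FALSE)
  kBT / delta
}

#' Unloaded detachment rate
#'
#' The detachment rate at zero load is fixed by the unloaded velocity and
#' unloaded run length: `eps0 = v0 / l0`, since the mean run length of an
#' exponential detachment process at constant velocity is `v0 / eps0`.
#'
#' @param v0 Unloaded velocity (nm/s), non-negative.
#' @param l0 Unloaded run length (nm), positive.
#' @return Rate (1/s).
#' @examples
#' unloaded_detachment_rate(800, 1500)  # 0.5333 /s
#' @export
unloaded_detachment_rate <- function(v0, l0) {
  if (!is.numeric(l0) || any(!is.finite(l0)) || any(l0 <= 0))
    stop("unloaded_detachment_rate: 'l0' must be positive", call. = FALSE)
  if (!is.numeric(v0) || any(!is.finite(v0)) || any(v0 < 0))
    stop("unloaded_detachment_rate: 'v0' must be non-negative", call. = FALSE)
  v0 / l0
}

#' Load-dependent stepping rate
#'
#' Stepping kinetics of the motor under a signed load `F` (pN): positive
#' loads assist motion, negative loads hinder it. The rate is zero at and
#' beyond stall, rises quadratically as the hindering load is released,
#' and saturates at the unloaded rate `v0 / step_size` for any assisting
#' load.
#'
#' @param F Signed load on the motor (pN); vectorized.
#' @param motor A [motor_params()] object.
#' @return Stepping rate (1/s), in `[0, v0/step_size]`.
#' @examples
#' stepping_rate(0, motor_params())      # 100 /s
#' stepping_rate(-3.5, motor_params())   # 75 /s
#' @export
stepping_rate <- function(F, motor = motor_params()) {
  stopifnot(inherits(motor, "motor_params"))
  k_max <- motor$v0 / motor$step_size
  ifelse(F <= -motor$Fs, 0,
         ifelse(F <= 0, k_max * (1 - (F / motor$Fs)^2), k_max))
}

.profile_variants <- c("measured", "symmetric_hindering",
                       "symmetric_assisting", "reversed")

#' Construct a load-detachment profile
#'
#' Builds the three-branch load-detachment rate law of the motor and its
#' symmetry variants. The measured kinesin-1 profile is
#' \deqn{\epsilon(F) = \epsilon_0 e^{|F|/F_{d-}} \; (F \le 0);\quad
#'       \epsilon_0 (1 + 3.8247 F) \; (0 < F \le 2);\quad
#'       7.4\,\epsilon_0 e^{F/F_{d+}} \; (F > 2),}
#' with `Fd- = kBT/delta_minus`, `Fd+ = kBT/delta_plus`, and
#' `eps0 = v0/l0`. The linear branch bridges the experimentally unprobed
#' 0--2 pN assisting range so that the profile is continuous at 0 and
#' (to < 0.1%) at +2 pN.
#'
#' Variants (used to probe which features of the law matter):
#' \describe{
#'   \item{`measured`}{the asymmetric law above.}
#'   \item{`symmetric_hindering`}{the hindering branch applied to `|F|` in
#'     both directions.}
#'   \item{`symmetric_assisting`}{the assisting branch (bridge then
#'     prefactored exponential) applied to `|F|` in both directions.}
#'   \item{`reversed`}{the measured law mirrored, `eps(F) = eps_meas(-F)`.}
#' }
#'
#' @param variant One of `"measured"`, `"symmetric_hindering"`,
#'   `"symmetric_assisting"`, `"reversed"`.
#' @param motor A [motor_params()] object supplying `v0` and `l0`.
#' @param kBT Thermal energy (pN nm).
#' @param delta_minus Hindering-direction detachment distance (nm).
#' @param delta_plus Assisting-direction detachment distance (nm).
#' @param bridge_slope Linear-bridge coefficient (1/pN).
#' @param bridge_prefactor Assisting-branch prefactor (dimensionless).
#' @return An object of class `detachment_profile` with derived fields
#'   `Fd_minus`, `Fd_plus` and `eps0`.
#' @examples
#' pr <- detachment_profile()
#' detachment_rate(c(-2, 0, 1, 3), pr)
#' @export
detachment_profile <- function(variant = "measured", motor = motor_params(),
                               kBT = 4.11, delta_minus = 0.60,
                               delta_plus = 0.32, bridge_slope = 3.8247,
                               bridge_prefactor = 7.4) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% .profile_variants)
    stop("detachment_profile: unknown variant; must be one of ",
         paste(.profile_variants, collapse = ", "), call. = FALSE)
  stopifnot(inherits(motor, "motor_params"))
  for (nm in c("kBT", "delta_minus", "delta_plus", "bridge_slope",
               "bridge_prefactor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("detachment_profile: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(list(
    variant = variant,
    kBT = kBT,
    delta_minus = delta_minus,
    delta_plus = delta_plus,
    Fd_minus = detachment_force(delta_minus, kBT),
    Fd_plus = detachment_force(delta_plus, kBT),
    bridge_slope = bridge_slope,
    bridge_prefactor = bridge_prefactor,
    eps0 = unloaded_detachment_rate(motor$v0, motor$l0)
  ), class = "detachment_profile")
}

#' @rdname detachment_profile
#' @export
make_profile <- function(variant = "measured", motor = motor_params(), ...) {
  detachment_profile(variant = variant, motor = motor, ...)
}

#' @export
print.detachment_profile <- function(x, ...) {
  cat(sprintf("Load-detachment profile '%s':\n", x$variant))
  cat(sprintf("  eps0 = %.4g /s  Fd- = %.4g pN  Fd+ = %.4g pN\n",
              x$eps0, x$Fd_minus, x$Fd_plus))
  cat(sprintf("  bridge: eps0*(1 + %g*F) on (0, 2] pN; prefactor %g beyond\n",
              x$bridge_slope, x$bridge_prefactor))
  invisible(x)
}

# measured law as a function of signed F for a given profile's constants
.eps_measured <- function(F, p) {
  ifelse(F <= 0, p$eps0 * exp(abs(F) / p$Fd_minus),
         ifelse(F <= 2, p$eps0 * (1 + p$bridge_slope * F),
                p$eps0 * p$bridge_prefactor * exp(F / p$Fd_plus)))
}

.eps_assisting_branch <- function(Fabs, p) {
  ifelse(Fabs <= 2, p$eps0 * (1 + p$bridge_slope * Fabs),
         p$eps0 * p$bridge_prefactor * exp(Fabs / p$Fd_plus))
}

#' Load-dependent detachment rate
#'
#' Evaluates the detachment rate of the motor under signed load `F` (pN,
#' positive assisting) for a given [detachment_profile()].
#'
#' @param F Signed load (pN); vectorized.
#' @param profile A [detachment_profile()] object.
#' @return Detachment rate (1/s).
#' @examples
#' detachment_rate(0, detachment_profile())    # eps0 = 0.5333 /s
#' detachment_rate(1, detachment_profile())    # 2.572 /s
#' @export
detachment_rate <- function(F, profile = detachment_profile()) {
  stopifnot(inherits(profile, "detachment_profile"))
  switch(profile$variant,
    measured = .eps_measured(F, profile),
    symmetric_hindering = profile$eps0 * exp(abs(F) / profile$Fd_minus),
    symmetric_assisting = .eps_assisting_branch(abs(F), profile),
    reversed = .eps_measured(-F, profile),
    stop("detachment_rate: unknown variant '", profile$variant, "'",
         call. = FALSE))
}

#' Tabulate rate laws over a force grid
#'
#' Convenience table of the detachment and stepping rates over a grid of
#' signed loads, e.g. for plotting a profile or exporting it as CSV.
#'
#' @param forces Signed loads (pN).
#' @param motor A [motor_params()] object.
#' @param profile A [detachment_profile()] object.
#' @return A data.frame with columns `force_pN`, `detach_rate_per_s`,
#'   `step_rate_per_s`.
#' @export
rate_table <- function(forces = seq(-10, 10, by = 0.1),
                       motor = motor_params(),
                       profile = detachment_profile(motor = motor)) {
  data.frame(force_pN = forces,
             detach_rate_per_s = detachment_rate(forces, profile),
             step_rate_per_s = stepping_rate(forces, motor))
}
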