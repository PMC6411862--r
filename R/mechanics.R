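#' Cargo-fluid coupling
#'
#' Describes a spherical cargo in a viscous medium: its diameter, the
#' solution viscosity, and a wall-correction multiplier on the free-space
#' Stokes friction. The friction coefficient is `xi = chi * 3 * pi * eta * d`
#' and the diffusion coefficient follows from the Einstein relation
#' `D = kBT / xi`, so fluctuation and dissipation are consistent by
#' construction.
#'
#' The default `chi = 3` gives an effective friction `9 * pi * eta * d`,
#' the Stokes drag on a sphere near a hard wall; `chi = 1` selects the
#' free-space value `3 * pi * eta * d`. With the default, the steady-state
#' tether load on a motor moving at velocity `v` equals the characteristic
#' drag `9 * pi * eta * d * v` used as the control parameter for sweeps.
#'
#' @param d Cargo diameter (nm).
#' @param eta Solution viscosity (pN s/nm^2). Water at room temperature is
#'   `1e-9` (i.e. 1 mPa s); see [water_viscosity].
#' @param chi Wall-correction multiplier (dimensionless, default 3).
#' @param kBT Thermal energy (pN nm).
#' @return An object of class `fluid_cargo` with derived `xi` (pN s/nm)
#'   and `D` (nm^2/s).
#' @examples
#' fluid_cargo(d = 500, eta = water_viscosity)
#' fluid_cargo(d = 500, eta = 22 * water_viscosity)
#' @export
fluid_cargo <- function(d = 500, eta = water_viscosity, chi = 3, kBT = 4.11) {
  vals <- list(d = d, eta = eta, chi = chi, kBT = kBT)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("fluid_cargo: fields must be single positive finite numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  xi <- friction_coefficient(eta, d, chi)
  structure(c(vals, list(xi = xi, D = diffusion_coefficient(xi, kBT))),
            class = "fluid_cargo")
}

#' Viscosity of water in internal units
#'
#' 1 mPa s = 1e-3 Pa s expressed in pN s/nm^2. Multiples of water are
#' written as `eta = k * water_viscosity`.
#' @export
water_viscosity <- 1e-9

#' @export
print.fluid_cargo <- function(x, ...) {
  cat(sprintf("Cargo in fluid: d = %g nm, eta = %g x water, chi = %g\n",
              x$d, x$eta / water_viscosity, x$chi))
  cat(sprintf("  xi = %.4g pN s/nm   D = %.4g nm^2/s\n", x$xi, x$D))
  invisible(x)
}

#' Friction coefficient of a spherical cargo
#'
#' `xi = chi * 3 * pi * eta * d`. `chi = 1` is the free-space Stokes value,
#' `chi = 3` the near-wall default.
#'
#' @param eta Viscosity (pN s/nm^2).
#' @param d Diameter (nm).
#' @param chi Wall-correction multiplier.
#' @return Friction coefficient (pN s/nm).
#' @export
friction_coefficient <- function(eta, d, chi = 3) {
  if (any(!is.finite(c(eta, d, chi))) || any(c(eta, d, chi) <= 0))
    stop("friction_coefficient: eta, d, chi must be positive", call. = FALSE)
  chi * 3 * pi * eta * d
}

#' Diffusion coefficient from the Einstein relation
#'
#' `D = kBT / xi`.
#'
#' @param xi Friction coefficient (pN s/nm).
#' @param kBT Thermal energy (pN nm).
#' @return Diffusion coefficient (nm^2/s).
#' @export
diffusion_coefficient <- function(xi, kBT = 4.11) {
  if (any(!is.finite(xi)) || any(xi <= 0))
    stop("diffusion_coefficient: 'xi' must be positive", call. = FALSE)
  kBT / xi
}

#' Characteristic viscous drag
#'
#' `9 * pi * eta * d * v`: the near-wall Stokes drag on the cargo at
#' velocity `v`. This single quantity collapses the effects of viscosity,
#' cargo size and motor velocity on run length, and is the x-axis of the
#' sweep summaries.
#'
#' @param eta Viscosity (pN s/nm^2).
#' @param d Cargo diameter (nm).
#' @param v Velocity (nm/s), non-negative.
#' @return Drag force (pN).
#' @examples
#' characteristic_drag(water_viscosity, 500, 800)  # 0.0113 pN
#' @export
characteristic_drag <- function(eta, d, v) {
  if (any(v < 0)) stop("characteristic_drag: 'v' must be non-negative",
                       call. = FALSE)
  9 * pi * eta * d * v
}

#' Tether load on the motor
#'
#' The motor and cargo are connected by an ideal spring with rest length
#' `L0`: no force is transmitted while the cargo-motor displacement is
#' within `[-L0, L0]`; beyond it the load is `kappa` times the extension.
#' The sign follows the transport convention: positive (assisting) when
#' the cargo leads the motor, negative (hindering) when it lags. The force
#' on the cargo is the negation of the returned value.
#'
#' @param delta Displacement cargo minus motor (nm); vectorized.
#' @param kappa Tether stiffness (pN/nm).
#' @param L0 Rest length (nm).
#' @return Signed load on the motor (pN).
#' @examples
#' tether_load_on_motor(45)    # +1.6 pN (assisting)
#' tether_load_on_motor(-50)   # -3.2 pN (hindering)
#' @export
tether_load_on_motor <- function(delta, kappa = 0.32, L0 = 40) {
  if (!is.finite(kappa) || kappa <= 0)
    stop("tether_load_on_motor: 'kappa' must be positive", call. = FALSE)
  if (!is.finite(L0) || L0 < 0)
    stop("tether_load_on_motor: 'L0' must be non-negative", call. = FALSE)
  ifelse(delta > L0, kappa * (delta - L0),
         ifelse(delta < -L0, -kappa * (abs(delta) - L0), 0))
}
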