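#' @useDynLib kinesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.config_schema <- list(
  motor = c("v0", "l0", "step_size", "Fs", "kappa", "L0", "k_on"),
  detachment = c("variant", "kBT", "delta_minus", "delta_plus",
                 "bridge_slope", "bridge_prefactor"),
  fluid = c("d", "eta", "eta_water", "chi"),
  simulation = c("dt", "n_replicates", "max_steps", "seed", "mode",
                 "equilibrium_steps", "record_stride",
                 "include_binding_wait", "burn_in", "init_delta"),
  sweep = c("eta_water", "d", "v0", "kappa", "variant", "diffusion",
            "n_replicates", "seed", "output_dir")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `motor`, `detachment`,
#' `fluid`, `simulation` and (optionally) `sweep`, applies the package
#' defaults for any key not given, validates every key, and returns the
#' resolved parameter objects. An empty or missing file yields the full
#' default configuration. Validation collects all offending keys before
#' erroring.
#'
#' Viscosity may be given either as `fluid.eta` (pN s/nm^2) or as
#' `fluid.eta_water` (multiples of the viscosity of water); if both are
#' present they must agree.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list merged over the file contents
#'   (same section structure), e.g. from command-line flags.
#' @return A list of class `kinesim_config` with elements `motor`,
#'   `profile`, `fluid`, `simulation` (a [sim_config()]), `sweep` (raw
#'   list or `NULL`) and `resolved` (flat list echoing every value, for
#'   the JSON sidecar).
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("load_config: file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  if (!is.null(overrides)) raw <- utils::modifyList(raw, overrides)

  problems <- character(0)
  for (sec in names(raw)) {
    if (!sec %in% names(.config_schema)) {
      problems <- c(problems, paste0("unknown section '", sec, "'"))
      next
    }
    extra <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(extra))
      problems <- c(problems, paste0("unknown key ", sec, ".", extra))
  }

  g <- function(sec, key, default = NULL) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }
  pos <- function(sec, key, v) {
    if (!is.null(v) && (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)))
      problems <<- c(problems, paste0("non-positive value for ", sec, ".", key))
    v
  }

  m <- list(v0 = pos("motor", "v0", g("motor", "v0", 800)),
            l0 = pos("motor", "l0", g("motor", "l0", 1500)),
            step_size = pos("motor", "step_size", g("motor", "step_size", 8)),
            Fs = pos("motor", "Fs", g("motor", "Fs", 7)),
            kappa = pos("motor", "kappa", g("motor", "kappa", 0.32)),
            L0 = pos("motor", "L0", g("motor", "L0", 40)),
            k_on = pos("motor", "k_on", g("motor", "k_on", 5)))

  variant <- g("detachment", "variant", "measured")
  if (!variant %in% .profile_variants)
    problems <- c(problems, paste0("detachment.variant must be one of ",
                                   paste(.profile_variants, collapse = ", ")))
  det <- list(kBT = pos("detachment", "kBT", g("detachment", "kBT", 4.11)),
              delta_minus = pos("detachment", "delta_minus",
                                g("detachment", "delta_minus", 0.60)),
              delta_plus = pos("detachment", "delta_plus",
                               g("detachment", "delta_plus", 0.32)),
              bridge_slope = pos("detachment", "bridge_slope",
                                 g("detachment", "bridge_slope", 3.8247)),
              bridge_prefactor = pos("detachment", "bridge_prefactor",
                                     g("detachment", "bridge_prefactor", 7.4)))

  eta_abs <- g("fluid", "eta")
  eta_rel <- g("fluid", "eta_water")
  if (!is.null(eta_abs) && !is.null(eta_rel) &&
      abs(eta_abs - eta_rel * water_viscosity) > 1e-15)
    problems <- c(problems, "fluid.eta and fluid.eta_water disagree")
  eta <- if (!is.null(eta_abs)) eta_abs
         else if (!is.null(eta_rel)) eta_rel * water_viscosity
         else water_viscosity
  fl <- list(d = pos("fluid", "d", g("fluid", "d", 500)),
             eta = pos("fluid", "eta", eta),
             chi = pos("fluid", "chi", g("fluid", "chi", 3)))

  mode <- g("simulation", "mode", "transport")
  if (!mode %in% c("transport", "equilibrium"))
    problems <- c(problems, "simulation.mode must be transport or equilibrium")
  dt <- g("simulation", "dt")
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0))
    problems <- c(problems, "non-positive value for simulation.dt")
  # stiffness-dependent default: stiffer tethers need finer time resolution
  if (is.null(dt) && is.numeric(m$kappa))
    dt <- if (m$kappa > 0.32) 1e-6 else 1e-5

  if (length(problems))
    stop("load_config: invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  motor <- do.call(motor_params, m)
  profile <- detachment_profile(variant = variant, motor = motor,
                                kBT = det$kBT,
                                delta_minus = det$delta_minus,
                                delta_plus = det$delta_plus,
                                bridge_slope = det$bridge_slope,
                                bridge_prefactor = det$bridge_prefactor)
  fluid <- fluid_cargo(d = fl$d, eta = fl$eta, chi = fl$chi, kBT = det$kBT)
  simulation <- sim_config(
    dt = dt,
    n_replicates = g("simulation", "n_replicates", 1000),
    max_steps = g("simulation", "max_steps", 1e7),
    seed = g("simulation", "seed"),
    mode = mode,
    equilibrium_steps = g("simulation", "equilibrium_steps", 20000),
    record_stride = g("simulation", "record_stride"),
    include_binding_wait = g("simulation", "include_binding_wait", FALSE),
    burn_in = g("simulation", "burn_in", 0),
    init_delta = g("simulation", "init_delta", 0))

  resolved <- list(motor = m,
                   detachment = c(list(variant = variant), det),
                   fluid = c(fl, list(eta_water = fl$eta / water_viscosity,
                                      xi = fluid$xi, D = fluid$D)),
                   simulation = unclass(simulation))
  structure(list(motor = motor, profile = profile, fluid = fluid,
                 simulation = simulation, sweep = raw$sweep,
                 resolved = resolved),
            class = "kinesim_config")
}

#' Write the resolved configuration as a JSON sidecar
#'
#' Records every resolved parameter (including derived quantities and the
#' seed) so a run can be reproduced bit-exactly.
#'
#' @param config A `kinesim_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_sidecar <- function(config, path) {
  stopifnot(inherits(config, "kinesim_config"))
  jsonlite::write_json(config$resolved, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
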