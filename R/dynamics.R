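#' Droplet parameters for rotation-dynamics calculations
#'
#' Bundles the physical constants of a trapped water-in-oil droplet driven by
#' external oil perfusion. The inner recirculation vortex follows a
#' Hadamard-Rybczynski flow, so the rotation dynamics depend only on the
#' droplet radius, the bulk flow velocity, and the inner/outer viscosity
#' ratio, plus a proportionality `alpha` linking the applied oil flow rate to
#' the bulk velocity at the droplet surface.
#'
#' Defaults reflect the operating point of the droplet trap array: a 70 um
#' diameter droplet (R0 = 35 um), aqueous interior (eta_i = 8.9e-4 Pa s),
#' HFE-7500 fluorinated oil exterior (eta_o = 1.24e-3 Pa s, manufacturer
#' value), and `alpha` calibrated so 1 uL/min of oil flow yields 0.44 rad/s
#' of cell angular velocity.
#'
#' @param R0 droplet radius, um.
#' @param U0 bulk flow velocity, um/s.
#' @param eta_i,eta_o inner / outer phase dynamic viscosities, Pa s.
#' @param alpha velocity-per-flow-rate proportionality, (um/s) per (uL/min);
#'   `NULL` calibrates it from the default operating point
#'   (1 uL/min -> 0.44 rad/s) via [calibrate_alpha()].
#' @return an object of class `droplet_params`.
#' @export
#' @examples
#' p <- droplet_params()
#' angular_velocity(1, p)  # 0.44 rad/s at the calibration point
droplet_params <- function(R0 = 35, U0 = 80, eta_i = 8.9e-4, eta_o = 1.24e-3,
                           alpha = NULL) {
  vals <- c(R0 = R0, U0 = U0, eta_i = eta_i, eta_o = eta_o)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .dt_stop("droplet_params: R0, U0, eta_i, eta_o must all be finite and > 0")
  if (is.null(alpha))
    alpha <- calibrate_alpha(1, 0.44, R0 = R0, eta_i = eta_i, eta_o = eta_o)
  if (!is.finite(alpha) || alpha <= 0)
    .dt_stop("droplet_params: alpha must be finite and > 0")
  structure(list(R0 = R0, U0 = U0, eta_i = eta_i, eta_o = eta_o,
                 alpha = alpha), class = "droplet_params")
}

#' Recirculation timescale of the intradroplet vortex
#'
#' Time for an infinitesimally small tracer to complete one loop of the
#' closed recirculation streamlines of a Hadamard-Rybczynski flow inside a
#' sheared droplet: tau = (2 R0 / U0) (1 + eta_i/eta_o). The cell rotation
#' period is of the order of tau.
#'
#' @param R0 droplet radius, um.
#' @param U0 bulk flow velocity, um/s.
#' @param eta_i,eta_o inner/outer phase viscosities, Pa s.
#' @return timescale in seconds.
#' @export
#' @examples
#' recirculation_timescale(35, 80, 8.9e-4, 1.24e-3)  # ~1.5 s
recirculation_timescale <- function(R0, U0, eta_i, eta_o) {
  if (any(!is.finite(c(R0, U0, eta_o))) || R0 <= 0 || U0 <= 0 || eta_o <= 0)
    .dt_stop("recirculation_timescale: R0, U0, eta_o must be finite and > 0")
  if (!is.finite(eta_i) || eta_i < 0)
    .dt_stop("recirculation_timescale: eta_i must be finite and >= 0")
  (2 * R0 / U0) * (1 + eta_i / eta_o)
}

#' Cell angular velocity as a function of oil flow rate
#'
#' Linear flow-to-rotation model: with the bulk velocity proportional to the
#' applied flow rate (U0 = alpha Q), the angular velocity of an encapsulated
#' cell is omega(Q) = alpha pi Q / (R0 (1 + eta_i/eta_o)), i.e. 2 pi over
#' the recirculation timescale evaluated at U0 = alpha Q.
#'
#' @param Q applied oil flow rate, uL/min (vectorized).
#' @param params a [droplet_params()] object.
#' @return angular velocity in rad/s.
#' @export
#' @examples
#' p <- droplet_params()
#' angular_velocity(c(1, 2), p)  # 0.44, 0.88 rad/s
angular_velocity <- function(Q, params = droplet_params()) {
  stopifnot(inherits(params, "droplet_params"))
  if (any(!is.finite(Q)) || any(Q < 0))
    .dt_stop("angular_velocity: Q must be finite and >= 0")
  params$alpha * pi * Q / (params$R0 * (1 + params$eta_i / params$eta_o))
}

#' Calibrate the flow-to-velocity proportionality
#'
#' Solves alpha from one measured operating point (Q_ref, omega_ref) so that
#' [angular_velocity()] reproduces omega_ref at Q_ref exactly.
#'
#' @param Q_ref reference flow rate, uL/min.
#' @param omega_ref measured angular velocity at `Q_ref`, rad/s.
#' @param R0 droplet radius, um.
#' @param eta_i,eta_o inner/outer phase viscosities, Pa s.
#' @return alpha in (um/s) per (uL/min).
#' @export
calibrate_alpha <- function(Q_ref, omega_ref, R0 = 35, eta_i = 8.9e-4,
                            eta_o = 1.24e-3) {
  if (any(!is.finite(c(Q_ref, omega_ref))) || Q_ref <= 0 || omega_ref <= 0)
    .dt_stop("calibrate_alpha: Q_ref and omega_ref must be finite and > 0")
  omega_ref * R0 * (1 + eta_i / eta_o) / (pi * Q_ref)
}

#' Shear stress on a rotating encapsulated cell
#'
#' Order-of-magnitude estimate taking the shear rate proportional to the
#' cell angular velocity: tau_s ~ eta * omega, reported in mPa. At the
#' imaging rotation periods of 5-8 s this evaluates to ~1.1-0.7 mPa, far
#' below vascular wall shear or flow-cytometry nozzle stresses.
#'
#' @param omega angular velocity, rad/s (vectorized).
#' @param eta dynamic viscosity, Pa s; default water at room temperature.
#' @return shear stress in mPa.
#' @export
#' @examples
#' shear_stress(2 * pi / 5)  # ~1.1 mPa
#' shear_stress(2 * pi / 8)  # ~0.7 mPa
shear_stress <- function(omega, eta = 8.9e-4) {
  if (any(!is.finite(omega)) || any(omega < 0))
    .dt_stop("shear_stress: omega must be finite and >= 0")
  if (!is.finite(eta) || eta <= 0)
    .dt_stop("shear_stress: eta must be finite and > 0")
  .pa_to_mpa(eta * omega)
}

#' Plan a tomographic acquisition from the rotation rate
#'
#' Fills in the mutually consistent acquisition quantities for one full-turn
#' projection series: angular velocity, rpm, rotation period, per-slice
#' exposure (the camera must complete `n_slices` frames in one period) and
#' angular step. Supply exactly one of `omega` or `rpm`.
#'
#' @param omega angular velocity, rad/s.
#' @param rpm rotation rate, revolutions per minute.
#' @param n_slices number of projection frames per 360 degrees (>= 2).
#' @return an `acquisition_plan` list with fields `omega`, `rpm`,
#'   `period_T` (s), `n_slices`, `exposure_per_slice` (ms), `angle_step`
#'   (degrees).
#' @export
#' @examples
#' plan_acquisition(rpm = 21, n_slices = 1200)$exposure_per_slice  # < 2.5 ms
#' plan_acquisition(omega = 2 * pi / 5.33, n_slices = 800)$angle_step  # 0.45
plan_acquisition <- function(omega = NULL, rpm = NULL, n_slices) {
  if (is.null(omega) == is.null(rpm))
    .dt_stop("plan_acquisition: supply exactly one of omega or rpm")
  if (is.null(omega)) omega <- rpm_to_rad_s(rpm)
  if (!is.finite(omega) || omega <= 0)
    .dt_stop("plan_acquisition: rotation rate must be finite and > 0")
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 2)
    .dt_stop("plan_acquisition: n_slices must be an integer >= 2")
  period <- 2 * pi / omega
  structure(list(
    omega = omega,
    rpm = rad_s_to_rpm(omega),
    period_T = period,
    n_slices = n_slices,
    exposure_per_slice = 1000 * period / n_slices,
    angle_step = 360 / n_slices
  ), class = "acquisition_plan")
}

#' Frame exposure time at a given frame rate
#'
#' @param fps camera frame rate, frames/s.
#' @return maximum exposure per frame in ms (1000/fps).
#' @export
#' @examples
#' exposure_ms(150)  # 6.67 ms
exposure_ms <- function(fps) {
  if (any(!is.finite(fps)) || any(fps <= 0))
    .dt_stop("exposure_ms: fps must be finite and > 0")
  1000 / fps
}

#' Rayleigh diffraction-limited resolution
#'
#' @param wavelength emission wavelength, nm.
#' @param NA_obj objective numerical aperture.
#' @return resolution 0.61 * wavelength / NA in nm.
#' @export
#' @examples
#' rayleigh_resolution(461, 1.3)  # ~216 nm
#' rayleigh_resolution(520, 1.3)  # ~244 nm
rayleigh_resolution <- function(wavelength, NA_obj) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    .dt_stop("rayleigh_resolution: wavelength must be finite and > 0")
  if (any(!is.finite(NA_obj)) || any(NA_obj <= 0))
    .dt_stop("rayleigh_resolution: NA must be finite and > 0")
  0.61 * wavelength / NA_obj
}
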