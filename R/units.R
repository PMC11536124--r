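#' Unit conversions used throughout the package
#'
#' All rotation-rate conversions are centralized here so the dynamics and
#' planning calculators never carry their own magic constants. External
#' interfaces use micrometres, seconds, degrees, rad/s, rpm, Hz and mPa.
#'
#' @param omega angular velocity in rad/s.
#' @param rpm rotation rate in revolutions per minute.
#' @param deg,rad angles in degrees / radians.
#' @return the converted numeric value(s).
#' @examples
#' rad_s_to_rpm(0.88)   # ~8.4 rpm
#' rpm_to_rad_s(rad_s_to_rpm(1)) # 1
#' @name units
NULL

#' @rdname units
#' @export
rad_s_to_rpm <- function(omega) omega * 60 / (2 * pi)

#' @rdname units
#' @export
rpm_to_rad_s <- function(rpm) rpm * 2 * pi / 60

#' @rdname units
#' @export
deg_to_rad <- function(deg) deg * pi / 180

#' @rdname units
#' @export
rad_to_deg <- function(rad) rad * 180 / pi

# Pa -> mPa
.pa_to_mpa <- function(x) x * 1e3
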