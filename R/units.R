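#' Speed of light in cm per picosecond
#'
#' All beat frequencies in this package are quoted in wavenumbers
#' (cm^-1) and all delays in picoseconds; the conversion between a
#' level gap in cm^-1 and an oscillation frequency in cycles/ps is
#' `f = c * gap` with `c` in cm/ps.
#'
#' @return The speed of light, 2.99792458e-2 cm/ps.
#' @export
speed_of_light_cm_ps <- function() 2.99792458e-2

# internal shorthand; never exported so it cannot drift from the accessor
.c_cm_ps <- 2.99792458e-2

#' Convert a vacuum wavelength to an energy relative to an origin
#'
#' `10^7 / lambda_nm` is the photon energy in cm^-1; subtracting the
#' absolute band origin gives the excitation energy relative to that
#' origin (negative values mean the pump is red of the origin).
#'
#' @param lambda_nm Vacuum wavelength in nm (> 0).
#' @param origin_cm1 Absolute origin energy in cm^-1.
#' @return Relative energy in cm^-1.
#' @examples
#' wavelength_to_relative_energy(346.6054, 28851) # ~0, the origin itself
#' wavelength_to_relative_energy(330, 28851)      # ~ +1452
#' @export
wavelength_to_relative_energy <- function(lambda_nm, origin_cm1) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop("'lambda_nm' must be a positive, finite wavelength in nm")
  1e7 / lambda_nm - origin_cm1
}

#' Oscillation period of a quantum beat
#'
#' @param gap_cm1 Level gap in cm^-1 (> 0).
#' @return Beat period in ps, `1 / (c * gap)`.
#' @examples
#' beat_period_ps(179) # 0.1864 ps
#' @export
beat_period_ps <- function(gap_cm1) {
  if (any(gap_cm1 <= 0)) stop("'gap_cm1' must be positive")
  1 / (.c_cm_ps * gap_cm1)
}

# unit-peak Gaussian parameterized by FWHM
gauss_peak1 <- function(x, center, fwhm) {
  exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
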