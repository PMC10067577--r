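#' Optical redox ratio
#'
#' NAD(P)H intensity divided by the summed NAD(P)H and FAD intensities, a
#' dimensionless proxy in `[0, 1]` for the cellular redox state.
#'
#' @param nadph_intensity,fad_intensity photon counts (>= 0, not both zero).
#' @return the ratio `N / (N + F)`.
#' @export
redox_ratio <- function(nadph_intensity, fad_intensity) {
  of_check(all(nadph_intensity >= 0) && all(fad_intensity >= 0),
           "intensities must be non-negative")
  s <- nadph_intensity + fad_intensity
  if (any(s == 0)) {
    of_stop("redox ratio undefined: both intensities are zero", "omiflim_undefined_ratio")
  }
  nadph_intensity / s
}

#' Two-color two-photon excitation wavelength
#'
#' The effective two-color two-photon wavelength obtained by mixing two
#' excitation lines satisfies `2 / lambda = 1 / lambda1 + 1 / lambda2`,
#' i.e. the harmonic mean of the two lines.
#'
#' @param lambda1,lambda2 wavelengths in nanometers (> 0).
#' @return combined wavelength in nanometers.
#' @examples
#' two_color_wavelength(750, 1041)  # ~872 nm
#' @export
two_color_wavelength <- function(lambda1, lambda2) {
  of_check(all(lambda1 > 0) && all(lambda2 > 0), "wavelengths must be positive")
  2 * lambda1 * lambda2 / (lambda1 + lambda2)
}

#' Caliper tumor volume
#'
#' Ellipsoid approximation from caliper measurements:
#' `volume = width^2 * length / 2`.
#'
#' @param width,length caliper measurements in millimeters (>= 0).
#' @return volume in cubic millimeters.
#' @export
tumor_volume <- function(width, length) {
  of_check(all(width >= 0) && all(length >= 0), "measurements must be non-negative")
  width^2 * length / 2
}
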