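#' Optical constants for water-window projection imaging
#'
#' Bundles the linear attenuation coefficients and beam parameters used by
#' the phantom projector and the absorbance pipeline.  In the water window
#' (2.3--4.3 nm) carbonaceous material absorbs roughly an order of magnitude
#' more strongly than water, which is what makes unstained hydrated cells
#' and virions visible.
#'
#' @param mu_water Linear attenuation coefficient of water/medium, per
#'   micrometre.  The default is derived from a measured transmission of 27%
#'   through 10 micrometres of incomplete growth medium, see
#'   [attenuation_from_transmission()].
#' @param mu_biomass Linear attenuation coefficient of dry biomass, per
#'   micrometre (order-of-magnitude water-window protein contrast).
#' @param flat_field_photons Expected photons per pixel with no sample in
#'   the beam (flat-field exposure).
#' @param ice_thickness Thickness in micrometres of medium/ice the beam
#'   traverses where there is no sample material.
#'
#' @return An object of class `optical_constants`.
#' @examples
#' optical_constants()
#' @export
optical_constants <- function(mu_water = attenuation_from_transmission(10, 0.27),
                              mu_biomass = 1.1,
                              flat_field_photons = 700,
                              ice_thickness = 10) {
  stopifnot(mu_water > 0, mu_biomass > 0, flat_field_photons > 0,
            ice_thickness > 0)
  if (mu_biomass <= mu_water) {
    stop("`mu_biomass` must exceed `mu_water`: dry biomass is the ",
         "high-contrast component in the water window")
  }
  structure(
    list(mu_water = mu_water, mu_biomass = mu_biomass,
         flat_field_photons = flat_field_photons,
         ice_thickness = ice_thickness),
    class = "optical_constants"
  )
}

#' @export
print.optical_constants <- function(x, ...) {
  cat("Optical constants (water window)\n")
  cat(sprintf("  mu_water   : %.4f / um\n", x$mu_water))
  cat(sprintf("  mu_biomass : %.4f / um\n", x$mu_biomass))
  cat(sprintf("  flat field : %g photons/pixel\n", x$flat_field_photons))
  cat(sprintf("  ice layer  : %g um\n", x$ice_thickness))
  invisible(x)
}

#' Linear attenuation coefficient from a transmission measurement
#'
#' Inverts the Beer--Lambert law `T = exp(-mu * t)` to recover the
#' attenuation coefficient from a transmitted fraction through a known
#' thickness, e.g. 27% transmission through 10 micrometres of growth medium
#' gives 0.1309 per micrometre.
#'
#' @param thickness Path length in micrometres, `> 0`.
#' @param transmission Transmitted fraction, strictly inside `(0, 1)`.
#' @return Attenuation coefficient in inverse micrometres.
#' @examples
#' attenuation_from_transmission(10, 0.27)
#' @export
attenuation_from_transmission <- function(thickness, transmission) {
  if (!is.numeric(thickness) || any(thickness <= 0)) {
    stop("`thickness` must be positive")
  }
  if (!is.numeric(transmission) || any(transmission <= 0) ||
      any(transmission >= 1)) {
    stop("`transmission` must lie strictly inside (0, 1)")
  }
  -log(transmission) / thickness
}
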