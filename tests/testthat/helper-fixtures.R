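# Shared fixtures: small optics and phantoms, built in code at test time.

test_optics <- function() optical_constants()

# Noiseless micrograph of a projection, photon expectation values as
# "counts" (valid: counts only need to be non-negative and finite).
noiseless_micrograph <- function(projection, optics) {
  micrograph(optics$flat_field_photons * projection$transmission,
             projection$pixel_size)
}

# Illumination fit object with known parameters (bypasses fitting); the
# amplitude is expressed in detected photons so absorbance maps read the
# water-excess absorbance directly when `through_medium = TRUE`.
known_illumination <- function(optics, nr, nc, amplitude = 1,
                               widths_px = c(nc, nr),
                               through_medium = TRUE) {
  structure(list(
    amplitude = amplitude * optics$flat_field_photons *
      (if (through_medium) exp(-optics$mu_water * optics$ice_thickness)
       else 1),
    center_px = c((nc - 1) / 2, (nr - 1) / 2),
    widths_px = widths_px, offset = 0, medium_factor = 1,
    residual_norm = 0, near_uniform = FALSE, n_points = 0
  ), class = "illumination_fit")
}

# Small infected-cell projection used across absorbance tests.
small_cell_projection <- function(n_virions = 12, seed = 42,
                                  optics = test_optics()) {
  ph <- default_phantom(n_virions = n_virions, seed = seed, fov_px = 240L,
                        pixel_size = 80, cell_semi_axes = c(6, 5, 2),
                        with_nucleus = FALSE, with_vacuoles = FALSE)
  project_phantom(ph, optics)
}
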