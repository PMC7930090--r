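#' Geometric components of an optical phantom
#'
#' Phantoms are built from ellipsoids (cell body, nucleus), spheres
#' (water-filled vacuoles) and prolate spheroids (virions).  All geometry is
#' expressed in micrometres in the sample plane, with the optical axis along
#' z; `center` is `c(x, y, z)` with the beam integrating along z.
#'
#' `density` is the dry-biomass volume fraction of the component: its
#' effective attenuation coefficient is
#' `density * mu_biomass + (1 - density) * mu_water`, so a vacuole
#' (`density = 0`) attenuates exactly like the surrounding medium and a
#' fully condensed virion has `density = 1`.
#'
#' @param center Numeric length-3, micrometres (z may be omitted and
#'   defaults to 0, the midplane).
#' @param semi_axes Numeric length-3 semi-axes in micrometres (x, y, z).
#' @param density Dry-biomass volume fraction in `[0, 1]`.
#' @param radius Sphere radius, micrometres.
#' @param length_nm,width_nm Polar length and equatorial width of a virion
#'   in nanometres; `length_nm >= width_nm`.
#' @param theta Polar angle of the virion long axis from the optical axis,
#'   radians; `pi/2` lies in the image plane (fully visible projected
#'   length), `0` points along the beam.
#' @param phi Azimuth of the long axis in the image plane, radians.
#' @return A component object (`vq_ellipsoid`, `vq_sphere`, `vq_virion`).
#' @name phantom-components
NULL

#' @rdname phantom-components
#' @export
ellipsoid <- function(center, semi_axes, density) {
  if (length(center) == 2L) center <- c(center, 0)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0), density >= 0, density <= 1)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 density = density),
            class = "vq_ellipsoid")
}

#' @rdname phantom-components
#' @export
sphere <- function(center, radius, density = 0) {
  if (length(center) == 2L) center <- c(center, 0)
  stopifnot(length(center) == 3L, radius > 0, density >= 0, density <= 1)
  structure(list(center = as.numeric(center), radius = radius,
                 density = density),
            class = "vq_sphere")
}

#' @rdname phantom-components
#' @export
virion <- function(center, length_nm = 1250, width_nm = 590,
                   theta = pi / 2, phi = 0, density = 1) {
  if (length(center) == 2L) center <- c(center, 0)
  stopifnot(length(center) == 3L, width_nm > 0, density >= 0, density <= 1)
  if (length_nm < width_nm) {
    stop("a prolate spheroid needs `length_nm >= width_nm`")
  }
  structure(list(center = as.numeric(center), length_nm = length_nm,
                 width_nm = width_nm, theta = theta, phi = phi,
                 density = density),
            class = "vq_virion")
}

#' 2D Gaussian illumination profile
#'
#' The condenser illumination of a full-field microscope is modelled as an
#' elliptical 2D Gaussian in the image plane, optionally on a constant
#' pedestal.  Amplitude is relative to the nominal flat field (1 means the
#' profile peak delivers the full `flat_field_photons`).
#'
#' @param amplitude Peak relative intensity, `> 0`.
#' @param center_px Peak position `c(x, y)` in 0-based pixel coordinates.
#' @param widths_px Gaussian sigma along x and y, pixels.
#' @param offset Constant pedestal added to the Gaussian (relative units).
#' @return An `illumination_profile` object.
#' @export
illumination_profile <- function(amplitude = 1, center_px, widths_px,
                                 offset = 0) {
  stopifnot(amplitude > 0, length(center_px) == 2L, length(widths_px) == 2L,
            all(widths_px > 0), offset >= 0)
  structure(list(amplitude = amplitude, center_px = as.numeric(center_px),
                 widths_px = as.numeric(widths_px), offset = offset),
            class = "illumination_profile")
}

# Evaluate an illumination profile on an nr x nc pixel grid (0-based
# centres), returning a matrix [row, col].
eval_illumination <- function(ill, nr, nc) {
  x <- (seq_len(nc) - 1)
  y <- (seq_len(nr) - 1)
  gx <- exp(-((x - ill$center_px[1])^2) / (2 * ill$widths_px[1]^2))
  gy <- exp(-((y - ill$center_px[2])^2) / (2 * ill$widths_px[2]^2))
  ill$amplitude * outer(gy, gx) + ill$offset
}

#' Assemble an optical phantom
#'
#' A phantom is the ground-truth scene projected by [project_phantom()]: an
#' amoeba-like cell ellipsoid of uniform dry-biomass density containing an
#' optional nucleus, water-filled vacuoles and a set of virions, under a 2D
#' Gaussian illumination.  Virion centres outside the cell ellipsoid are
#' allowed but flagged extracellular.
#'
#' @param cell A `vq_ellipsoid` (the cell body), or `NULL` for an empty
#'   scene (medium only).
#' @param virions List of [virion()] objects.
#' @param nucleus Optional `vq_ellipsoid`.
#' @param vacuoles List of [sphere()] objects (zero biomass).
#' @param illumination An [illumination_profile()]; default is a broad
#'   centred Gaussian with amplitude 1.
#' @param fov_px Field of view in pixels, `c(nrow, ncol)` or a scalar.
#' @param pixel_size Pixel pitch in nanometres in the sample plane.
#' @return A `vq_phantom` object.
#' @seealso [default_phantom()], [project_phantom()]
#' @export
phantom <- function(cell = NULL, virions = list(), nucleus = NULL,
                    vacuoles = list(), illumination = NULL,
                    fov_px = c(2048L, 2048L), pixel_size = 19.3) {
  if (length(fov_px) == 1L) fov_px <- c(fov_px, fov_px)
  check_scalar(pixel_size, "pixel_size")
  stopifnot(all(fov_px >= 4))
  if (!is.null(cell)) stopifnot(inherits(cell, "vq_ellipsoid"))
  if (!is.null(nucleus)) stopifnot(inherits(nucleus, "vq_ellipsoid"))
  stopifnot(all(vapply(virions, inherits, TRUE, "vq_virion")),
            all(vapply(vacuoles, inherits, TRUE, "vq_sphere")))
  if (is.null(illumination)) {
    illumination <- illumination_profile(
      amplitude = 1,
      center_px = (rev(fov_px) - 1) / 2,
      widths_px = rev(fov_px)
    )
  }
  extracellular <- vapply(virions, function(v) {
    if (is.null(cell)) return(TRUE)
    d <- (v$center - cell$center) / cell$semi_axes
    sum(d^2) > 1
  }, logical(1))
  structure(list(cell = cell, virions = virions, nucleus = nucleus,
                 vacuoles = vacuoles, illumination = illumination,
                 fov_px = as.integer(fov_px), pixel_size = pixel_size,
                 extracellular = extracellular),
            class = "vq_phantom")
}

#' @export
print.vq_phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d x %d px @ %.3g nm/px, %d virion(s)%s\n",
              x$fov_px[1], x$fov_px[2], x$pixel_size, length(x$virions),
              if (is.null(x$cell)) ", no cell" else ""))
  invisible(x)
}

#' Default infected-cell phantom
#'
#' Builds a phantom emulating a typical adhered amoeba: a flattened cell
#' ellipsoid 30 x 25 x 4 micrometres whose 4 um thickness matches a typical
#' cryo-fixed cell, a nucleus, two vacuoles, and `n_virions` randomly
#' placed, uniformly oriented virions of 1250 x 590 nm.  The default
#' dry-biomass density of the cell (0.14) is calibrated so that the mean
#' photon expectation inside the cell is close to 130 photons/pixel under a
#' 700 photons/pixel flat field.
#'
#' @param n_virions Number of virions to place inside the cell.
#' @param seed Integer seed controlling placement and orientations.
#' @param fov_px Field of view (pixels), scalar or `c(nrow, ncol)`.
#' @param pixel_size Pixel pitch, nm.
#' @param cell_semi_axes Cell semi-axes `c(x, y, z)` in micrometres.
#' @param cell_density Dry-biomass volume fraction of the cytoplasm.
#' @param virion_length_nm,virion_width_nm Virion axes in nm.
#' @param with_nucleus,with_vacuoles Include the organelle components.
#' @return A `vq_phantom`.
#' @export
default_phantom <- function(n_virions = 0, seed = 0,
                            fov_px = 2048L, pixel_size = 19.3,
                            cell_semi_axes = c(15, 12.5, 2),
                            cell_density = 0.14,
                            virion_length_nm = 1250, virion_width_nm = 590,
                            with_nucleus = TRUE, with_vacuoles = TRUE) {
  if (length(fov_px) == 1L) fov_px <- c(fov_px, fov_px)
  px_um <- pixel_size / 1000
  fov_um <- rev(fov_px) * px_um          # c(x extent, y extent)
  centre <- c(fov_um / 2, 0)
  cell <- ellipsoid(centre, cell_semi_axes, cell_density)
  nucleus <- if (with_nucleus) {
    ellipsoid(centre + c(-0.35, 0.25, 0) * cell_semi_axes,
              cell_semi_axes * c(0.2, 0.22, 0.45),
              min(1, cell_density * 1.6))
  }
  vacuoles <- if (with_vacuoles) {
    r <- 0.12 * min(cell_semi_axes[1:2])
    list(sphere(centre + c(0.4, -0.3, 0) * cell_semi_axes, r),
         sphere(centre + c(0.1, 0.45, 0) * cell_semi_axes, r * 0.8))
  } else {
    list()
  }
  virions <- list()
  if (n_virions > 0) {
    virions <- with_seed(seed, {
      theta <- sample_orientation_impl(n_virions)
      phi <- stats::runif(n_virions, 0, 2 * pi)
      # rejection-sample centres uniformly inside a shrunken cell ellipsoid
      # so virions stay (essentially) inside the cytoplasm
      margin <- virion_length_nm / 2000
      scale <- pmax(0.1, 1 - margin / cell_semi_axes)
      out <- vector("list", n_virions)
      k <- 0
      while (k < n_virions) {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) {
          k <- k + 1
          out[[k]] <- virion(centre + p * cell_semi_axes * scale,
                             virion_length_nm, virion_width_nm,
                             theta = theta[k], phi = phi[k])
        }
      }
      out
    })
  }
  phantom(cell = cell, virions = virions, nucleus = nucleus,
          vacuoles = vacuoles, fov_px = fov_px, pixel_size = pixel_size)
}

# Chord length along z through an axis-aligned ellipsoid, evaluated on the
# pixel grid (xs, ys in um).  Returns matrix [row, col].
chord_ellipsoid <- function(xs, ys, center, semi_axes) {
  ux <- ((xs - center[1]) / semi_axes[1])^2
  uy <- ((ys - center[2]) / semi_axes[2])^2
  u <- 1 - outer(uy, ux, "+")
  2 * semi_axes[3] * sqrt(pmax(u, 0))
}

# Chord length along z through an arbitrarily oriented prolate spheroid.
# Returns NULL or list(rows, cols, chord matrix) restricted to the
# bounding box of the projected outline.
chord_spheroid <- function(xs, ys, v) {
  ap <- v$length_nm / 2000   # polar semi-axis, um
  ae <- v$width_nm / 2000    # equatorial semi-axis, um
  u <- c(sin(v$theta) * cos(v$phi), sin(v$theta) * sin(v$phi), cos(v$theta))
  A <- tcrossprod(u) / ap^2 + (diag(3) - tcrossprod(u)) / ae^2
  r <- ap
  cols <- which(xs >= v$center[1] - r & xs <= v$center[1] + r)
  rows <- which(ys >= v$center[2] - r & ys <= v$center[2] + r)
  if (!length(rows) || !length(cols)) return(NULL)
  dx <- rep(xs[cols] - v$center[1], each = length(rows))
  dy <- rep(ys[rows] - v$center[2], times = length(cols))
  a33 <- A[3, 3]
  b <- 2 * (A[1, 3] * dx + A[2, 3] * dy)
  c0 <- A[1, 1] * dx^2 + 2 * A[1, 2] * dx * dy + A[2, 2] * dy^2 - 1
  disc <- b^2 - 4 * a33 * c0
  chord <- sqrt(pmax(disc, 0)) / a33
  list(rows = rows, cols = cols,
       chord = matrix(chord, nrow = length(rows)))
}

#' Project a phantom to a noiseless transmission map
#'
#' Parallel-beam forward model: for every pixel the chord lengths of the
#' beam through each component are computed analytically (ray--ellipsoid
#' intersections along the optical axis), overlaps are resolved by material
#' priority virion > nucleus > vacuole > cell, medium fills the remaining
#' `ice_thickness`, and the transmitted fraction is
#' `exp(-sum(mu_i * t_i))` multiplied by the illumination profile.
#'
#' The returned ground truth records the projected mark of every virion
#' (projected length `sqrt(L^2 sin^2 theta + W^2 cos^2 theta)`, width `W`,
#' angle = azimuth), the cell mask, and the fraction of the water-excess
#' absorbance attributable to virions -- the quantity the image-based
#' conversion estimates try to recover.
#'
#' @param ph A [phantom()].
#' @param optics An [optical_constants()].
#' @return A `phantom_projection`: list with `transmission` (illumination
#'   times Beer--Lambert transmission, matrix), `illumination`,
#'   `absorbance_excess` (total material absorbance above the medium
#'   baseline), and `ground_truth` (`marks` data frame,
#'   `true_biomass_fraction`, `cell_mask`).
#' @export
project_phantom <- function(ph, optics) {
  stopifnot(inherits(ph, "vq_phantom"), inherits(optics, "optical_constants"))
  nr <- ph$fov_px[1]; nc <- ph$fov_px[2]
  px_um <- ph$pixel_size / 1000
  xs <- (seq_len(nc) - 0.5) * px_um
  ys <- (seq_len(nr) - 0.5) * px_um
  fov_um <- c(nc, nr) * px_um

  mu_of <- function(density) {
    density * optics$mu_biomass + (1 - density) * optics$mu_water
  }
  check_clip <- function(center, extent, what) {
    if (any(center[1:2] - extent < 0) ||
        center[1] + extent > fov_um[1] || center[2] + extent > fov_um[2]) {
      warning(sprintf("%s extends outside the field of view; clipped", what))
    }
  }

  zero <- matrix(0, nr, nc)
  t_cell <- zero; t_nuc <- zero; t_vac <- zero; t_vir <- zero
  if (!is.null(ph$cell)) {
    check_clip(ph$cell$center, max(ph$cell$semi_axes[1:2]), "cell")
    t_cell <- chord_ellipsoid(xs, ys, ph$cell$center, ph$cell$semi_axes)
  }
  if (!is.null(ph$nucleus)) {
    check_clip(ph$nucleus$center, max(ph$nucleus$semi_axes[1:2]), "nucleus")
    t_nuc <- chord_ellipsoid(xs, ys, ph$nucleus$center, ph$nucleus$semi_axes)
  }
  for (vac in ph$vacuoles) {
    check_clip(vac$center, vac$radius, "vacuole")
    t_vac <- t_vac +
      chord_ellipsoid(xs, ys, vac$center, rep(vac$radius, 3))
  }
  vir_density <- 1
  for (v in ph$virions) {
    check_clip(v$center, v$length_nm / 2000, "virion")
    ch <- chord_spheroid(xs, ys, v)
    if (!is.null(ch)) {
      t_vir[ch$rows, ch$cols] <- t_vir[ch$rows, ch$cols] + ch$chord
    }
    vir_density <- v$density   # uniform density across virions assumed
  }

  # material priority: virions displace nucleus/cell material along the ray
  t_nuc_eff <- pmax(pmin(t_nuc, t_cell - t_vir), 0)
  t_vac_eff <- pmax(pmin(t_vac, t_cell - t_vir - t_nuc_eff), 0)
  t_cell_eff <- pmax(t_cell - t_vir - t_nuc_eff - t_vac_eff, 0)
  t_material <- t_vir + t_nuc_eff + t_vac_eff + t_cell_eff
  t_medium <- pmax(optics$ice_thickness - t_material, 0)

  mu_cell <- if (is.null(ph$cell)) optics$mu_water else mu_of(ph$cell$density)
  mu_nuc <- if (is.null(ph$nucleus)) optics$mu_water else
    mu_of(ph$nucleus$density)
  mu_vir <- mu_of(vir_density)

  absorbance <- mu_vir * t_vir + mu_nuc * t_nuc_eff +
    optics$mu_water * t_vac_eff + mu_cell * t_cell_eff +
    optics$mu_water * t_medium
  excess <- absorbance - optics$mu_water * optics$ice_thickness
  vir_excess <- (mu_vir - optics$mu_water) * t_vir

  illum <- eval_illumination(ph$illumination, nr, nc)
  transmission <- illum * exp(-absorbance)

  marks <- if (length(ph$virions)) {
    do.call(rbind, lapply(seq_along(ph$virions), function(i) {
      v <- ph$virions[[i]]
      lp <- sqrt(v$length_nm^2 * sin(v$theta)^2 +
                 v$width_nm^2 * cos(v$theta)^2)
      data.frame(center_x_px = v$center[1] / px_um - 0.5,
                 center_y_px = v$center[2] / px_um - 0.5,
                 length_nm = max(lp, v$width_nm),
                 width_nm = v$width_nm,
                 angle_deg = v$phi * 180 / pi,
                 true_length_nm = v$length_nm,
                 theta = v$theta,
                 is_virion = TRUE,
                 extracellular = ph$extracellular[i])
    }))
  } else {
    data.frame(center_x_px = numeric(0), center_y_px = numeric(0),
               length_nm = numeric(0), width_nm = numeric(0),
               angle_deg = numeric(0), true_length_nm = numeric(0),
               theta = numeric(0), is_virion = logical(0),
               extracellular = logical(0))
  }

  tot <- sum(excess)
  structure(list(
    transmission = transmission,
    illumination = illum,
    absorbance_excess = excess,
    pixel_size = ph$pixel_size,
    optics = optics,
    ground_truth = list(
      marks = marks,
      true_biomass_fraction = if (tot > 0) sum(vir_excess) / tot else NA_real_,
      cell_mask = t_cell > 0,
      virion_excess_absorbance = sum(vir_excess) * px_um^2,
      total_excess_absorbance = tot * px_um^2
    )
  ), class = "phantom_projection")
}

#' Render a photon-noise micrograph from a transmission map
#'
#' Draws each pixel from a Poisson distribution with mean
#' `flat_field_photons * transmission` (shot noise of the imaging system).
#' Identical seeds give bit-identical rasters.
#'
#' @param x A `phantom_projection` from [project_phantom()], or a bare
#'   transmission matrix.
#' @param optics An [optical_constants()] (supplies the flat field).
#' @param seed Integer seed (required; rendering is always reproducible).
#' @param pixel_size Pixel pitch, nm; taken from `x` when it is a
#'   projection.
#' @param hpi Optional infection time (hours post infection) stored in the
#'   metadata.
#' @return A [micrograph()].
#' @export
render_micrograph <- function(x, optics, seed, pixel_size = NULL,
                              hpi = NA_real_) {
  stopifnot(inherits(optics, "optical_constants"))
  if (inherits(x, "phantom_projection")) {
    tmap <- x$transmission
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
  } else {
    tmap <- as.matrix(x)
    if (is.null(pixel_size)) {
      stop("`pixel_size` must be given when rendering a bare matrix")
    }
  }
  if (any(tmap < 0) || any(!is.finite(tmap))) {
    stop("transmission map must be finite and non-negative")
  }
  mu <- optics$flat_field_photons * tmap
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  micrograph(matrix(counts, nrow(mu), ncol(mu)), pixel_size,
             metadata = list(hpi = hpi, seed = as.integer(seed),
                             ground_truth = inherits(x, "phantom_projection")))
}

#' Photon-count micrograph container
#'
#' @param pixels Matrix of non-negative, finite photon counts (row-major
#'   raster; pixel `(0, 0)` is the top-left element).
#' @param pixel_size Pixel pitch in nanometres, `> 0`.
#' @param metadata List of free-form metadata (e.g. `hpi`, `seed`).
#' @return A `micrograph` object.
#' @export
micrograph <- function(pixels, pixel_size, metadata = list()) {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel counts must be finite and non-negative")
  }
  check_scalar(pixel_size, "pixel_size")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 metadata = metadata),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("Micrograph %d x %d px @ %.3g nm/px, mean %.1f photons\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              mean(x$pixels)))
  invisible(x)
}

# Uniform-on-the-sphere polar angles, folded to [0, pi/2]: cos(theta)
# uniform on [0, 1].  Assumes the RNG state is already set by the caller.
sample_orientation_impl <- function(n) acos(stats::runif(n))

#' Sample random 3D orientations of a rod-like particle
#'
#' Polar angles theta (from the optical axis) of uniformly oriented axes in
#' 3D, folded onto `[0, pi/2]`; equivalently `cos(theta)` is uniform on
#' `[0, 1]`.  The projected length of a rod of length `L` is then
#' `L * sin(theta)`, which is what drives the orientation undercount of
#' elongated virions in projection images.
#'
#' @param n Number of samples, `>= 1`.
#' @param seed Integer seed.
#' @return Numeric vector of polar angles in radians.
#' @seealso [orientation_miss_probability()]
#' @export
sample_orientation <- function(n, seed = 0) {
  stopifnot(n >= 1)
  with_seed(seed, sample_orientation_impl(n))
}
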