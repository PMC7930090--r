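#' Simulate an end-point dilution titration
#'
#' Poisson partitioning of a virion suspension across serial dilutions: at
#' dilution `d_i` the number of infectious units per well is Poisson with
#' mean `a * d_i`, so a well is positive with probability
#' `1 - exp(-a * d_i)` and the positive count per step is binomial.
#'
#' @param a Expected infectious units per well at dilution 1 (step 0),
#'   `>= 0`.
#' @param dilutions Dilution factors relative to step 0, each in `(0, 1]`.
#' @param wells Number of replicate wells per step, `>= 1`.
#' @param seed Integer seed.
#' @return A [titration_series()].
#' @examples
#' simulate_titration(1210, 2^-(9:12), wells = 15, seed = 1)
#' @export
simulate_titration <- function(a, dilutions, wells, seed = 0) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0) {
    stop("`a` must be a single non-negative number")
  }
  stopifnot(all(dilutions > 0), all(dilutions <= 1), wells >= 1)
  p <- 1 - exp(-a * dilutions)
  k <- with_seed(seed, stats::rbinom(length(dilutions), wells, p))
  titration_series(dilution = dilutions, positives = k,
                   wells = rep(as.integer(wells), length(dilutions)),
                   label = sprintf("simulated a=%g seed=%d", a,
                                   as.integer(seed)))
}

#' Simulate a TGA thermogram with a known residual plateau
#'
#' Generates a pyrolysis mass-loss curve that decays smoothly (logistic in
#' temperature) from 1 to a programmed residual plateau, with optional
#' Gaussian measurement noise.  Used as ground truth for
#' [residual_fraction()].
#'
#' @param plateau Residual mass fraction after pyrolysis, in `(0, 1)`.
#' @param t_range Temperature range in degrees C.
#' @param step Sampling step, degrees C.
#' @param midpoint,scale Logistic decay midpoint and width, degrees C.
#' @param noise_sd Standard deviation of additive mass-fraction noise.
#' @param seed Integer seed.
#' @param label Sample label (e.g. `"virus"` or `"cell"`).
#' @return A [thermogram()].
#' @export
simulate_thermogram <- function(plateau, t_range = c(25, 800), step = 2,
                                midpoint = 300, scale = 40,
                                noise_sd = 0.002, seed = 0,
                                label = "synthetic") {
  stopifnot(plateau > 0, plateau < 1, t_range[2] > t_range[1], step > 0)
  tt <- seq(t_range[1], t_range[2], by = step)
  s <- 1 / (1 + exp((tt - midpoint) / scale))
  s <- (s - s[length(s)]) / (s[1] - s[length(s)])   # 1 at start, 0 at end
  m <- plateau + (1 - plateau) * s
  if (noise_sd > 0) {
    m <- m + with_seed(seed, stats::rnorm(length(m), 0, noise_sd))
    m[1] <- 1
    m <- pmin(pmax(m, 1e-6), 1)
  }
  thermogram(temperature = tt, mass = m, label = label)
}

#' Isolated-virion reference projection
#'
#' A phantom containing a single virion and no cell, as used to measure the
#' typical integrated absorbance of one virion from images containing only
#' the virus.
#'
#' @param optics An [optical_constants()].
#' @param theta,phi Virion orientation (radians).
#' @param length_nm,width_nm Virion axes, nm.
#' @param fov_px,pixel_size Field of view (pixels) and pixel pitch (nm).
#' @return A `phantom_projection` (see [project_phantom()]).
#' @export
isolated_virion_projection <- function(optics, theta = pi / 2, phi = 0,
                                       length_nm = 1250, width_nm = 590,
                                       fov_px = 96L, pixel_size = 40) {
  px_um <- pixel_size / 1000
  centre <- c(fov_px, fov_px) * px_um / 2
  ph <- phantom(cell = NULL,
                virions = list(virion(c(centre, 0), length_nm, width_nm,
                                      theta = theta, phi = phi)),
                fov_px = fov_px, pixel_size = pixel_size)
  project_phantom(ph, optics)
}

#' Simulate a cohort of infected-cell phantoms at a programmed conversion
#'
#' Generates `n_cells` phantoms whose virion load is chosen so that the
#' virions carry approximately the fraction `fraction` of the cell's
#' water-excess absorbance (the image-based "conversion of biomass"), then
#' renders each with Poisson photon noise.  The exact per-cell ground-truth
#' fraction is returned alongside, so estimator bias can be measured
#' against truth rather than against the programmed target.
#'
#' @param fraction Target virion share of the projected biomass absorbance.
#' @param n_cells Number of cells to generate.
#' @param optics An [optical_constants()].
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param fov_px,pixel_size Raster geometry (pixels, nm).
#' @param cell_semi_axes Cell semi-axes, micrometres.
#' @param cell_density Cytoplasm dry-biomass volume fraction.
#' @param virion_length_nm,virion_width_nm Virion axes, nm.
#' @return List of per-cell records: `micrograph`, `projection`,
#'   `n_virions`, `true_fraction`.
#' @export
simulate_conversion_cohort <- function(fraction, n_cells, optics, seed = 0,
                                       fov_px = 360L, pixel_size = 80,
                                       cell_semi_axes = c(8, 7, 2),
                                       cell_density = 0.14,
                                       virion_length_nm = 1250,
                                       virion_width_nm = 590) {
  stopifnot(fraction > 0, fraction < 1, n_cells >= 1)
  mu_w <- optics$mu_water
  mu_c <- cell_density * optics$mu_biomass + (1 - cell_density) * mu_w
  v_cell <- 4 / 3 * pi * prod(cell_semi_axes)
  v_vir <- spheroid_volume(virion_length_nm / 1000, virion_width_nm / 1000)
  eps_c <- (mu_c - mu_w) * v_cell           # cell excess absorbance, um^3/um
  eps_v <- (optics$mu_biomass - mu_w) * v_vir
  occl <- (mu_c - mu_w) * v_vir             # cell material displaced
  n_vir <- max(1L, round(fraction * eps_c / (eps_v - fraction * (eps_v - occl))))
  lapply(seq_len(n_cells), function(i) {
    cell_seed <- as.integer(seed) * 1000L + i
    ph <- default_phantom(n_virions = n_vir, seed = cell_seed,
                          fov_px = fov_px, pixel_size = pixel_size,
                          cell_semi_axes = cell_semi_axes,
                          cell_density = cell_density,
                          virion_length_nm = virion_length_nm,
                          virion_width_nm = virion_width_nm,
                          with_nucleus = FALSE, with_vacuoles = FALSE)
    pr <- project_phantom(ph, optics)
    mg <- render_micrograph(pr, optics, seed = cell_seed + 1L)
    list(micrograph = mg, projection = pr, n_virions = n_vir,
         true_fraction = pr$ground_truth$true_biomass_fraction)
  })
}

#' Simulate mark-level annotations for a time series of infected cells
#'
#' Emulates the semi-manual annotation workflow directly at the mark level
#' (no rendering): each cell at `hpi` carries a Poisson number of virions
#' around the programmed growth curve, each virion is observed at its
#' projected length for a uniformly random 3D orientation, and a background
#' population of distractor objects (near-circular granules below 500 nm,
#' plus a small fraction of elongated debris that can fool the classifier)
#' is added.  Non-infected control cells contain only distractors.
#'
#' @param hpi Vector of infection times, hours post infection.
#' @param cells_per_time Cells to simulate at each time.
#' @param mean_virions Expected true virion count at each `hpi` (recycled).
#' @param n_distractors Expected distractor marks per cell.
#' @param elongated_fraction Fraction of distractors that are elongated
#'   debris (700--1500 nm, ellipticity above 1.3) and hence false positives
#'   by construction.
#' @param virion_length_nm,virion_width_nm Mean true virion axes, nm.
#' @param seed Integer seed.
#' @return List of `cell_annotation` objects; marks carry a ground-truth
#'   `is_virion` column.
#' @export
simulate_annotation_cohort <- function(hpi, cells_per_time = 5,
                                       mean_virions,
                                       n_distractors = 12,
                                       elongated_fraction = 0.02,
                                       virion_length_nm = 1250,
                                       virion_width_nm = 590,
                                       seed = 0) {
  stopifnot(length(mean_virions) %in% c(1L, length(hpi)))
  mean_virions <- rep_len(mean_virions, length(hpi))
  with_seed(seed, {
    out <- list()
    id <- 0L
    for (j in seq_along(hpi)) {
      for (k in seq_len(cells_per_time)) {
        id <- id + 1L
        nv <- stats::rpois(1, mean_virions[j])
        vir <- if (nv > 0) {
          th <- sample_orientation_impl(nv)
          L <- pmax(stats::rnorm(nv, virion_length_nm, 40), virion_width_nm)
          W <- pmax(stats::rnorm(nv, virion_width_nm, 25), 200)
          lp <- pmax(sqrt(L^2 * sin(th)^2 + W^2 * cos(th)^2), W)
          data.frame(length_nm = lp, width_nm = W,
                     angle_deg = stats::runif(nv, 0, 180),
                     true_length_nm = L, is_virion = TRUE)
        }
        nd <- stats::rpois(1, n_distractors)
        dis <- if (nd > 0) {
          elong <- stats::runif(nd) < elongated_fraction
          L <- ifelse(elong, stats::runif(nd, 750, 1450),
                      stats::runif(nd, 250, 500))
          W <- ifelse(elong, L / stats::runif(nd, 1.4, 2.2),
                      L / stats::runif(nd, 1.0, 1.15))
          data.frame(length_nm = L, width_nm = W,
                     angle_deg = stats::runif(nd, 0, 180),
                     true_length_nm = L, is_virion = FALSE)
        }
        marks <- rbind(vir, dis)
        if (is.null(marks)) {
          marks <- data.frame(length_nm = numeric(0), width_nm = numeric(0),
                              angle_deg = numeric(0),
                              true_length_nm = numeric(0),
                              is_virion = logical(0))
        }
        out[[id]] <- cell_annotation(cell_id = sprintf("cell%03d", id),
                                     hpi = hpi[j], marks = marks,
                                     approximate = hpi[j] >= 70)
      }
    }
    out
  })
}
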