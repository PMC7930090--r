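#' Gaussian smoothing of a micrograph
#'
#' Separable Gaussian convolution with a normalised discrete kernel
#' (truncated at 4 sigma) and reflective boundary handling.  `sigma = 0`
#' returns the input unchanged.
#'
#' @param mg A [micrograph()].
#' @param sigma Kernel standard deviation in pixels, `>= 0` (default 1).
#' @return A smoothed [micrograph()].
#' @export
smooth_micrograph <- function(mg, sigma = 1) {
  stopifnot(inherits(mg, "micrograph"), sigma >= 0)
  if (sigma == 0) return(mg)
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[r:1, , drop = FALSE], m,
                    m[n:(n - r + 1), , drop = FALSE])
    f <- stats::filter(padded, k, method = "convolution", sides = 2)
    matrix(as.numeric(f[(r + 1):(r + n), ]), nrow = n)
  }
  s <- t(conv_cols(t(conv_cols(mg$pixels))))
  micrograph(pmax(s, 0), mg$pixel_size,
             metadata = c(mg$metadata, list(smoothed_sigma = sigma)))
}

#' Background sampling ring around a cell mask
#'
#' Deterministic sampling positions for illumination estimation: for each
#' of `n` azimuths the support radius of the mask is found and a point is
#' placed at one of the configured offsets beyond it (offsets cycle across
#' azimuths, covering a 2--5 micrometre annulus around the cell by
#' default).
#'
#' @param mask Logical matrix (TRUE inside the cell).
#' @param pixel_size Pixel pitch, nm.
#' @param n Number of sample points.
#' @param offsets_um Radial offsets outside the mask, micrometres.
#' @return Data frame with 0-based `x_px`, `y_px` columns.
#' @export
background_ring <- function(mask, pixel_size, n = 36,
                            offsets_um = c(2, 3.5, 5)) {
  stopifnot(is.matrix(mask), any(mask), n >= 6)
  px_um <- pixel_size / 1000
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2] - 1)
  cy <- mean(idx[, 1] - 1)
  dx <- (idx[, 2] - 1) - cx
  dy <- (idx[, 1] - 1) - cy
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  off <- rep_len(offsets_um, n) / px_um
  pts <- t(vapply(seq_len(n), function(i) {
    u <- c(cos(ang[i]), sin(ang[i]))
    r_support <- max(dx * u[1] + dy * u[2])
    c(cx, cy) + (r_support + off[i]) * u
  }, numeric(2)))
  data.frame(x_px = pts[, 1], y_px = pts[, 2])
}

#' Fit a 2D Gaussian illumination profile to background samples
#'
#' Least-squares fit of
#' `A * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2)))` (plus an
#' optional constant offset) to pixel values sampled around the cell,
#' using Levenberg--Marquardt.  Note the fitted amplitude absorbs the
#' attenuation of the full medium layer, since the samples are taken
#' through medium only; [medium_compensation()] corrects for the medium
#' displaced by the cell.
#'
#' @param mg A [micrograph()].
#' @param samples Data frame with 0-based `x_px`, `y_px` columns (e.g. from
#'   [background_ring()]); a `value` column overrides lookup in the image.
#' @param offset Fit a constant pedestal as well (default `FALSE`).
#' @param patch_px Each sample value is the mean over a
#'   `patch_px x patch_px` pixel patch centred on the sample point
#'   (default 5).  Patch averaging suppresses shot noise, which the
#'   annular sampling geometry would otherwise amplify when the fitted
#'   peak is extrapolated to the cell centre.
#' @return An `illumination_fit`: amplitude, `center_px`, `widths_px`,
#'   `offset`, `medium_factor` (1 until compensated), `residual_norm`, and
#'   a `near_uniform` flag raised when the fitted widths dwarf the sampled
#'   extent.
#' @export
fit_illumination <- function(mg, samples, offset = FALSE, patch_px = 5) {
  stopifnot(inherits(mg, "micrograph"), patch_px >= 1)
  samples <- as.data.frame(samples)
  if (nrow(samples) < 6) {
    stop("need at least 6 background sample points")
  }
  if (qr(cbind(1, samples$x_px, samples$y_px))$rank < 3) {
    stop("degenerate background samples (collinear points)")
  }
  if (is.null(samples$value)) {
    r <- floor(patch_px / 2)
    samples$value <- vapply(seq_len(nrow(samples)), function(k) {
      i <- pmin(pmax(round(samples$y_px[k]) + 1 + (-r:r), 1),
                nrow(mg$pixels))
      j <- pmin(pmax(round(samples$x_px[k]) + 1 + (-r:r), 1),
                ncol(mg$pixels))
      mean(mg$pixels[i, j])
    }, numeric(1))
  }
  x <- samples$x_px; y <- samples$y_px; v <- samples$value
  extent <- max(diff(range(x)), diff(range(y)))
  start <- list(A = max(v),
                x0 = sum(x * v) / sum(v), y0 = sum(y * v) / sum(v),
                sx = extent, sy = extent)
  lower <- c(A = 1e-12, x0 = -Inf, y0 = -Inf, sx = extent / 50,
             sy = extent / 50)
  fmla <- value ~ A * exp(-((x_px - x0)^2 / (2 * sx^2) +
                            (y_px - y0)^2 / (2 * sy^2)))
  if (offset) {
    fmla <- value ~ c0 + A * exp(-((x_px - x0)^2 / (2 * sx^2) +
                                   (y_px - y0)^2 / (2 * sy^2)))
    start$c0 <- min(v)
    lower <- c(lower, c0 = 0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fmla, data = samples, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("illumination fit did not converge: ", conditionMessage(e))
    })
  p <- as.list(stats::coef(fit))
  pred <- stats::predict(fit)
  structure(list(amplitude = p$A, center_px = c(p$x0, p$y0),
                 widths_px = c(p$sx, p$sy),
                 offset = if (offset) p$c0 else 0,
                 medium_factor = 1,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 # profile varies by < 1% over the sampled extent
                 near_uniform = diff(range(pred)) < 0.01 * max(pred),
                 n_points = nrow(samples)),
            class = "illumination_fit")
}

#' @export
print.illumination_fit <- function(x, ...) {
  cat(sprintf(
    "Illumination fit: A=%.4g at (%.1f, %.1f) px, sigma=(%.1f, %.1f) px%s%s\n",
    x$amplitude, x$center_px[1], x$center_px[2], x$widths_px[1],
    x$widths_px[2],
    if (x$medium_factor != 1) sprintf(", medium factor %.3f", x$medium_factor)
    else "",
    if (x$near_uniform) " [near-uniform]" else ""))
  invisible(x)
}

#' Compensate the illumination estimate for displaced medium
#'
#' The background around the cell is seen through the full medium layer,
#' but over the cell the cell body displaces a slab of medium of roughly
#' its own thickness.  The illumination used over the cell is therefore the
#' fitted value increased by `exp(mu_water * displaced_thickness)` -- the
#' absorption of a 4 micrometre ice layer by default, matching a typical
#' cell thickness.
#'
#' @param fit An `illumination_fit`.
#' @param mu_water Medium attenuation coefficient, per micrometre.
#' @param displaced_thickness Thickness of displaced medium, micrometres.
#' @return The fit with its `medium_factor` set.
#' @export
medium_compensation <- function(fit, mu_water, displaced_thickness = 4) {
  stopifnot(inherits(fit, "illumination_fit"), mu_water > 0,
            displaced_thickness >= 0)
  fit$medium_factor <- exp(mu_water * displaced_thickness)
  fit
}

# Evaluate an illumination fit (including medium factor) on the pixel grid.
eval_illumination_fit <- function(fit, nr, nc) {
  x <- seq_len(nc) - 1
  y <- seq_len(nr) - 1
  gx <- exp(-((x - fit$center_px[1])^2) / (2 * fit$widths_px[1]^2))
  gy <- exp(-((y - fit$center_px[2])^2) / (2 * fit$widths_px[2]^2))
  (fit$amplitude * outer(gy, gx) + fit$offset) * fit$medium_factor
}

#' Beer--Lambert absorbance map
#'
#' Converts photon counts to absorbance `-ln(I / I0)` per pixel, where `I0`
#' is the (optionally medium-compensated) illumination estimate evaluated
#' at each pixel.  Pixels with zero counts are masked (`NA`).
#'
#' @param mg A [micrograph()].
#' @param fit An `illumination_fit` (see [fit_illumination()]).
#' @return An `absorbance_map`: `values` matrix, `pixel_size`, provenance.
#' @export
absorbance_map <- function(mg, fit) {
  stopifnot(inherits(mg, "micrograph"), inherits(fit, "illumination_fit"))
  i0 <- eval_illumination_fit(fit, nrow(mg$pixels), ncol(mg$pixels))
  v <- -log(mg$pixels / i0)
  v[mg$pixels <= 0] <- NA_real_
  if (all(is.na(v))) stop("all pixels masked: no positive counts")
  structure(list(values = v, pixel_size = mg$pixel_size,
                 provenance = list(metadata = mg$metadata, fit = fit)),
            class = "absorbance_map")
}

# Sum of absorbance over a logical mask, scaled by pixel area so the
# result is in absorbance * um^2 and independent of pixelation.
integrate_absorbance <- function(map, mask) {
  stopifnot(inherits(map, "absorbance_map"))
  px_um <- map$pixel_size / 1000
  sum(map$values[mask], na.rm = TRUE) * px_um^2
}

#' Rasterise mark footprints
#'
#' Logical mask of the union of mark ellipses: each mark contributes the
#' ellipse of its length x width at its angle, centred on its 0-based
#' pixel position.
#'
#' @param marks Data frame of marks (see [as_object_marks()]).
#' @param dim Raster dimensions `c(nrow, ncol)`.
#' @param pixel_size Pixel pitch, nm.
#' @return Logical matrix, TRUE inside any footprint.
#' @export
mark_footprints <- function(marks, dim, pixel_size) {
  out <- matrix(FALSE, dim[1], dim[2])
  if (is.null(marks) || nrow(marks) == 0) return(out)
  marks <- as_object_marks(marks)
  ang <- if ("angle_deg" %in% names(marks)) marks$angle_deg else
    rep(0, nrow(marks))
  for (m in seq_len(nrow(marks))) {
    a <- marks$length_nm[m] / 2 / pixel_size
    b <- marks$width_nm[m] / 2 / pixel_size
    cx <- marks$center_x_px[m]
    cy <- marks$center_y_px[m]
    th <- ang[m] * pi / 180
    cols <- max(1, floor(cx - a + 1)):min(dim[2], ceiling(cx + a + 1))
    rows <- max(1, floor(cy - a + 1)):min(dim[1], ceiling(cy + a + 1))
    dx <- rep((cols - 1) - cx, each = length(rows))
    dy <- rep((rows - 1) - cy, times = length(cols))
    u <- (dx * cos(th) + dy * sin(th)) / a
    w <- (-dx * sin(th) + dy * cos(th)) / b
    out[rows, cols] <- out[rows, cols] |
      matrix(u^2 + w^2 <= 1, nrow = length(rows))
  }
  out
}

#' Typical integrated absorbance of a single virion
#'
#' Mean footprint-integrated absorbance per virion over a set of reference
#' images containing only the virus (no cell).  Each reference is a list
#' with an `absorbance_map` (`map`) and its `marks` data frame; the
#' footprint of each mark is the ellipse of its length x width at its
#' angle.
#'
#' @param references List of `list(map = , marks = )` records.
#' @return Mean integrated absorbance per virion (absorbance x um^2).
#' @export
typical_virion_absorbance <- function(references) {
  if (length(references) == 0) stop("no reference virion images supplied")
  per_virion <- unlist(lapply(references, function(ref) {
    stopifnot(inherits(ref$map, "absorbance_map"))
    marks <- as_object_marks(ref$marks)
    if (nrow(marks) == 0) return(numeric(0))
    vapply(seq_len(nrow(marks)), function(i) {
      fp <- mark_footprints(marks[i, , drop = FALSE],
                            dim(ref$map$values), ref$map$pixel_size)
      integrate_absorbance(ref$map, fp)
    }, numeric(1))
  }))
  if (length(per_virion) == 0) stop("reference images contain no marks")
  mean(per_virion)
}

#' High and low estimates of biomass conversion from an absorbance map
#'
#' Compares the total absorbance of the cell with the absorbance
#' attributable to virions, after discounting the share of absorption due
#' to water (about 15% for the cell, about 3% for the much denser
#' virions).  The high estimate sums the map over the marked virion
#' footprints -- it includes cell material above and below each virion,
#' which projection imaging cannot separate.  The low estimate multiplies
#' the virion count by the typical absorbance of one isolated virion.
#'
#' @param map An `absorbance_map`.
#' @param cell_mask Logical matrix, TRUE inside the cell.
#' @param virion_marks Data frame of marks classified as virions.
#' @param typical Typical per-virion integrated absorbance, from
#'   [typical_virion_absorbance()].
#' @param water_correction_cell,water_correction_virion Fraction of the
#'   respective absorbance attributed to water and removed
#'   (multiplicative `1 - w`); defaults 0.15 and 0.03.
#' @param count_scale Multiplier applied to the identified virion count in
#'   the low estimate, e.g. `1 / (1 - p)` to undo the orientation
#'   undercount with miss probability `p`.  Default 1 (no correction).
#' @return A `conversion_estimate`: `low`, `high`, `cell_total_absorbance`,
#'   `virion_absorbance_sum`, `typical_virion_absorbance`, `n_virions`.
#' @export
conversion_estimates <- function(map, cell_mask, virion_marks, typical,
                                 water_correction_cell = 0.15,
                                 water_correction_virion = 0.03,
                                 count_scale = 1) {
  stopifnot(inherits(map, "absorbance_map"), is.matrix(cell_mask),
            water_correction_cell >= 0, water_correction_cell < 1,
            water_correction_virion >= 0, water_correction_virion < 1,
            count_scale > 0)
  if (!any(cell_mask)) stop("empty cell mask")
  cell_total <- integrate_absorbance(map, cell_mask) *
    (1 - water_correction_cell)
  if (cell_total <= 0) stop("no cell absorbance")
  marks <- as_object_marks(virion_marks)
  fp <- mark_footprints(marks, dim(map$values), map$pixel_size)
  virion_sum <- integrate_absorbance(map, fp) * (1 - water_correction_virion)
  n <- nrow(marks)
  low <- n * count_scale * typical * (1 - water_correction_virion) /
    cell_total
  structure(list(low = low, high = virion_sum / cell_total,
                 cell_total_absorbance = cell_total,
                 virion_absorbance_sum = virion_sum,
                 typical_virion_absorbance = typical,
                 n_virions = n,
                 water_correction_cell = water_correction_cell,
                 water_correction_virion = water_correction_virion),
            class = "conversion_estimate")
}

#' @export
print.conversion_estimate <- function(x, ...) {
  cat(sprintf(
    "Conversion of biomass: low %.1f%%, high %.1f%% (%d virions, cell total %.3g)\n",
    100 * x$low, 100 * x$high, x$n_virions, x$cell_total_absorbance))
  invisible(x)
}
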