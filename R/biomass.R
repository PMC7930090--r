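#' TGA thermogram container
#'
#' @param temperature Strictly increasing temperatures, degrees C.
#' @param mass Sample mass; normalised to fractions of the initial mass on
#'   ingest (so the first value is exactly 1).
#' @param label Sample label (e.g. `"virus"`, `"cell"`).
#' @param replicate Optional replicate id.
#' @return A `thermogram`.
#' @export
thermogram <- function(temperature, mass, label = NULL, replicate = NULL) {
  stopifnot(length(temperature) == length(mass), length(mass) >= 10,
            all(is.finite(temperature)), all(is.finite(mass)))
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("`temperature` must be strictly increasing")
  }
  mass <- mass / mass[1]
  if (any(mass <= 0) || any(mass > 1 + 1e-9)) {
    stop("mass fractions must lie in (0, 1] after normalisation")
  }
  structure(list(temperature = as.numeric(temperature),
                 mass = pmin(as.numeric(mass), 1),
                 label = label, replicate = replicate),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram%s: %d points, %.0f-%.0f C, final mass %.3f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$mass), min(x$temperature), max(x$temperature),
              x$mass[length(x$mass)]))
  invisible(x)
}

#' Read a thermogram from CSV
#'
#' Expects columns `temperature_C` and `mass_pct` (mass in percent of the
#' initial mass, or any consistent unit -- the constructor renormalises).
#'
#' @param path CSV file path.
#' @param label,replicate Passed to [thermogram()].
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path, label = NULL, replicate = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("temperature_C", "mass_pct") %in% names(df)))
  thermogram(df$temperature_C, df$mass_pct, label = label,
             replicate = replicate)
}

#' Residual mass fraction after pyrolysis
#'
#' Detects the final plateau of a thermogram -- the trailing run of points
#' over which the local mass-loss rate `|dm/dT|` (estimated by linear
#' regression over a sliding window, which keeps measurement noise from
#' masking a true plateau) stays below `tolerance` -- and returns the mean
#' mass fraction over it.  The plateau must span at least `min_span` of
#' the temperature range, otherwise weight stabilisation was not achieved
#' and an error is raised.
#'
#' @param tg A [thermogram()].
#' @param tolerance Maximum plateau slope, mass fraction per degree C
#'   (default `1e-4`).
#' @param min_span Minimum plateau extent as a fraction of the temperature
#'   range (default 0.05, i.e. the last 5%).
#' @param window_frac Sliding-window width for the slope estimate, as a
#'   fraction of the temperature range (default 0.10).
#' @return Residual mass fraction of the initial mass.
#' @examples
#' residual_fraction(simulate_thermogram(0.68, seed = 1))
#' @export
residual_fraction <- function(tg, tolerance = 1e-4, min_span = 0.05,
                              window_frac = 0.10) {
  stopifnot(inherits(tg, "thermogram"), tolerance > 0, min_span > 0,
            window_frac > 0)
  tt <- tg$temperature
  m <- tg$mass
  n <- length(m)
  t_range <- tt[n] - tt[1]
  w <- max(5L, sum(tt >= tt[n] - window_frac * t_range))
  # slope at i from a trailing regression window ending at i
  slope_at <- function(i) {
    j <- max(1L, i - w + 1L):i
    stats::cov(tt[j], m[j]) / stats::var(tt[j])
  }
  i <- n
  while (i >= w && abs(slope_at(i)) < tolerance) i <- i - 1L
  # plateau spans points (i - w + 2) .. n: the last window that failed
  # ends at i, so points beyond i - w + 1 are inside passing windows
  start <- i + 1L
  if (i == n || tt[n] - tt[start] < min_span * t_range) {
    stop("weight stabilization not achieved: no plateau below the ",
         "tolerated mass-loss rate")
  }
  mean(m[start:n])
}

#' Relative carbon content from residual masses
#'
#' Ratio of the post-pyrolysis residual mass of the virus sample to that of
#' the cell sample, used as a proxy for their relative carbon (biomass)
#' concentration.  Kept unrounded: 68/28 = 2.43.
#'
#' @param residual_virus,residual_cell Residual masses in percent of the
#'   initial mass, each in `(0, 100)`.
#' @return The ratio `residual_virus / residual_cell`.
#' @examples
#' carbon_ratio(68, 28)
#' @export
carbon_ratio <- function(residual_virus, residual_cell) {
  stopifnot(residual_virus > 0, residual_virus < 100)
  if (residual_cell <= 0 || residual_cell >= 100) {
    stop("`residual_cell` must lie in (0, 100)")
  }
  residual_virus / residual_cell
}

#' Volume of a prolate spheroid
#'
#' `pi/6 * length * width^2` -- the ovoid virion modelled as an ellipsoid
#' of revolution about its long axis.  The 1.25 x 0.59 micrometre virion
#' has a volume of 0.23 cubic micrometres.
#'
#' @param length,width Polar length and equatorial width, micrometres
#'   (`length >= width`).
#' @return Volume in cubic micrometres.
#' @examples
#' spheroid_volume(1.25, 0.59)
#' @export
spheroid_volume <- function(length, width) {
  stopifnot(all(width > 0), all(length >= width))
  pi / 6 * length * width^2
}

#' Fraction of the host cell volume occupied by virions at burst
#'
#' @param burst Virions produced per cell.
#' @param v_virion Virion volume, cubic micrometres.
#' @param v_cell Host cell volume, cubic micrometres (a typical amoeba is
#'   about 3000).
#' @return Volume fraction `burst * v_virion / v_cell`.
#' @examples
#' volume_fraction(280, 0.23, 3000)
#' @export
volume_fraction <- function(burst, v_virion, v_cell) {
  stopifnot(all(burst >= 0), v_virion > 0, v_cell > 0)
  burst * v_virion / v_cell
}

#' Biomass conversion from volume fraction and carbon ratio
#'
#' The volume fraction understates the transferred biomass because virions
#' are much denser in carbon than the host; multiplying by the
#' virus-to-cell carbon ratio (about 2.5 from TGA) corrects for it.
#'
#' @param volume_fraction Volume fraction of the cell occupied by virions.
#' @param carbon_ratio Virus/cell carbon concentration ratio.
#' @return Biomass-conversion fraction.
#' @examples
#' biomass_conversion(volume_fraction(280, 0.23, 3000), carbon_ratio(68, 28))
#' @export
biomass_conversion <- function(volume_fraction, carbon_ratio) {
  stopifnot(all(volume_fraction >= 0), carbon_ratio > 0)
  volume_fraction * carbon_ratio
}

#' Intersection of two intervals
#'
#' Used to combine independently derived conversion intervals (titration +
#' TGA versus image-based) into the overlapping best-guess interval.  The
#' empty intersection is a value, returned as `numeric(0)`.
#'
#' @param a,b Numeric length-2 intervals `c(lo, hi)` with `lo <= hi`.
#' @return `c(max(lo), min(hi))`, or `numeric(0)` if disjoint.
#' @examples
#' interval_intersection(c(5, 12), c(6, 17))
#' @export
interval_intersection <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, a[1] <= a[2], b[1] <= b[2])
  lo <- max(a[1], b[1])
  hi <- min(a[2], b[2])
  if (lo > hi) numeric(0) else c(lo, hi)
}
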