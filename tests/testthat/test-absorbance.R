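optics <- test_optics()

test_that("Gaussian smoothing is an identity at sigma 0 and on constants", {
  mg <- micrograph(matrix(runif(400, 10, 20), 20, 20), 19.3)
  expect_identical(smooth_micrograph(mg, 0)$pixels, mg$pixels)
  flat <- micrograph(matrix(7, 30, 30), 19.3)
  expect_equal(smooth_micrograph(flat, 1)$pixels, flat$pixels,
               tolerance = 1e-12)
})

test_that("smoothing kernel has unit mass", {
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  sm <- smooth_micrograph(micrograph(imp, 19.3), 1.7)
  expect_equal(sum(sm$pixels), 1, tolerance = 1e-6)
  expect_lt(max(sm$pixels), 1)  # mass has spread
})

test_that("illumination fit recovers known Gaussian parameters", {
  truth <- illumination_profile(500, c(46, 40), c(33, 29))
  nr <- 81L; nc <- 93L
  img <- 500 * exp(-((rep(0:(nc - 1), each = nr) - 46)^2 / (2 * 33^2) +
                     (rep(0:(nr - 1), nc) - 40)^2 / (2 * 29^2)))
  mg <- micrograph(matrix(img, nr, nc), 19.3)
  pts <- expand.grid(x_px = seq(5, 88, by = 12), y_px = seq(5, 76, by = 10))
  fit <- fit_illumination(mg, pts, patch_px = 1)
  expect_equal(fit$amplitude, 500, tolerance = 1e-3)
  expect_equal(fit$center_px, c(46, 40), tolerance = 1e-3)
  expect_equal(fit$widths_px, c(33, 29), tolerance = 1e-3)
  expect_false(fit$near_uniform)
})

test_that("illumination amplitude is recovered within 1% under shot noise", {
  nr <- 201L; nc <- 201L
  g <- outer(exp(-((0:(nr - 1)) - 100)^2 / (2 * 160^2)),
             exp(-((0:(nc - 1)) - 100)^2 / (2 * 160^2)))
  mg <- render_micrograph(g, optics, seed = 23, pixel_size = 19.3)
  mask <- matrix(FALSE, nr, nc); mask[81:121, 81:121] <- TRUE
  fit <- fit_illumination(mg, background_ring(mask, 19.3 * 50))
  expect_equal(fit$amplitude, 700, tolerance = 0.01)
})

test_that("a flat image is flagged near-uniform with amplitude at its level", {
  mg <- micrograph(matrix(200, 60, 60), 19.3)
  pts <- expand.grid(x_px = seq(4, 56, by = 9), y_px = seq(4, 56, by = 9))
  fit <- fit_illumination(mg, pts)
  expect_true(fit$near_uniform)
  expect_equal(fit$amplitude *
                 exp(-((28 - fit$center_px[1])^2 / (2 * fit$widths_px[1]^2) +
                       (28 - fit$center_px[2])^2 / (2 * fit$widths_px[2]^2))),
               200, tolerance = 0.01)
})

test_that("degenerate background samples are rejected", {
  mg <- micrograph(matrix(1, 20, 20), 19.3)
  expect_error(fit_illumination(mg, data.frame(x_px = 1:4, y_px = 1:4)),
               "at least 6")
  expect_error(fit_illumination(mg, data.frame(x_px = 1:8, y_px = 1:8)),
               "collinear")
})

test_that("medium compensation applies the displaced-ice factor", {
  fit <- known_illumination(optics, 10, 10)
  comp <- medium_compensation(fit, mu_water = 0.1309,
                              displaced_thickness = 4)
  expect_equal(comp$medium_factor, exp(0.1309 * 4), tolerance = 1e-12)
  expect_equal(round(comp$medium_factor, 3), 1.688)
  expect_equal(medium_compensation(fit, 0.1309, 0)$medium_factor, 1)
})

test_that("medium compensation removes the displaced-medium bias", {
  # a pancake cell of essentially constant 4 um thickness: compensated
  # absorbance should equal the full material absorbance mu_cell * t
  ph <- phantom(cell = ellipsoid(c(12.8, 12.8), c(200, 200, 2), 0.14),
                fov_px = 64L, pixel_size = 400)
  pr <- suppressWarnings(project_phantom(ph, optics))
  mg <- noiseless_micrograph(pr, optics)
  fit <- medium_compensation(
    known_illumination(optics, 64, 64), optics$mu_water, 4)
  am <- absorbance_map(mg, fit)
  mu_cell <- 0.14 * optics$mu_biomass + 0.86 * optics$mu_water
  expect_equal(mean(am$values), mu_cell * 4, tolerance = 0.01)
})

test_that("absorbance of the illumination itself is zero and maps add", {
  fit <- known_illumination(optics, 24, 24, through_medium = FALSE)
  i0 <- virionquant:::eval_illumination_fit(fit, 24, 24)
  expect_equal(absorbance_map(micrograph(i0, 19.3), fit)$values,
               matrix(0, 24, 24), tolerance = 1e-12)
  # stacking phantoms multiplies transmissions, adds absorbances
  # (flat illumination, so the material term is the only one that stacks)
  pr <- small_cell_projection(n_virions = 5, seed = 2)
  tm <- pr$transmission / pr$illumination
  mg1 <- micrograph(optics$flat_field_photons * tm, 80)
  stacked <- micrograph(optics$flat_field_photons * tm^2, 80)
  f1 <- known_illumination(optics, nrow(tm), ncol(tm),
                           widths_px = c(1e9, 1e9), through_medium = FALSE)
  a1 <- absorbance_map(mg1, f1)$values
  a2 <- absorbance_map(stacked, f1)$values
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("zero-count pixels are masked and empty maps error", {
  fit <- known_illumination(optics, 4, 4, through_medium = FALSE)
  px <- matrix(c(0, 1, 2, 3), 4, 4)
  am <- absorbance_map(micrograph(px, 19.3), fit)
  expect_true(all(is.na(am$values[px == 0])))
  expect_error(absorbance_map(micrograph(matrix(0, 4, 4), 19.3), fit),
               "all pixels masked")
})

test_that("typical virion absorbance equals its forward-model integral", {
  pr <- isolated_virion_projection(optics, theta = pi / 3, phi = 0.4)
  mg <- noiseless_micrograph(pr, optics)
  fit <- known_illumination(optics, nrow(mg$pixels), ncol(mg$pixels))
  am <- absorbance_map(mg, fit)
  ref <- list(map = am, marks = pr$ground_truth$marks)
  tv <- typical_virion_absorbance(list(ref))
  fp <- mark_footprints(pr$ground_truth$marks, dim(am$values), 40)
  oracle <- sum(pr$absorbance_excess[fp]) * (40 / 1000)^2
  expect_equal(tv, oracle, tolerance = 1e-6)
  # duplicates leave the mean unchanged
  expect_equal(typical_virion_absorbance(list(ref, ref)), tv,
               tolerance = 1e-12)
  expect_error(typical_virion_absorbance(list()), "no reference")
})

test_that("integrated virion absorbance is orientation-invariant while the
           projection shortens", {
  thetas <- c(pi / 2, pi / 3, pi / 6, 0.05)
  vals <- vapply(thetas, function(th) {
    pr <- isolated_virion_projection(optics, theta = th)
    mg <- noiseless_micrograph(pr, optics)
    fit <- known_illumination(optics, nrow(mg$pixels), ncol(mg$pixels))
    typical_virion_absorbance(list(list(map = absorbance_map(mg, fit),
                                        marks = pr$ground_truth$marks)))
  }, numeric(1))
  # the volume integral does not depend on orientation...
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
  # ...and matches mu_excess * V
  v <- spheroid_volume(1.25, 0.59)
  expect_equal(mean(vals), (optics$mu_biomass - optics$mu_water) * v,
               tolerance = 0.01)
  # but the marks record the projection shortening
  pr_tilt <- isolated_virion_projection(optics, theta = pi / 6)
  expect_lt(pr_tilt$ground_truth$marks$length_nm, 1250)
})

test_that("conversion estimates recover a known noiseless fraction", {
  pr <- small_cell_projection(n_virions = 15, seed = 8)
  mg <- noiseless_micrograph(pr, optics)
  fit <- known_illumination(optics, nrow(mg$pixels), ncol(mg$pixels))
  am <- absorbance_map(mg, fit)
  iv <- isolated_virion_projection(optics, pixel_size = 80)
  ivm <- noiseless_micrograph(iv, optics)
  ivf <- known_illumination(optics, nrow(ivm$pixels), ncol(ivm$pixels))
  typ <- typical_virion_absorbance(
    list(list(map = absorbance_map(ivm, ivf),
              marks = iv$ground_truth$marks)))
  est <- conversion_estimates(am, pr$ground_truth$cell_mask,
                              pr$ground_truth$marks, typ,
                              water_correction_cell = 0,
                              water_correction_virion = 0)
  f <- pr$ground_truth$true_biomass_fraction
  expect_equal(est$low, f, tolerance = 0.02)
  expect_gte(est$high, f * 0.999)
  # no virions at all
  none <- conversion_estimates(am, pr$ground_truth$cell_mask,
                               pr$ground_truth$marks[0, ], typ)
  expect_equal(none$low, 0)
  expect_equal(none$high, 0)
})

test_that("water corrections act as exact multiplicative factors", {
  pr <- small_cell_projection(n_virions = 6, seed = 3)
  mg <- noiseless_micrograph(pr, optics)
  fit <- known_illumination(optics, nrow(mg$pixels), ncol(mg$pixels))
  am <- absorbance_map(mg, fit)
  args <- list(am, pr$ground_truth$cell_mask, pr$ground_truth$marks, 0.22)
  off <- do.call(conversion_estimates,
                 c(args, water_correction_cell = 0,
                   water_correction_virion = 0))
  on <- do.call(conversion_estimates,
                c(args, water_correction_cell = 0.15,
                  water_correction_virion = 0.03))
  expect_equal(on$low / off$low, (1 - 0.03) / (1 - 0.15), tolerance = 1e-9)
  expect_equal(on$high / off$high, (1 - 0.03) / (1 - 0.15),
               tolerance = 1e-9)
})

test_that("estimates are invariant to consistent amplitude rescaling", {
  pr <- small_cell_projection(n_virions = 6, seed = 5)
  mg <- noiseless_micrograph(pr, optics)
  nr <- nrow(mg$pixels); nc <- ncol(mg$pixels)
  f1 <- known_illumination(optics, nr, nc)
  f2 <- f1; f2$amplitude <- f1$amplitude * 3.7
  mg2 <- micrograph(mg$pixels * 3.7, mg$pixel_size)
  a1 <- absorbance_map(mg, f1)
  a2 <- absorbance_map(mg2, f2)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
})

test_that("estimates are invariant to a 90-degree rotation of the scene", {
  pr <- small_cell_projection(n_virions = 6, seed = 12)
  mg <- noiseless_micrograph(pr, optics)
  nr <- nrow(mg$pixels); nc <- ncol(mg$pixels)
  fit <- known_illumination(optics, nr, nc, widths_px = c(1e7, 1e7))
  am <- absorbance_map(mg, fit)
  marks <- pr$ground_truth$marks
  mask <- pr$ground_truth$cell_mask
  typ <- 0.21
  est <- conversion_estimates(am, mask, marks, typ)
  # rotate image, mask and marks together by 90 degrees (clockwise)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  mg_r <- micrograph(rot(mg$pixels), mg$pixel_size)
  fit_r <- known_illumination(optics, nc, nr, widths_px = c(1e7, 1e7))
  marks_r <- marks
  marks_r$center_x_px <- (nr - 1) - marks$center_y_px
  marks_r$center_y_px <- marks$center_x_px
  marks_r$angle_deg <- marks$angle_deg + 90
  est_r <- conversion_estimates(absorbance_map(mg_r, fit_r), rot(mask),
                                marks_r, typ)
  expect_equal(est_r$low, est$low, tolerance = 1e-9)
  expect_equal(est_r$high, est$high, tolerance = 1e-9)
  expect_equal(est_r$cell_total_absorbance, est$cell_total_absorbance,
               tolerance = 1e-9)
})
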