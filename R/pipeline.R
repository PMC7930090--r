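#' Run the full quantification pipeline on synthetic data
#'
#' Chains every stage of the analysis end to end on generated inputs with
#' known ground truth: phantom cohort generation and rendering; virion
#' counting with the two-part uncertainty; illumination fitting, absorbance
#' mapping and image-based conversion estimates; end-point dilution
#' titration simulation, Poisson ML fit, TCID50 and burst size; TGA
#' residuals, carbon ratio and the volume/conversion arithmetic, ending in
#' the intersection of the titration+TGA and image-based conversion
#' intervals.  Deterministic given the configured seeds.
#'
#' @param config A configuration list from [read_config()] /
#'   [default_config()], or a YAML path.
#' @param out_dir Output directory; created if missing.  Receives
#'   `counts.tsv`, `conversion.tsv`, `report.json` and (optionally)
#'   rendered micrographs.
#' @param verbose Narrate stage boundaries.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  optics <- config_optics(config)
  rule <- classification_rule(config$classification$min_length_nm,
                              config$classification$max_length_nm,
                              config$classification$min_ellipticity)
  co <- config$cohort
  ab <- config$absorbance

  ## stage 1: phantom cohort -------------------------------------------
  say("stage phantom: %d cells at target fraction %.2f", co$n_cells,
      co$fraction)
  cohort <- simulate_conversion_cohort(
    fraction = co$fraction, n_cells = co$n_cells, optics = optics,
    seed = config$seeds$phantom, fov_px = co$fov_px,
    pixel_size = co$pixel_size_nm,
    cell_semi_axes = unlist(co$cell_semi_axes_um),
    cell_density = config$phantom$cell_density,
    virion_length_nm = config$phantom$virion_length_nm,
    virion_width_nm = config$phantom$virion_width_nm)
  refs <- lapply(seq_len(co$n_reference_virions), function(i) {
    th <- sample_orientation(1, seed = config$seeds$phantom + 7000L + i)
    pr <- isolated_virion_projection(
      optics, theta = th,
      length_nm = config$phantom$virion_length_nm,
      width_nm = config$phantom$virion_width_nm,
      fov_px = 128L, pixel_size = co$pixel_size_nm)
    mg <- render_micrograph(pr, optics,
                            seed = config$seeds$phantom + 8000L + i)
    # the reference field of view is small, so the ring hugs the virion
    fit <- fit_illumination(mg, background_ring(
      mark_footprints(pr$ground_truth$marks, dim(mg$pixels),
                      mg$pixel_size),
      mg$pixel_size, n = ab$background_ring$n_points,
      offsets_um = c(0.8, 1.2, 1.6)))
    list(map = absorbance_map(mg, fit), marks = pr$ground_truth$marks)
  })
  typical <- typical_virion_absorbance(refs)
  if (isTRUE(config$output$write_images)) {
    for (i in seq_along(cohort)) {
      write_micrograph(cohort[[i]]$micrograph,
                       file.path(out_dir, sprintf("cell%03d.tif", i)))
      write_marks_csv(cohort[[i]]$projection$ground_truth$marks,
                      file.path(out_dir, sprintf("cell%03d_marks.csv", i)))
    }
  }

  ## stage 2: counting --------------------------------------------------
  say("stage count: classifying marks in %d cells", length(cohort))
  controls <- simulate_annotation_cohort(hpi = 0, cells_per_time = 5,
                                         mean_virions = 0,
                                         seed = config$seeds$phantom + 1L)
  fp_rate <- false_positive_rate(controls, rule)
  eff_cut <- effective_min_projected_length(
    rule, config$phantom$virion_width_nm)
  miss_p <- spheroid_miss_probability(config$phantom$virion_length_nm,
                                      config$phantom$virion_width_nm,
                                      eff_cut)
  counts <- lapply(seq_along(cohort), function(i) {
    ann <- cell_annotation(sprintf("cell%03d", i), hpi = NA_real_,
                           marks = cohort[[i]]$projection$ground_truth$marks)
    count_with_uncertainty(ann, rule, fp_rate, miss_p)
  })
  counts_df <- data.frame(
    cell_id = vapply(counts, `[[`, "", "cell_id"),
    hpi = vapply(counts, `[[`, 0, "hpi"),
    n_marks = vapply(counts, `[[`, 0, "n_marks_total"),
    n_virions = vapply(counts, `[[`, 0, "n_virions"),
    uncertainty = vapply(counts, `[[`, 0, "uncertainty"))
  write_tsv_table(counts_df, file.path(out_dir, "counts.tsv"))

  ## stage 3: absorbance and conversion ---------------------------------
  say("stage absorb: illumination fits and conversion estimates")
  count_scale <- if (isTRUE(ab$orientation_count_correction)) {
    1 / (1 - miss_p)
  } else {
    1
  }
  conv <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    mg <- rec$micrograph
    if (ab$smoothing_sigma_px > 0) {
      mg <- smooth_micrograph(mg, ab$smoothing_sigma_px)
    }
    mask <- rec$projection$ground_truth$cell_mask
    fit <- fit_illumination(mg, background_ring(
      mask, mg$pixel_size, n = ab$background_ring$n_points,
      offsets_um = unlist(ab$background_ring$offsets_um)))
    if (isTRUE(ab$medium_compensation)) {
      fit <- medium_compensation(fit, optics$mu_water,
                                 ab$displaced_medium_um)
    }
    amap <- absorbance_map(mg, fit)
    marks <- rec$projection$ground_truth$marks
    vir_marks <- marks[classify_marks(marks, rule) == "virion", ,
                       drop = FALSE]
    est <- conversion_estimates(
      amap, mask, vir_marks, typical,
      water_correction_cell = ab$water_correction_cell,
      water_correction_virion = ab$water_correction_virion,
      count_scale = count_scale)
    data.frame(cell_id = sprintf("cell%03d", i), hpi = NA_real_,
               low = est$low, high = est$high,
               cell_total_absorbance = est$cell_total_absorbance,
               true_fraction = rec$true_fraction)
  })
  conv_df <- do.call(rbind, conv)
  write_tsv_table(conv_df, file.path(out_dir, "conversion.tsv"))
  image_interval <- 100 * c(mean(conv_df$low), mean(conv_df$high))

  ## stage 4: titration --------------------------------------------------
  ti <- config$titration
  say("stage titer: %s fit of simulated series", ti$method)
  series <- simulate_titration(ti$a, parse_dilution(unlist(ti$dilutions)),
                               wells = ti$wells,
                               seed = config$seeds$titration)
  fit <- fit_titration(series, method = ti$method,
                       seed = config$seeds$titration + 1L)
  bk <- burst_bookkeeping(ti$bookkeeping$well0_dilution,
                          ti$bookkeeping$inoculum_volume_ml,
                          ti$bookkeeping$suspension_volume_ml,
                          ti$bookkeeping$n_cells)
  burst <- burst_size(fit, bk)

  ## stage 5: biomass -----------------------------------------------------
  say("stage biomass: TGA reduction and conversion arithmetic")
  tg <- config$tga
  tg_virus <- simulate_thermogram(tg$plateau_virus, noise_sd = tg$noise_sd,
                                  seed = config$seeds$tga, label = "virus")
  tg_cell <- simulate_thermogram(tg$plateau_cell, noise_sd = tg$noise_sd,
                                 seed = config$seeds$tga + 1L,
                                 label = "cell")
  res_v <- residual_fraction(tg_virus)
  res_c <- residual_fraction(tg_cell)
  cr <- carbon_ratio(100 * res_v, 100 * res_c)
  v_vir <- spheroid_volume(config$phantom$virion_length_nm / 1000,
                           config$phantom$virion_width_nm / 1000)
  vf <- volume_fraction(burst$ci95, v_vir, config$biomass$cell_volume_um3)
  titration_interval <- 100 * biomass_conversion(vf, cr)
  overlap <- interval_intersection(titration_interval, image_interval)

  report <- list(
    package_version = as.character(utils::packageVersion("virionquant")),
    config_hash = hash,
    counts = counts_df,
    false_positive_rate = fp_rate,
    orientation_miss_probability = miss_p,
    typical_virion_absorbance = typical,
    conversion = conv_df,
    image_interval_pct = image_interval,
    titration = list(a_hat = fit$a_hat, ci95 = fit$ci95,
                     tcid50_dilution = tcid50(fit),
                     burst = burst$burst, burst_ci95 = burst$ci95),
    tga = list(residual_virus = res_v, residual_cell = res_c,
               carbon_ratio = cr),
    virion_volume_um3 = v_vir,
    titration_interval_pct = titration_interval,
    overlap_interval_pct = overlap
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  say("pipeline done: %s", out_dir)
  invisible(report)
}
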