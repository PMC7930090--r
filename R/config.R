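#' Pipeline configuration
#'
#' All physical constants and tunables of the pipeline live in the
#' configuration, not in code: attenuation of the medium (27% transmission
#' through 10 um), the 700 photons/pixel flat field, the 19.3 nm pixel,
#' the 700/1500 nm and 1.3 classification thresholds, the 15%/3% water
#' corrections, the 4 um displaced-medium compensation and the sigma = 1 px
#' smoothing.  `default_config()` returns the bundled defaults
#' (`inst/extdata/default_config.yaml`); `read_config()` loads a user YAML
#' and fills unspecified fields from the defaults.
#'
#' @param path YAML file path.
#' @return A nested configuration list (class `vq_config`).
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "virionquant"))
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  defaults_path <- system.file("extdata", "default_config.yaml",
                               package = "virionquant")
  if (nzchar(defaults_path) && normalizePath(path) !=
      normalizePath(defaults_path)) {
    cfg <- modify_defaults(yaml::read_yaml(defaults_path), cfg)
  }
  validate_config(cfg)
  structure(cfg, class = "vq_config")
}

# Recursively overlay `over` onto `base`.
modify_defaults <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_defaults(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' @rdname default_config
#' @param cfg Configuration list to validate.
#' @export
validate_config <- function(cfg) {
  need <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg)
  o <- cfg$optics
  need(is.list(o), "missing `optics` section")
  need(o$medium_transmission > 0 && o$medium_transmission < 1,
       "`optics$medium_transmission` must be in (0, 1)")
  need(o$medium_thickness_um > 0, "`optics$medium_thickness_um` > 0")
  need(o$mu_biomass > 0, "`optics$mu_biomass` > 0")
  need(o$flat_field_photons > 0, "`optics$flat_field_photons` > 0")
  need(o$ice_thickness_um > 0, "`optics$ice_thickness_um` > 0")
  r <- cfg$classification
  need(r$min_length_nm > 0 && r$max_length_nm > r$min_length_nm,
       "classification lengths must satisfy 0 < min < max")
  need(r$min_ellipticity >= 1, "`min_ellipticity` >= 1")
  a <- cfg$absorbance
  need(a$water_correction_cell >= 0 && a$water_correction_cell < 1,
       "`water_correction_cell` in [0, 1)")
  need(a$water_correction_virion >= 0 && a$water_correction_virion < 1,
       "`water_correction_virion` in [0, 1)")
  need(a$smoothing_sigma_px >= 0, "`smoothing_sigma_px` >= 0")
  t <- cfg$titration
  need(t$method %in% c("ml", "lsq"), "`titration$method` must be ml or lsq")
  need(all(vapply(cfg$seeds, function(s)
    is.numeric(s) && length(s) == 1 && s == round(s), TRUE)),
    "every seed must be a single integer")
  invisible(cfg)
}

# Optics object from a config.
config_optics <- function(cfg) {
  o <- cfg$optics
  optical_constants(
    mu_water = attenuation_from_transmission(o$medium_thickness_um,
                                             o$medium_transmission),
    mu_biomass = o$mu_biomass,
    flat_field_photons = o$flat_field_photons,
    ice_thickness = o$ice_thickness_um
  )
}

# Stable hash of a configuration (md5 of its canonical JSON).
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[sort(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}
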