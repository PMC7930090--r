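#' Write and read photon-count micrographs as 16-bit TIFF
#'
#' Micrographs are stored as single-channel 16-bit grayscale TIFF with a
#' JSON sidecar (`<path>.json`) holding the pixel size and metadata, so
#' integer photon counts survive a write/read cycle losslessly.
#'
#' @param mg A [micrograph()] with integer counts below 65536.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(mg, path) {
  stopifnot(inherits(mg, "micrograph"))
  if (any(mg$pixels > 65535) || any(mg$pixels != round(mg$pixels))) {
    stop("16-bit storage needs integer counts in [0, 65535]")
  }
  tiff::writeTIFF(mg$pixels / 65535, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = mg$pixel_size,
                            metadata = mg$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_micrograph
#' @param pixel_size Pixel pitch in nm; required when no sidecar exists.
#' @export
read_micrograph <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2L) {
    stop("expected a single-channel grayscale TIFF, got ",
         paste(dim(px), collapse = " x "), " (multi-channel/RGB?)")
  }
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- sc$pixel_size_nm
    meta <- as.list(sc$metadata)
  }
  if (is.null(pixel_size)) {
    stop("pixel size unknown: no sidecar `", basename(sidecar),
         "` and no `pixel_size` argument")
  }
  micrograph(px, pixel_size, metadata = meta)
}

#' Write and read absorbance maps as 32-bit float TIFF
#'
#' Absorbance values can be negative (noise) or exceed 1, while TIFF float
#' storage here is defined on `[0, 1]`; the map is therefore affinely
#' rescaled to `[0, 1]` for storage and the exact scale recorded in the
#' JSON sidecar, giving round trips accurate to 32-bit float precision.
#'
#' @param map An `absorbance_map` (see [absorbance_map()]).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_absorbance_map <- function(map, path) {
  stopifnot(inherits(map, "absorbance_map"))
  v <- map$values
  finite <- is.finite(v)
  lo <- min(v[finite]); hi <- max(v[finite])
  span <- if (hi > lo) hi - lo else 1
  s <- (v - lo) / span
  s[!finite] <- 0
  tiff::writeTIFF(s, path, bits.per.sample = 32)
  jsonlite::write_json(list(pixel_size_nm = map$pixel_size,
                            offset = lo, scale = span,
                            masked = which(!finite) - 1L),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_absorbance_map
#' @export
read_absorbance_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop("absorbance map needs both the TIFF and its `.json` sidecar")
  }
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * sc$scale + sc$offset
  if (length(sc$masked)) v[sc$masked + 1L] <- NA_real_
  structure(list(values = v, pixel_size = sc$pixel_size_nm,
                 provenance = list(path = path)),
            class = "absorbance_map")
}

#' Read and write annotation marks as CSV
#'
#' The mark CSV convention: one row per mark with columns `center_x_px`,
#' `center_y_px`, `length_nm`, `width_nm`, `angle_deg` and (for ground
#' truth written by the generator) `is_virion`.
#'
#' @param marks Data frame of marks.
#' @param path CSV path.
#' @return The marks data frame (read) or `path` invisibly (write).
#' @export
write_marks_csv <- function(marks, path) {
  utils::write.csv(marks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marks_csv
#' @export
read_marks_csv <- function(path) {
  as_object_marks(utils::read.csv(path))
}

#' Read a titration table
#'
#' TSV/CSV with columns `dilution`, `positives`, `wells`; dilutions may be
#' decimals or power strings such as `"2^-10"` or `"10^-5"`.
#'
#' @param path File path (delimiter inferred from the extension).
#' @param label Optional series label.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path, label = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(dilution = "character"))
  stopifnot(all(c("dilution", "positives", "wells") %in% names(df)))
  titration_series(df$dilution, df$positives, df$wells, label = label)
}

#' Write per-cell count and conversion tables
#'
#' Fixed-header TSV writers used by the pipeline: counts have columns
#' `cell_id`, `hpi`, `n_marks`, `n_virions`, `uncertainty`; conversions
#' have `cell_id`, `hpi`, `low`, `high`, `cell_total_absorbance`.
#'
#' @param x Data frame with the respective columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
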