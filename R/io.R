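#' Read an AFM trace from delimited text
#'
#' Traces are UTF-8 CSV with a header naming the columns `time_s`,
#' `force_nN`, `piezo_um`; the units are part of the column names on purpose,
#' to prevent silent unit mistakes.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the three columns.
#' @export
read_afm_trace <- function(path) {
  if (!file.exists(path)) {
    stop_cortexmech_io("trace file not found: ", path)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "force_nN", "piezo_um")
  if (!all(need %in% names(df))) {
    stop_cortexmech_io("trace file must have header columns ",
                       paste(need, collapse = ", "))
  }
  tibble::as_tibble(df[need])
}

#' Write an AFM trace as CSV
#' @param trace Tibble with `time_s`, `force_nN`, `piezo_um`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_afm_trace <- function(trace, path) {
  utils::write.csv(trace[c("time_s", "force_nN", "piezo_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write an AFM calibration sidecar (JSON)
#' @param path JSON file with fields `k`, `elevation_um`, `spike_um`,
#'   `piezo_ref_um`, `f`, `drive_amplitude_um`.
#' @return An [afm_calibration()] object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_cortexmech_io("calibration file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k", "elevation_um")
  if (!all(need %in% names(j))) {
    stop_cortexmech_io("calibration JSON must contain at least: ",
                       paste(need, collapse = ", "))
  }
  afm_calibration(k = j$k, elevation_um = j$elevation_um,
                  spike_um = j$spike_um %||% 0,
                  piezo_ref_um = j$piezo_ref_um %||% 0,
                  f = j$f %||% 1,
                  drive_amplitude_um = j$drive_amplitude_um %||% 0.25)
}

#' @rdname read_calibration
#' @param calibration An [afm_calibration()] object.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pre-extracted radial profile (CSV with `r_um`, `intensity`)
#' @param path CSV path.
#' @return A `radial_profile` tibble.
#' @export
read_radial_profile <- function(path) {
  if (!file.exists(path)) stop_cortexmech_io("profile file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("r_um", "intensity") %in% names(df))) {
    stop_cortexmech_io("profile CSV must have columns r_um, intensity")
  }
  new_radial_profile(df$r_um, df$intensity)
}

#' Read an image or binary mask (TIFF/PNG)
#' @param path Image path; multi-frame images return the first frame.
#' @return A numeric matrix (x, y indexing).
#' @export
read_image_matrix <- function(path) {
  if (!file.exists(path)) stop_cortexmech_io("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) > 2) as.matrix(img[, , 1]) else as.matrix(img)
  m
}
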