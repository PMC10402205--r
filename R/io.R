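# Containers: RF channel data as raw float32 + JSON sidecar, volumes as
# NIfTI (mm spacing in the header; complex payloads as a real/imag pair),
# tracks and vessels as CSV. All round-trips are lossless for float32.

rf_schema <- "ulmpact/rf/1"

#' Write / read an RF dataset
#'
#' The native RF container is a pair of files: `<stem>.bin` holding the
#' channel samples as little-endian float32 (samples fastest, then
#' elements, then transmit events), and `<stem>.json` holding shape,
#' sampling rate, sound speed, mode, wavelength or transmit indices, and
#' the embedded array geometry. The sidecar is schema-versioned;
#' mismatched or corrupted versions raise an explicit error.
#'
#' @param rf An `rf_data`.
#' @param stem Path stem (without extension).
#' @return `write_rf`: the stem, invisibly. `read_rf`: the `rf_data`.
#' @export
write_rf <- function(rf, stem) {
  stopifnot(inherits(rf, "rf_data"))
  d <- rf$data
  dims <- if (rf$mode == "PA") c(1L, dim(d)) else dim(d)
  meta <- list(schema = rf_schema, mode = rf$mode, dims = dims,
               fs_hz = rf$fs, sound_speed_ms = rf$sound_speed,
               center_frequency_hz = rf$center_frequency,
               wavelength_nm = rf$wavelength,
               tx_indices = rf$tx_indices,
               geometry = list(
                 n_elements = rf$geometry$n_elements,
                 curvature_radius_mm = rf$geometry$curvature_radius,
                 aperture_diameter_mm = rf$geometry$aperture_diameter,
                 center_frequency_hz = rf$geometry$center_frequency,
                 fractional_bandwidth_rx = rf$geometry$fractional_bandwidth_rx,
                 layout_seed = rf$geometry$layout_seed))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  # samples fastest on disk
  flat <- if (rf$mode == "PA") as.vector(t(d)) else
    as.vector(aperm(d, c(3, 2, 1)))
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(flat), con, size = 4, endian = "little")
  invisible(stem)
}

#' @rdname write_rf
#' @export
read_rf <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(meta$schema) || !identical(meta$schema, rf_schema)) {
    stop("RF container schema version mismatch (found ",
         if (is.null(meta$schema)) "none" else meta$schema, ", need ",
         rf_schema, ")", call. = FALSE)
  }
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(flat) != n) {
    stop("RF payload truncated: expected ", n, " samples, read ",
         length(flat), call. = FALSE)
  }
  g <- meta$geometry
  geometry <- build_spherical_array(g$n_elements, g$curvature_radius_mm,
                                    g$aperture_diameter_mm, g$layout_seed,
                                    g$center_frequency_hz,
                                    g$fractional_bandwidth_rx)
  if (meta$mode == "PA") {
    d <- t(matrix(flat, nrow = dims[3]))
  } else {
    d <- aperm(array(flat, dim = rev(dims)), c(3, 2, 1))
  }
  rf_data(d, meta$fs_hz, meta$mode, geometry,
          sound_speed = meta$sound_speed_ms,
          wavelength = meta$wavelength_nm,
          tx_indices = meta$tx_indices,
          center_frequency = meta$center_frequency_hz)
}

#' Write / read a volume as NIfTI
#'
#' Scalar volumes go to a single `.nii.gz` with the voxel spacing (mm) in
#' the header and the world origin in the qform translation; complex IQ
#' volumes are written as a `<stem>_real.nii.gz` / `<stem>_imag.nii.gz`
#' pair. Kind and wavelength ride in a small JSON sidecar.
#'
#' @param volume An `ulm_volume`.
#' @param stem Path stem (without extension).
#' @return `write_volume`: the stem, invisibly. `read_volume`: the
#'   `ulm_volume`.
#' @export
write_volume <- function(volume, stem) {
  stopifnot(inherits(volume, "ulm_volume"))
  g <- volume$grid
  meta <- list(schema = "ulmpact/volume/1", kind = volume$kind,
               wavelength_nm = volume$wavelength,
               origin_mm = g$origin, spacing_mm = g$spacing,
               shape = g$shape, complex = is.complex(volume$data))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- g$spacing
    RNifti::writeNifti(img, path)
  }
  if (is.complex(volume$data)) {
    wr(Re(volume$data), paste0(stem, "_real.nii.gz"))
    wr(Im(volume$data), paste0(stem, "_imag.nii.gz"))
  } else {
    wr(volume$data, paste0(stem, ".nii.gz"))
  }
  invisible(stem)
}

#' @rdname write_volume
#' @export
read_volume <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(meta$schema) || !identical(meta$schema, "ulmpact/volume/1")) {
    stop("volume container schema version mismatch", call. = FALSE)
  }
  grid <- voxel_grid(meta$shape, meta$spacing_mm, meta$origin_mm)
  rd <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.numeric(img), dim = dim(img))  # plain array, header dropped
  }
  if (isTRUE(meta$complex)) {
    re <- rd(paste0(stem, "_real.nii.gz"))
    im <- rd(paste0(stem, "_imag.nii.gz"))
    data <- array(complex(real = re, imaginary = im), dim = dim(re))
  } else {
    data <- rd(paste0(stem, ".nii.gz"))
  }
  ulm_volume(data, grid, kind = meta$kind, wavelength = meta$wavelength_nm)
}

#' Write / read tracks as CSV
#'
#' Columns: `track_id`, `frame`, `x_mm`, `y_mm`, `z_mm`, `intensity`,
#' `vx_mms`, `vy_mms`, `vz_mms`, `speed_mms`; the frame rate is stored in a
#' header comment.
#'
#' @param tracks A `track_set`.
#' @param path CSV path.
#' @return `write_tracks`: `path` invisibly; `read_tracks`: a `track_set`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  tb <- tibble::as_tibble(tracks)
  names(tb) <- c("track_id", "frame", "x_mm", "y_mm", "z_mm", "intensity",
                 "vx_mms", "vy_mms", "vz_mms", "speed_mms")
  writeLines(sprintf("# ulmpact/tracks/1 frame_rate_hz=%.10g",
                     attr(tracks, "frame_rate")), path)
  readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# ulmpact/tracks/1", hdr)) {
    stop("track CSV schema version mismatch", call. = FALSE)
  }
  fr <- as.numeric(sub(".*frame_rate_hz=", "", hdr))
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  out <- tibble::tibble(track_id = tb$track_id, frame = tb$frame,
                        x = tb$x_mm, y = tb$y_mm, z = tb$z_mm,
                        intensity = tb$intensity, vx = tb$vx_mms,
                        vy = tb$vy_mms, vz = tb$vz_mms,
                        speed = tb$speed_mms)
  as_track_set(out, fr)
}

#' Write vessels as CSV
#'
#' One row per vessel (centerlines are not serialized): id, hemisphere,
#' radius, length, volume, mean sO2, mean speed.
#'
#' @param vessels A `vessel_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_vessels <- function(vessels, path) {
  stopifnot(inherits(vessels, "vessel_set"))
  tb <- tidy.vessel_set(vessels)
  tb <- tb[c("vessel_id", "hemisphere", "radius_mm", "length_mm",
             "volume_mm3", "mean_so2", "mean_speed_mms")]
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname write_vessels
#' @export
read_vessels <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  tb$n_voxels <- NA_integer_
  tb$centerline <- vector("list", nrow(tb))
  as_vessel_set(tb[c("vessel_id", "radius_mm", "length_mm", "volume_mm3",
                     "n_voxels", "hemisphere", "mean_so2", "mean_speed_mms",
                     "centerline")])
}
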