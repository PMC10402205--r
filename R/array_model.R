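#' Build a spherical-cap receiver array
#'
#' Places `n_elements` transducer elements quasi-uniformly on a spherical cap
#' using a Fibonacci (golden-angle) spiral. The coordinate frame is centred on
#' the geometric focus (the sphere centre): the array sits below the focus and
#' the +z axis points away from the array, into the imaged medium. Every
#' element therefore lies at distance `curvature_radius` from the origin, and
#' element normals point at the focus.
#'
#' The physical array this emulates has 256 elements at 4 MHz centre frequency
#' on a 40 mm radius-of-curvature cap with a 57 mm total aperture; the exact
#' element tiling of such probes is proprietary, so a deterministic
#' quasi-uniform layout is used as a documented stand-in (resolution is set by
#' aperture and bandwidth, not the precise tiling).
#'
#' @param n_elements Number of elements (>= 1).
#' @param curvature_radius Radius of curvature in mm (distance cap to focus).
#' @param aperture_diameter Total projected aperture diameter in mm; must not
#'   exceed the sphere diameter.
#' @param layout_seed Integer seed controlling the spiral's azimuthal phase;
#'   identical seeds give identical layouts.
#' @param center_frequency Centre frequency in Hz.
#' @param fractional_bandwidth_rx Receive-only -6 dB fractional bandwidth.
#' @return An object of class `array_geometry` with fields
#'   `element_positions` (n x 3 matrix, mm), `element_normals` (n x 3, unit),
#'   `curvature_radius`, `aperture_diameter`, `center_frequency`,
#'   `fractional_bandwidth_rx`, `n_elements`.
#' @examples
#' geom <- build_spherical_array(256, 40, 57, layout_seed = 0)
#' range(sqrt(rowSums(geom$element_positions^2)))  # all 40 mm from the focus
#' @export
build_spherical_array <- function(n_elements, curvature_radius = 40,
                                  aperture_diameter = 57, layout_seed = 0,
                                  center_frequency = 4e6,
                                  fractional_bandwidth_rx = 0.75) {
  stopifnot(n_elements >= 1, curvature_radius > 0)
  if (aperture_diameter <= 0 || aperture_diameter > 2 * curvature_radius) {
    stop("aperture_diameter must lie in (0, 2*curvature_radius]: the cap ",
         "cannot exceed the sphere diameter", call. = FALSE)
  }
  R <- curvature_radius
  theta_max <- asin((aperture_diameter / 2) / R)  # cap half-angle

  # golden-angle spiral with equal-area polar spacing over the cap
  i <- seq_len(n_elements) - 0.5
  cos_t <- 1 - (i / n_elements) * (1 - cos(theta_max))
  theta <- acos(pmin(1, pmax(-1, cos_t)))
  golden <- pi * (3 - sqrt(5))
  phase <- golden_phase(layout_seed)
  phi <- (seq_len(n_elements) - 1) * golden + phase
  if (n_elements == 1L) theta <- 0  # degenerate layout: the cap pole

  sin_t <- sin(theta)
  pos <- cbind(R * sin_t * cos(phi),
               R * sin_t * sin(phi),
               -R * cos(theta))
  normals <- -pos / R

  structure(list(element_positions = pos,
                 element_normals = normals,
                 curvature_radius = R,
                 aperture_diameter = aperture_diameter,
                 center_frequency = center_frequency,
                 fractional_bandwidth_rx = fractional_bandwidth_rx,
                 n_elements = as.integer(n_elements),
                 layout_seed = as.integer(layout_seed)),
            class = "array_geometry")
}

# deterministic azimuthal phase derived from the seed, no RNG state touched
golden_phase <- function(seed) {
  (as.numeric(seed) * pi * (sqrt(2) - 1)) %% (2 * pi)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(paste0("<array_geometry> %d elements, ROC %.1f mm, aperture ",
                     "%.1f mm, fc %.2f MHz, Rx BW %.0f%%\n"),
              x$n_elements, x$curvature_radius, x$aperture_diameter,
              x$center_frequency / 1e6, 100 * x$fractional_bandwidth_rx))
  invisible(x)
}

#' Select a spatially uniform transmit subset
#'
#' Chooses `n_tx` elements for synthetic-aperture transmission by
#' farthest-point (maximin) sampling over the element positions: the first two
#' picks are the most distant element pair, and each further pick maximises
#' its minimum distance to the already chosen set. Ties are broken by lowest
#' element index, so the result is deterministic for a fixed geometry. With 31
#' transmitters on the 256-element cap this reproduces the published ~7.5 mm
#' spacing between neighbouring transmit elements.
#'
#' @param geometry An `array_geometry`.
#' @param n_tx Number of transmit elements, between 1 and `n_elements`.
#' @return Integer vector of `n_tx` element indices (sorted ascending).
#' @export
select_tx_subset <- function(geometry, n_tx) {
  stopifnot(inherits(geometry, "array_geometry"))
  n <- geometry$n_elements
  if (n_tx < 1 || n_tx > n) {
    stop("n_tx must be between 1 and n_elements (", n, ")", call. = FALSE)
  }
  n_tx <- as.integer(n_tx)
  if (n_tx == n) return(seq_len(n))
  pos <- geometry$element_positions
  if (n_tx == 1L) {
    # the element closest to the cap pole (array axis)
    lat <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    return(which.min(lat))
  }
  d <- as.matrix(stats::dist(pos))
  # seed with the most distant pair, lowest indices on ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  chosen <- sort(c(best[1, 1], best[1, 2]))
  mind <- pmin(d[, chosen[1]], d[, chosen[2]])
  while (length(chosen) < n_tx) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind)  # which.max takes the first (lowest) index on ties
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  sort(chosen)
}

#' Acquisition sequence descriptor
#'
#' @param tx_indices Integer vector of transmitting element indices (unique).
#' @param pulse_repetition_interval Seconds between transmission events (> 0).
#' @param n_frames Number of volumetric frames in the acquisition.
#' @param fs RF sampling frequency in Hz.
#' @param mode `"PA"` (one-way photoacoustic) or `"US"` (pulse-echo).
#' @return An object of class `acq_sequence`.
#' @export
acq_sequence <- function(tx_indices, pulse_repetition_interval, n_frames = 1L,
                         fs = 20.83e6, mode = c("US", "PA")) {
  mode <- match.arg(mode)
  tx_indices <- as.integer(tx_indices)
  stopifnot(pulse_repetition_interval > 0, n_frames >= 1, fs > 0)
  if (anyDuplicated(tx_indices) || any(tx_indices < 1)) {
    stop("tx_indices must be unique positive element indices", call. = FALSE)
  }
  structure(list(tx_indices = tx_indices,
                 pulse_repetition_interval = pulse_repetition_interval,
                 n_frames = as.integer(n_frames), fs = fs, mode = mode),
            class = "acq_sequence")
}

#' Volumetric frame rate of a synthetic-aperture sequence
#'
#' One volume needs `n_tx` sequential single-element transmissions separated
#' by the pulse-repetition interval, so the volume rate is `1 / (n_tx * pri)`.
#' The published sequence (31 transmitters, 150 microsecond spacing) gives
#' 215 Hz.
#'
#' @param n_tx Number of transmit events per volume.
#' @param pri Pulse repetition interval in seconds.
#' @return Volume rate in Hz (exact, not rounded).
#' @examples
#' volumetric_frame_rate(31, 150e-6)  # 215.05 Hz
#' @export
volumetric_frame_rate <- function(n_tx, pri) {
  stopifnot(n_tx >= 1, pri > 0)
  1 / (n_tx * pri)
}

#' Raster-scan grid of lateral positions
#'
#' @param n_x,n_y Number of scan positions along x and y.
#' @param step Lateral step in mm between neighbouring positions.
#' @param base_fov Length-3 numeric, per-position field of view (x, y, z) mm.
#' @return An object of class `scan_grid` with a `positions` matrix of
#'   lateral (x, y) offsets centred on zero.
#' @export
scan_grid <- function(n_x, n_y, step, base_fov = c(8, 8, 8)) {
  stopifnot(n_x >= 1, n_y >= 1, step >= 0, length(base_fov) == 3)
  xs <- (seq_len(n_x) - (n_x + 1) / 2) * step
  ys <- (seq_len(n_y) - (n_y + 1) / 2) * step
  positions <- as.matrix(expand.grid(x = xs, y = ys))
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y), step = step,
                 base_fov = as.numeric(base_fov), positions = positions),
            class = "scan_grid")
}

#' Stitched field of view of a raster scan
#'
#' Each lateral axis extends the per-position field of view by
#' `(n - 1) * step`; the axial (z) extent is unchanged. The published scan
#' (3 x 2 positions, 3 mm step, 8 mm base) yields 14 x 11 x 8 mm^3.
#'
#' @param grid A `scan_grid`.
#' @return Named numeric length 3: stitched (x, y, z) extent in mm.
#' @examples
#' stitched_fov(scan_grid(3, 2, 3, c(8, 8, 8)))  # 14 11 8
#' @export
stitched_fov <- function(grid) {
  stopifnot(inherits(grid, "scan_grid"))
  c(x = grid$base_fov[1] + (grid$n_x - 1) * grid$step,
    y = grid$base_fov[2] + (grid$n_y - 1) * grid$step,
    z = grid$base_fov[3])
}

#' Serialize array geometry to JSON
#'
#' Coordinates in mm, frequencies in Hz. `read_geometry_json` inverts it.
#' @param geometry An `array_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "array_geometry"))
  obj <- list(schema = "ulmpact/geometry/1",
              n_elements = geometry$n_elements,
              curvature_radius_mm = geometry$curvature_radius,
              aperture_diameter_mm = geometry$aperture_diameter,
              center_frequency_hz = geometry$center_frequency,
              fractional_bandwidth_rx = geometry$fractional_bandwidth_rx,
              layout_seed = geometry$layout_seed,
              element_positions_mm = geometry$element_positions,
              element_normals = geometry$element_normals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "ulmpact/geometry/1")) {
    stop("unrecognised geometry schema version in ", path, call. = FALSE)
  }
  structure(list(element_positions = as.matrix(obj$element_positions_mm),
                 element_normals = as.matrix(obj$element_normals),
                 curvature_radius = obj$curvature_radius_mm,
                 aperture_diameter = obj$aperture_diameter_mm,
                 center_frequency = obj$center_frequency_hz,
                 fractional_bandwidth_rx = obj$fractional_bandwidth_rx,
                 n_elements = as.integer(obj$n_elements),
                 layout_seed = as.integer(obj$layout_seed)),
            class = "array_geometry")
}
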