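#' Metric voxel grid
#'
#' Axis-aligned 3D voxel lattice in mm, by default centred on the array focus
#' (the coordinate origin). `origin` is the centre of voxel (1,1,1).
#'
#' @param shape Integer length 3, voxel counts (nx, ny, nz).
#' @param spacing Voxel pitch in mm; scalar or length 3.
#' @param origin Centre of the first voxel in mm; default centres the grid on
#'   the origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(c(67, 67, 67), 0.06)  # 4 mm cube of 60-um voxels at the focus
#' @export
voxel_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  stopifnot(length(origin) == 3)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' Voxel centre coordinates of a grid
#'
#' @param grid A `voxel_grid`.
#' @return An (nx*ny*nz) x 3 matrix of voxel centres in mm, in R array order
#'   (x fastest).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  ax <- lapply(1:3, function(k) grid$origin[k] +
                 (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
  cbind(rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
        rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

#' Grid axis coordinates
#' @param grid A `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-centre coordinates along that axis (mm).
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Volumetric image on a voxel grid
#'
#' The common container for every reconstructed payload: photoacoustic
#' amplitude (`PA`), complex beamformed baseband (`BMODE_IQ`), power Doppler
#' (`PD`), oxygen saturation (`SO2`), and ULM density/velocity maps
#' (`DENSITY`, `VELOCITY`).
#'
#' @param data 3D numeric or complex array matching `grid$shape`.
#' @param grid A `voxel_grid`.
#' @param kind Payload kind.
#' @param wavelength Optional excitation wavelength tag in nm (PA payloads).
#' @param extra Optional named list of per-volume metadata (for example the
#'   beamformer's truncation fraction).
#' @return An object of class `ulm_volume`.
#' @export
ulm_volume <- function(data, grid, kind = c("PA", "BMODE_IQ", "PD", "SO2",
                                            "DENSITY", "VELOCITY", "GENERIC"),
                       wavelength = NULL, extra = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "voxel_grid"))
  data <- as.array(data)
  if (!identical(dim(data), as.integer(grid$shape))) {
    stop("payload shape ", paste(dim(data), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"),
         call. = FALSE)
  }
  if (kind == "SO2") {
    ok <- is.na(data) | (data >= 0 & data <= 1)
    if (!all(ok)) stop("SO2 payload must lie in [0,1] or be NA-flagged",
                       call. = FALSE)
  }
  structure(list(data = data, grid = grid, kind = kind,
                 wavelength = wavelength, extra = extra),
            class = "ulm_volume")
}

#' @export
print.ulm_volume <- function(x, ...) {
  cat(sprintf("<ulm_volume:%s> %s voxels @ %s mm, origin (%s) mm%s\n",
              x$kind, paste(x$grid$shape, collapse = "x"),
              paste(signif(x$grid$spacing, 3), collapse = "x"),
              paste(signif(x$grid$origin, 3), collapse = ", "),
              if (!is.null(x$wavelength))
                sprintf(", lambda %g nm", x$wavelength) else ""))
  invisible(x)
}

#' Long-format voxel table of a volume
#'
#' @param x An `ulm_volume`.
#' @param drop_zero Drop zero/NA voxels (keeps tables small).
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z` (mm) and `value`.
#' @export
as_tibble.ulm_volume <- function(x, ..., drop_zero = TRUE) {
  co <- grid_coords(x$grid)
  v <- as.vector(x$data)
  keep <- if (drop_zero) which(!is.na(v) & Mod(v) > 0) else seq_along(v)
  tibble::tibble(x = co[keep, 1], y = co[keep, 2], z = co[keep, 3],
                 value = v[keep])
}

#' Envelope of a signed PA volume
#'
#' Analytic-signal magnitude computed column-by-column along the axial (z)
#' direction, the standard display detector for signed delay-and-sum output.
#'
#' @param volume An `ulm_volume` with real payload.
#' @return An `ulm_volume` of the same kind with non-negative payload.
#' @export
envelope_volume <- function(volume) {
  stopifnot(inherits(volume, "ulm_volume"))
  d <- volume$data
  nz <- dim(d)[3]
  if (nz < 4) {
    volume$data <- abs(d)
    return(volume)
  }
  m <- matrix(aperm(d, c(3, 1, 2)), nrow = nz)  # columns along z
  env <- abs(analytic_columns(m))
  volume$data <- aperm(array(env, dim = dim(d)[c(3, 1, 2)]), c(2, 3, 1))
  volume
}

# analytic signal of each column via one-sided spectrum
analytic_columns <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
}

#' Maximum-intensity projection
#'
#' @param volume An `ulm_volume`.
#' @param axis Axis to project along (default 3, the axial direction, giving
#'   the lateral MIP used for motion gating).
#' @return A matrix (magnitude for complex payloads).
#' @export
mip <- function(volume, axis = 3) {
  stopifnot(inherits(volume, "ulm_volume"), axis %in% 1:3)
  apply(Mod(volume$data), setdiff(1:3, axis), max)
}
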