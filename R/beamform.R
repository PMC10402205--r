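#' 3D delay-and-sum photoacoustic reconstruction
#'
#' One-way DAS: each voxel sums, over all receive elements, the RF sample at
#' the one-way time of flight `|p_vox - p_elem| / c`, with linear temporal
#' interpolation, normalised by the element count. Delays falling outside
#' the record contribute zero; the fraction of truncated (voxel, element)
#' lookups is reported in the volume's `extra$truncation_fraction` and more
#' than 50% truncation is an error.
#'
#' @param rf An `rf_data` in PA mode.
#' @param grid A `voxel_grid` (mm, focus-centred frame).
#' @param c Speed of sound, m/s (defaults to the value stored in `rf`).
#' @param envelope If `TRUE`, return the axial-envelope-detected volume.
#' @return An `ulm_volume` of kind `"PA"` (signed unless `envelope`).
#' @export
das_pa <- function(rf, grid, c = rf$sound_speed, envelope = FALSE) {
  stopifnot(inherits(rf, "rf_data"), rf$mode == "PA",
            inherits(grid, "voxel_grid"))
  co <- grid_coords(grid)
  nvox <- nrow(co)
  ns <- ncol(rf$data)
  acc <- numeric(nvox)
  trunc_n <- 0
  cs <- c * mm_per_s
  for (e in seq_len(rf$geometry$n_elements)) {
    dp <- sweep(co, 2, rf$geometry$element_positions[e, ])
    tau <- sqrt(rowSums(dp^2)) / cs * rf$fs + 1  # 1-based sample position
    acc <- acc + interp_channel(rf$data[e, ], tau)
    trunc_n <- trunc_n + sum(tau < 1 | tau > ns)
  }
  tf <- trunc_n / (nvox * rf$geometry$n_elements)
  if (tf > 0.5) {
    stop(sprintf(paste0("more than 50%% of delays fall outside the record ",
                        "window (truncation fraction %.2f); grid and record ",
                        "are inconsistent"), tf), call. = FALSE)
  }
  vol <- ulm_volume(array(acc / rf$geometry$n_elements, dim = grid$shape),
                    grid, kind = "PA", wavelength = rf$wavelength,
                    extra = list(truncation_fraction = tf))
  if (envelope) envelope_volume(vol) else vol
}

# linear interpolation of one channel at fractional sample positions;
# out-of-window positions contribute zero
interp_channel <- function(ch, tau) {
  ns <- length(ch)
  i0 <- floor(tau)
  w <- tau - i0
  ok0 <- i0 >= 1 & i0 <= ns
  ok1 <- i0 + 1 >= 1 & i0 + 1 <= ns
  v <- numeric(length(tau))
  v[ok0] <- v[ok0] + (1 - w[ok0]) * ch[i0[ok0]]
  v[ok1] <- v[ok1] + w[ok1] * ch[i0[ok1] + 1]
  v
}

#' 3D delay-and-sum synthetic-aperture ultrasound reconstruction
#'
#' Two-way DAS producing complex (IQ) voxels: per transmit event and receive
#' element the analytic RF signal (one-sided spectrum via the frequency
#' domain) is sampled at the round-trip time of flight
#' `(|p_tx - p_vox| + |p_vox - p_rx|) / c` with linear interpolation and
#' summed. This equals channel-wise baseband demodulation followed by
#' delay-matched phase rotation, so the carrier terms align coherently at a
#' scatterer and the voxel phase tracks round-trip path changes at
#' `2*pi*fc/c` per unit path — the phase sensitivity slow-time Doppler
#' processing relies on.
#'
#' @param rf An `rf_data` in US mode (tx-events x elements x samples).
#' @param grid A `voxel_grid`.
#' @param c Speed of sound, m/s.
#' @return An `ulm_volume` of kind `"BMODE_IQ"` with complex payload.
#' @export
das_us <- function(rf, grid, c = rf$sound_speed) {
  stopifnot(inherits(rf, "rf_data"), rf$mode == "US",
            inherits(grid, "voxel_grid"))
  co <- grid_coords(grid)
  nvox <- nrow(co)
  ns <- dim(rf$data)[3]
  cs <- c * mm_per_s
  acc <- complex(nvox)
  trunc_n <- 0
  pos <- rf$geometry$element_positions
  for (ti in seq_along(rf$tx_indices)) {
    dtx <- sweep(co, 2, pos[rf$tx_indices[ti], ])
    r_tx <- sqrt(rowSums(dtx^2))
    for (e in seq_len(rf$geometry$n_elements)) {
      an <- analytic_columns(matrix(rf$data[ti, e, ], ncol = 1))[, 1]
      drx <- sweep(co, 2, pos[e, ])
      tau <- (r_tx + sqrt(rowSums(drx^2))) / cs * rf$fs + 1
      acc <- acc + interp_channel_cplx(an, tau)
      trunc_n <- trunc_n + sum(tau < 1 | tau > ns)
    }
  }
  npair <- length(rf$tx_indices) * rf$geometry$n_elements
  tf <- trunc_n / (nvox * npair)
  if (tf > 0.5) {
    stop(sprintf("more than 50%% of delays fall outside the record window (truncation fraction %.2f)",
                 tf), call. = FALSE)
  }
  ulm_volume(array(acc / npair, dim = grid$shape), grid, kind = "BMODE_IQ",
             extra = list(truncation_fraction = tf))
}

interp_channel_cplx <- function(ch, tau) {
  ns <- length(ch)
  i0 <- floor(tau)
  w <- tau - i0
  ok0 <- i0 >= 1 & i0 <= ns
  ok1 <- i0 + 1 >= 1 & i0 + 1 <= ns
  v <- complex(length(tau))
  v[ok0] <- v[ok0] + (1 - w[ok0]) * ch[i0[ok0]]
  v[ok1] <- v[ok1] + w[ok1] * ch[i0[ok1] + 1]
  v
}

#' Sparse-matrix delay-and-sum operator
#'
#' Precomputes DAS as a sparse linear map from flattened RF to flattened
#' volume, the CPU analogue of sparse-matrix-multiplication beamforming used
#' for real-time display. Each (voxel, channel) pair contributes two
#' nonzeros implementing linear temporal interpolation, so applying the
#' operator reproduces [das_pa()]/[das_us()] to numerical precision (for US
#' mode it is applied to the real and imaginary parts of the analytic RF).
#'
#' @param geometry An `array_geometry`.
#' @param sequence An `acq_sequence`; its `mode` selects one-way PA (tx
#'   ignored) or two-way US delays, `fs` the sample clock.
#' @param grid A `voxel_grid`.
#' @param c Speed of sound, m/s.
#' @param n_samples Record length the operator expects.
#' @param fc Baseband rotation frequency for US mode.
#' @param memory_cap_bytes Refuse to build if the nonzero estimate exceeds
#'   this cap (default 2 GiB).
#' @return An object of class `sparse_das` with `apply_sparse_das()`.
#' @export
build_sparse_das <- function(geometry, sequence, grid, c = 1540,
                             n_samples, fc = geometry$center_frequency,
                             memory_cap_bytes = 2 * 1024^3) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(sequence, "acq_sequence"), inherits(grid, "voxel_grid"),
            n_samples >= 2)
  co <- grid_coords(grid)
  nvox <- nrow(co)
  ne <- geometry$n_elements
  mode <- sequence$mode
  ntx <- if (mode == "US") length(sequence$tx_indices) else 1L
  nnz_est <- 2 * as.numeric(nvox) * ne * ntx
  bytes <- nnz_est * (8 + 4 + 4) * (if (mode == "US") 2 else 1)
  if (bytes > memory_cap_bytes) {
    stop(sprintf("sparse DAS operator would need ~%.1f GiB (cap %.1f GiB)",
                 bytes / 1024^3, memory_cap_bytes / 1024^3), call. = FALSE)
  }
  fs <- sequence$fs
  cs <- c * mm_per_s
  pos <- geometry$element_positions

  blocks_i <- vector("list", ntx * ne)
  blocks_j <- vector("list", ntx * ne)
  blocks_w <- vector("list", ntx * ne)
  bi <- 0L
  for (ti in seq_len(ntx)) {
    r_tx <- if (mode == "US") {
      dtx <- sweep(co, 2, pos[sequence$tx_indices[ti], ])
      sqrt(rowSums(dtx^2))
    } else 0
    for (e in seq_len(ne)) {
      drx <- sweep(co, 2, pos[e, ])
      tau <- (r_tx + sqrt(rowSums(drx^2))) / cs * fs + 1
      i0 <- floor(tau)
      w <- tau - i0
      ch_off <- ((ti - 1L) * ne + (e - 1L)) * n_samples
      ok0 <- which(i0 >= 1 & i0 <= n_samples)
      ok1 <- which(i0 + 1 >= 1 & i0 + 1 <= n_samples)
      bi <- bi + 1L
      blocks_i[[bi]] <- c(ok0, ok1)
      blocks_j[[bi]] <- c(ch_off + i0[ok0], ch_off + i0[ok1] + 1L)
      blocks_w[[bi]] <- c(1 - w[ok0], w[ok1])
    }
  }
  ii <- unlist(blocks_i, use.names = FALSE)
  jj <- unlist(blocks_j, use.names = FALSE)
  norm <- ntx * ne
  W <- Matrix::sparseMatrix(i = ii, j = jj,
                            x = unlist(blocks_w, use.names = FALSE) / norm,
                            dims = c(nvox, as.numeric(ntx) * ne * n_samples))
  structure(list(W = W, grid = grid, mode = mode, fs = fs,
                 n_samples = as.integer(n_samples), fc = fc,
                 n_elements = ne,
                 tx_indices = if (mode == "US") sequence$tx_indices),
            class = "sparse_das")
}

#' Apply a sparse DAS operator to RF data
#'
#' @param op A `sparse_das` operator.
#' @param rf An `rf_data` whose mode, channel count and record length match
#'   the operator.
#' @return An `ulm_volume` (`"PA"` for one-way real output, `"BMODE_IQ"` for
#'   two-way complex output), equal to the direct beamformer's result.
#' @export
apply_sparse_das <- function(op, rf) {
  stopifnot(inherits(op, "sparse_das"), inherits(rf, "rf_data"),
            identical(op$mode, rf$mode))
  if (op$mode == "PA") {
    stopifnot(ncol(rf$data) == op$n_samples)
    x <- as.vector(t(rf$data))  # channel-major: samples fastest
    v <- as.vector(op$W %*% x)
    return(ulm_volume(array(v, dim = op$grid$shape), op$grid, kind = "PA",
                      wavelength = rf$wavelength))
  }
  stopifnot(dim(rf$data)[3] == op$n_samples,
            identical(op$tx_indices, rf$tx_indices))
  ns <- dim(rf$data)[3]
  # analytic signal per channel, flattened with samples fastest
  m <- matrix(aperm(rf$data, c(3, 2, 1)), nrow = ns)
  an <- analytic_columns(m)
  re <- as.vector(op$W %*% as.vector(Re(an)))
  im <- as.vector(op$W %*% as.vector(Im(an)))
  ulm_volume(array(complex(real = re, imaginary = im), dim = op$grid$shape),
             op$grid, kind = "BMODE_IQ")
}

#' Wiener deconvolution of RF data by the transducer impulse response
#'
#' Divides each channel's spectrum by the impulse-response spectrum,
#' regularised as `conj(H) / (|H|^2 + noise_floor * max|H|^2)`. Used before
#' low-frequency PA reconstruction to undo the band shaping of the receive
#' electronics.
#'
#' @param rf An `rf_data`.
#' @param ir An `impulse_response` (resampled to the RF clock if needed).
#' @param noise_floor Positive regularisation constant (relative to the
#'   spectral peak power).
#' @return An `rf_data` of the same shape.
#' @export
deconvolve_rf <- function(rf, ir, noise_floor = 1e-3) {
  stopifnot(inherits(rf, "rf_data"))
  if (noise_floor <= 0) stop("noise_floor must be > 0", call. = FALSE)
  ir <- resample_ir(ir, rf$fs)
  apply_channels(rf, function(ch) {
    n <- length(ch)
    nfft <- stats::nextn(n + length(ir$waveform), 2)
    H <- stats::fft(c(ir$waveform, numeric(nfft - length(ir$waveform))))
    # undo the waveform-centre group delay so timing is preserved
    f <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) / nfft
    H <- H * exp(2i * pi * f * (ir$center_index - 1))
    G <- Conj(H) / (Mod(H)^2 + noise_floor * max(Mod(H)^2))
    X <- stats::fft(c(ch, numeric(nfft - n)))
    Re(stats::fft(X * G, inverse = TRUE) / nfft)[seq_len(n)]
  })
}

#' Zero-phase low-pass filtering of RF data
#'
#' Forward-backward Butterworth low-pass; two passes of the -3 dB design put
#' the -6 dB point at the cutoff. The published sO2 conditioning uses a
#' 1 MHz cutoff.
#'
#' @param rf An `rf_data`.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist.
#' @param order Per-pass Butterworth order.
#' @return An `rf_data` of the same shape.
#' @export
lowpass_rf <- function(rf, cutoff = 1e6, order = 4) {
  stopifnot(inherits(rf, "rf_data"))
  if (cutoff >= rf$fs / 2) stop("cutoff must be below Nyquist", call. = FALSE)
  bt <- signal::butter(order, cutoff / (rf$fs / 2), type = "low")
  apply_channels(rf, function(ch) signal::filtfilt(bt, ch))
}

apply_channels <- function(rf, f) {
  d <- rf$data
  if (rf$mode == "PA") {
    for (e in seq_len(nrow(d))) d[e, ] <- f(d[e, ])
  } else {
    for (ti in seq_len(dim(d)[1])) for (e in seq_len(dim(d)[2])) {
      d[ti, e, ] <- f(d[ti, e, ])
    }
  }
  rf$data <- d
  rf
}

#' Stitch raster-scanned volumes into an extended field of view
#'
#' Places each per-position volume at its lateral scan offset on a common
#' lattice and combines overlaps by maximum (default, robust to seam
#' dropout) or mean. Offsets must sit on the voxel lattice so no resampling
#' is needed.
#'
#' @param volumes List of `ulm_volume` with identical spacing and shape-z.
#' @param offsets n x 2 (or n x 3) matrix of lateral offsets in mm, one row
#'   per volume.
#' @param blend `"max"` or `"mean"`.
#' @return An `ulm_volume` spanning the union bounding box.
#' @export
stitch <- function(volumes, offsets, blend = c("max", "mean")) {
  blend <- match.arg(blend)
  stopifnot(length(volumes) >= 1)
  if (length(volumes) == 1 && is.null(offsets)) return(volumes[[1]])
  offsets <- as.matrix(offsets)
  if (ncol(offsets) == 2) offsets <- cbind(offsets, 0)
  stopifnot(nrow(offsets) == length(volumes))
  sp <- volumes[[1]]$grid$spacing
  for (v in volumes) {
    if (!isTRUE(all.equal(v$grid$spacing, sp))) {
      stop("all volumes must share voxel spacing", call. = FALSE)
    }
  }
  # voxel-lattice check and integer shifts
  shifts <- matrix(0L, length(volumes), 3)
  for (i in seq_along(volumes)) {
    s <- (volumes[[i]]$grid$origin + offsets[i, ] - volumes[[1]]$grid$origin) / sp
    if (any(abs(s - round(s)) > 1e-6)) {
      stop("offsets must lie on the voxel lattice", call. = FALSE)
    }
    shifts[i, ] <- as.integer(round(s))
  }
  lo <- apply(shifts, 2, min)
  hi_ext <- sapply(seq_along(volumes), function(i)
    shifts[i, ] + volumes[[i]]$grid$shape)
  hi <- apply(t(hi_ext), 2, max)
  shape <- hi - lo
  first_cplx <- is.complex(volumes[[1]]$data)
  acc <- array(if (first_cplx) 0i else 0, dim = shape)
  cnt <- array(0L, dim = shape)
  for (i in seq_along(volumes)) {
    s <- shifts[i, ] - lo
    ix <- (s[1] + 1):(s[1] + volumes[[i]]$grid$shape[1])
    iy <- (s[2] + 1):(s[2] + volumes[[i]]$grid$shape[2])
    iz <- (s[3] + 1):(s[3] + volumes[[i]]$grid$shape[3])
    if (blend == "max") {
      acc[ix, iy, iz] <- pmax(acc[ix, iy, iz], volumes[[i]]$data)
    } else {
      acc[ix, iy, iz] <- acc[ix, iy, iz] + volumes[[i]]$data
      cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
    }
  }
  if (blend == "mean") acc <- acc / pmax(cnt, 1L)
  grid <- voxel_grid(shape, sp,
                     origin = volumes[[1]]$grid$origin + lo * sp)
  ulm_volume(acc, grid, kind = volumes[[1]]$kind,
             wavelength = volumes[[1]]$wavelength)
}
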