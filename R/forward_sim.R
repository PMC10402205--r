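#' Gaussian-modulated transducer impulse response
#'
#' Stand-in for a measured electrical impulse response: a Gaussian-windowed
#' sinusoid at the centre frequency whose -6 dB (half-amplitude) spectral
#' full width equals `fractional_bw * fc`. The waveform is symmetric about
#' its centre sample, which marks zero delay.
#'
#' @param fc Centre frequency, Hz.
#' @param fractional_bw Fractional -6 dB bandwidth in (0, 2).
#' @param fs Sampling frequency, Hz; must exceed 4 * fc.
#' @return An object of class `impulse_response` with fields `waveform`,
#'   `fs`, `center_frequency`, `fractional_bandwidth`, `center_index`.
#' @examples
#' ir <- gaussian_pulse(4e6, 0.75, 62.5e6)
#' @export
gaussian_pulse <- function(fc, fractional_bw, fs) {
  stopifnot(fc > 0)
  if (fractional_bw <= 0 || fractional_bw >= 2) {
    stop("fractional_bw must lie in (0, 2)", call. = FALSE)
  }
  if (fs <= 4 * fc) {
    stop("fs must exceed 4*fc: the pulse would be undersampled", call. = FALSE)
  }
  # amplitude spectrum exp(-df^2 / (2 sf^2)) hits 1/2 at df = sf*sqrt(2 ln 2);
  # full -6 dB width 2*sf*sqrt(2 ln 2) = bw*fc
  sf <- fractional_bw * fc / (2 * sqrt(2 * log(2)))
  st <- 1 / (2 * pi * sf)
  half <- ceiling(4 * st * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * st^2)) * cos(2 * pi * fc * t)
  structure(list(waveform = w, fs = fs, center_frequency = fc,
                 fractional_bandwidth = fractional_bw,
                 center_index = half + 1L),
            class = "impulse_response")
}

#' Point photoacoustic source
#'
#' @param position Length-3 position in mm (focus-centred frame).
#' @param absorbed_energy Source strength, arbitrary units.
#' @param spectrum Named numeric vector mapping wavelength (nm, as names) to
#'   relative optical absorption (>= 0).
#' @return An object of class `pa_source`.
#' @export
pa_source <- function(position, absorbed_energy = 1,
                      spectrum = c("700" = 1, "750" = 1, "1064" = 1)) {
  stopifnot(length(position) == 3, absorbed_energy >= 0)
  if (any(spectrum < 0)) stop("relative absorption must be >= 0", call. = FALSE)
  structure(list(position = as.numeric(position),
                 absorbed_energy = absorbed_energy, spectrum = spectrum),
            class = "pa_source")
}

#' Point ultrasound scatterer
#'
#' @param trajectory Either a length-3 position (static) or a function
#'   mapping a slow-time frame index to a length-3 position in mm.
#' @param echogenicity Scattering strength, arbitrary units.
#' @param kind `"clutter"` or `"microbubble"`.
#' @return An object of class `scatterer`.
#' @export
scatterer <- function(trajectory, echogenicity = 1,
                      kind = c("microbubble", "clutter")) {
  kind <- match.arg(kind)
  if (!is.function(trajectory)) {
    p <- as.numeric(trajectory)
    stopifnot(length(p) == 3)
    trajectory <- function(frame) p
  }
  structure(list(trajectory = trajectory, echogenicity = echogenicity,
                 kind = kind),
            class = "scatterer")
}

scatterer_position <- function(s, frame) as.numeric(s$trajectory(frame))

#' RF channel dataset
#'
#' Container for simulated or imported channel data. For PA mode `data` is an
#' elements x samples matrix; for US mode a tx-events x elements x samples
#' array.
#'
#' @param data Numeric matrix/array of channel samples.
#' @param fs Sampling frequency, Hz.
#' @param mode `"PA"` or `"US"`.
#' @param geometry The `array_geometry` the data refer to.
#' @param sound_speed Speed of sound, m/s.
#' @param wavelength Excitation wavelength tag (nm) for PA data.
#' @param tx_indices Transmit element indices (US mode).
#' @param center_frequency Pulse centre frequency, Hz.
#' @return An object of class `rf_data`.
#' @export
rf_data <- function(data, fs, mode, geometry, sound_speed = 1540,
                    wavelength = NULL, tx_indices = NULL,
                    center_frequency = geometry$center_frequency) {
  mode <- match.arg(mode, c("PA", "US"))
  if (mode == "PA") {
    stopifnot(is.matrix(data), nrow(data) == geometry$n_elements)
  } else {
    stopifnot(length(dim(data)) == 3, dim(data)[2] == geometry$n_elements,
              !is.null(tx_indices), dim(data)[1] == length(tx_indices))
  }
  nyq <- geometry$center_frequency *
    (1 + geometry$fractional_bandwidth_rx / 2)
  if (fs <= 2 * nyq) {
    stop("fs must exceed twice the band edge fc*(1+bw/2)", call. = FALSE)
  }
  structure(list(data = data, fs = fs, mode = mode, geometry = geometry,
                 sound_speed = sound_speed, wavelength = wavelength,
                 tx_indices = if (!is.null(tx_indices)) as.integer(tx_indices),
                 center_frequency = center_frequency),
            class = "rf_data")
}

#' @export
print.rf_data <- function(x, ...) {
  cat(sprintf("<rf_data:%s> %s @ %.2f MHz fs, c = %g m/s%s\n", x$mode,
              paste(dim(x$data), collapse = "x"), x$fs / 1e6, x$sound_speed,
              if (!is.null(x$wavelength))
                sprintf(", lambda %g nm", x$wavelength) else ""))
  invisible(x)
}

# Place the impulse response at fractional sample delays via a frequency
# domain phase ramp (band-limited sinc interpolation). `delays` in samples,
# `amps` per delay; returns a length-n record.
place_echoes <- function(ir, delays, amps, n) {
  w <- ir$waveform
  nfft <- stats::nextn(n + length(w), 2)
  wp <- c(w, numeric(nfft - length(w)))
  Wf <- stats::fft(wp)
  f <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) / nfft
  # shift so the waveform centre (zero-delay mark) lands on the delay
  ph <- outer(f, delays - (ir$center_index - 1), function(fr, d)
    exp(-2i * pi * fr * d))
  spec <- Wf * as.vector(ph %*% amps)
  Re(stats::fft(spec, inverse = TRUE) / nfft)[seq_len(n)]
}

# distances from a point (mm) to every element (mm); returns mm
element_ranges <- function(geometry, p) {
  dp <- sweep(geometry$element_positions, 2, p)
  sqrt(rowSums(dp^2))
}

mm_per_s <- 1e3  # c in m/s -> mm/s

#' Simulate one-way photoacoustic channel data
#'
#' Analytic propagation from point absorbers to the array: each element
#' records the impulse response delayed by range/c and scaled by
#' `absorbed_energy * spectrum(wavelength) / range` (spherical spreading),
#' superposed over sources, plus additive white Gaussian noise. Fractional
#' delays use band-limited interpolation so sub-voxel structure survives.
#'
#' @param sources List of `pa_source` (or a single one).
#' @param geometry An `array_geometry`.
#' @param wavelength Excitation wavelength in nm; must be present in every
#'   source's spectrum.
#' @param fs Sampling frequency, Hz (default the published 20.83 MHz).
#' @param ir An `impulse_response` (resampled to `fs` if needed).
#' @param c Speed of sound, m/s.
#' @param noise_rms RMS of additive Gaussian channel noise.
#' @param seed Integer seed making the noise reproducible.
#' @param n_samples Record length; default covers the farthest source plus
#'   the pulse duration.
#' @return An `rf_data` in PA mode.
#' @export
simulate_pa_rf <- function(sources, geometry, wavelength = 700, fs = 20.83e6,
                           ir = gaussian_pulse(geometry$center_frequency,
                                               geometry$fractional_bandwidth_rx,
                                               fs),
                           c = 1540, noise_rms = 0, seed = 0,
                           n_samples = NULL) {
  if (inherits(sources, "pa_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1)
  ir <- resample_ir(ir, fs)
  wl <- as.character(wavelength)

  ranges <- lapply(sources, function(s) element_ranges(geometry, s$position))
  if (any(unlist(ranges) == 0)) {
    stop("source coincides with an element (zero range)", call. = FALSE)
  }
  tmax <- max(unlist(ranges)) / (c * mm_per_s)
  if (is.null(n_samples)) {
    n_samples <- ceiling(tmax * fs) + length(ir$waveform) + 8L
  }
  amps <- vapply(sources, function(s) {
    if (!wl %in% names(s$spectrum)) {
      stop("wavelength ", wl, " nm absent from a source spectrum",
           call. = FALSE)
    }
    s$absorbed_energy * unname(s$spectrum[wl])
  }, numeric(1))

  data <- matrix(0, geometry$n_elements, n_samples)
  for (e in seq_len(geometry$n_elements)) {
    r <- vapply(ranges, `[`, numeric(1), e)
    delays <- r / (c * mm_per_s) * fs
    data[e, ] <- place_echoes(ir, delays, amps / r, n_samples)
  }
  if (noise_rms > 0) {
    withr::with_seed(as.integer(seed), {
      data <- data + matrix(stats::rnorm(length(data), 0, noise_rms),
                            nrow(data))
    })
  }
  rf_data(data, fs, "PA", geometry, sound_speed = c, wavelength = wavelength,
          center_frequency = ir$center_frequency)
}

resample_ir <- function(ir, fs) {
  stopifnot(inherits(ir, "impulse_response"))
  if (isTRUE(all.equal(ir$fs, fs))) return(ir)
  gaussian_pulse(ir$center_frequency, ir$fractional_bandwidth, fs)
}

#' Simulate two-way synthetic-aperture ultrasound channel data
#'
#' For each transmit event (single element) every receive element records the
#' pulse delayed by the two-way time of flight
#' `(|p_tx - p_s| + |p_s - p_rx|) / c` and scaled by
#' `echogenicity / (r_tx * r_rx)`, superposed over scatterers. An empty
#' scatterer list yields noise-only data.
#'
#' @param scatterers List of `scatterer` objects (possibly empty).
#' @param geometry An `array_geometry`.
#' @param sequence An `acq_sequence` in US mode supplying `tx_indices`.
#' @param frame_index Slow-time frame index at which trajectories are
#'   evaluated.
#' @param fs Sampling frequency, Hz.
#' @param pulse An `impulse_response` for the transmitted waveform.
#' @param c Speed of sound, m/s.
#' @param noise_rms RMS of additive Gaussian channel noise.
#' @param seed Integer noise seed (combined with `frame_index` so every
#'   frame's noise differs but reproduces).
#' @param n_samples Record length; default covers the longest two-way path.
#' @return An `rf_data` in US mode (tx-events x elements x samples).
#' @export
simulate_us_rf <- function(scatterers, geometry, sequence, frame_index = 1,
                           fs = 25e6,
                           pulse = gaussian_pulse(geometry$center_frequency,
                                                  geometry$fractional_bandwidth_rx,
                                                  fs),
                           c = 1540, noise_rms = 0, seed = 0,
                           n_samples = NULL) {
  stopifnot(inherits(sequence, "acq_sequence"))
  pulse <- resample_ir(pulse, fs)
  tx <- sequence$tx_indices
  ne <- geometry$n_elements
  pos <- lapply(scatterers, scatterer_position, frame = frame_index)
  rng <- lapply(pos, element_ranges, geometry = geometry)
  if (length(rng) && any(unlist(rng) == 0)) {
    stop("scatterer coincides with an element (zero range)", call. = FALSE)
  }
  if (is.null(n_samples)) {
    tmax <- if (length(rng)) 2 * max(unlist(rng)) / (c * mm_per_s) else
      2 * (geometry$curvature_radius + geometry$aperture_diameter / 2) /
        (c * mm_per_s)
    n_samples <- ceiling(tmax * fs) + length(pulse$waveform) + 8L
  }
  data <- array(0, dim = c(length(tx), ne, n_samples))
  ech <- vapply(scatterers, function(s) s$echogenicity, numeric(1))
  for (ti in seq_along(tx)) {
    r_tx <- vapply(rng, `[`, numeric(1), tx[ti])
    for (e in seq_len(ne)) {
      r_rx <- vapply(rng, `[`, numeric(1), e)
      if (length(r_rx)) {
        delays <- (r_tx + r_rx) / (c * mm_per_s) * fs
        data[ti, e, ] <- place_echoes(pulse, delays, ech / (r_tx * r_rx),
                                      n_samples)
      }
    }
  }
  if (noise_rms > 0) {
    withr::with_seed(as.integer(seed) + 1009L * as.integer(frame_index), {
      data <- data + array(stats::rnorm(length(data), 0, noise_rms), dim(data))
    })
  }
  rf_data(data, fs, "US", geometry, sound_speed = c, tx_indices = tx,
          center_frequency = pulse$center_frequency)
}

#' Microbubble flow phantom
#'
#' Seeds bubbles along vessel-like polyline paths and advects them at a
#' constant speed; each bubble keeps a fixed random lateral offset within the
#' vessel radius. Bubbles leaving the distal end re-enter at the start, so
#' the bubble count per frame is stationary.
#'
#' @param paths A single n x 3 matrix (mm) or a list of them: vessel
#'   centrelines.
#' @param radius Vessel radius in mm (lateral jitter bound).
#' @param speed Advection speed, mm/s (>= 0).
#' @param bubbles_per_frame Bubbles maintained per path.
#' @param frame_rate Slow-time volume rate, Hz.
#' @param n_frames Number of frames the trajectories must cover.
#' @param seed Integer seed.
#' @return List of `scatterer` objects of kind `"microbubble"` whose
#'   trajectory functions accept frame indices `1..n_frames`.
#' @examples
#' path <- cbind(seq(-2.5, 2.5, length.out = 50), 0, 0)
#' mb <- make_flow_phantom(path, 0.1, 5, 4, 215, 100, seed = 1)
#' @export
make_flow_phantom <- function(paths, radius, speed, bubbles_per_frame,
                              frame_rate, n_frames, seed = 0) {
  if (is.matrix(paths)) paths <- list(paths)
  stopifnot(length(paths) >= 1, speed >= 0, frame_rate > 0, n_frames >= 1)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  step <- speed / frame_rate  # mm per frame
  out <- list()
  withr::with_seed(as.integer(seed), {
    for (path in paths) {
      path <- as.matrix(path)
      stopifnot(ncol(path) == 3, nrow(path) >= 2)
      seg <- diff(path)
      seglen <- sqrt(rowSums(seg^2))
      if (sum(seglen) <= 0) stop("degenerate path", call. = FALSE)
      cum <- c(0, cumsum(seglen))
      L <- cum[length(cum)]
      for (b in seq_len(bubbles_per_frame)) {
        s0 <- stats::runif(1, 0, L)
        # fixed lateral offset within the vessel radius
        u <- stats::rnorm(3)
        off <- u / sqrt(sum(u^2)) * stats::runif(1, 0, radius)
        out[[length(out) + 1L]] <- scatterer(
          local({
            s0l <- s0; offl <- off; pl <- path; cuml <- cum; Ll <- L
            stl <- step
            function(frame) {
              s <- (s0l + (frame - 1) * stl) %% Ll
              k <- findInterval(s, cuml, rightmost.closed = TRUE)
              k <- min(max(k, 1L), nrow(pl) - 1L)
              w <- (s - cuml[k]) / (cuml[k + 1] - cuml[k])
              pl[k, ] + w * (pl[k + 1, ] - pl[k, ]) + offl
            }
          }),
          echogenicity = 1, kind = "microbubble")
      }
    }
  })
  out
}

#' Static tissue clutter
#'
#' `n` strong static scatterers inside a box, each performing an independent
#' sub-wavelength random walk of the given per-frame RMS; echogenicities are
#' exponentially distributed. Clutter must move much less than a wavelength
#' per frame for it to be separable by slow-time filtering, so `jitter_rms`
#' is checked against lambda/20.
#'
#' @param n Number of clutter scatterers (0 gives an empty list).
#' @param region 2 x 3 matrix: rows are the (min, max) corners of the box, mm.
#' @param echogenicity_scale Mean of the exponential echogenicity draw.
#' @param jitter_rms Per-frame RMS displacement, mm (per axis total).
#' @param seed Integer seed.
#' @param n_frames Frames the jitter tracks must cover.
#' @param wavelength_mm Acoustic wavelength used for the sub-wavelength
#'   check, mm (default 4 MHz in 1540 m/s water).
#' @return List of `scatterer` objects of kind `"clutter"`.
#' @export
make_clutter <- function(n, region, echogenicity_scale = 1, jitter_rms = 0,
                         seed = 0, n_frames = 1,
                         wavelength_mm = 1540e3 / 4e6) {
  stopifnot(n >= 0, jitter_rms >= 0)
  if (n == 0) return(list())
  region <- as.matrix(region)
  stopifnot(nrow(region) == 2, ncol(region) == 3)
  if (jitter_rms >= wavelength_mm / 20) {
    stop("jitter_rms must stay well below a wavelength (lambda/20 = ",
         signif(wavelength_mm / 20, 3), " mm)", call. = FALSE)
  }
  out <- vector("list", n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      p0 <- stats::runif(3, region[1, ], region[2, ])
      ech <- stats::rexp(1, rate = 1 / echogenicity_scale)
      if (jitter_rms > 0) {
        steps <- matrix(stats::rnorm(3 * n_frames, 0, jitter_rms / sqrt(3)),
                        ncol = 3)
        walk <- rbind(p0, t(p0 + t(apply(steps, 2, cumsum))))
        traj <- local({
          w <- walk
          function(frame) w[min(max(frame, 1L), nrow(w)), ]
        })
      } else {
        traj <- local({p <- p0; function(frame) p})
      }
      out[[i]] <- scatterer(traj, echogenicity = ech, kind = "clutter")
    }
  })
  out
}
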