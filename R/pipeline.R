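# Configuration-driven pipeline: simulate -> beamform -> so2 / ulm ->
# quantify, with per-stage seeds fanned out from one global seed and every
# artifact regenerable from (config, seed) alone.

config_schema <- "ulmpact/config/1"

#' Default pipeline configuration
#'
#' A desk-scale two-vessel demo: a reduced spherical array (48 receive
#' elements, 3 transmitters) images two parallel vessel paths carrying
#' flowing microbubbles over static clutter; photoacoustic frames at
#' 700/750 nm encode a different oxygenation in each vessel. Every
#' parameter, including all seeds, lives in this one serializable record.
#'
#' @param seed Global seed; per-stage seeds are derived from it by stable
#'   hashing of the stage name, so adding a stage never perturbs others.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    schema = config_schema,
    seed = as.integer(seed),
    geometry = list(n_elements = 48L, curvature_radius_mm = 40,
                    aperture_diameter_mm = 57, layout_seed = 0L,
                    center_frequency_hz = 4e6, fractional_bandwidth_rx = 0.75),
    sequence = list(n_tx = 3L, pri_s = 1.5504e-3, fs_us_hz = 20e6,
                    fs_pa_hz = 20.83e6, n_frames = 200L,
                    sound_speed_ms = 1540),
    grid = list(shape = c(24L, 24L, 16L), spacing_mm = 0.1),
    phantom = list(vessel_offsets_mm = c(-0.5, 0.5), vessel_axis = "x",
                   vessel_length_mm = 2.0, vessel_radius_mm = 0.05,
                   flow_speed_mms = 5, bubbles_per_vessel = 4L,
                   clutter_n = 30L, clutter_echogenicity = 2,
                   bubble_echogenicity = 1, noise_rms = 0,
                   vessel_so2 = c(0.8, 0.65), pa_sources_per_vessel = 7L),
    spectral = list(wavelengths_nm = c(700, 750), amp_threshold = 0.1,
                    conditioning = FALSE),
    ulm = list(block_size = 100L, n_remove = 8L, band_hz = c(20, 107),
               motion_threshold = 0, detect_threshold = 0.35,
               window_voxels = 5L, max_link_mm = 0.12, max_gap = 2L,
               min_length = 5L, upsample = 4L, velocity_source = "track"),
    quantify = list(smooth_sigma_mm = 0.12, threshold = 0.15,
                    min_voxels = 20L, split_axis = 2L)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the schema version and rejects unknown keys at every nesting
#' level (comparing against [default_config()]'s key set).
#'
#' @param config A list or `run_config`.
#' @return The validated `run_config`, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.null(config$schema) || !identical(config$schema, config_schema)) {
    stop("config schema version mismatch (need ", config_schema, ")",
         call. = FALSE)
  }
  check_keys <- function(got, ref, path) {
    unknown <- setdiff(names(got), names(ref))
    if (length(unknown)) {
      stop("unknown config key", if (length(unknown) > 1) "s", " at ", path,
           ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(got)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        check_keys(as.list(got[[k]]), ref[[k]], paste0(path, "$", k))
      }
    }
  }
  check_keys(config, unclass(default_config()), "config")
  if (is.null(config$seed)) stop("config must carry an explicit seed",
                                 call. = FALSE)
  class(config) <- "run_config"
  config
}

#' Write / read a pipeline configuration
#' @param config A `run_config`.
#' @param path JSON path.
#' @return The config (read) or the path (write, invisibly).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Per-stage seed derived from the global seed
#'
#' Stable string hash of the stage name mixed with the global seed; result
#' is a non-negative 31-bit integer, so adding stages never shifts the
#' seeds of existing ones.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

pipeline_stages <- c("simulate", "beamform", "so2", "ulm", "quantify")

#' Run the pipeline
#'
#' Executes the requested stages in order inside `out_dir`, writing
#' volumes, CSVs, the resolved configuration, a JSON-lines log with
#' per-stage parameters, and MD5 checksums of every artifact. Each stage
#' reads only on-disk artifacts of earlier stages, so any subset can be
#' re-run; a missing upstream artifact raises a dependency error naming
#' the stage. Re-running with the same config regenerates bit-identical
#' artifacts.
#'
#' @param config A `run_config` (validated).
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "beamform", "so2", "ulm",
#'   "quantify")`.
#' @return `out_dir`, invisibly; artifacts and `checksums.json` inside.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = pipeline_stages) {
  config <- validate_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.json"))
  logf <- file.path(out_dir, "log.jsonl")
  log_line <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = logf, append = TRUE, sep = "")
  }
  need <- function(stage, paths) {
    miss <- paths[!file.exists(paths)]
    if (length(miss)) {
      stop("stage '", stage, "' is missing upstream artifacts: ",
           paste(basename(miss), collapse = ", "),
           " (run the producing stage first)", call. = FALSE)
    }
  }
  ctx <- pipeline_context(config)

  for (st in pipeline_stages[pipeline_stages %in% stages]) {
    t0 <- Sys.time()
    switch(st,
      simulate = stage_simulate(config, ctx, out_dir),
      beamform = {
        need(st, file.path(out_dir, c("us_rf.json", "pa_w1.json",
                                      "pa_w2.json")))
        stage_beamform(config, ctx, out_dir)
      },
      so2 = {
        need(st, file.path(out_dir, c("pa_vol_w1.json", "pa_vol_w2.json")))
        stage_so2(config, ctx, out_dir)
      },
      ulm = {
        need(st, file.path(out_dir, "iq_series.json"))
        stage_ulm(config, ctx, out_dir)
      },
      quantify = {
        need(st, file.path(out_dir, c("pd.json", "so2.json",
                                      "velocity.json", "tracks.csv")))
        stage_quantify(config, ctx, out_dir)
      })
    log_line(st, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
             seed = stage_seed(config$seed, st))
  }
  write_checksums(out_dir)
  invisible(out_dir)
}

# shared derived objects (deterministic, cheap)
pipeline_context <- function(config) {
  g <- config$geometry
  geometry <- build_spherical_array(g$n_elements, g$curvature_radius_mm,
                                    g$aperture_diameter_mm, g$layout_seed,
                                    g$center_frequency_hz,
                                    g$fractional_bandwidth_rx)
  s <- config$sequence
  tx <- select_tx_subset(geometry, s$n_tx)
  seq_us <- acq_sequence(tx, s$pri_s, n_frames = s$n_frames,
                         fs = s$fs_us_hz, mode = "US")
  grid <- voxel_grid(config$grid$shape, config$grid$spacing_mm)
  ph <- config$phantom
  half <- ph$vessel_length_mm / 2
  paths <- lapply(ph$vessel_offsets_mm, function(off) {
    t <- seq(-half, half, length.out = 41)
    if (ph$vessel_axis == "x") cbind(t, off, 0) else cbind(off, t, 0)
  })
  list(geometry = geometry, seq_us = seq_us, grid = grid, paths = paths)
}

stage_simulate <- function(config, ctx, out_dir) {
  ph <- config$phantom
  s <- config$sequence
  fr <- volumetric_frame_rate(length(ctx$seq_us$tx_indices), s$pri_s)
  seed <- stage_seed(config$seed, "simulate")
  bubbles <- make_flow_phantom(ctx$paths, ph$vessel_radius_mm,
                               ph$flow_speed_mms, ph$bubbles_per_vessel,
                               fr, s$n_frames, seed = seed)
  for (i in seq_along(bubbles)) {
    bubbles[[i]]$echogenicity <- ph$bubble_echogenicity
  }
  box <- rbind(ctx$grid$origin,
               ctx$grid$origin + (ctx$grid$shape - 1) * ctx$grid$spacing)
  clutter <- make_clutter(ph$clutter_n, box, ph$clutter_echogenicity,
                          jitter_rms = 0, seed = seed + 1L)
  scat <- c(clutter, bubbles)
  # one RF container holding all slow-time frames
  frames <- vector("list", s$n_frames)
  for (f in seq_len(s$n_frames)) {
    frames[[f]] <- simulate_us_rf(scat, ctx$geometry, ctx$seq_us,
                                  frame_index = f, fs = s$fs_us_hz,
                                  c = s$sound_speed_ms,
                                  noise_rms = ph$noise_rms,
                                  seed = seed, n_samples = us_record_len(ctx, s))
  }
  write_rf_series(frames, file.path(out_dir, "us_rf"))

  # PA: point absorbers along each vessel with the configured oxygenation
  tbl <- read_extinction_table()
  wl <- config$spectral$wavelengths_nm
  sources <- list()
  for (v in seq_along(ctx$paths)) {
    so2 <- ph$vessel_so2[v]
    E <- extinction_matrix(tbl, wl[1], wl[2])
    spec <- stats::setNames(as.numeric(E %*% c(so2, 1 - so2)),
                            as.character(wl))
    idx <- round(seq(1, nrow(ctx$paths[[v]]),
                     length.out = ph$pa_sources_per_vessel))
    for (i in idx) {
      sources[[length(sources) + 1L]] <-
        pa_source(ctx$paths[[v]][i, ], absorbed_energy = 1, spectrum = spec)
    }
  }
  for (k in 1:2) {
    rf <- simulate_pa_rf(sources, ctx$geometry, wavelength = wl[k],
                         fs = s$fs_pa_hz, c = s$sound_speed_ms,
                         noise_rms = ph$noise_rms, seed = seed + 10L + k)
    write_rf(rf, file.path(out_dir, paste0("pa_w", k)))
  }
}

us_record_len <- function(ctx, s) {
  rmax <- ctx$geometry$curvature_radius + max(abs(ctx$grid$origin)) + 2
  ceiling(2 * rmax / (s$sound_speed_ms * 1e3) * s$fs_us_hz) + 220L
}

stage_beamform <- function(config, ctx, out_dir) {
  s <- config$sequence
  frames <- read_rf_series(file.path(out_dir, "us_rf"))
  op <- build_sparse_das(ctx$geometry, ctx$seq_us, ctx$grid,
                         c = s$sound_speed_ms,
                         n_samples = dim(frames[[1]]$data)[3])
  nf <- length(frames)
  iq <- array(0i, dim = c(ctx$grid$shape, nf))
  for (f in seq_len(nf)) {
    iq[, , , f] <- apply_sparse_das(op, frames[[f]])$data
  }
  fr <- volumetric_frame_rate(length(ctx$seq_us$tx_indices), s$pri_s)
  series <- iq_series(iq, ctx$grid, fr)
  write_iq_series(series, file.path(out_dir, "iq_series"))
  write_volume(frame_volume(series, 1), file.path(out_dir, "bmode"))
  for (k in 1:2) {
    rf <- read_rf(file.path(out_dir, paste0("pa_w", k)))
    if (isTRUE(config$spectral$conditioning)) {
      ir <- gaussian_pulse(ctx$geometry$center_frequency,
                           ctx$geometry$fractional_bandwidth_rx, rf$fs)
      rf <- lowpass_rf(deconvolve_rf(rf, ir), 1e6)
    }
    vol <- das_pa(rf, ctx$grid, c = s$sound_speed_ms, envelope = TRUE)
    write_volume(vol, file.path(out_dir, paste0("pa_vol_w", k)))
  }
}

stage_so2 <- function(config, ctx, out_dir) {
  v1 <- read_volume(file.path(out_dir, "pa_vol_w1"))
  v2 <- read_volume(file.path(out_dir, "pa_vol_w2"))
  v1$wavelength <- config$spectral$wavelengths_nm[1]
  v2$wavelength <- config$spectral$wavelengths_nm[2]
  so2 <- unmix_so2(v1, v2, read_extinction_table(),
                   amp_threshold = config$spectral$amp_threshold)
  write_volume(so2, file.path(out_dir, "so2"))
}

stage_ulm <- function(config, ctx, out_dir) {
  u <- config$ulm
  series <- read_iq_series(file.path(out_dir, "iq_series"))
  if (u$motion_threshold > 0) {
    series <- filter_frames(series, reject_motion(series,
                                                  u$motion_threshold))
  }
  filt <- svd_filter(series, u$block_size, u$n_remove)
  filt <- temporal_bandpass(filt, u$band_hz)
  write_volume(power_doppler(filt), file.path(out_dir, "pd"))
  locs <- lapply(seq_len(n_frames(filt)), function(f) {
    localize_radial_symmetry(frame_volume(filt, f), u$detect_threshold,
                             u$window_voxels)
  })
  tracks <- track_bubbles(locs, filt$frame_rate, max_link = u$max_link_mm,
                          max_gap = u$max_gap, min_length = u$min_length)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  maps <- render_maps(tracks, filt$grid, upsample = u$upsample,
                      speed_source = u$velocity_source)
  write_volume(maps$density, file.path(out_dir, "density"))
  write_volume(maps$velocity, file.path(out_dir, "velocity"))
}

stage_quantify <- function(config, ctx, out_dir) {
  q <- config$quantify
  pd <- read_volume(file.path(out_dir, "pd"))
  so2 <- read_volume(file.path(out_dir, "so2"))
  vel <- read_volume(file.path(out_dir, "velocity"))
  vessels <- segment_vessels(pd, q$smooth_sigma_mm, q$threshold,
                             q$min_voxels)
  vessels <- split_hemispheres(vessels, axis = q$split_axis)
  vessels <- extract_vessel_functions(vessels, so2, vel)
  write_vessels(vessels, file.path(out_dir, "vessels.csv"))
  if (nrow(vessels) >= 2 &&
      dplyr::n_distinct(vessels$hemisphere) == 2) {
    gs <- vessel_group_stats(vessels)
    readr::write_csv(gs, file.path(out_dir, "group_stats.csv"))
  }
}

write_checksums <- function(out_dir) {
  files <- setdiff(list.files(out_dir),
                   c("log.jsonl", "checksums.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  jsonlite::write_json(as.list(sums), file.path(out_dir, "checksums.json"),
                       auto_unbox = TRUE)
}

# IQ series container: interleaved float32 re/im + JSON sidecar
#' Write / read an IQ series
#' @param series An `iq_series`.
#' @param stem Path stem.
#' @return The stem (write, invisibly) or the `iq_series` (read).
#' @export
write_iq_series <- function(series, stem) {
  stopifnot(inherits(series, "iq_series"))
  g <- series$grid
  meta <- list(schema = "ulmpact/iq/1", shape = g$shape,
               spacing_mm = g$spacing, origin_mm = g$origin,
               n_frames = n_frames(series), frame_rate_hz = series$frame_rate)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- as.vector(rbind(Re(as.vector(series$data)),
                          Im(as.vector(series$data))))
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 4, endian = "little")
  invisible(stem)
}

#' @rdname write_iq_series
#' @export
read_iq_series <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "ulmpact/iq/1")) {
    stop("IQ container schema version mismatch", call. = FALSE)
  }
  n <- prod(meta$shape) * meta$n_frames
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, numeric(), n = 2 * n, size = 4, endian = "little")
  z <- complex(real = flat[c(TRUE, FALSE)], imaginary = flat[c(FALSE, TRUE)])
  iq_series(array(z, dim = c(meta$shape, meta$n_frames)),
            voxel_grid(meta$shape, meta$spacing_mm, meta$origin_mm),
            meta$frame_rate_hz)
}

# RF series: stack of same-shape US frames in one binary
write_rf_series <- function(frames, stem) {
  meta0 <- frames[[1]]
  dims <- dim(meta0$data)
  meta <- list(schema = "ulmpact/rfseries/1", n_frames = length(frames),
               dims = dims, fs_hz = meta0$fs,
               sound_speed_ms = meta0$sound_speed,
               center_frequency_hz = meta0$center_frequency,
               tx_indices = meta0$tx_indices,
               geometry = list(
                 n_elements = meta0$geometry$n_elements,
                 curvature_radius_mm = meta0$geometry$curvature_radius,
                 aperture_diameter_mm = meta0$geometry$aperture_diameter,
                 center_frequency_hz = meta0$geometry$center_frequency,
                 fractional_bandwidth_rx =
                   meta0$geometry$fractional_bandwidth_rx,
                 layout_seed = meta0$geometry$layout_seed))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  for (f in frames) {
    writeBin(as.numeric(aperm(f$data, c(3, 2, 1))), con, size = 4,
             endian = "little")
  }
  invisible(stem)
}

read_rf_series <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "ulmpact/rfseries/1")) {
    stop("RF series schema version mismatch", call. = FALSE)
  }
  g <- meta$geometry
  geometry <- build_spherical_array(g$n_elements, g$curvature_radius_mm,
                                    g$aperture_diameter_mm, g$layout_seed,
                                    g$center_frequency_hz,
                                    g$fractional_bandwidth_rx)
  dims <- as.integer(meta$dims)
  per <- prod(dims)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  lapply(seq_len(meta$n_frames), function(f) {
    flat <- readBin(con, numeric(), n = per, size = 4, endian = "little")
    rf_data(aperm(array(flat, dim = rev(dims)), c(3, 2, 1)), meta$fs_hz,
            "US", geometry, sound_speed = meta$sound_speed_ms,
            tx_indices = meta$tx_indices,
            center_frequency = meta$center_frequency_hz)
  })
}
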