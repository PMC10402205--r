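# brute-force reference beamformers: plain loops, no vectorisation, kept
# deliberately independent of the implementation under test
naive_das_pa <- function(rf, p_vox, c = 1540) {
  acc <- 0
  for (e in seq_len(rf$geometry$n_elements)) {
    r <- sqrt(sum((p_vox - rf$geometry$element_positions[e, ])^2))
    tau <- r / (c * 1e3) * rf$fs + 1
    i0 <- floor(tau); w <- tau - i0
    v <- 0
    if (i0 >= 1 && i0 <= ncol(rf$data)) v <- v + (1 - w) * rf$data[e, i0]
    if (i0 + 1 >= 1 && i0 + 1 <= ncol(rf$data)) {
      v <- v + w * rf$data[e, i0 + 1]
    }
    acc <- acc + v
  }
  acc / rf$geometry$n_elements
}

naive_das_us <- function(rf, p_vox, c = 1540) {
  acc <- 0 + 0i
  ne <- rf$geometry$n_elements
  for (ti in seq_along(rf$tx_indices)) {
    r_tx <- sqrt(sum((p_vox -
                        rf$geometry$element_positions[rf$tx_indices[ti], ])^2))
    for (e in seq_len(ne)) {
      an <- ulmpact:::analytic_columns(matrix(rf$data[ti, e, ], ncol = 1))[, 1]
      r_rx <- sqrt(sum((p_vox - rf$geometry$element_positions[e, ])^2))
      tau <- (r_tx + r_rx) / (c * 1e3) * rf$fs + 1
      i0 <- floor(tau); w <- tau - i0
      v <- 0 + 0i
      if (i0 >= 1 && i0 <= length(an)) v <- v + (1 - w) * an[i0]
      if (i0 + 1 >= 1 && i0 + 1 <= length(an)) v <- v + w * an[i0 + 1]
      acc <- acc + v
    }
  }
  acc / (length(rf$tx_indices) * ne)
}

test_that("PA delay-and-sum focuses a focal point source", {
  g <- geom64()
  rf <- simulate_pa_rf(pa_source(c(0, 0, 0)), g, 700, fs = 20.83e6)
  grid <- voxel_grid(c(21, 21, 15), 0.1)
  vol <- das_pa(rf, grid, envelope = TRUE)
  pk <- which(vol$data == max(vol$data), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(11, 11, 8))
  expect_equal(vol$extra$truncation_fraction, 0)
})

test_that("PA DAS equals the naive triple-loop oracle", {
  g <- geom64()
  rf <- simulate_pa_rf(pa_source(c(0, 0, 0)), g, 700, fs = 20.83e6)
  grid <- voxel_grid(c(5, 5, 5), 0.1)
  vol <- das_pa(rf, grid)
  co <- grid_coords(grid)
  for (k in c(1, 32, 63, 125)) {
    expect_equal(vol$data[k], naive_das_pa(rf, co[k, ]), tolerance = 1e-9)
  }
})

test_that("two PA sources keep their amplitude ratio after reconstruction", {
  g <- geom64()
  srcs <- list(pa_source(c(-1.5, 0, 0), 1), pa_source(c(1.5, 0, 0), 2))
  rf <- simulate_pa_rf(srcs, g, 700, fs = 20.83e6)
  grid <- voxel_grid(c(61, 7, 7), 0.06)
  vol <- das_pa(rf, grid, envelope = TRUE)
  a1 <- max(vol$data[1:30, , ])
  a2 <- max(vol$data[32:61, , ])
  expect_lt(abs(a2 / a1 - 2), 0.1)
})

test_that("DAS is linear in the RF data", {
  g <- geom64()
  rf1 <- simulate_pa_rf(pa_source(c(0, 0, 0.4)), g, 700, fs = 20.83e6)
  rf2 <- simulate_pa_rf(pa_source(c(0.4, 0, -0.2), 2), g, 700,
                        fs = 20.83e6, n_samples = ncol(rf1$data))
  grid <- voxel_grid(c(9, 9, 9), 0.1)
  v1 <- das_pa(rf1, grid)
  v2 <- das_pa(rf2, grid)
  rf12 <- rf1
  rf12$data <- rf1$data + rf2$data
  v12 <- das_pa(rf12, grid)
  expect_lt(max(abs(v12$data - v1$data - v2$data)) / max(abs(v12$data)),
            1e-9)
})

test_that("point sources land within one voxel across the focal zone", {
  g <- geom64()
  grid <- voxel_grid(c(17, 17, 17), 0.25)  # 4 mm cube around the focus
  for (p in list(c(0, 0, 0), c(1.2, -0.9, 0.7), c(-1.5, 1.5, -1.2))) {
    rf <- simulate_pa_rf(pa_source(p), g, 700, fs = 20.83e6)
    vol <- das_pa(rf, grid, envelope = TRUE)
    pk <- which(vol$data == max(vol$data), arr.ind = TRUE)[1, ]
    mm <- grid$origin + (pk - 1) * grid$spacing
    expect_lt(max(abs(mm - p)), 0.25 + 1e-9)
  }
})

test_that("US DAS focuses and matches its naive loop oracle", {
  g <- geom64()
  sq <- acq_sequence(select_tx_subset(g, 4), 150e-6, fs = 20e6, mode = "US")
  rf <- simulate_us_rf(list(scatterer(c(0, 0, 0))), g, sq, 1, fs = 20e6)
  grid <- voxel_grid(c(15, 15, 11), 0.1)
  vol <- das_us(rf, grid)
  pk <- which(Mod(vol$data) == max(Mod(vol$data)), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(8, 8, 6))
  co <- grid_coords(grid)
  for (k in c(1, 800, 1600)) {
    expect_equal(vol$data[k], naive_das_us(rf, co[k, ]), tolerance = 1e-9)
  }
})

test_that("IQ phase tracks a 30 um axial displacement", {
  g <- geom64()
  sq <- acq_sequence(select_tx_subset(g, 4), 150e-6, fs = 20e6, mode = "US")
  grid <- voxel_grid(c(5, 5, 5), 0.1)
  rf1 <- simulate_us_rf(list(scatterer(c(0, 0, 0))), g, sq, 1, fs = 20e6)
  rf2 <- simulate_us_rf(list(scatterer(c(0, 0, 0.03))), g, sq, 1,
                        fs = 20e6, n_samples = dim(rf1$data)[3])
  v1 <- das_us(rf1, grid); v2 <- das_us(rf2, grid)
  dphi <- Arg(v2$data[3, 3, 3] / v1$data[3, 3, 3])
  # oracle: carrier times the mean two-way path change over all pairs
  dpath <- 0; cnt <- 0
  for (ti in sq$tx_indices) for (e in seq_len(g$n_elements)) {
    p0 <- sqrt(sum(g$element_positions[ti, ]^2)) +
      sqrt(sum(g$element_positions[e, ]^2))
    p1 <- sqrt(sum((g$element_positions[ti, ] - c(0, 0, 0.03))^2)) +
      sqrt(sum((g$element_positions[e, ] - c(0, 0, 0.03))^2))
    dpath <- dpath + (p1 - p0); cnt <- cnt + 1
  }
  # a longer round trip retards the carrier, so the phase drops by
  # 2*pi*fc*dpath/c
  expected <- -2 * pi * 4e6 * (dpath / cnt) / 1540e3
  expect_lt(abs(dphi - expected) / abs(expected), 0.05)
})

test_that("sparse operator reproduces direct DAS in both modes", {
  g <- geom64()
  # PA
  rf <- simulate_pa_rf(list(pa_source(c(0, 0, 0)),
                            pa_source(c(0.5, -0.4, 0.3), 2)),
                       g, 700, fs = 20.83e6)
  grid <- voxel_grid(c(13, 13, 9), 0.1)
  sq_pa <- acq_sequence(1L, 1 / 10, fs = 20.83e6, mode = "PA")
  op <- build_sparse_das(g, sq_pa, grid, n_samples = ncol(rf$data))
  v_direct <- das_pa(rf, grid)
  v_op <- apply_sparse_das(op, rf)
  expect_lt(max(abs(v_op$data - v_direct$data)) / max(abs(v_direct$data)),
            1e-6)
  # zero RF maps to a zero volume
  rf0 <- rf; rf0$data[] <- 0
  expect_true(all(apply_sparse_das(op, rf0)$data == 0))
  # row weights for the focus voxel sum to the normalized element count
  foc <- which(rowSums(abs(grid_coords(grid))) == 0)
  expect_equal(sum(op$W[foc, ]), 1)  # 64 pairs * (w + (1-w)) / 64
  # US
  sq <- acq_sequence(select_tx_subset(g, 3), 150e-6, fs = 20e6, mode = "US")
  rfu <- simulate_us_rf(list(scatterer(c(0.3, 0.2, -0.1))), g, sq, 1,
                        fs = 20e6)
  opu <- build_sparse_das(g, sq, grid, n_samples = dim(rfu$data)[3])
  vu <- das_us(rfu, grid)
  vu_op <- apply_sparse_das(opu, rfu)
  expect_lt(max(Mod(vu_op$data - vu$data)) / max(Mod(vu$data)), 1e-6)
})

test_that("sparse operator refuses to exceed its memory cap", {
  g <- geom256()
  sq <- acq_sequence(select_tx_subset(g, 31), 150e-6, fs = 20e6, mode = "US")
  grid <- voxel_grid(c(100, 100, 100), 0.06)
  expect_error(build_sparse_das(g, sq, grid, n_samples = 2000,
                                memory_cap_bytes = 1e6),
               "cap")
})

test_that("Wiener deconvolution sharpens and is bounded", {
  ir <- gaussian_pulse(4e6, 0.75, 20.83e6)
  g <- geom64()
  rf <- simulate_pa_rf(pa_source(c(0, 0, 0)), g, 700, fs = 20.83e6)
  out <- deconvolve_rf(rf, ir, noise_floor = 1e-3)
  # peak stays at the arrival time, -6 dB envelope width at most halves
  w_in <- sum(channel_envelope(rf$data[1, ]) >
                max(channel_envelope(rf$data[1, ])) / 2)
  env_out <- channel_envelope(out$data[1, ])
  w_out <- sum(env_out > max(env_out) / 2)
  expect_lte(w_out, ceiling(w_in / 2))
  expect_lt(abs(which.max(env_out) -
                  which.max(channel_envelope(rf$data[1, ]))), 2)
  # enormous regularisation drives the output toward zero
  out_inf <- deconvolve_rf(rf, ir, noise_floor = 1e12)
  expect_lt(max(abs(out_inf$data)), 1e-9 * max(abs(rf$data)))
  # white noise is amplified at most by 1/noise_floor in power
  set.seed(1)
  rfn <- rf; rfn$data <- matrix(rnorm(length(rf$data)), nrow(rf$data))
  nf <- 1e-2
  outn <- deconvolve_rf(rfn, ir, noise_floor = nf)
  expect_lt(sum(outn$data^2) / sum(rfn$data^2), 1 / nf)
  expect_error(deconvolve_rf(rf, ir, 0), "noise_floor")
})

test_that("zero-phase low-pass has the designed band edges", {
  g <- geom64()
  fs <- 20.83e6
  n <- 2048
  mk <- function(f) {
    d <- matrix(rep(cos(2 * pi * f * (0:(n - 1)) / fs), each = 64), 64)
    rf_data(d, fs, "PA", g)
  }
  # 0.2 MHz tone passes within 2%
  out <- lowpass_rf(mk(0.2e6), 1e6)
  mid <- 500:1500
  expect_lt(abs(stats::sd(out$data[1, mid]) /
                  stats::sd(mk(0.2e6)$data[1, mid]) - 1), 0.02)
  # 4 MHz tone attenuated at least 40 dB
  out4 <- lowpass_rf(mk(4e6), 1e6)
  expect_lt(stats::sd(out4$data[1, mid]) / stats::sd(mk(4e6)$data[1, mid]),
            10^(-40 / 20))
  # DC passes unchanged (away from the filtfilt edge transients)
  dc <- mk(0); dc$data[] <- 1
  expect_equal(lowpass_rf(dc, 1e6)$data[, mid], dc$data[, mid],
               tolerance = 1e-3)
  expect_error(lowpass_rf(mk(1e6), 11e6), "Nyquist")
})

test_that("stitching reproduces the scan-grid arithmetic", {
  sp <- 0.1
  base <- voxel_grid(c(81, 81, 81), sp)  # 8 mm cube
  mkvol <- function(val) ulm_volume(array(val, base$shape), base, "PA")
  grid <- scan_grid(3, 2, 3, c(8, 8, 8))
  vols <- replicate(6, mkvol(1), simplify = FALSE)
  out <- stitch(vols, grid$positions, blend = "max")
  extent <- out$grid$shape * sp
  expect_equal(unname(round(extent - sp, 6)), c(14, 11, 8))
  # single volume is the identity
  one <- stitch(list(mkvol(3)), matrix(c(0, 0), 1))
  expect_equal(one$data, mkvol(3)$data)
  # mean blend of identical constants is constant
  two <- stitch(list(mkvol(2), mkvol(2)), rbind(c(0, 0), c(3, 0)),
                blend = "mean")
  expect_true(all(two$data == 2))
  expect_error(stitch(list(mkvol(1), mkvol(1)), rbind(c(0, 0), c(0.05, 0))),
               "lattice")
})

test_that("the simulated point target reproduces the diffraction-scale resolution", {
  # full published parameter set: 4 MHz, 75% Rx bandwidth, 40 mm ROC,
  # 57 mm aperture, c = 1540 m/s, 60 um voxels
  res <- psf_resolution(grid = voxel_grid(c(61, 9, 41), 0.06))
  expect_lt(abs(res$lateral_fwhm_um - 260) / 260, 0.2)
})
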