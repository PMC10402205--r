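test_that("gaussian pulse has the requested spectral geometry", {
  ir <- gaussian_pulse(4e6, 0.75, 62.5e6)
  n <- 8192
  S <- Mod(stats::fft(c(ir$waveform, numeric(n - length(ir$waveform)))))
  S <- S[1:(n / 2)]
  f <- (0:(n / 2 - 1)) / n * 62.5e6
  pk <- which.max(S)
  expect_lt(abs(f[pk] - 4e6) / 4e6, 0.02)
  # -6 dB (half amplitude) width measured by FFT equals bw*fc within 2%
  above <- which(S > S[pk] / 2)
  width <- f[max(above)] - f[min(above)]
  expect_lt(abs(width - 0.75 * 4e6) / (0.75 * 4e6), 0.02)
  # band roughly [2.5, 5.5] MHz
  expect_lt(abs(f[min(above)] - 2.5e6), 0.2e6)
  expect_lt(abs(f[max(above)] - 5.5e6), 0.2e6)
  expect_error(gaussian_pulse(4e6, 0.75, 10e6), "undersampled")
  expect_error(gaussian_pulse(4e6, 2.5, 62.5e6), "fractional_bw")
})

test_that("focal PA source arrives simultaneously on every element", {
  g <- geom64()
  rf <- simulate_pa_rf(pa_source(c(0, 0, 0)), g, 700, fs = 20.83e6)
  peaks <- apply(rf$data, 1, function(ch) which.max(channel_envelope(ch)))
  expect_equal(unname(peaks), rep(round(40 / 1540e3 * 20.83e6) + 1, 64))
  amps <- apply(rf$data, 1, function(ch) max(channel_envelope(ch)))
  expect_lt(diff(range(amps)) / mean(amps), 1e-6)
})

test_that("per-element PA arrival times match the distance oracle", {
  g <- geom64()
  src <- c(0, 0, 1)
  rf <- simulate_pa_rf(pa_source(src), g, 700, fs = 20.83e6)
  for (e in c(1, 17, 40, 64)) {
    r <- sqrt(sum((src - g$element_positions[e, ])^2))
    expected <- r / 1540e3 * 20.83e6 + 1
    got <- which.max(channel_envelope(rf$data[e, ]))
    expect_lt(abs(got - expected), 1)
  }
})

test_that("PA amplitudes scale linearly with the optical spectrum", {
  g <- geom64()
  src <- pa_source(c(0.5, -0.3, 0.2), spectrum = c("700" = 2, "750" = 1))
  rf700 <- simulate_pa_rf(src, g, 700, fs = 20.83e6)
  rf750 <- simulate_pa_rf(src, g, 750, fs = 20.83e6)
  expect_equal(rf700$data, 2 * rf750$data, tolerance = 1e-6)
})

test_that("the simulator is linear and errors on zero range", {
  g <- geom64()
  a <- pa_source(c(0, 0, 0.5)); b <- pa_source(c(0.5, 0, -0.5), 2)
  rf_ab <- simulate_pa_rf(list(a, b), g, 700, fs = 20.83e6)
  n <- ncol(rf_ab$data)
  rf_a <- simulate_pa_rf(a, g, 700, fs = 20.83e6, n_samples = n)
  rf_b <- simulate_pa_rf(b, g, 700, fs = 20.83e6, n_samples = n)
  expect_lt(max(abs(rf_ab$data - rf_a$data - rf_b$data)) /
              max(abs(rf_ab$data)), 1e-9)
  expect_error(
    simulate_pa_rf(pa_source(g$element_positions[1, ]), g, 700,
                   fs = 20.83e6),
    "zero range")
})

test_that("channel noise is reproducible by seed", {
  g <- geom64()
  s <- pa_source(c(0, 0, 0))
  r1 <- simulate_pa_rf(s, g, 700, fs = 20.83e6, noise_rms = 0.1, seed = 3)
  r2 <- simulate_pa_rf(s, g, 700, fs = 20.83e6, noise_rms = 0.1, seed = 3)
  r3 <- simulate_pa_rf(s, g, 700, fs = 20.83e6, noise_rms = 0.1, seed = 4)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
})

test_that("pulse-echo timing through the focus is exact", {
  g <- geom64()
  pole <- which.min(sqrt(rowSums(g$element_positions[, 1:2]^2)))
  sq <- acq_sequence(pole, 150e-6, fs = 20e6, mode = "US")
  rf <- simulate_us_rf(list(scatterer(c(0, 0, 0))), g, sq, 1, fs = 20e6)
  r <- sqrt(sum(g$element_positions[pole, ]^2))
  got <- which.max(channel_envelope(rf$data[1, pole, ]))
  expect_lt(abs(got - (2 * r / 1540e3 * 20e6 + 1)), 1)
})

test_that("every tx-rx pair's echo matches the path-length oracle", {
  g <- geom64()
  tx <- select_tx_subset(g, 5)
  sq <- acq_sequence(tx, 150e-6, fs = 20e6, mode = "US")
  p <- c(0.4, -0.2, 0.3)
  rf <- simulate_us_rf(list(scatterer(p)), g, sq, 1, fs = 20e6)
  for (ti in seq_along(tx)) for (e in c(3, 31, 62)) {
    path <- sqrt(sum((g$element_positions[tx[ti], ] - p)^2)) +
      sqrt(sum((g$element_positions[e, ] - p)^2))
    got <- which.max(channel_envelope(rf$data[ti, e, ]))
    expect_lt(abs(got - (path / 1540e3 * 20e6 + 1)), 1)
  }
})

test_that("sub-sample displacement shows up as the oracle's delay change", {
  g <- geom64()
  tx <- select_tx_subset(g, 3)
  sq <- acq_sequence(tx, 150e-6, fs = 20e6, mode = "US")
  dz <- 0.025  # 25 um between frames
  rf1 <- simulate_us_rf(list(scatterer(c(0, 0, 0))), g, sq, 1, fs = 20e6)
  rf2 <- simulate_us_rf(list(scatterer(c(0, 0, dz))), g, sq, 1, fs = 20e6,
                        n_samples = dim(rf1$data)[3])
  for (ti in 1:3) for (e in c(10, 50)) {
    p0 <- sqrt(sum((g$element_positions[tx[ti], ])^2)) +
      sqrt(sum((g$element_positions[e, ])^2))
    p1 <- sqrt(sum((g$element_positions[tx[ti], ] - c(0, 0, dz))^2)) +
      sqrt(sum((g$element_positions[e, ] - c(0, 0, dz))^2))
    expected_lag <- (p1 - p0) / 1540e3 * 20e6
    got <- xcorr_lag(rf1$data[ti, e, ], rf2$data[ti, e, ])
    expect_lt(abs(got - expected_lag), 0.5)
  }
})

test_that("swapping tx and rx elements leaves the echo time unchanged", {
  g <- geom64()
  p <- c(0.6, 0.1, -0.4)
  sq_ab <- acq_sequence(c(5L), 150e-6, fs = 20e6, mode = "US")
  sq_ba <- acq_sequence(c(33L), 150e-6, fs = 20e6, mode = "US")
  rf_ab <- simulate_us_rf(list(scatterer(p)), g, sq_ab, 1, fs = 20e6)
  rf_ba <- simulate_us_rf(list(scatterer(p)), g, sq_ba, 1, fs = 20e6,
                          n_samples = dim(rf_ab$data)[3])
  t_ab <- which.max(channel_envelope(rf_ab$data[1, 33, ]))
  t_ba <- which.max(channel_envelope(rf_ba$data[1, 5, ]))
  expect_equal(t_ab, t_ba)
})

test_that("empty scatterer lists give noise-only data, zero range errors", {
  g <- geom64()
  sq <- acq_sequence(1:2, 150e-6, fs = 20e6, mode = "US")
  rf0 <- simulate_us_rf(list(), g, sq, 1, fs = 20e6, noise_rms = 0)
  expect_true(all(rf0$data == 0))
  rfn <- simulate_us_rf(list(), g, sq, 1, fs = 20e6, noise_rms = 0.5,
                        seed = 2)
  expect_gt(stats::sd(rfn$data), 0.4)
  expect_error(
    simulate_us_rf(list(scatterer(g$element_positions[2, ])), g, sq, 1,
                   fs = 20e6),
    "zero range")
})

test_that("flow phantom advects bubbles at the configured speed", {
  path <- cbind(seq(-2.5, 2.5, length.out = 51), 0, 0)
  mb <- make_flow_phantom(path, radius = 0.1, speed = 5,
                          bubbles_per_frame = 6, frame_rate = 215,
                          n_frames = 100, seed = 7)
  expect_length(mb, 6)
  # per-frame step 5/215 mm = 23.26 um along the path
  steps <- vapply(mb, function(b) {
    p1 <- ulmpact:::scatterer_position(b, 10)
    p2 <- ulmpact:::scatterer_position(b, 11)
    sqrt(sum((p2 - p1)^2))
  }, numeric(1))
  # wrap-around re-entry makes one step long occasionally; check the median
  expect_lt(abs(stats::median(steps) - 5 / 215), 1e-9)
  # Monte-Carlo mean displacement over 100 frames (excluding wrap jumps)
  disp <- unlist(lapply(mb, function(b) {
    p <- t(vapply(1:100, function(f) ulmpact:::scatterer_position(b, f),
                  numeric(3)))
    d <- sqrt(rowSums(diff(p)^2))
    d[d < 1]  # drop re-entry jumps
  }))
  expect_lt(abs(mean(disp) - 5 / 215) / (5 / 215), 0.01)
  # zero speed freezes all trajectories
  mb0 <- make_flow_phantom(path, 0.1, 0, 3, 215, 10, seed = 1)
  for (b in mb0) {
    expect_equal(ulmpact:::scatterer_position(b, 1),
                 ulmpact:::scatterer_position(b, 10))
  }
  expect_error(make_flow_phantom(path, -0.1, 5, 3, 215, 10), "radius")
})

test_that("clutter is static without jitter and walks at the given rms", {
  box <- rbind(c(-1, -1, -1), c(1, 1, 1))
  cl <- make_clutter(100, box, 1, jitter_rms = 0, seed = 5, n_frames = 10)
  expect_length(cl, 100)
  for (s in cl[1:10]) {
    expect_identical(ulmpact:::scatterer_position(s, 1),
                     ulmpact:::scatterer_position(s, 10))
  }
  clj <- make_clutter(200, box, 1, jitter_rms = 1e-3, seed = 5,
                      n_frames = 40)
  st <- unlist(lapply(clj, function(s) {
    p <- t(vapply(1:40, function(f) ulmpact:::scatterer_position(s, f),
                  numeric(3)))
    sqrt(rowSums(diff(p)^2))
  }))
  expect_lt(abs(sqrt(mean(st^2)) - 1e-3) / 1e-3, 0.1)
  expect_identical(make_clutter(0, box, 1, 0, 1), list())
  expect_error(make_clutter(5, box, 1, jitter_rms = 0.05, seed = 1),
               "wavelength")
})
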