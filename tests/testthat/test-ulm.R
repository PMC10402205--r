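test_that("motion gating keeps identical frames and flags shifted ones", {
  grid <- voxel_grid(c(12, 12, 8), 0.1)
  base <- paint_blob(c(0, 0, 0), grid, 2)
  arr <- array(rep(base, 20), c(grid$shape, 20))
  shifted <- paint_blob(c(0.6, 0, 0), grid, 2)
  bad <- c(3L, 9L, 15L)
  for (f in bad) arr[, , , f] <- shifted
  ser <- iq_series(arr, grid, 215)
  keep <- reject_motion(ser, 0.99)
  expect_identical(which(!keep), bad)
  # threshold 0 keeps everything; identical frames all pass
  expect_true(all(reject_motion(ser, 0)))
  same <- iq_series(array(rep(base, 5), c(grid$shape, 5)), grid, 215)
  expect_true(all(reject_motion(same, 0.99)))
  all_same_dropped <- iq_series(arr[, , , bad], grid, 215)
  expect_error(reject_motion(iq_series(array(rep(base, 3) *
                                               rep(c(1, 0, 1), each =
                                                     prod(grid$shape)),
                                             c(grid$shape, 3)), grid, 215),
                             1.1),
               "rejected")
})

test_that("SVD filter is the identity at zero removal and kills full rank", {
  grid <- voxel_grid(c(6, 6, 4), 0.1)
  set.seed(2)
  arr <- array(complex(real = rnorm(prod(grid$shape) * 10),
                       imaginary = rnorm(prod(grid$shape) * 10)),
               c(grid$shape, 10))
  ser <- iq_series(arr, grid, 215)
  expect_lt(max(Mod(svd_filter(ser, 10, 0)$data - arr)), 1e-9)
  expect_error(svd_filter(ser, 10, 10), "n_remove")
  expect_lt(max(Mod(svd_filter(ser, 10, 9)$data)) / max(Mod(arr)), 1)
})

test_that("SVD filter suppresses rank-1 clutter and keeps the moving bubble", {
  grid <- voxel_grid(c(24, 24, 12), 0.1)
  nf <- 40
  clutter <- 10 * paint_blob(c(0.4, 0.4, 0), grid, 3)
  arr <- array(0 + 0i, c(grid$shape, nf))
  for (f in 1:nf) {
    arr[, , , f] <- clutter +
      paint_blob(c(-1 + f * 0.05, -0.6, 0), grid, 1.2)
  }
  ser <- iq_series(arr, grid, 215)
  filt <- svd_filter(ser, block_size = nf, n_remove = 1)
  cmask <- array(clutter > 0.5 * max(clutter), dim(arr)[1:3])
  sel <- array(cmask, dim(arr))
  expect_lt(sum(Mod(filt$data[sel])^2) / sum(Mod(arr[sel])^2), 0.01)
  # bubble peak at mid-frame survives at >= 50%
  expect_gt(max(Mod(filt$data[, , , 20])), 0.5)
  # energy never grows, and equality holds only for n_remove = 0
  expect_lt(sum(Mod(filt$data)^2), sum(Mod(arr)^2))
  expect_equal(sum(Mod(svd_filter(ser, nf, 0)$data)^2), sum(Mod(arr)^2),
               tolerance = 1e-9)
})

test_that("partial final SVD blocks scale the cutoff proportionally", {
  grid <- voxel_grid(c(4, 4, 2), 0.1)
  nf <- 25  # one full block of 20 + partial block of 5
  set.seed(3)
  arr <- array(complex(real = rnorm(prod(grid$shape) * nf),
                       imaginary = rnorm(prod(grid$shape) * nf)),
               c(grid$shape, nf))
  ser <- iq_series(arr, grid, 215)
  filt <- svd_filter(ser, block_size = 20, n_remove = 4)
  # partial block keeps 4 * 5 / 20 = 1 removed component: rank drop by 1
  M <- matrix(filt$data[, , , 21:25], ncol = 5)
  expect_equal(sum(svd(M)$d > 1e-9), 4)
})

test_that("slow-time band-pass has the designed response", {
  grid <- voxel_grid(c(3, 3, 2), 0.1)
  mk_tone <- function(f_hz, nf = 86, rate = 215) {
    arr <- array(0 + 0i, c(grid$shape, nf))
    for (f in seq_len(nf)) {
      arr[, , , f] <- (1 + 0i) * cos(2 * pi * f_hz * (f - 1) / rate)
    }
    iq_series(arr, grid, rate)
  }
  gain <- function(f_hz) {
    o <- temporal_bandpass(mk_tone(f_hz), c(20, 107))
    sqrt(sum(Mod(o$data)^2) / sum(Mod(mk_tone(f_hz)$data)^2))
  }
  # DC annihilated
  dc <- temporal_bandpass(mk_tone(0), c(20, 107))
  expect_lt(sum(Mod(dc$data)^2) / sum(Mod(mk_tone(0)$data)^2), 1e-6)
  # in-band 50 Hz tone preserved within 5%
  expect_lt(abs(gain(50) - 1), 0.05)
  # 5 Hz tone attenuated by at least 20 dB
  expect_lt(gain(5), 10^(-20 / 20))
  expect_error(temporal_bandpass(mk_tone(50), c(107, 20)), "lo < hi")
  expect_error(temporal_bandpass(mk_tone(50), c(20, 150)), "Nyquist")
})

test_that("directional filtering separates axial motion directions", {
  grid <- voxel_grid(c(6, 6, 32), 0.06)
  nf <- 32
  zs <- seq(-0.8, 0.8, length.out = nf)
  up_mover <- blob_series(lapply(zs, function(z) c(0, 0, z)), grid)
  ds <- directional_split(up_mover)
  eu <- sum(Mod(ds$up$data)^2)
  ed <- sum(Mod(ds$down$data)^2)
  expect_gt(eu / (eu + ed), 0.8)
  # reversing the motion swaps the channels
  down_mover <- blob_series(lapply(rev(zs), function(z) c(0, 0, z)), grid)
  ds2 <- directional_split(down_mover)
  eu2 <- sum(Mod(ds2$up$data)^2); ed2 <- sum(Mod(ds2$down$data)^2)
  expect_lt(abs(eu2 - ed) / ed, 0.01)
  expect_lt(abs(ed2 - eu) / eu, 0.01)
  # static scene splits evenly; channels sum to the input
  static <- blob_series(rep(list(c(0, 0, 0)), 8), grid)
  ds3 <- directional_split(static)
  e3u <- sum(Mod(ds3$up$data)^2); e3d <- sum(Mod(ds3$down$data)^2)
  expect_lt(abs(e3u - e3d) / (e3u + e3d), 0.05)
  expect_lt(max(Mod(ds3$up$data + ds3$down$data - static$data)), 1e-10)
})

test_that("power Doppler is the slow-time mean squared magnitude", {
  grid <- voxel_grid(c(4, 4, 3), 0.1)
  amp <- complex(real = 1.2, imaginary = -0.7)
  arr <- array(amp, c(grid$shape, 7))
  pd <- power_doppler(iq_series(arr, grid, 215))
  expect_equal(pd$data, array(Mod(amp)^2, grid$shape), tolerance = 1e-12)
  zero <- power_doppler(iq_series(array(0i, c(grid$shape, 2)), grid, 215))
  expect_true(all(zero$data == 0))
})

test_that("radial-symmetry localization is sub-voxel accurate", {
  grid <- voxel_grid(c(32, 32, 20), 0.06)
  # on-grid blob: essentially exact
  on <- ulm_volume(paint_blob(c(0, 0, 0), grid), grid, "PD")
  l0 <- localize_radial_symmetry(on, 0.3, 7)
  expect_equal(nrow(l0), 1)
  expect_lt(sqrt(sum(c(l0$x, l0$y, l0$z)^2)) / 0.06, 0.02)
  # known off-grid offset recovered within 0.1 voxel
  off <- c(0.3, -0.2, 0.4) * 0.06
  lo <- localize_radial_symmetry(ulm_volume(paint_blob(off, grid), grid,
                                            "PD"), 0.3, 7)
  expect_lt(sqrt(sum((c(lo$x, lo$y, lo$z) - off)^2)) / 0.06, 0.1)
  # two blobs 6 voxels apart: both found, each within 0.15 voxel
  c1 <- c(-3 * 0.06, 0, 0); c2 <- c(3 * 0.06, 0, 0)
  two <- ulm_volume(paint_blob(c1, grid) + paint_blob(c2, grid), grid, "PD")
  lt <- localize_radial_symmetry(two, 0.3, 7)
  expect_equal(nrow(lt), 2)
  lt <- lt[order(lt$x), ]
  expect_lt(sqrt(sum((c(lt$x[1], lt$y[1], lt$z[1]) - c1)^2)) / 0.06, 0.15)
  expect_lt(sqrt(sum((c(lt$x[2], lt$y[2], lt$z[2]) - c2)^2)) / 0.06, 0.15)
  # flat volume: no detections
  flat <- ulm_volume(array(1, grid$shape), grid, "PD")
  expect_equal(nrow(localize_radial_symmetry(flat, 0.3, 7)), 0)
  expect_error(localize_radial_symmetry(on, 0.3, 4), "odd")
  expect_error(localize_radial_symmetry(on, 1.2, 7), "detect_threshold")
})

test_that("localization precision beats 0.2 voxel at 20 dB SNR", {
  grid <- voxel_grid(c(32, 32, 20), 0.06)
  set.seed(11)
  errs <- vapply(1:40, function(i) {
    truth <- (runif(3) - 0.5) * 0.06
    noisy <- paint_blob(truth, grid) +
      array(rnorm(prod(grid$shape), 0, 0.1), grid$shape)  # 20 dB
    l <- localize_radial_symmetry(ulm_volume(noisy, grid, "PD"), 0.5, 7)
    l <- l[which.max(l$intensity), ]
    sqrt(sum((c(l$x, l$y, l$z) - truth)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)) / 0.06, 0.2)
})

test_that("tracking recovers a constant-velocity bubble exactly", {
  step <- 5 / 215  # 23.26 um per frame at 5 mm/s
  locs <- lapply(1:30, function(f) {
    tibble::tibble(x = -0.8 + f * step, y = 0.2, z = -0.1, frame = f,
                   intensity = 1)
  })
  tr <- track_bubbles(locs, 215, max_link = 0.1, max_gap = 2,
                      min_length = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_lt(abs(mean(tr$speed, na.rm = TRUE) - 5) / 5, 0.01)
  # per-step velocity vector points along +x
  expect_equal(mean(tr$vx, na.rm = TRUE), 5, tolerance = 1e-6)
  expect_equal(mean(tr$vy, na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("optimal assignment avoids identity swaps and matches brute force", {
  # two parallel bubbles separated by 3x their step
  step <- 0.02
  locs <- lapply(1:12, function(f) {
    tibble::tibble(x = c(f * step, f * step),
                   y = c(0, 3 * step), z = 0, frame = f,
                   intensity = 1)
  })
  tr <- track_bubbles(locs, 215, max_link = 0.05, max_gap = 0,
                      min_length = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 2)
  for (id in unique(tr$track_id)) {
    ys <- tr$y[tr$track_id == id]
    expect_equal(length(unique(ys)), 1)  # no swap ever
  }
  # Hungarian result equals exhaustive-permutation optimum on random costs
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    asg <- solve_assignment(C)
    best <- Inf
    for (p in ulmpact_permutations(n)) {
      best <- min(best, sum(C[cbind(1:n, p)]))
    }
    expect_equal(sum(C[cbind(1:n, asg)]), best, tolerance = 1e-12)
  }
})

test_that("gap closing bridges missed detections, short tracks are dropped", {
  step <- 0.02
  frames <- setdiff(1:20, c(7, 13))  # two single-frame dropouts
  locs <- lapply(1:20, function(f) {
    if (f %in% frames) {
      tibble::tibble(x = f * step, y = 0, z = 0, frame = f, intensity = 1)
    } else {
      tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                     frame = integer(0), intensity = numeric(0))
    }
  })
  tr <- track_bubbles(locs, 215, max_link = 0.05, max_gap = 2,
                      min_length = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 18)
  # no gap closing: the dropouts split the trajectory into short pieces
  tr0 <- track_bubbles(locs, 215, max_link = 0.05, max_gap = 0,
                       min_length = 7)
  expect_lt(dplyr::n_distinct(tr0$track_id), 2)
  # empty input
  expect_equal(nrow(track_bubbles(list(), 215, 0.1)), 0)
  expect_error(track_bubbles(locs, 215, max_link = 0), "max_link")
})

test_that("rendered maps confine density to the track and read its speed", {
  grid <- voxel_grid(c(24, 24, 12), 0.1)
  step <- 5 / 215
  locs <- lapply(1:40, function(f) {
    tibble::tibble(x = -1 + f * step, y = 0.25, z = 0.15, frame = f,
                   intensity = 1)
  })
  tr <- track_bubbles(locs, 215, max_link = 0.1, min_length = 5)
  maps <- render_maps(tr, grid, upsample = 4)
  expect_equal(maps$density$grid$spacing, rep(0.025, 3))
  nz <- which(maps$density$data > 0, arr.ind = TRUE)
  co <- cbind(maps$density$grid$origin[1] + (nz[, 1] - 1) * 0.025,
              maps$density$grid$origin[2] + (nz[, 2] - 1) * 0.025,
              maps$density$grid$origin[3] + (nz[, 3] - 1) * 0.025)
  # distance from the true line y=0.25, z=0.15 within one super-voxel
  d <- sqrt((co[, 2] - 0.25)^2 + (co[, 3] - 0.15)^2)
  expect_lt(max(d), 0.025 + 1e-9)
  v <- maps$velocity$data
  expect_lt(abs(mean(v[!is.na(v)]) - 5) / 5, 0.01)
})

test_that("velocity recovery holds across the 1-10 mm/s range", {
  grid <- voxel_grid(c(24, 12, 8), 0.1)
  for (speed in c(1, 5, 10)) {
    step <- speed / 215
    locs <- lapply(1:30, function(f) {
      tibble::tibble(x = -1 + f * step, y = 0, z = 0, frame = f,
                     intensity = 1)
    })
    tr <- track_bubbles(locs, 215, max_link = 3 * step + 0.01,
                        min_length = 5)
    maps <- render_maps(tr, grid, upsample = 4)
    v <- maps$velocity$data
    expect_lt(abs(mean(v[!is.na(v)]) - speed) / speed, 0.05)
  }
})

test_that("a two-vessel phantom unresolved in PD separates in the ULM map", {
  grid <- voxel_grid(c(24, 24, 10), 0.1)
  sep <- 0.2  # two coarse voxels apart: under the PD diffraction footprint
  y1 <- -sep / 2; y2 <- sep / 2
  nf <- 60
  step <- 5 / 215
  # PD scene: the two vessels blurred by the system PSF (sigma ~1.5 voxels)
  pd_img <- array(0, grid$shape)
  for (x in seq(-1, 1, by = 0.05)) {
    pd_img <- pd_img + paint_blob(c(x, y1, 0), grid, 1.5) +
      paint_blob(c(x, y2, 0), grid, 1.5)
  }
  pd <- ulm_volume(pd_img, grid, "PD")
  # ULM: localizations along each vessel, tracked and rendered at 4x
  locs <- lapply(1:nf, function(f) {
    tibble::tibble(x = c(-1 + f * step, -0.8 + f * step),
                   y = c(y1, y2), z = 0, frame = f, intensity = 1)
  })
  tr <- track_bubbles(locs, 215, max_link = 0.06, min_length = 5)
  maps <- render_maps(tr, grid, upsample = 4)
  # cross-vessel profiles (max over the along-vessel and axial directions)
  prof_pd <- apply(pd$data, 2, max)
  prof_ulm <- apply(maps$density$data, 2, max)
  fine <- maps$density$grid
  ys <- grid_axis(fine, 2)
  # ULM: two distinct ridges with a zero valley between them
  ridge1 <- max(prof_ulm[abs(ys - y1) <= 0.026])
  ridge2 <- max(prof_ulm[abs(ys - y2) <= 0.026])
  valley <- min(prof_ulm[abs(ys) <= 0.05])
  expect_gt(ridge1, 0)
  expect_gt(ridge2, 0)
  expect_equal(valley, 0)
  # PD: no valley — the mid-point is at least as bright as the flanks
  iy_mid_pd <- which.min(abs(grid_axis(grid, 2)))
  iy_off_pd <- which.min(abs(grid_axis(grid, 2) - 2 * sep))
  expect_gte(prof_pd[iy_mid_pd], 0.9 * max(prof_pd))
})

test_that("iq series bookkeeping: frame filtering and volume extraction", {
  grid <- voxel_grid(c(5, 5, 4), 0.1)
  arr <- array(seq_len(prod(grid$shape) * 6) + 0i, c(grid$shape, 6))
  ser <- iq_series(arr, grid, 100)
  sub <- filter_frames(ser, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(dim(sub$data)[4], 4)
  expect_equal(sub$data[, , , 2], arr[, , , 3])
  v <- ulmpact::power_doppler(sub)
  expect_s3_class(v, "ulm_volume")
  expect_error(iq_series(arr[, , , 1, drop = FALSE], grid, 100), "2 frames")
})
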