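# Shared fixtures, all generated in code.

# small arrays keep the forward model cheap; resolution-critical tests
# build the full 256-element array themselves
geom64 <- function() build_spherical_array(64, 40, 57, layout_seed = 0)
geom256 <- function() build_spherical_array(256, 40, 57, layout_seed = 0)

# paint an isotropic Gaussian blob (sigma in voxels) at a mm position
paint_blob <- function(center_mm, grid, sigma_vox = 1.5, amp = 1) {
  co <- grid_coords(grid)
  d2 <- rowSums(sweep(sweep(co, 2, center_mm), 2, grid$spacing, "/")^2)
  array(amp * exp(-d2 / (2 * sigma_vox^2)), dim = grid$shape)
}

# complex IQ series from a list of per-frame blob centres
blob_series <- function(centers_by_frame, grid, frame_rate = 215,
                        sigma_vox = 1.5, amp = 1) {
  nf <- length(centers_by_frame)
  arr <- array(0 + 0i, dim = c(grid$shape, nf))
  for (f in seq_len(nf)) {
    cs <- centers_by_frame[[f]]
    if (is.null(dim(cs))) cs <- matrix(cs, 1)
    fr <- array(0, grid$shape)
    for (k in seq_len(nrow(cs))) {
      fr <- fr + paint_blob(cs[k, ], grid, sigma_vox, amp)
    }
    arr[, , , f] <- fr
  }
  iq_series(arr, grid, frame_rate)
}

# envelope of one RF channel
channel_envelope <- function(ch) {
  abs(ulmpact:::analytic_columns(matrix(ch, ncol = 1))[, 1])
}

# all permutations of 1:n (tiny n only), for brute-force assignment oracles
ulmpact_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in ulmpact_permutations(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# sub-sample cross-correlation lag between two records: 16x band-limited
# upsampling of the cross-correlation, then a parabolic peak fit
xcorr_lag <- function(a, b, up = 16L) {
  n <- length(a)
  nfft <- stats::nextn(2 * n, 2)
  A <- stats::fft(c(a, numeric(nfft - n)))
  B <- stats::fft(c(b, numeric(nfft - n)))
  X <- A * Conj(B)
  # zero-pad the spectrum (split at Nyquist) to interpolate the lag axis
  half <- nfft / 2
  Xu <- c(X[1:half], numeric(nfft * (up - 1)), X[(half + 1):nfft])
  cc <- Re(stats::fft(Xu, inverse = TRUE))
  m <- length(cc)
  cc <- c(cc[(m / 2 + 1):m], cc[1:(m / 2)])
  lags <- seq(-m / 2, m / 2 - 1) / up
  i <- which.max(cc)
  frac <- 0
  if (i > 1 && i < length(cc)) {
    y0 <- cc[i - 1]; y1 <- cc[i]; y2 <- cc[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (abs(denom) > 0) frac <- 0.5 * (y0 - y2) / denom / up
  }
  -(lags[i] + frac)
}
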