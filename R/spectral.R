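#' Haemoglobin extinction table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_hbo2`, `eps_hb` (molar
#' extinction, 1/(cm*M)). The package ships a default table at the
#' wavelengths used for oxygenation imaging (700, 750, 800 nm) taken from
#' the standard tabulated haemoglobin spectra compilation.
#'
#' @param path CSV path; default the packaged table.
#' @return A tibble of class `extinction_table`.
#' @export
read_extinction_table <- function(path = system.file("extdata",
                                                     "hb_extinction.csv",
                                                     package = "ulmpact")) {
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(req %in% names(tb))) {
    stop("extinction table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(tb$eps_hbo2 <= 0) || any(tb$eps_hb <= 0)) {
    stop("extinction coefficients must be strictly positive", call. = FALSE)
  }
  class(tb) <- c("extinction_table", class(tb))
  tb
}

#' Two-wavelength extinction matrix
#'
#' @param table An `extinction_table`.
#' @param w1,w2 Wavelengths in nm; both must be tabulated.
#' @return 2x2 matrix `E` with rows (w1, w2) and columns (HbO2, Hb); its
#'   condition number is attached as attribute `condition`.
#' @export
extinction_matrix <- function(table, w1, w2) {
  r1 <- which(table$wavelength_nm == w1)
  r2 <- which(table$wavelength_nm == w2)
  if (!length(r1) || !length(r2)) {
    stop("wavelengths ", w1, "/", w2, " nm not in the extinction table",
         call. = FALSE)
  }
  E <- rbind(c(table$eps_hbo2[r1], table$eps_hb[r1]),
             c(table$eps_hbo2[r2], table$eps_hb[r2]))
  d <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(d) < 1e-12 * max(abs(E))^2) {
    stop("singular unmixing matrix for wavelength pair ", w1, "/", w2, " nm",
         call. = FALSE)
  }
  attr(E, "condition") <- kappa(E, exact = TRUE)
  E
}

#' Linear spectral unmixing of oxygen saturation
#'
#' Solves, voxel by voxel, the 2x2 linear system
#' `[pa(w1); pa(w2)] = E [C_HbO2; C_Hb]` and forms
#' `sO2 = C_HbO2 / (C_HbO2 + C_Hb)`. No fluence compensation is applied: at
#' nearby wavelengths (700/750 nm) the fluence largely cancels in the ratio,
#' which also makes the result invariant to a common positive scaling of
#' both input volumes. Voxels whose PA amplitude falls below
#' `amp_threshold` of the volume maximum, or whose concentrations are both
#' non-positive, are flagged invalid (NA); a single negative concentration
#' is clipped to zero before the ratio.
#'
#' @param pa_w1,pa_w2 Co-registered `ulm_volume`s of kind `"PA"` with
#'   wavelength tags.
#' @param table An `extinction_table`.
#' @param amp_threshold Validity threshold as a fraction of the maximum PA
#'   amplitude (default 0.1).
#' @return An `ulm_volume` of kind `"SO2"` (values in [0,1], NA where
#'   invalid) with `extra$valid` the logical validity mask and
#'   `extra$condition` the unmixing matrix condition number.
#' @export
unmix_so2 <- function(pa_w1, pa_w2, table, amp_threshold = 0.1) {
  stopifnot(inherits(pa_w1, "ulm_volume"), inherits(pa_w2, "ulm_volume"))
  if (!identical(pa_w1$grid, pa_w2$grid)) {
    stop("PA volumes must share one voxel grid", call. = FALSE)
  }
  if (is.null(pa_w1$wavelength) || is.null(pa_w2$wavelength)) {
    stop("PA volumes must carry wavelength tags", call. = FALSE)
  }
  E <- extinction_matrix(table, pa_w1$wavelength, pa_w2$wavelength)
  det <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  p1 <- as.vector(pa_w1$data)
  p2 <- as.vector(pa_w2$data)
  c_hbo2 <- (E[2, 2] * p1 - E[1, 2] * p2) / det
  c_hb <- (-E[2, 1] * p1 + E[1, 1] * p2) / det

  amp <- pmax(abs(p1), abs(p2))
  valid <- amp >= amp_threshold * max(amp) & !(c_hbo2 <= 0 & c_hb <= 0)
  c_hbo2 <- pmax(c_hbo2, 0)
  c_hb <- pmax(c_hb, 0)
  so2 <- rep(NA_real_, length(p1))
  tot <- c_hbo2 + c_hb
  so2[valid] <- c_hbo2[valid] / tot[valid]
  ulm_volume(array(so2, dim = pa_w1$grid$shape), pa_w1$grid, kind = "SO2",
             extra = list(valid = array(valid, dim = pa_w1$grid$shape),
                          condition = attr(E, "condition")))
}

#' Hemisphere oxygenation contrast
#'
#' Masked mean sO2 of two disjoint regions (for example left and right
#' hemispheres) and their difference, the quantity summarised in the
#' stroke-vs-healthy comparison.
#'
#' @param so2 An `ulm_volume` of kind `"SO2"`.
#' @param mask_left,mask_right Logical arrays of the grid shape; must be
#'   disjoint and non-empty.
#' @return A one-row tibble with `mean_left`, `mean_right`, `difference`.
#' @export
so2_difference_stats <- function(so2, mask_left, mask_right) {
  stopifnot(inherits(so2, "ulm_volume"), so2$kind == "SO2")
  mask_left <- as.logical(mask_left); mask_right <- as.logical(mask_right)
  if (!any(mask_left) || !any(mask_right)) {
    stop("masks must be non-empty", call. = FALSE)
  }
  if (any(mask_left & mask_right)) {
    stop("masks must be disjoint", call. = FALSE)
  }
  v <- as.vector(so2$data)
  ml <- mean(v[mask_left], na.rm = TRUE)
  mr <- mean(v[mask_right], na.rm = TRUE)
  tibble::tibble(mean_left = ml, mean_right = mr, difference = ml - mr)
}

#' Amplitude-weighted slab sO2 projection
#'
#' Collapses a slab of the sO2 volume along the axial direction using the PA
#' amplitude as weight, the projection used for slab oxygenation maps.
#'
#' @param so2 `ulm_volume` of kind `"SO2"`.
#' @param amplitude Co-registered PA `ulm_volume` providing weights.
#' @param z_range Length-2 axial window in mm.
#' @return A matrix (nx x ny) of weighted-mean sO2; NA where no valid voxel.
#' @export
so2_slab <- function(so2, amplitude, z_range) {
  stopifnot(identical(so2$grid, amplitude$grid))
  z <- grid_axis(so2$grid, 3)
  sel <- which(z >= z_range[1] & z <= z_range[2])
  s <- so2$data[, , sel, drop = FALSE]
  w <- abs(amplitude$data[, , sel, drop = FALSE])
  w[is.na(s)] <- 0
  s[is.na(s)] <- 0
  num <- apply(s * w, c(1, 2), sum)
  den <- apply(w, c(1, 2), sum)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
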