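# Sliding-window construction of the five QUS parametric maps
# (MBF, SS, SI, ASD, AAC) and region summary statistics.

#' Sliding-window configuration for parametric imaging
#'
#' @param kernel_mm square kernel side length in mm (default 2).
#' @param overlap fractional overlap between adjacent kernels in both
#'   directions (default 0.94); the lattice step is
#'   `kernel_mm * (1 - overlap)`.
#' @export
sliding_window_config <- function(kernel_mm = 2, overlap = 0.94) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (kernel_mm <= 0) stop("kernel_mm must be > 0")
  structure(list(kernel_mm = kernel_mm, overlap = overlap,
                 step_mm = kernel_mm * (1 - overlap)),
            class = "qus_window_config")
}

# number of kernel positions fitting in `extent` with kernel `k`, step `s`
lattice_count <- function(extent, k, s) {
  if (extent < k) return(0L)
  as.integer(floor((extent - k) / s + 1e-9)) + 1L
}

#' Build the five QUS spectral parametric images for one frame
#'
#' Slides a square kernel over the frame on a regular lattice; at every
#' position the sample and reference window spectra are computed, the
#' backscatter coefficient is formed via reference-phantom normalization
#' with a piecewise attenuation path (intervening tissue above the tumour
#' at `beta_intervening`, tumour tissue below the proximal contour depth at
#' the frame ACE), and the linear-fit (MBF/SS/SI) and Gaussian form-factor
#' (ASD/AAC) parameters are assigned to the window-center pixel. Kernels
#' that would exit the frame are dropped; there is no padding.
#'
#' The frame ACE is estimated once over the tumour ROI by the
#' spectral-difference method and applied to all windows whose center lies
#' at or below the proximal tumour depth (including margin windows at
#' tumour depth); windows above use the intervening-tissue assumption.
#'
#' @param frame a [rf_frame()].
#' @param phantom a [reference_phantom()] carrying matched RF frames and a
#'   BSC curve.
#' @param cfg a [sliding_window_config()].
#' @param tumour_contour n x 2 matrix `(x_mm, z_mm)` of the tumour core.
#' @param beta_intervening attenuation slope assumed for intervening
#'   tissue, dB/cm/MHz (default 1).
#' @param ace optional [attenuation_model()]; when NULL it is estimated
#'   from the frame over the tumour ROI (falling back to the intervening
#'   assumption when the ROI is too short for the depth fit).
#' @param asd_grid_um candidate scatterer diameters for the form-factor fit.
#' @return Object of class `qus_parametric_images`: `maps` (named list of
#'   five matrices, rows = axial pixels), `grid` ([pixel_grid()] of pixel
#'   centers in mm), `frame_id`, `ace`.
#' @export
build_parametric_images <- function(frame, phantom, cfg, tumour_contour,
                                    beta_intervening = 1, ace = NULL,
                                    asd_grid_um = seq(10, 200, by = 1)) {
  stopifnot(inherits(frame, "qus_rf_frame"),
            inherits(phantom, "qus_reference_phantom"),
            inherits(cfg, "qus_window_config"))
  if (is.null(phantom$frames) || length(phantom$frames) == 0)
    stop("phantom must carry matched reference RF frames")
  g <- frame$geometry
  band <- g$analysis_band
  ax_step_mm <- axial_step_m(g) * 1e3
  lat_step_mm <- line_spacing_m(g) * 1e3
  k_ax <- max(4L, as.integer(round(cfg$kernel_mm / ax_step_mm)))
  k_lat <- max(2L, as.integer(round(cfg$kernel_mm / lat_step_mm)))
  s_ax <- max(1L, as.integer(round(cfg$step_mm / ax_step_mm)))
  s_lat <- max(1L, as.integer(round(cfg$step_mm / lat_step_mm)))
  if (k_ax > g$axial_samples || k_lat > g$n_lines)
    stop("kernel larger than frame")
  n_ax <- lattice_count(g$axial_samples, k_ax, s_ax)
  n_lat <- lattice_count(g$n_lines, k_lat, s_lat)

  # proximal tumour depth (cm) from the contour
  z_prox_cm <- min(tumour_contour[, 2]) / 10
  if (is.null(ace)) {
    ace <- tryCatch(
      estimate_frame_ace(frame, phantom, tumour_contour, k_ax,
                         beta_ref = phantom$attenuation_slope),
      error = function(e) attenuation_model(beta_intervening,
                                            "assumed_intervening"))
  }

  ref_frames <- phantom$frames
  maps <- replicate(5, matrix(NA_real_, n_ax, n_lat), simplify = FALSE)
  names(maps) <- c("MBF", "SS", "SI", "ASD", "AAC")
  fc <- mean(band)

  # precompute the form-factor design matrix on the window frequency grid
  nfft <- next_pow2(4 * k_ax)
  fgrid <- (0:(nfft / 2)) * g$sampling_frequency / nfft / 1e6
  fidx <- band_index(fgrid, band)
  fband <- fgrid[fidx]
  theor <- form_factor_design(fband, asd_grid_um, g$speed_of_sound)
  sigma_r_band <- stats::approx(phantom$bsc_curve$f_MHz,
                                phantom$bsc_curve$sigma,
                                xout = fband, rule = 2)$y

  for (ia in seq_len(n_ax)) {
    a0 <- (ia - 1L) * s_ax
    a1 <- a0 + k_ax
    for (il in seq_len(n_lat)) {
      l0 <- (il - 1L) * s_lat
      l1 <- l0 + k_lat
      sm <- compute_window_spectrum(frame, c(a0, a1), c(l0, l1))
      pr <- rowMeans(vapply(ref_frames, function(rf)
        compute_window_spectrum(rf, c(a0, a1), c(l0, l1))$power_db,
        numeric(nfft / 2 + 1)))
      depth <- sm$R_cm + sm$dz_cm / 2
      # piecewise one-way attenuation path, in dB/cm (per MHz)
      tum_path <- max(0, depth - z_prox_cm)
      int_path <- depth - tum_path
      path_db_per_mhz <- beta_intervening * int_path + ace$slope * tum_path
      ref_db_per_mhz <- phantom$attenuation_slope * depth
      ratio_db <- sm$power_db[fidx] - pr[fidx]
      corr_np <- DB_TO_NP * (path_db_per_mhz - ref_db_per_mhz) * fband
      sigma_m <- sigma_r_band * 10^(ratio_db / 10) * exp(4 * corr_np)
      meas_db <- 10 * log10(pmax(sigma_m, .Machine$double.xmin))
      # linear fit
      fm <- mean(fband)
      ss <- sum((fband - fm) * (meas_db - mean(meas_db))) / sum((fband - fm)^2)
      si <- mean(meas_db) - ss * fm
      maps$SS[ia, il] <- ss
      maps$SI[ia, il] <- si
      maps$MBF[ia, il] <- ss * fc + si
      # form-factor fit (closed-form n_z per candidate)
      resid <- sweep(-theor, 2, meas_db, `+`)
      offset <- rowMeans(resid)
      obj <- rowMeans((resid - offset)^2)
      ibest <- which.min(obj)
      maps$ASD[ia, il] <- asd_grid_um[ibest]
      maps$AAC[ia, il] <- offset[ibest]
    }
  }
  grid <- pixel_grid(
    origin_mm = c((k_lat / 2) * lat_step_mm, (k_ax / 2) * ax_step_mm),
    spacing_mm = c(s_lat * lat_step_mm, s_ax * ax_step_mm),
    dims = c(n_ax, n_lat))
  structure(list(maps = maps, grid = grid, frame_id = frame$frame_id,
                 ace = ace),
            class = "qus_parametric_images")
}

# Estimate the frame ACE over the tumour ROI using windows marching down
# the ROI depth extent, averaged laterally over the ROI's line range.
estimate_frame_ace <- function(frame, phantom, tumour_contour, k_ax,
                               beta_ref = 0.786, n_depths = 6) {
  g <- frame$geometry
  ax_step_cm <- axial_step_m(g) * 100
  lat_mm <- line_spacing_m(g) * 1e3
  z0 <- min(tumour_contour[, 2]) / 10  # cm
  z1 <- max(tumour_contour[, 2]) / 10
  l0 <- max(0L, as.integer(floor(min(tumour_contour[, 1]) / lat_mm)))
  l1 <- min(g$n_lines, as.integer(ceiling(max(tumour_contour[, 1]) / lat_mm)))
  a_start <- as.integer(round(z0 / ax_step_cm))
  a_stop <- as.integer(round(z1 / ax_step_cm))
  span <- a_stop - a_start - k_ax
  if (span < 2 || l1 - l0 < 1) stop("tumour ROI too small for ACE estimation")
  n_depths <- min(n_depths, span + 1L)
  starts <- a_start + unique(as.integer(round(seq(0, span, length.out = n_depths))))
  if (length(starts) < 3) stop("tumour ROI too short for the depth fit")
  sample_spectra <- lapply(starts, function(a)
    compute_window_spectrum(frame, c(a, a + k_ax), c(l0, l1)))
  reference_spectra <- lapply(starts, function(a) {
    sps <- lapply(phantom$frames, function(rf)
      compute_window_spectrum(rf, c(a, a + k_ax), c(l0, l1)))
    avg <- sps[[1]]
    if (length(sps) > 1) {
      pw <- rowMeans(vapply(sps, function(s) 10^(s$power_db / 10),
                            numeric(length(avg$power_db))))
      avg$power_db <- 10 * log10(pw)
    }
    avg
  })
  estimate_ace_spectral_difference(sample_spectra, reference_spectra,
                                   band = g$analysis_band,
                                   beta_ref = beta_ref)
}

#' Summary statistics of a parametric map over an ROI
#'
#' Arithmetic mean and population (N-denominator) standard deviation of the
#' masked pixels.
#'
#' @param map numeric matrix.
#' @param mask a `qus_roi_mask` (or logical matrix) of the same dimensions.
#' @return list with `mean`, `sd`, `n`.
#' @export
region_summary <- function(map, mask) {
  m <- if (inherits(mask, "qus_roi_mask")) mask$mask else mask
  if (!identical(dim(m), dim(map)))
    stop("mask dimensions do not match the map")
  v <- map[m]
  v <- v[is.finite(v)]
  if (length(v) < 1) stop("empty (or all-NA) region")
  mu <- mean(v)
  list(mean = mu, sd = sqrt(mean((v - mu)^2)), n = length(v))
}

#' Core-to-margin ratio
#'
#' `CMR = mean(core) / sd(margin)`; degenerate margins (zero spread) yield
#' `NA` rather than an error.
#' @param core,margin [region_summary()] results.
#' @export
compute_cmr <- function(core, margin) {
  if (margin$sd <= 0) return(NA_real_)
  core$mean / margin$sd
}

#' Core-to-margin contrast ratio
#'
#' `CMCR = |mean(core) - mean(margin)| / ((sd(core) + sd(margin)) / 2)`;
#' `NA` when both spreads are zero.
#' @param core,margin [region_summary()] results.
#' @export
compute_cmcr <- function(core, margin) {
  denom <- (core$sd + margin$sd) / 2
  if (denom <= 0) return(NA_real_)
  abs(core$mean - margin$mean) / denom
}
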