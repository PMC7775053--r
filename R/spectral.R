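# Spectral estimation: windowed power spectra, reference-phantom BSC
# normalization, spectral-difference attenuation estimation, linear
# spectral fit (MBF/SS/SI) and Gaussian form-factor fit (ASD/AAC).
#
# Attenuation convention used throughout: a slope beta in dB/cm/MHz refers
# to one-way amplitude attenuation, i.e. pressure amplitude decays as
# 10^(-beta * f_MHz * z_cm / 20). Equivalently alpha_np = 0.11513 * beta *
# f_MHz Np/cm and round-trip POWER carries exp(-4 * alpha_np * z_cm).
# In dB the round-trip power therefore drops by 2 * beta * f_MHz per cm of
# one-way depth.

DB_TO_NP <- log(10) / 20  # 0.11513: dB (amplitude) -> Np

#' Attenuation model with a linear frequency dependence
#'
#' @param slope attenuation slope beta in dB/cm/MHz; `alpha(f) = beta * f`.
#' @param provenance one of `"assumed_intervening"`, `"estimated_tumour"`,
#'   `"reference"`.
#' @export
attenuation_model <- function(slope,
                              provenance = c("estimated_tumour",
                                             "assumed_intervening",
                                             "reference")) {
  provenance <- match.arg(provenance)
  if (!is.finite(slope) || slope < 0) stop("attenuation slope must be >= 0")
  structure(list(slope = slope, provenance = provenance),
            class = "qus_attenuation")
}

hanning_window <- function(n) {
  if (n < 2) return(rep(1, n))
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Averaged windowed power spectrum of an RF window
#'
#' Each scan line segment inside the window is gated with a Hanning taper,
#' zero-padded to the next power of two at least four times the gate
#' length, Fourier transformed and squared; the periodograms are averaged
#' across lines and returned in dB. Window geometry (`R_cm`: distance from
#' the transducer to the proximal window edge; `dz_cm`: axial gate length)
#' is recorded for later attenuation bookkeeping.
#'
#' @param frame a [rf_frame()].
#' @param axial_range integer length-2 half-open 0-based sample range
#'   `[a0, a1)`.
#' @param line_range integer length-2 half-open 0-based line range
#'   `[l0, l1)`.
#' @return An object of class `qus_spectrum` with `freq_MHz`, `power_db`,
#'   `n_lines_averaged`, `R_cm`, `dz_cm`.
#' @export
compute_window_spectrum <- function(frame, axial_range, line_range) {
  stopifnot(inherits(frame, "qus_rf_frame"))
  a0 <- axial_range[1]; a1 <- axial_range[2]
  l0 <- line_range[1]; l1 <- line_range[2]
  g <- frame$geometry
  if (a0 < 0 || a1 > g$axial_samples || l0 < 0 || l1 > g$n_lines)
    stop("window exceeds frame bounds")
  n <- a1 - a0
  if (n < 4) stop("window must span at least 4 axial samples")
  if (l1 - l0 < 1) stop("window must include at least one line")
  seg <- frame$samples[(a0 + 1):a1, (l0 + 1):l1, drop = FALSE]
  w <- hanning_window(n)
  seg <- seg * w
  nfft <- next_pow2(4 * n)
  pad <- matrix(0, nfft, ncol(seg))
  pad[1:n, ] <- seg
  sp <- stats::mvfft(pad)
  pxx <- rowMeans(Mod(sp)^2)
  keep <- 1:(nfft / 2 + 1)
  freq <- (keep - 1) * g$sampling_frequency / nfft / 1e6
  structure(list(
    freq_MHz = freq,
    power_db = 10 * log10(pmax(pxx[keep], .Machine$double.xmin)),
    n_lines_averaged = l1 - l0,
    R_cm = a0 * axial_step_m(g) * 100,
    dz_cm = n * axial_step_m(g) * 100
  ), class = "qus_spectrum")
}

band_index <- function(freq_MHz, band) {
  idx <- which(freq_MHz >= band[1] & freq_MHz <= band[2])
  if (length(idx) < 3) stop("fewer than 3 frequency points in the analysis band")
  idx
}

#' Spectral-difference local attenuation estimation (ACE)
#'
#' Estimates the tumour attenuation slope from the rate of change of the
#' log power-spectral difference between sample and reference over depth.
#' For each analysis frequency the slope of `power_m(f, z) - power_r(f, z)`
#' (dB) against one-way depth `z` (cm, window centers) is computed; under a
#' linear frequency dependence this per-frequency slope is `-2 * dbeta * f`,
#' so a through-origin fit against `f` recovers `dbeta` and
#' `ACE = beta_ref + dbeta`.
#'
#' @param sample_spectra,reference_spectra lists of `qus_spectrum` at
#'   matched depths (same window geometry).
#' @param band analysis band in MHz.
#' @param beta_ref reference phantom attenuation slope, dB/cm/MHz.
#' @return an [attenuation_model()] with provenance `"estimated_tumour"`.
#' @export
estimate_ace_spectral_difference <- function(sample_spectra,
                                             reference_spectra,
                                             band, beta_ref = 0.786) {
  if (length(sample_spectra) < 3)
    stop("need at least 3 depth positions for the spectral-difference fit")
  if (length(sample_spectra) != length(reference_spectra))
    stop("sample and reference depth grids differ in length")
  z <- vapply(sample_spectra, function(s) s$R_cm + s$dz_cm / 2, 0)
  zr <- vapply(reference_spectra, function(s) s$R_cm + s$dz_cm / 2, 0)
  if (max(abs(z - zr)) > 1e-9) stop("sample and reference depth grids differ")
  f0 <- sample_spectra[[1]]$freq_MHz
  for (s in c(sample_spectra, reference_spectra))
    if (length(s$freq_MHz) != length(f0) || max(abs(s$freq_MHz - f0)) > 1e-9)
      stop("frequency grids do not match across depths")
  idx <- band_index(f0, band)
  diffs <- vapply(seq_along(sample_spectra), function(i)
    sample_spectra[[i]]$power_db[idx] - reference_spectra[[i]]$power_db[idx],
    numeric(length(idx)))
  # per-frequency dB slope vs depth (cm)
  zc <- z - mean(z)
  s_f <- as.numeric(diffs %*% zc) / sum(zc^2)
  f <- f0[idx]
  m <- sum(s_f * f) / sum(f^2)   # through-origin fit: s(f) = m * f
  dbeta <- -m / 2                # round-trip dB power slope = -2 dbeta f
  attenuation_model(max(beta_ref + dbeta, 0), "estimated_tumour")
}

#' Backscatter coefficient via reference-phantom normalization
#'
#' \deqn{\sigma_m(f) = \sigma_r(f) \frac{|S_m|^2}{|S_r|^2}
#'   e^{4(\alpha_m - \alpha_r)(R + \Delta z / 2)}}
#' with attenuations in Np/cm (dB slopes are converted internally) and the
#' factor 4 accounting for two-way travel of power.
#'
#' @param sample,reference `qus_spectrum` objects from the same window
#'   geometry.
#' @param phantom a [reference_phantom()] with a `bsc_curve`.
#' @param alpha_m sample [attenuation_model()].
#' @param band optional band (MHz) to restrict the output grid; defaults to
#'   the span of the phantom's BSC curve.
#' @return object of class `qus_bsc` with `freq_MHz` and `sigma`.
#' @export
compute_bsc <- function(sample, reference, phantom, alpha_m, band = NULL) {
  stopifnot(inherits(phantom, "qus_reference_phantom"),
            inherits(alpha_m, "qus_attenuation"))
  if (is.null(phantom$bsc_curve))
    stop("phantom has no tabulated BSC curve")
  if (length(sample$freq_MHz) != length(reference$freq_MHz) ||
      max(abs(sample$freq_MHz - reference$freq_MHz)) > 1e-9)
    stop("sample and reference frequency grids differ")
  if (abs(sample$R_cm - reference$R_cm) > 1e-9 ||
      abs(sample$dz_cm - reference$dz_cm) > 1e-9)
    stop("sample and reference window geometries differ")
  if (is.null(band))
    band <- range(phantom$bsc_curve$f_MHz)
  idx <- band_index(sample$freq_MHz, band)
  f <- sample$freq_MHz[idx]
  sigma_r <- stats::approx(phantom$bsc_curve$f_MHz, phantom$bsc_curve$sigma,
                           xout = f, rule = 2)$y
  if (any(sigma_r <= 0)) stop("reference BSC must be strictly positive")
  ratio_db <- sample$power_db[idx] - reference$power_db[idx]
  depth <- sample$R_cm + sample$dz_cm / 2
  d_alpha_np <- DB_TO_NP * (alpha_m$slope - phantom$attenuation_slope) * f
  sigma_m <- sigma_r * 10^(ratio_db / 10) * exp(4 * d_alpha_np * depth)
  structure(list(freq_MHz = f, sigma = sigma_m), class = "qus_bsc")
}

as_db_curve <- function(x) {
  if (inherits(x, "qus_bsc"))
    list(freq_MHz = x$freq_MHz, db = 10 * log10(x$sigma))
  else if (inherits(x, "qus_spectrum"))
    list(freq_MHz = x$freq_MHz, db = x$power_db)
  else stop("expected a qus_bsc or qus_spectrum")
}

#' Linear spectral fit: mid-band fit, spectral slope, spectral intercept
#'
#' Ordinary least squares of the dB spectrum against frequency (MHz)
#' restricted to the analysis band. `SS` is the slope (dB/MHz), `SI` the
#' 0-MHz intercept (dB) and `MBF = SS * f_c + SI` the value of the fitted
#' line at the band center.
#'
#' @param x a `qus_bsc` or `qus_spectrum`.
#' @param band numeric length-2, analysis band in MHz.
#' @return list with `MBF`, `SS`, `SI`, `f_center`.
#' @export
fit_linear_spectrum <- function(x, band) {
  cv <- as_db_curve(x)
  idx <- band_index(cv$freq_MHz, band)
  f <- cv$freq_MHz[idx]; y <- cv$db[idx]
  fm <- mean(f)
  ss <- sum((f - fm) * (y - mean(y))) / sum((f - fm)^2)
  si <- mean(y) - ss * fm
  fc <- mean(band)
  list(MBF = ss * fc + si, SS = ss, SI = si, f_center = fc)
}

# Gaussian form-factor (spherical scatterer): F = exp(-0.827 k^2 a^2),
# k = 2 pi f / c_l, a = effective radius = ASD / 2.
gaussian_form_factor_db <- function(f_MHz, asd_um, c_l) {
  a <- asd_um * 1e-6 / 2
  f <- f_MHz * 1e6
  k <- 2 * pi * f / c_l
  C <- pi^2 / (36 * c_l^4)
  10 * log10(C) + 40 * log10(f) + 60 * log10(a) +
    10 * log10(exp(1)) * (-0.827 * k^2 * a^2)
}

#' Gaussian form-factor fit: scatterer diameter and acoustic concentration
#'
#' Fits the theoretical backscatter coefficient
#' \deqn{\sigma_{theor}(f) = C f^4 a_{eff}^6 n_z F(f, a_{eff}),\quad
#'   C = \pi^2 / (36 c_l^4),\quad F = e^{-0.827 k^2 a_{eff}^2}}
#' to the measured BSC in dB by grid search over candidate diameters
#' (`ASD = 2 a_eff`). For each candidate the optimal acoustic concentration
#' has the closed form `n_z = 10^(mean dB offset / 10)`, so the objective
#' reduces to the population variance of the dB residual over the band.
#'
#' @param bsc a `qus_bsc`, strictly positive on the band.
#' @param c_l speed of sound in m/s.
#' @param asd_grid_um candidate diameters, micrometres.
#' @param band optional analysis band (MHz); defaults to the curve's span.
#' @return list with `ASD` (um), `AAC_dB` (10 log10 n_z), `fit_residual`
#'   (mean squared dB error) and `low_confidence` flag set when the
#'   objective is essentially flat across the grid.
#' @export
fit_gaussian_form_factor <- function(bsc, c_l = 1540,
                                     asd_grid_um = seq(10, 200, by = 1),
                                     band = NULL) {
  stopifnot(inherits(bsc, "qus_bsc"), length(asd_grid_um) >= 1)
  if (is.null(band)) band <- range(bsc$freq_MHz)
  idx <- band_index(bsc$freq_MHz, band)
  f <- bsc$freq_MHz[idx]
  if (any(bsc$sigma[idx] <= 0)) stop("BSC must be positive on the band")
  meas_db <- 10 * log10(bsc$sigma[idx])
  theor <- form_factor_design(f, asd_grid_um, c_l)   # n_asd x n_f
  resid <- sweep(-theor, 2, meas_db, `+`)            # meas - theor
  offset <- rowMeans(resid)
  centred <- resid - offset
  obj <- rowMeans(centred^2)
  i <- which.min(obj)
  flat <- (max(obj) - min(obj)) < 1e-9
  list(ASD = asd_grid_um[i], AAC_dB = offset[i], fit_residual = obj[i],
       low_confidence = flat)
}

# design matrix of theoretical dB BSC (without n_z) for a frequency grid
form_factor_design <- function(f_MHz, asd_grid_um, c_l) {
  t(vapply(asd_grid_um, function(a) gaussian_form_factor_db(f_MHz, a, c_l),
           numeric(length(f_MHz))))
}
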