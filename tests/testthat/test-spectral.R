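make_frame <- function(f_signal_MHz = 5, n = 256, n_lines = 4, fs = 40e6,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  g <- acquisition_geometry(fs, 1540, 6.5e6, c(3, 8), n_lines,
                            0.01, n)
  t <- (0:(n - 1)) / fs
  base <- sin(2 * pi * f_signal_MHz * 1e6 * t)
  s <- matrix(rep(base, n_lines), n, n_lines) +
    matrix(rnorm(n * n_lines, sd = noise_sd), n, n_lines)
  rf_frame(s, g)
}

test_that("window spectrum peaks at the tone frequency and averages lines", {
  fr <- make_frame(5)
  sp <- compute_window_spectrum(fr, c(0, 256), c(0, 4))
  expect_equal(sp$freq_MHz[which.max(sp$power_db)], 5, tolerance = 0.05)
  # identical lines: averaging is idempotent
  sp1 <- compute_window_spectrum(fr, c(0, 256), c(0, 1))
  expect_equal(sp$power_db, sp1$power_db)
  expect_equal(sp$n_lines_averaged, 4)
  # window geometry bookkeeping: R from proximal edge, dz from gate length
  sp2 <- compute_window_spectrum(fr, c(64, 128), c(0, 2))
  expect_equal(sp2$R_cm, 64 * 1540 / (2 * 40e6) * 100)
  expect_equal(sp2$dz_cm, 64 * 1540 / (2 * 40e6) * 100)
  expect_error(compute_window_spectrum(fr, c(0, 3), c(0, 2)), "4 axial")
  expect_error(compute_window_spectrum(fr, c(0, 512), c(0, 2)), "bounds")
})

test_that("averaging K lines cuts periodogram variance about K-fold", {
  # white-noise Monte-Carlo: variance of dB-domain periodogram ordinates
  set.seed(99)
  K <- 17; n <- 64; reps <- 200
  g <- acquisition_geometry(40e6, 1540, 6.5e6, c(3, 8), K, 0.01, n)
  p1 <- matrix(0, reps, 3); pK <- matrix(0, reps, 3)
  bins <- c(10, 16, 22)
  for (r in seq_len(reps)) {
    fr <- rf_frame(matrix(rnorm(n * K), n, K), g)
    sK <- compute_window_spectrum(fr, c(0, n), c(0, K))
    s1 <- compute_window_spectrum(fr, c(0, n), c(0, 1))
    pK[r, ] <- 10^(sK$power_db[bins] / 10)
    p1[r, ] <- 10^(s1$power_db[bins] / 10)
  }
  ratio <- apply(p1, 2, var) / apply(pK, 2, var)
  expect_gt(mean(ratio), K * 0.6)
  expect_lt(mean(ratio), K * 1.6)
})

mk_spec <- function(power_db, freq, R_cm, dz_cm = 0.2, n_lines = 10) {
  structure(list(freq_MHz = freq, power_db = power_db,
                 n_lines_averaged = n_lines, R_cm = R_cm, dz_cm = dz_cm),
            class = "qus_spectrum")
}

test_that("spectral-difference ACE inverts forward-constructed spectra", {
  freq <- seq(2, 9, by = 0.1)
  depths <- seq(1, 2, by = 0.1)   # cm, window proximal edges
  base <- -0.5 * freq + 30
  dbeta <- 0.214
  sample <- lapply(depths, function(R)
    mk_spec(base - 2 * dbeta * freq * (R + 0.1), freq, R))
  reference <- lapply(depths, function(R) mk_spec(base, freq, R))
  ace <- estimate_ace_spectral_difference(sample, reference, c(3, 8),
                                          beta_ref = 0.786)
  expect_equal(ace$slope, 1.000, tolerance = 1e-10)
  # zero difference: ACE equals the reference slope
  ace0 <- estimate_ace_spectral_difference(reference, reference, c(3, 8))
  expect_equal(ace0$slope, 0.786)
  expect_error(estimate_ace_spectral_difference(sample[1:2], reference[1:2],
                                                c(3, 8)), "3 depth")
})

test_that("compute_bsc implements the normalization identity and exponent", {
  freq <- seq(2.5, 8.5, by = 0.25)
  phantom <- reference_phantom(
    bsc_curve = data.frame(f_MHz = freq, sigma = 1e-4 * freq^4))
  s <- mk_spec(rep(40, length(freq)), freq, R_cm = 1.9, dz_cm = 0.2)
  r <- mk_spec(rep(40, length(freq)), freq, R_cm = 1.9, dz_cm = 0.2)
  # matched spectra and attenuations: sigma_m == sigma_r
  b <- compute_bsc(s, r, phantom, attenuation_model(0.786), band = c(3, 8))
  expect_equal(b$sigma,
               approx(freq, 1e-4 * freq^4, xout = b$freq_MHz)$y)
  # doubling the sample power doubles the BSC
  s2 <- mk_spec(rep(40, length(freq)) + 10 * log10(2), freq, 1.9, 0.2)
  b2 <- compute_bsc(s2, r, phantom, attenuation_model(0.786), band = c(3, 8))
  expect_equal(b2$sigma, 2 * b$sigma)
  # attenuation exponent: 0.1 Np/cm at f over R + dz/2 = 2 cm -> e^0.8
  beta_m <- 0.786 + 0.1 / (log(10) / 20)   # 0.1 Np/cm/MHz above reference
  b3 <- compute_bsc(s, r, phantom, attenuation_model(beta_m), band = c(3, 8))
  f <- b3$freq_MHz
  expect_equal(b3$sigma / b$sigma, exp(4 * 0.1 * f * 2), tolerance = 1e-10)
  expect_equal(exp(0.8), 2.2255, tolerance = 1e-4)
})

test_that("linear spectral fit matches exact and noisy oracles", {
  freq <- seq(3, 8, by = 0.1)
  fit <- fit_linear_spectrum(mk_spec(2 * freq + 3, freq, 1), c(3, 8))
  expect_equal(fit$SS, 2)
  expect_equal(fit$SI, 3)
  expect_equal(fit$MBF, 2 * 5.5 + 3)
  flat <- fit_linear_spectrum(mk_spec(rep(7, length(freq)), freq, 1), c(3, 8))
  expect_equal(unlist(flat[c("MBF", "SS", "SI")]),
               c(MBF = 7, SS = 0, SI = 7))
  # noisy case against the closed-form normal-equations oracle
  set.seed(3)
  y <- 1.5 * freq - 4 + rnorm(length(freq), sd = 0.8)
  fit2 <- fit_linear_spectrum(mk_spec(y, freq, 1), c(3, 8))
  A <- cbind(1, freq)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(fit2$SI, beta[1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit2$SS, beta[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_linear_spectrum(mk_spec(y, freq, 1), c(10, 12)), "band")
})

test_that("MBF always equals SS * f_c + SI", {
  set.seed(8)
  freq <- seq(3, 8, by = 0.05)
  for (i in 1:20) {
    y <- rnorm(1, 0, 3) * freq + rnorm(1, 0, 10) + rnorm(length(freq))
    fit <- fit_linear_spectrum(mk_spec(y, freq, 1), c(3, 8))
    expect_equal(fit$MBF, fit$SS * fit$f_center + fit$SI)
  }
})

test_that("Gaussian form-factor fit recovers forward-generated parameters", {
  b <- synthesize_bsc(50, 42, band = c(3, 8))
  fit <- fit_gaussian_form_factor(b)
  expect_equal(fit$ASD, 50)
  expect_equal(fit$AAC_dB, 42, tolerance = 0.01)
  expect_false(fit$low_confidence)
  # f^4 spectrum (F -> 1 limit): smallest diameter on the grid wins
  f <- seq(3, 8, by = 0.1)
  ray <- structure(list(freq_MHz = f, sigma = 1e-3 * f^4),
                   class = "qus_bsc")
  grid <- seq(10, 200, by = 1)
  expect_equal(fit_gaussian_form_factor(ray, asd_grid_um = grid)$ASD, 10)
  # determinism for fixed grid and input
  expect_identical(fit_gaussian_form_factor(b), fit_gaussian_form_factor(b))
})

test_that("form-factor fit tolerates 0.5 dB noise (median ASD error < 10%)", {
  set.seed(21)
  errs <- replicate(50, {
    b <- synthesize_bsc(70, 44, band = c(3, 8))
    b$sigma <- 10^((10 * log10(b$sigma) +
                      rnorm(length(b$sigma), sd = 0.5)) / 10)
    abs(fit_gaussian_form_factor(b)$ASD - 70) / 70
  })
  expect_lt(median(errs), 0.10)
})
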