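#' Read and write RF studies
#'
#' An RF study on disk is a directory containing one little-endian float32
#' binary file per frame (`frame_000.bin`, axial-sample-major, i.e. samples
#' along one scan line are contiguous), a `study.json` sidecar with the
#' acquisition geometry, and an optional `rois.json` with tumour-core
#' contours as lists of `[x_mm, z_mm]` vertices per frame.
#'
#' @param study list with elements `frames` (list of [rf_frame()]),
#'   `geometry`, and optionally `contours` (list of n x 2 matrices, mm).
#' @param path directory to write to / read from.
#' @return `load_rf_study` returns a list of class `qus_rf_study` with
#'   `frames`, `geometry` and `contours`.
#' @export
write_rf_study <- function(study, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- study$geometry
  stopifnot(inherits(g, "qus_geometry"))
  meta <- list(
    sampling_frequency_hz = g$sampling_frequency,
    speed_of_sound_m_s = g$speed_of_sound,
    center_frequency_hz = g$center_frequency,
    analysis_band_mhz = g$analysis_band,
    n_lines = g$n_lines,
    lateral_fov_m = g$lateral_fov,
    axial_samples = g$axial_samples,
    n_frames = length(study$frames),
    sample_format = "float32_le_axial_major"
  )
  jsonlite::write_json(meta, file.path(path, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(study$frames)) {
    fr <- study$frames[[i]]
    con <- file(file.path(path, sprintf("frame_%03d.bin", i - 1L)), "wb")
    writeBin(as.numeric(fr$samples), con, size = 4L, endian = "little")
    close(con)
  }
  if (!is.null(study$contours)) {
    cts <- lapply(study$contours, function(m) {
      if (is.null(m)) list() else unname(apply(m, 1, as.list))
    })
    jsonlite::write_json(cts, file.path(path, "rois.json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_rf_study
#' @export
load_rf_study <- function(path) {
  meta_path <- file.path(path, "study.json")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("sampling_frequency_hz", "speed_of_sound_m_s",
                "center_frequency_hz", "analysis_band_mhz", "n_lines",
                "lateral_fov_m", "axial_samples", "n_frames")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("study.json is missing required field(s): ",
         paste(missing, collapse = ", "))
  geom <- acquisition_geometry(
    meta$sampling_frequency_hz, meta$speed_of_sound_m_s,
    meta$center_frequency_hz, meta$analysis_band_mhz,
    meta$n_lines, meta$lateral_fov_m, meta$axial_samples)
  n_expected <- geom$axial_samples * geom$n_lines
  frames <- vector("list", meta$n_frames)
  for (i in seq_len(meta$n_frames)) {
    f <- file.path(path, sprintf("frame_%03d.bin", i - 1L))
    if (!file.exists(f)) stop("missing frame file: ", f)
    n_avail <- file.size(f) / 4L
    if (n_avail != n_expected)
      stop("frame ", f, " holds ", n_avail, " samples but sidecar implies ",
           geom$axial_samples, " x ", geom$n_lines, " = ", n_expected)
    con <- file(f, "rb")
    v <- readBin(con, "numeric", n = n_expected, size = 4L, endian = "little")
    close(con)
    frames[[i]] <- rf_frame(matrix(v, nrow = geom$axial_samples),
                            geom, sprintf("frame_%03d", i - 1L))
  }
  contours <- NULL
  roi_path <- file.path(path, "rois.json")
  if (file.exists(roi_path)) {
    raw <- jsonlite::read_json(roi_path, simplifyVector = FALSE)
    contours <- lapply(raw, function(ct) {
      if (length(ct) == 0) return(NULL)
      do.call(rbind, lapply(ct, function(v) as.numeric(unlist(v))))
    })
  }
  structure(list(frames = frames, geometry = geom, contours = contours),
            class = "qus_rf_study")
}

#' Reference phantom specification
#'
#' The reference phantom used for power-spectrum normalization: a homogeneous
#' well-characterized medium with known attenuation slope and sound speed,
#' plus either a tabulated backscatter coefficient curve over the analysis
#' band or matched RF frames (or both). Attenuation and BSC values follow
#' the convention used throughout the package: attenuation slopes in
#' dB/cm/MHz (one-way), BSC in relative units consistent across sample and
#' reference.
#'
#' @param attenuation_slope dB/cm/MHz, must be > 0. Default 0.786.
#' @param speed_of_sound m/s. Default 1540.
#' @param bsc_curve data.frame with columns `f_MHz` and `sigma` (positive).
#' @param frames optional list of matched [rf_frame()] objects.
#' @export
reference_phantom <- function(attenuation_slope = 0.786,
                              speed_of_sound = 1540,
                              bsc_curve = NULL, frames = NULL) {
  if (attenuation_slope <= 0) stop("attenuation_slope must be > 0")
  if (!is.null(bsc_curve)) {
    stopifnot(all(c("f_MHz", "sigma") %in% names(bsc_curve)))
    if (any(bsc_curve$sigma <= 0))
      stop("reference bsc_curve must be strictly positive")
  }
  structure(list(attenuation_slope = attenuation_slope,
                 speed_of_sound = speed_of_sound,
                 bsc_curve = bsc_curve, frames = frames),
            class = "qus_reference_phantom")
}

#' @rdname reference_phantom
#' @param phantom a `qus_reference_phantom`.
#' @param path file path for the JSON representation.
#' @export
write_reference_phantom <- function(phantom, path) {
  obj <- list(attenuation_slope_db_cm_mhz = phantom$attenuation_slope,
              speed_of_sound_m_s = phantom$speed_of_sound)
  if (!is.null(phantom$bsc_curve))
    obj$bsc_curve <- list(f_MHz = phantom$bsc_curve$f_MHz,
                          sigma = phantom$bsc_curve$sigma)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname reference_phantom
#' @export
read_reference_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curve <- NULL
  if (!is.null(obj$bsc_curve))
    curve <- data.frame(f_MHz = obj$bsc_curve$f_MHz,
                        sigma = obj$bsc_curve$sigma)
  reference_phantom(obj$attenuation_slope_db_cm_mhz,
                    obj$speed_of_sound_m_s, curve)
}
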