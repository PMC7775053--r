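#' Acquisition geometry of a beamformed RF frame
#'
#' Bundles the acquisition parameters needed to map RF sample indices to
#' physical coordinates: depth of axial sample \code{i} (0-based) is
#' \code{z = i * c / (2 * fs)} and the lateral position of scan line \code{j}
#' is \code{x = j * lateral_fov / n_lines}.
#'
#' @param sampling_frequency RF sampling frequency in Hz.
#' @param speed_of_sound assumed sound speed in m/s.
#' @param center_frequency transducer center frequency in Hz.
#' @param analysis_band numeric length-2, analysis bandwidth in MHz
#'   (low, high).
#' @param n_lines number of scan lines per frame.
#' @param lateral_fov lateral field of view in m.
#' @param axial_samples number of axial samples per line.
#' @return An object of class \code{qus_geometry}.
#' @examples
#' geom <- acquisition_geometry(40e6, 1540, 6.5e6, c(3, 8), 512, 0.06, 2078)
#' wavelength_m(geom) * 1e3  # acoustic wavelength, mm
#' @export
acquisition_geometry <- function(sampling_frequency, speed_of_sound,
                                 center_frequency, analysis_band,
                                 n_lines, lateral_fov, axial_samples) {
  stopifnot(length(analysis_band) == 2L)
  if (!is.finite(sampling_frequency) || sampling_frequency <= 0)
    stop("sampling_frequency must be positive")
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive")
  if (center_frequency <= 0) stop("center_frequency must be positive")
  if (analysis_band[1] <= 0 || analysis_band[2] <= analysis_band[1])
    stop("analysis_band must be an increasing positive pair (MHz)")
  if (sampling_frequency <= 2 * analysis_band[2] * 1e6)
    stop("sampling_frequency violates Nyquist for the analysis band: ",
         sampling_frequency, " Hz vs band top ", analysis_band[2], " MHz")
  if (n_lines < 1 || lateral_fov <= 0)
    stop("n_lines and lateral_fov must be positive")
  if (axial_samples < 1) stop("axial_samples must be >= 1")
  structure(list(
    sampling_frequency = sampling_frequency,
    speed_of_sound = speed_of_sound,
    center_frequency = center_frequency,
    analysis_band = as.numeric(analysis_band),
    n_lines = as.integer(n_lines),
    lateral_fov = lateral_fov,
    axial_samples = as.integer(axial_samples)
  ), class = "qus_geometry")
}

#' @rdname acquisition_geometry
#' @param geometry a \code{qus_geometry} object.
#' @export
wavelength_m <- function(geometry) {
  geometry$speed_of_sound / geometry$center_frequency
}

#' @rdname acquisition_geometry
#' @export
line_spacing_m <- function(geometry) {
  geometry$lateral_fov / geometry$n_lines
}

#' @rdname acquisition_geometry
#' @export
axial_step_m <- function(geometry) {
  geometry$speed_of_sound / (2 * geometry$sampling_frequency)
}

# depth (m) of each axial sample, 0-based indexing
depth_axis_m <- function(geometry) {
  (seq_len(geometry$axial_samples) - 1L) * axial_step_m(geometry)
}

lateral_axis_m <- function(geometry) {
  (seq_len(geometry$n_lines) - 1L) * line_spacing_m(geometry)
}

#' A single beamformed RF frame
#'
#' @param samples numeric matrix, axial samples in rows, scan lines in
#'   columns; dimensions must match the geometry.
#' @param geometry a \code{qus_geometry}.
#' @param frame_id identifier string.
#' @return An object of class \code{qus_rf_frame}.
#' @export
rf_frame <- function(samples, geometry, frame_id = "frame_000") {
  stopifnot(inherits(geometry, "qus_geometry"), is.matrix(samples))
  if (nrow(samples) != geometry$axial_samples)
    stop("frame has ", nrow(samples), " axial samples but geometry declares ",
         geometry$axial_samples)
  if (ncol(samples) != geometry$n_lines)
    stop("frame has ", ncol(samples), " lines but geometry declares n_lines=",
         geometry$n_lines)
  if (!all(is.finite(samples))) stop("RF samples must be finite")
  structure(list(samples = samples, geometry = geometry,
                 frame_id = frame_id),
            class = "qus_rf_frame")
}

#' Regular pixel grid of a parametric image, in physical mm
#'
#' Pixel (r, c) (1-based) has its center at
#' \code{x = origin_x + (c - 1) * dx} and \code{z = origin_z + (r - 1) * dz}.
#' Rows run along depth (z), columns along the lateral direction (x).
#'
#' @param origin_mm numeric length-2 \code{(x0, z0)}: center of pixel (1, 1).
#' @param spacing_mm numeric length-2 \code{(dx, dz)}.
#' @param dims integer length-2 \code{(n_rows, n_cols)} = (n_z, n_x).
#' @export
pixel_grid <- function(origin_mm, spacing_mm, dims) {
  stopifnot(length(origin_mm) == 2L, length(spacing_mm) == 2L,
            length(dims) == 2L, all(spacing_mm > 0), all(dims >= 1))
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 dims = as.integer(dims)),
            class = "qus_pixel_grid")
}

grid_x_centers <- function(grid) {
  grid$origin_mm[1] + (seq_len(grid$dims[2]) - 1) * grid$spacing_mm[1]
}

grid_z_centers <- function(grid) {
  grid$origin_mm[2] + (seq_len(grid$dims[1]) - 1) * grid$spacing_mm[2]
}
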