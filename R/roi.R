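# ROI rasterization and margin construction in physical (mm) coordinates.

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test. Points that fall exactly on a polygon
#' edge count as inside (deterministic tie rule).
#'
#' @param px,pz numeric vectors of point coordinates (mm).
#' @param poly n x 2 matrix of polygon vertices `(x, z)` in mm; the polygon
#'   is closed implicitly (last vertex connects to the first).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, pz, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; zi <- poly[i, 2]
    xj <- poly[j, 1]; zj <- poly[j, 2]
    # exact on-edge detection: collinear and within the segment bbox
    cross <- (px - xi) * (zj - zi) - (pz - zi) * (xj - xi)
    seg <- abs(cross) < 1e-12 &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      pz >= pmin(zi, zj) - 1e-12 & pz <= pmax(zi, zj) + 1e-12
    on_edge <- on_edge | seg
    crosses <- ((zi > pz) != (zj > pz)) &
      (px < (xj - xi) * (pz - zi) / (zj - zi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize a tumour contour onto a parametric-image pixel grid
#'
#' A pixel belongs to the region iff its center lies inside the polygon
#' under the even-odd rule; centers exactly on an edge count as inside.
#'
#' @param contour n x 2 matrix of `(x_mm, z_mm)` vertices, n >= 3.
#' @param grid a [pixel_grid()].
#' @param region_kind `"core"` or `"margin"`.
#' @return An object of class `qus_roi_mask`: logical matrix `mask`
#'   (same dims as the grid), `region_kind`, `grid`, `usable` flag.
#' @export
rasterize_roi <- function(contour, grid, region_kind = "core") {
  stopifnot(inherits(grid, "qus_pixel_grid"))
  if (is.null(contour) || nrow(contour) < 3)
    stop("contour must have at least 3 vertices")
  xs <- grid_x_centers(grid)
  zs <- grid_z_centers(grid)
  pts_x <- rep(xs, each = length(zs))
  pts_z <- rep(zs, times = length(xs))
  m <- matrix(point_in_polygon(pts_x, pts_z, contour),
              nrow = length(zs), ncol = length(xs))
  roi_mask(m, grid, region_kind)
}

roi_mask <- function(mask, grid, region_kind = "core") {
  structure(list(mask = mask, grid = grid, region_kind = region_kind,
                 usable = any(mask)),
            class = "qus_roi_mask")
}

# Felzenszwalb-Huttenlocher 1-D squared distance transform along a vector.
# f: squared distances at sites (Inf where no site), h: sample spacing.
dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + (q * h)^2) - (f[p] + (p * h)^2)) / (2 * h * (q - p))
      }
      if (s <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q * h) k <- k + 1L
    p <- v[k]
    d[q] <- (q * h - p * h)^2 + f[p]
  }
  d
}

# Exact Euclidean distance transform (mm) to the TRUE pixels of `mask`,
# respecting anisotropic pixel spacing. Returns a matrix of distances.
distance_transform_mm <- function(mask, spacing_mm) {
  dz <- spacing_mm[2]; dx <- spacing_mm[1]
  f <- ifelse(mask, 0, Inf)
  # columns first (axial direction, spacing dz)
  g <- apply(f, 2, dt1d, h = dz)
  # then rows (lateral direction, spacing dx)
  g <- t(apply(g, 1, dt1d, h = dx))
  sqrt(g)
}

#' Build the peritumoural margin ring around a core ROI
#'
#' The margin is the set of pixels outside the core whose centers lie within
#' a Euclidean distance of `distance_mm` (default 5 mm) of the core,
#' measured in physical millimetres (anisotropic pixels respected), clipped
#' at the image bounds. It is disjoint from the core by construction.
#'
#' @param core a `qus_roi_mask` with at least one TRUE pixel.
#' @param distance_mm maximum margin extension in mm (> 0).
#' @return a `qus_roi_mask` with `region_kind = "margin"`.
#' @export
build_margin <- function(core, distance_mm = 5) {
  stopifnot(inherits(core, "qus_roi_mask"))
  if (!any(core$mask)) stop("core ROI is empty")
  if (distance_mm <= 0) stop("distance_mm must be > 0")
  d <- distance_transform_mm(core$mask, core$grid$spacing_mm)
  m <- (d <= distance_mm) & !core$mask
  roi_mask(m, core$grid, "margin")
}
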