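# Gray-level texture analysis of parametric images over irregular masks:
# 16-level quantization, co-occurrence (GLCM), run-length (GRLM) and
# size-zone (GLSZM) matrices and their derived features.
#
# Mask handling: co-occurring pairs require both pixels inside the mask;
# runs and zones are broken at mask boundaries; the N used by run/zone
# percentage features is the masked pixel count.

#' Quantize a parametric map over an ROI into discrete gray levels
#'
#' Linear scaling of the full masked value range into `n_levels` levels:
#' `level = 1 + floor(n_levels * (v - min) / (max - min))`, with the
#' maximum mapped to `n_levels`. A constant region maps entirely to level
#' 1. Pixels outside the mask are `NA`.
#'
#' @param map numeric matrix.
#' @param mask `qus_roi_mask` or logical matrix, same dims.
#' @param n_levels number of gray levels (default 16).
#' @return object of class `qus_quantized`: integer matrix `levels` with
#'   `NA` outside the mask, plus `n_levels` and the `bounds` used.
#' @export
quantize_roi <- function(map, mask, n_levels = 16) {
  m <- if (inherits(mask, "qus_roi_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(map)), n_levels >= 2)
  v <- map[m]
  if (length(v) < 1) stop("empty mask")
  if (!all(is.finite(v))) stop("map must be finite on the mask")
  lo <- min(v); hi <- max(v)
  lv <- matrix(NA_integer_, nrow(map), ncol(map))
  if (hi > lo) {
    q <- 1L + as.integer(floor(n_levels * (map[m] - lo) / (hi - lo)))
    q[q > n_levels] <- as.integer(n_levels)
    lv[m] <- q
  } else {
    lv[m] <- 1L
  }
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 bounds = c(lo, hi)),
            class = "qus_quantized")
}

# (drow, dcol) offset for a direction in degrees; rows increase downward.
# 0 deg: horizontal; 45: up-right; 90: vertical; 135: up-left.
angle_offset <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix over a masked image
#'
#' Counts pairs of masked pixels separated by `distance` pixels along
#' `angle`, symmetrizes (transpose added) and normalizes to probabilities.
#'
#' @param q a [quantize_roi()] result.
#' @param distance inter-pixel distance in pixels (1..5 typical).
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @return `N_g x N_g` probability matrix of class `qus_glcm`.
#' @export
compute_glcm <- function(q, distance = 1, angle = 0) {
  stopifnot(inherits(q, "qus_quantized"), distance >= 1)
  off <- angle_offset(angle) * as.integer(distance)
  lv <- q$levels
  nr <- nrow(lv); nc <- ncol(lv)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) < 1 || length(c1) < 1 ||
      (nr - abs(off[1])) < 1 || (nc - abs(off[2])) < 1)
    stop("no valid pixel pairs at this offset")
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("ROI admits no valid co-occurring pairs at distance ",
                     distance, ", angle ", angle)
  ng <- q$n_levels
  counts <- matrix(0, ng, ng)
  tab <- table(factor(a[ok], levels = 1:ng), factor(b[ok], levels = 1:ng))
  counts <- counts + unclass(tab)
  counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(p, class = c("qus_glcm", "matrix"),
            distance = distance, angle = angle)
}

#' GLCM features: contrast, correlation, energy, homogeneity
#'
#' @param p a normalized (symmetric) GLCM probability matrix.
#' @return named list `CON`, `COR`, `ENE`, `HOM`; `COR` is `NA` for a
#'   constant region (zero marginal spread).
#' @export
glcm_features <- function(p) {
  p <- unclass(p)
  ng <- nrow(p)
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum((1:ng) * pi_); mu_j <- sum((1:ng) * pj_)
  s_i <- sqrt(sum((1:ng - mu_i)^2 * pi_))
  s_j <- sqrt(sum((1:ng - mu_j)^2 * pj_))
  cor <- if (s_i * s_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else NA_real_
  list(CON = sum((i - j)^2 * p),
       COR = cor,
       ENE = sum(p^2),
       HOM = sum(p / (1 + abs(i - j))))
}

# Extract all maximal lines of the level image along a direction, as a list
# of integer vectors (NA where unmasked).
direction_lines <- function(lv, angle) {
  nr <- nrow(lv); nc <- ncol(lv)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) lv[r, ]),
    "90" = lapply(seq_len(nc), function(c) lv[, c]),
    "45" = lapply(seq(2, nr + nc), function(ssum) {
      # up-right movement keeps r + c constant (anti-diagonals)
      r <- seq_len(nr); c <- ssum - r
      ok <- c >= 1 & c <= nc
      lv[cbind(r[ok], c[ok])]
    }),
    "135" = lapply(seq(-(nr - 1), nc - 1), function(d) {
      # up-left movement keeps c - r constant (main diagonals)
      r <- seq_len(nr); c <- r + d
      ok <- c >= 1 & c <= nc
      lv[cbind(rev(r[ok]), rev(c[ok]))]
    }),
    stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level run-length matrix
#'
#' A run is a maximal set of consecutive collinear masked pixels with the
#' same gray level in direction `angle`; runs break at mask boundaries.
#'
#' @param q a [quantize_roi()] result.
#' @param angle direction in degrees: 0, 45, 90, 135.
#' @return matrix `N_g x N_r` of run counts (class `qus_grlm`) with
#'   attribute `n_pixels` (masked pixel count).
#' @export
compute_grlm <- function(q, angle = 0) {
  stopifnot(inherits(q, "qus_quantized"))
  lv <- q$levels
  n_pixels <- sum(!is.na(lv))
  if (n_pixels < 1) stop("empty quantized image")
  runs_level <- integer(0); runs_len <- integer(0)
  for (line in direction_lines(lv, angle)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    runs_level <- c(runs_level, r$values[keep])
    runs_len <- c(runs_len, r$lengths[keep])
  }
  nrl <- max(runs_len)
  m <- matrix(0, q$n_levels, nrl)
  for (k in seq_along(runs_level))
    m[runs_level[k], runs_len[k]] <- m[runs_level[k], runs_len[k]] + 1
  structure(m, class = c("qus_grlm", "matrix"),
            angle = angle, n_pixels = n_pixels)
}

#' Run-length features (14)
#'
#' Emphasis and nonuniformity features use raw run counts with `1/s`
#' prefactors (`s` = total number of runs); run percentage uses `1/N`
#' (`N` = masked pixel count); the variance and entropy features are
#' evaluated on the count matrix normalized by `s` so the means involved
#' are proper expectations. `0 log 0` terms contribute 0.
#'
#' @param m a `qus_grlm` matrix.
#' @return named list of SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE,
#'   LRLGE, LRHGE, GV, RV, RE.
#' @export
grlm_features <- function(m) {
  n_pixels <- attr(m, "n_pixels")
  m <- unclass(m)
  ng <- nrow(m); nrl <- ncol(m)
  i <- matrix(1:ng, ng, nrl)
  j <- matrix(1:nrl, ng, nrl, byrow = TRUE)
  s <- sum(m)
  p <- m / s
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  plog <- ifelse(p > 0, p * log2(p), 0)
  list(
    SRE = sum(m / j^2) / s,
    LRE = sum(m * j^2) / s,
    GLN = sum(rowSums(m)^2) / s,
    RLN = sum(colSums(m)^2) / s,
    RP = s / n_pixels,
    LGRE = sum(m / i^2) / s,
    HGRE = sum(m * i^2) / s,
    SRLGE = sum(m / (i^2 * j^2)) / s,
    SRHGE = sum(m * i^2 / j^2) / s,
    LRLGE = sum(m * j^2 / i^2) / s,
    LRHGE = sum(m * i^2 * j^2) / s,
    GV = sum(p * (i - mu_i)^2),
    RV = sum(p * (j - mu_j)^2),
    RE = -sum(plog))
}

# iterative 8-connected flood fill labelling of equal-level zones
label_zones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  shifts <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (idx in which(!is.na(lv) & labels == 0L)) {
    if (labels[idx] != 0L) next
    cur <- cur + 1L
    level <- lv[idx]
    stack <- idx
    labels[idx] <- cur
    while (length(stack)) {
      pix <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (pix - 1L) %% nr + 1L
      c <- (pix - 1L) %/% nr + 1L
      for (k in 1:8) {
        rr <- r + shifts[k, 1]; cc <- c + shifts[k, 2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        nb <- (cc - 1L) * nr + rr
        if (labels[nb] == 0L && !is.na(lv[nb]) && lv[nb] == level) {
          labels[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  labels
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal gray level inside the mask;
#' the matrix is direction independent.
#'
#' @param q a [quantize_roi()] result.
#' @return matrix `N_g x N_s` (`N_s` = largest zone size) of zone counts,
#'   class `qus_glszm`, with attribute `n_pixels`.
#' @export
compute_glszm <- function(q) {
  stopifnot(inherits(q, "qus_quantized"))
  lv <- q$levels
  n_pixels <- sum(!is.na(lv))
  if (n_pixels < 1) stop("empty quantized image")
  labels <- label_zones(lv)
  nz <- max(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = nz)
  zone_level <- vapply(seq_len(nz),
                       function(z) lv[match(z, labels)], integer(1))
  ns <- max(sizes)
  m <- matrix(0, q$n_levels, ns)
  for (z in seq_len(nz))
    m[zone_level[z], sizes[z]] <- m[zone_level[z], sizes[z]] + 1
  structure(m, class = c("qus_glszm", "matrix"), n_pixels = n_pixels)
}

#' Size-zone features (14)
#'
#' Same normalization scheme as [grlm_features()] with the total zone count
#' `N_Z` in place of the run count, and zone percentage `ZP = N_Z / N`.
#' Feature short names follow the reporting convention used in the feature
#' tables (`GLN-SZ`, `GV-SZ` disambiguate from their run-length
#' counterparts; `LGZE`/`HGZE` are the low/high gray-level zone emphases).
#'
#' @param m a `qus_glszm` matrix.
#' @return named list of SAE, LAE, GLN-SZ, SZN, ZP, LGZE, HGZE, SALGE,
#'   SAHGE, LALGE, LAHGE, GV-SZ, ZV, ZE.
#' @export
glszm_features <- function(m) {
  n_pixels <- attr(m, "n_pixels")
  m <- unclass(m)
  ng <- nrow(m); ns <- ncol(m)
  i <- matrix(1:ng, ng, ns)
  j <- matrix(1:ns, ng, ns, byrow = TRUE)
  nz <- sum(m)
  p <- m / nz
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  plog <- ifelse(p > 0, p * log2(p), 0)
  out <- list(
    SAE = sum(m / j^2) / nz,
    LAE = sum(m * j^2) / nz,
    `GLN-SZ` = sum(rowSums(m)^2) / nz,
    SZN = sum(colSums(m)^2) / nz,
    ZP = nz / n_pixels,
    LGZE = sum(m / i^2) / nz,
    HGZE = sum(m * i^2) / nz,
    SALGE = sum(m / (i^2 * j^2)) / nz,
    SAHGE = sum(m * i^2 / j^2) / nz,
    LALGE = sum(m * j^2 / i^2) / nz,
    LAHGE = sum(m * i^2 * j^2) / nz,
    `GV-SZ` = sum(p * (i - mu_i)^2),
    ZV = sum(p * (j - mu_j)^2),
    ZE = -sum(plog))
  out
}

#' Average texture features over a configuration sweep
#'
#' Arithmetic mean per feature name across configurations (e.g. the 5
#' distances x 4 angles of the GLCM sweep, or the 4 GRLM directions).
#' Missing values propagate benignly: the mean is over non-missing entries
#' and a feature missing at every configuration stays missing.
#'
#' @param feature_list list of equally-named feature lists.
#' @return named list of averaged features.
#' @export
aggregate_texture <- function(feature_list) {
  if (length(feature_list) < 1) stop("empty sweep")
  nms <- names(feature_list[[1]])
  for (f in feature_list)
    if (!identical(names(f), nms))
      stop("incomplete or inconsistent configuration sweep")
  out <- lapply(nms, function(nm) {
    v <- vapply(feature_list, function(f) as.numeric(f[[nm]]), 0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out) <- nms
  out
}

#' Full texture sweeps for one quantized region
#'
#' `glcm_texture` averages the 4 GLCM features over distances 1..5 and
#' angles 0/45/90/135 (20 configurations); `grlm_texture` averages the 14
#' run-length features over the 4 directions; `glszm_texture` computes the
#' 14 size-zone features (direction independent). Configurations at which
#' a matrix cannot be formed (ROI too small for the offset) contribute
#' missing values.
#'
#' @param q a [quantize_roi()] result.
#' @param distances,angles sweep parameters.
#' @return named list of averaged features.
#' @export
glcm_texture <- function(q, distances = 1:5, angles = c(0, 45, 90, 135)) {
  configs <- list()
  for (d in distances) for (a in angles) {
    feats <- tryCatch(glcm_features(compute_glcm(q, d, a)),
                      error = function(e)
                        list(CON = NA_real_, COR = NA_real_,
                             ENE = NA_real_, HOM = NA_real_))
    configs[[length(configs) + 1L]] <- feats
  }
  aggregate_texture(configs)
}

#' @rdname glcm_texture
#' @export
grlm_texture <- function(q, angles = c(0, 45, 90, 135)) {
  aggregate_texture(lapply(angles, function(a)
    grlm_features(compute_grlm(q, a))))
}

#' @rdname glcm_texture
#' @export
glszm_texture <- function(q) {
  glszm_features(compute_glszm(q))
}

texture_feature_names <- function(method) {
  switch(method,
         GLCM = c("CON", "COR", "ENE", "HOM"),
         GRLM = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                  "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GV", "RV", "RE"),
         GLSZM = c("SAE", "LAE", "GLN-SZ", "SZN", "ZP", "LGZE", "HGZE",
                   "SALGE", "SAHGE", "LALGE", "LAHGE", "GV-SZ", "ZV", "ZE"),
         stop("unknown texture method: ", method))
}

map_names <- c("MBF", "SS", "SI", "ASD", "AAC")

#' Extract the full per-lesion feature set from parametric images
#'
#' For each scan plane: region means of the five parametric maps over core
#' and margin, texture features of each map over each region, and the
#' CMR/CMCR image-quality features; planes are averaged weighted by the
#' plane's core ROI pixel count. Feature names follow the
#' `Region-Parameter-Feature` convention (e.g. `Core-MBF-CON`,
#' `Margin-ASD-SAE`, `CMR-AAC`), with plain `Core-MBF` for mean values.
#'
#' @param images_list list of `qus_parametric_images`, one per scan plane.
#' @param core_masks,margin_masks lists of `qus_roi_mask` per plane,
#'   aligned to each plane's pixel grid.
#' @param method `"GLCM"`, `"GRLM"` or `"GLSZM"`.
#' @return named numeric vector of 60 (GLCM) or 160 (GRLM/GLSZM) features.
#' @export
extract_lesion_features <- function(images_list, core_masks, margin_masks,
                                    method = c("GLCM", "GRLM", "GLSZM")) {
  method <- match.arg(method)
  stopifnot(length(images_list) == length(core_masks),
            length(images_list) == length(margin_masks))
  per_plane <- list()
  weights <- numeric(0)
  for (k in seq_along(images_list)) {
    img <- images_list[[k]]
    core <- core_masks[[k]]; margin <- margin_masks[[k]]
    if (!any(core$mask)) next
    feats <- plane_features(img, core, margin, method)
    per_plane[[length(per_plane) + 1L]] <- feats
    weights <- c(weights, sum(core$mask))
  }
  if (!length(per_plane)) stop("no usable scan plane (empty core ROIs)")
  nms <- names(per_plane[[1]])
  vals <- vapply(nms, function(nm) {
    v <- vapply(per_plane, function(p) p[[nm]], 0)
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * weights[ok]) / sum(weights[ok])
  }, 0)
  names(vals) <- nms
  vals
}

plane_features <- function(img, core, margin, method) {
  tex_fun <- switch(method, GLCM = glcm_texture, GRLM = grlm_texture,
                    GLSZM = glszm_texture)
  out <- list()
  summaries <- list()
  for (region in c("Core", "Margin")) {
    mask <- if (region == "Core") core else margin
    for (p in map_names) {
      rs <- region_summary(img$maps[[p]], mask)
      summaries[[paste(region, p)]] <- rs
      out[[paste(region, p, sep = "-")]] <- rs$mean
    }
    for (p in map_names) {
      q <- quantize_roi(img$maps[[p]], mask)
      tf <- tex_fun(q)
      for (nm in names(tf))
        out[[paste(region, p, nm, sep = "-")]] <- tf[[nm]]
    }
  }
  for (p in map_names) {
    cs <- summaries[[paste("Core", p)]]
    ms <- summaries[[paste("Margin", p)]]
    out[[paste0("CMR-", p)]] <- compute_cmr(cs, ms)
    out[[paste0("CMCR-", p)]] <- compute_cmcr(cs, ms)
  }
  unlist(out)
}

#' Assemble the cohort feature table for a region/method configuration
#'
#' Selects the feature columns belonging to a configuration from full
#' per-lesion feature vectors and attaches the class label. Column counts
#' are forced by the design: 25 (GLCM, single region), 60 (GLCM,
#' core+margin), 75 (GRLM/GLSZM, single region), 160 (GRLM/GLSZM,
#' core+margin); CMR and CMCR enter only the combined configuration.
#'
#' @param lesion_features list of named numeric vectors from
#'   [extract_lesion_features()] (or compatible).
#' @param labels character/factor vector, `"benign"` or `"malignant"`.
#' @param region `"core"`, `"margin"` or `"both"`.
#' @param method `"GLCM"`, `"GRLM"` or `"GLSZM"`.
#' @return data.frame with the feature columns plus a `label` factor.
#' @export
assemble_feature_table <- function(lesion_features, labels,
                                   region = c("core", "margin", "both"),
                                   method = c("GLCM", "GRLM", "GLSZM")) {
  region <- match.arg(region)
  method <- match.arg(method)
  stopifnot(length(lesion_features) == length(labels))
  cols <- configuration_columns(region, method)
  nms0 <- names(lesion_features[[1]])
  rows <- lapply(lesion_features, function(v) {
    if (!identical(names(v), nms0))
      stop("inconsistent feature names across lesions")
    if (!all(cols %in% names(v)))
      stop("lesion feature vectors lack required columns for ", method,
           "/", region)
    v[cols]
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  df$label <- factor(labels, levels = c("benign", "malignant"))
  df
}

configuration_columns <- function(region, method) {
  tex <- texture_feature_names(method)
  regs <- switch(region, core = "Core", margin = "Margin",
                 both = c("Core", "Margin"))
  cols <- character(0)
  for (r in regs) {
    cols <- c(cols, paste(r, map_names, sep = "-"))
    cols <- c(cols, as.vector(t(outer(map_names, tex,
                                      function(p, t) paste(r, p, t, sep = "-")))))
  }
  if (region == "both")
    cols <- c(cols, paste0("CMR-", map_names), paste0("CMCR-", map_names))
  cols
}
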