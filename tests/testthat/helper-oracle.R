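# Independent brute-force oracles for the texture matrices and features.
# Deliberately naive: explicit loops over pixel pairs, runs found by
# walking each line, zones by repeated neighbour expansion. These share no
# code with the package implementation.

oracle_glcm <- function(lv, d, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  ng <- 16
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
    a <- lv[r, c]; b <- lv[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  con <- 0; ene <- 0; hom <- 0
  for (i in 1:ng) for (j in 1:ng) {
    con <- con + (i - j)^2 * p[i, j]
    ene <- ene + p[i, j]^2
    hom <- hom + p[i, j] / (1 + abs(i - j))
  }
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:ng) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  s_i <- 0; s_j <- 0
  for (i in 1:ng) for (j in 1:ng) {
    s_i <- s_i + (i - mu_i)^2 * p[i, j]
    s_j <- s_j + (j - mu_j)^2 * p[i, j]
  }
  s_i <- sqrt(s_i); s_j <- sqrt(s_j)
  cor <- NA_real_
  if (s_i > 0 && s_j > 0) {
    cor <- 0
    for (i in 1:ng) for (j in 1:ng)
      cor <- cor + (i - mu_i) * (j - mu_j) * p[i, j] / (s_i * s_j)
  }
  list(CON = con, COR = cor, ENE = ene, HOM = hom)
}

# walk every line of the image in the given direction, collecting runs
oracle_runs <- function(lv, angle) {
  nr <- nrow(lv); nc <- ncol(lv)
  step <- switch(as.character(angle),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                 "135" = c(-1, -1))
  # starting cells: those with no in-line predecessor
  runs <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    pr <- r0 - step[1]; pc <- c0 - step[2]
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next
    vals <- c()
    r <- r0; c <- c0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      vals <- c(vals, lv[r, c])
      r <- r + step[1]; c <- c + step[2]
    }
    i <- 1
    while (i <= length(vals)) {
      if (is.na(vals[i])) { i <- i + 1; next }
      j <- i
      while (j < length(vals) && !is.na(vals[j + 1]) &&
             vals[j + 1] == vals[i]) j <- j + 1
      runs[[length(runs) + 1]] <- c(vals[i], j - i + 1)
      i <- j + 1
    }
  }
  runs
}

oracle_grlm <- function(lv, angle) {
  runs <- oracle_runs(lv, angle)
  lens <- vapply(runs, `[`, 0, 2)
  m <- matrix(0, 16, max(lens))
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

oracle_grlm_features <- function(m, n_pixels) {
  s <- sum(m)
  out <- list(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = s / n_pixels,
              LGRE = 0, HGRE = 0, SRLGE = 0, SRHGE = 0, LRLGE = 0,
              LRHGE = 0, GV = 0, RV = 0, RE = 0)
  ng <- nrow(m); nr <- ncol(m)
  for (i in 1:ng) for (j in 1:nr) {
    v <- m[i, j]
    out$SRE <- out$SRE + v / j^2 / s
    out$LRE <- out$LRE + v * j^2 / s
    out$LGRE <- out$LGRE + v / i^2 / s
    out$HGRE <- out$HGRE + v * i^2 / s
    out$SRLGE <- out$SRLGE + v / (i^2 * j^2) / s
    out$SRHGE <- out$SRHGE + v * i^2 / j^2 / s
    out$LRLGE <- out$LRLGE + v * j^2 / i^2 / s
    out$LRHGE <- out$LRHGE + v * i^2 * j^2 / s
  }
  for (i in 1:ng) out$GLN <- out$GLN + sum(m[i, ])^2 / s
  for (j in 1:nr) out$RLN <- out$RLN + sum(m[, j])^2 / s
  p <- m / s
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nr) {
    mu_i <- mu_i + p[i, j] * i; mu_j <- mu_j + p[i, j] * j
  }
  for (i in 1:ng) for (j in 1:nr) {
    out$GV <- out$GV + p[i, j] * (i - mu_i)^2
    out$RV <- out$RV + p[i, j] * (j - mu_j)^2
    if (p[i, j] > 0) out$RE <- out$RE - p[i, j] * log2(p[i, j])
  }
  out
}

# zones by repeated neighbour expansion (8-connectivity)
oracle_zones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0] || is.na(lv[r0, c0])) next
    members <- matrix(c(r0, c0), 1, 2)
    seen[r0, c0] <- TRUE
    repeat {
      added <- FALSE
      for (m in seq_len(nrow(members))) {
        for (dr in -1:1) for (dc in -1:1) {
          r <- members[m, 1] + dr; c <- members[m, 2] + dc
          if (r < 1 || r > nr || c < 1 || c > nc) next
          if (seen[r, c] || is.na(lv[r, c])) next
          if (lv[r, c] == lv[r0, c0]) {
            members <- rbind(members, c(r, c))
            seen[r, c] <- TRUE
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
    zones[[length(zones) + 1]] <- c(lv[r0, c0], nrow(members))
  }
  zones
}

oracle_glszm <- function(lv) {
  zones <- oracle_zones(lv)
  sizes <- vapply(zones, `[`, 0, 2)
  m <- matrix(0, 16, max(sizes))
  for (z in zones) m[z[1], z[2]] <- m[z[1], z[2]] + 1
  m
}

oracle_glszm_features <- function(m, n_pixels) {
  f <- oracle_grlm_features(m, n_pixels)
  nz <- sum(m)
  list(SAE = f$SRE, LAE = f$LRE, `GLN-SZ` = f$GLN, SZN = f$RLN,
       ZP = nz / n_pixels, LGZE = f$LGRE, HGZE = f$HGRE,
       SALGE = f$SRLGE, SAHGE = f$SRHGE, LALGE = f$LRLGE,
       LAHGE = f$LRHGE, `GV-SZ` = f$GV, ZV = f$RV, ZE = f$RE)
}

random_masked_image <- function(seed, nr = 6, nc = 6, levels = 4) {
  set.seed(seed)
  lv <- matrix(sample.int(levels, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) > 0.25, nr, nc)
  lv[!mask] <- NA_integer_
  if (!any(!is.na(lv))) lv[1, 1] <- 1L
  lv
}

# wrap a raw level matrix as a quantized image (bypassing quantize_roi)
as_quantized <- function(lv, n_levels = 16) {
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 bounds = range(lv, na.rm = TRUE)),
            class = "qus_quantized")
}
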