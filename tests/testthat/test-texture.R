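test_that("quantization maps the masked range linearly onto 16 levels", {
  ramp <- matrix(seq(0, 15) * 2 + 5, 4, 4)
  q <- quantize_roi(ramp, matrix(TRUE, 4, 4))
  expect_setequal(as.vector(q$levels), 1:16)
  expect_equal(q$levels[which.min(ramp)], 1L)
  expect_equal(q$levels[which.max(ramp)], 16L)
  # constant region: all level 1
  qc <- quantize_roi(matrix(3, 3, 3), matrix(TRUE, 3, 3))
  expect_true(all(qc$levels == 1L))
  # unmasked pixels are excluded markers
  mask <- matrix(TRUE, 4, 4); mask[1, ] <- FALSE
  qm <- quantize_roi(ramp, mask)
  expect_true(all(is.na(qm$levels[1, ])))
  expect_error(quantize_roi(matrix(NaN, 2, 2), matrix(TRUE, 2, 2)),
               "finite")
})

test_that("GLCM matches hand-enumerated examples", {
  lv <- matrix(c(1L, 2L, 1L, 2L), 2, 2)   # rows: [1,1],[2,2]
  p <- compute_glcm(as_quantized(lv), 1, 0)
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[2, 2], 0.5)
  expect_equal(sum(p), 1)
  f <- glcm_features(p)
  expect_equal(f$CON, 0)
  expect_equal(f$ENE, 0.5)
  expect_equal(f$HOM, 1)
  expect_equal(f$COR, 1)
  # constant image: single entry, correlation undefined
  fc <- glcm_features(compute_glcm(as_quantized(matrix(1L, 3, 3)), 1, 0))
  expect_equal(c(fc$CON, fc$ENE, fc$HOM), c(0, 1, 1))
  expect_true(is.na(fc$COR))
  # checkerboard of levels 1/16 at d = 1: all pairs differ by 15
  cb <- matrix(1L + 15L * ((outer(1:6, 1:6, `+`)) %% 2L), 6, 6)
  expect_equal(glcm_features(compute_glcm(as_quantized(cb), 1, 0))$CON,
               225)
  # mask split: pairs across the excluded column are not counted
  lv2 <- matrix(1L, 3, 5); lv2[, 3] <- NA
  lv2[, 4:5] <- 2L
  p2 <- compute_glcm(as_quantized(lv2), 2, 0)
  expect_equal(unclass(p2), oracle_glcm(lv2, 2, 0), ignore_attr = TRUE)
  expect_error(compute_glcm(as_quantized(matrix(c(1L, NA, NA, 1L), 2, 2)),
                            1, 0), "pairs")
})

test_that("GRLM matches hand-enumerated examples", {
  r <- compute_grlm(as_quantized(matrix(c(1L, 1L, 2L), 1, 3)), 0)
  expect_equal(sum(r), 2)          # two runs
  expect_equal(r[1, 2], 1)         # level 1, length 2
  expect_equal(r[2, 1], 1)         # level 2, length 1
  f <- grlm_features(r)
  expect_equal(f$SRE, 0.5 * (1 / 4 + 1))
  expect_equal(f$LRE, 0.5 * (4 + 1))
  expect_equal(f$RP, 2 / 3)
  # all-distinct row: n runs of length 1
  rd <- compute_grlm(as_quantized(matrix(1:5, 1, 5)), 0)
  expect_equal(dim(rd)[2], 1)
  expect_equal(sum(rd), 5)
  fd <- grlm_features(rd)
  expect_equal(c(fd$SRE, fd$LRE, fd$RP), c(1, 1, 1))
  # constant n x n image scanned horizontally: n runs of length n
  rc <- compute_grlm(as_quantized(matrix(1L, 4, 4)), 0)
  expect_equal(rc[1, 4], 4)
  # single run at level g: HGRE = g^2, LGRE = 1/g^2
  rg <- compute_grlm(as_quantized(matrix(3L, 1, 6)), 0)
  fg <- grlm_features(rg)
  expect_equal(fg$HGRE, 9)
  expect_equal(fg$LGRE, 1 / 9)
})

test_that("GLSZM matches hand examples and uses 8-connectivity", {
  m <- compute_glszm(as_quantized(matrix(c(1L, 2L, 1L, 2L), 2, 2)))
  expect_equal(sum(m), 2)
  f <- glszm_features(m)
  expect_equal(f$SAE, 0.25)
  expect_equal(f$LAE, 4)
  expect_equal(f$ZP, 0.5)
  # constant image: one zone of size n
  n <- 12
  mc <- compute_glszm(as_quantized(matrix(1L, 3, 4)))
  fc <- glszm_features(mc)
  expect_equal(c(fc$SAE, fc$LAE, fc$ZP), c(1 / n^2, n^2, 1 / n))
  # diagonal pair of equal levels: one zone under 8-connectivity
  dg <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_equal(sum(compute_glszm(as_quantized(dg))), 2)  # two 2-px zones
  # two zones at levels 1 and 4 of equal size: HGLZE = (1 + 16) / 2
  two <- matrix(c(1L, 1L, NA, 4L, 4L, NA), 2, 3)
  expect_equal(glszm_features(compute_glszm(as_quantized(two)))$HGZE, 8.5)
})

test_that("all three matrices and 32 features match brute-force oracles", {
  for (seed in 1:12) {
    lv <- random_masked_image(seed)
    q <- as_quantized(lv)
    n_px <- sum(!is.na(lv))
    for (ang in c(0, 45, 90, 135)) {
      for (d in 1:2) {
        po <- oracle_glcm(lv, d, ang)
        got <- tryCatch(compute_glcm(q, d, ang), error = function(e) NULL)
        if (all(is.nan(po))) {
          expect_null(got)
        } else {
          expect_equal(unclass(got), po, ignore_attr = TRUE)
          expect_equal(glcm_features(got), oracle_glcm_features(po))
        }
      }
      go <- oracle_grlm(lv, ang)
      gg <- compute_grlm(q, ang)
      expect_equal(unclass(gg), go, ignore_attr = TRUE)
      expect_equal(grlm_features(gg), oracle_grlm_features(go, n_px))
    }
    zo <- oracle_glszm(lv)
    zg <- compute_glszm(q)
    expect_equal(unclass(zg), zo, ignore_attr = TRUE)
    expect_equal(glszm_features(zg), oracle_glszm_features(zo, n_px))
  }
})

test_that("runs and zones partition the mask (mass conservation)", {
  for (seed in 13:24) {
    lv <- random_masked_image(seed, nr = 8, nc = 7, levels = 5)
    q <- as_quantized(lv)
    n_px <- sum(!is.na(lv))
    for (ang in c(0, 45, 90, 135)) {
      m <- compute_grlm(q, ang)
      expect_equal(sum(m * matrix(1:ncol(m), nrow(m), ncol(m),
                                  byrow = TRUE)), n_px)
    }
    z <- compute_glszm(q)
    expect_equal(sum(z * matrix(1:ncol(z), nrow(z), ncol(z),
                                byrow = TRUE)), n_px)
    expect_gte(sum(z), 1)
  }
})

test_that("GLCM feature ranges hold on random images", {
  for (seed in 25:34) {
    lv <- random_masked_image(seed, levels = 16)
    f <- glcm_features(compute_glcm(as_quantized(lv), 1, 0))
    expect_gt(f$ENE, 0); expect_lte(f$ENE, 1)
    expect_gt(f$HOM, 0); expect_lte(f$HOM, 1)
    expect_gte(f$CON, 0)
    if (!is.na(f$COR)) {
      expect_gte(f$COR, -1); expect_lte(f$COR, 1)
    }
  }
})

test_that("smoothing reduces GLCM contrast and grows GLSZM large areas", {
  blur <- function(m) {
    out <- m
    for (r in 2:(nrow(m) - 1)) for (c in 2:(ncol(m) - 1))
      out[r, c] <- mean(m[(r - 1):(r + 1), (c - 1):(c + 1)])
    out
  }
  mask <- matrix(TRUE, 12, 12)
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rnorm(144), 12, 12)
    q_raw <- quantize_roi(m, mask)
    q_sm <- quantize_roi(blur(m), mask)
    expect_lte(glcm_features(compute_glcm(q_sm, 1, 0))$CON,
               glcm_features(compute_glcm(q_raw, 1, 0))$CON)
    expect_gte(glszm_features(compute_glszm(q_sm))$LAE,
               glszm_features(compute_glszm(q_raw))$LAE)
  }
})

test_that("sweep averaging propagates values and missing flags", {
  a <- list(CON = 1, COR = NA_real_, ENE = 0.5, HOM = 1)
  b <- list(CON = 3, COR = NA_real_, ENE = 0.7, HOM = 0.8)
  avg <- aggregate_texture(list(a, b))
  expect_equal(avg$CON, 2)
  expect_true(is.na(avg$COR))
  expect_equal(avg$ENE, 0.6)
  # identical matrices: the average equals the single value
  expect_equal(aggregate_texture(list(a, a))$CON, a$CON)
  expect_error(aggregate_texture(list(a, list(CON = 1))), "inconsistent")
})

test_that("feature tables carry the forced column counts", {
  set.seed(5)
  mk_lesion <- function() {
    maps <- replicate(5, matrix(rnorm(400), 20, 20), simplify = FALSE)
    names(maps) <- c("MBF", "SS", "SI", "ASD", "AAC")
    img <- structure(list(maps = maps,
                          grid = pixel_grid(c(0.5, 0.5), c(1, 1),
                                            c(20, 20)),
                          frame_id = "f"),
                     class = "qus_parametric_images")
    core_mask <- matrix(FALSE, 20, 20); core_mask[5:12, 5:12] <- TRUE
    margin_mask <- matrix(FALSE, 20, 20); margin_mask[3:16, 3:16] <- TRUE
    margin_mask <- margin_mask & !core_mask
    extract_lesion_features(
      list(img),
      list(qusradiomics:::roi_mask(core_mask, img$grid)),
      list(qusradiomics:::roi_mask(margin_mask, img$grid)),
      "GLSZM")
  }
  lesions <- replicate(6, mk_lesion(), simplify = FALSE)
  labels <- rep(c("benign", "malignant"), 3)
  expect_equal(ncol(assemble_feature_table(lesions, labels, "core",
                                           "GLSZM")), 75 + 1)
  expect_equal(ncol(assemble_feature_table(lesions, labels, "margin",
                                           "GLSZM")), 75 + 1)
  expect_equal(ncol(assemble_feature_table(lesions, labels, "both",
                                           "GLSZM")), 160 + 1)
  # inconsistent names across lesions fail loudly
  bad <- lesions
  names(bad[[2]])[3] <- "Core-XX"
  expect_error(assemble_feature_table(bad, labels, "core", "GLSZM"),
               "inconsistent")
})
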