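test_that("color features respect the mask and match hand arithmetic", {
  img <- array(0.3, c(6, 6, 3)); img[, , 1] <- 0.7
  full <- lesion_mask(matrix(1, 6, 6))
  cf <- color_features(rgb_image(img), full)
  expect_length(cf, 12)
  expect_true(all(cf[grep("_sd$", names(cf))] == 0))
  expect_equal(unname(cf["color_r_mean"]), 0.7)

  # lesion value a inside mask, b outside -> masked mean = a
  img2 <- array(0.2, c(6, 6, 3))
  inside <- matrix(0, 6, 6); inside[2:4, 2:4] <- 1
  for (c in 1:3) img2[, , c][inside == 1] <- 0.9
  cf2 <- color_features(rgb_image(img2), lesion_mask(inside))
  expect_equal(unname(cf2["color_g_mean"]), 0.9)

  # two-pixel region {0.2, 0.4} in R: mean 0.3, population sd 0.1
  img3 <- array(0, c(1, 2, 3)); img3[1, 1, 1] <- 0.2; img3[1, 2, 1] <- 0.4
  cf3 <- color_features(rgb_image(img3), lesion_mask(matrix(1, 1, 2)))
  expect_equal(unname(cf3["color_r_mean"]), 0.3)
  expect_equal(unname(cf3["color_r_sd"]), 0.1)
  expect_error(color_features(rgb_image(img), lesion_mask(matrix(0, 6, 6))),
               "empty mask")
})

test_that("glcm normalizes, localizes mass and matches pair enumeration", {
  const <- gray_image(matrix(0.5, 5, 5))
  gl <- glcm(const, levels = 4)
  for (m in gl) {
    expect_equal(sum(m), 1)
    expect_equal(sum(diag(m)), 1)       # constant region: diagonal only
  }
  # two-level checkerboard, 0 degrees, d = 1: all mass off-diagonal
  cb <- gray_image((outer(1:4, 1:4, `+`) %% 2))
  m <- glcm(cb, levels = 2, angles = 0)[[1]]
  expect_equal(m[1, 1] + m[2, 2], 0)
  expect_equal(m[1, 2] + m[2, 1], 1)
  expect_error(glcm(const, lesion_mask(matrix(0, 5, 5))), "masked pixels")
})

test_that("glcm + haralick equal the brute-force oracle on random images", {
  set.seed(21)
  for (rep in 1:20) {
    g <- matrix(runif(64), 8, 8)
    mask <- matrix(rbinom(64, 1, 0.85), 8, 8)
    if (sum(mask) < 8) mask[] <- 1
    for (ang in c(0, 45, 90, 135)) {
      ref <- oracle_glcm(g, mask, 8, 1, ang)
      got <- glcm(gray_image(g), lesion_mask(mask), levels = 8,
                  angles = ang)[[1]]
      expect_equal(got, ref, tolerance = 1e-12)
      hf <- haralick_features(got)
      ho <- oracle_haralick(ref)
      expect_equal(unname(hf[c("contrast", "dissimilarity", "asm",
                               "homogeneity")]),
                   unname(ho[c("contrast", "dissimilarity", "asm",
                               "homogeneity")]), tolerance = 1e-12)
      expect_equal(unname(hf[c("energy", "correlation")]),
                   unname(ho[c("energy", "correlation")]), tolerance = 1e-9)
    }
  }
})

test_that("haralick descriptors: degenerate case, count, hand values, bounds", {
  p1 <- matrix(0, 3, 3); p1[2, 2] <- 1
  h <- haralick_features(p1)
  expect_length(h, 6)
  expect_equal(unname(h[c("contrast", "dissimilarity", "asm", "homogeneity",
                          "energy", "correlation")]), c(0, 0, 1, 1, 1, 1))
  # checkerboard matrix: two cells of 0.5 at |m-n| = 1
  p2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  h2 <- haralick_features(p2)
  expect_equal(unname(h2["contrast"]), 1)
  expect_equal(unname(h2["homogeneity"]), 0.5)
  expect_equal(unname(h2["asm"]), 0.5)
  expect_equal(unname(h2["energy"]), sqrt(0.5))
  expect_error(haralick_features(p2 * 2), "sum to 1")
  # bounds on random normalized matrices
  set.seed(4)
  for (i in 1:25) {
    p <- matrix(runif(16), 4, 4); p <- p / sum(p)
    h <- haralick_features(p)
    expect_gt(h[["homogeneity"]], 0); expect_lte(h[["homogeneity"]], 1)
    expect_gt(h[["asm"]], 0); expect_lte(h[["asm"]], 1)
    expect_gte(h[["contrast"]], 0)
    expect_lte(abs(h[["correlation"]]), 1 + 1e-9)
  }
})

test_that("lbp codes and histogram match the bitwise oracle", {
  # constant region: ties count as 1 -> every code 255
  h <- lbp_histogram(gray_image(matrix(0.5, 5, 5)))
  expect_length(h, 256)
  expect_equal(sum(h), 1)
  expect_equal(unname(h["lbp_255"]), 1)
  # center 0.5, neighbors alternating 0.6/0.4 clockwise from top-left -> 170
  g <- matrix(0.5, 3, 3)
  nb <- c(0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (k in 1:8) g[2 + offs[[k]][1], 2 + offs[[k]][2]] <- nb[k]
  codes <- lesionkit:::lbp_codes(g, matrix(TRUE, 3, 3))
  expect_equal(codes[2, 2], 170L)
  # random 6x6 vs per-pixel oracle
  set.seed(13)
  for (rep in 1:10) {
    g6 <- matrix(runif(36), 6, 6)
    expect_equal(lesionkit:::lbp_codes(g6, matrix(TRUE, 6, 6)),
                 oracle_lbp_codes(g6))
  }
  expect_error(lbp_histogram(gray_image(matrix(runif(36), 6, 6)),
                             lesion_mask(matrix(0, 6, 6))), "3x3 window")
})

test_that("shape features approach analytic disk and square limits", {
  s32 <- shape_features(disk_mask(32))
  expect_lt(abs(s32[["roundness"]] - 1), 0.05)
  # analytic circle limit of perimeter^2/area is 4*pi (not the garbled
  # printed constant); see the methods vignette
  expect_lt(abs(s32[["dispersity"]] / (4 * pi) - 1), 0.05)
  expect_lt(abs(s32[["saturation"]] / 16 - 1), 0.05)
  # monotone error decrease with radius
  errs <- vapply(c(8, 16, 32, 64), function(r)
    abs(shape_features(disk_mask(r))[["roundness"]] - 1), numeric(1))
  expect_true(all(diff(errs) < 0))
  # axis-aligned square -> pi/4 with the corrected perimeter estimator
  sq <- matrix(0, 330, 330); sq[6:325, 6:325] <- 1
  ssq <- shape_features(lesion_mask(sq))
  expect_lt(abs(ssq[["roundness"]] / (pi / 4) - 1), 0.05)
  expect_error(shape_features(lesion_mask(matrix(0, 4, 4))), "empty")
})

test_that("shape features use the largest connected component", {
  m <- matrix(0, 40, 40)
  m[5:25, 5:25] <- 1          # large square
  m[35, 35] <- 1              # stray pixel
  s <- shape_features(lesion_mask(m))
  expect_equal(s[["area"]], 441)
})

test_that("extract_features has the documented layout and is deterministic", {
  set.seed(31)
  it <- make_lesion_image(1, synth_image_params(size = 48), seed = 5)
  fv <- extract_features(it$image, it$mask)
  expect_length(fv, 12 + 6 + 256 + 3)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(fv, extract_features(it$image, it$mask))
  # block ordering: color, texture, lbp, shape
  expect_true(all(startsWith(names(fv)[1:12], "color_")))
  expect_true(all(startsWith(names(fv)[13:18], "glcm_")))
  expect_true(all(startsWith(names(fv)[19:274], "lbp_")))
  expect_true(all(startsWith(names(fv)[275:277], "shape_")))
})

test_that("features are invariant to translating the lesion", {
  set.seed(8)
  img <- array(runif(40 * 40 * 3, 0.6, 0.9), c(40, 40, 3))
  blob <- matrix(0, 40, 40); blob[8:18, 8:20] <- 1
  tex <- matrix(runif(40 * 40, 0.1, 0.4), 40, 40)
  for (c in 1:3) img[, , c][blob == 1] <- tex[blob == 1]
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- img
  for (c in 1:3) img2[, , c] <- shift(img[, , c], 12, 9)
  f1 <- extract_features(rgb_image(img), lesion_mask(blob))
  f2 <- extract_features(rgb_image(img2), lesion_mask(shift(blob, 12, 9)))
  expect_equal(f1, f2, tolerance = 1e-12)
})
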