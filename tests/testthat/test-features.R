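test_that("Zernike index list and result shape", {
  idx <- zernike_index_list(8)
  expect_equal(nrow(idx), 25)
  expect_true(all(idx$m <= idx$n))
  expect_true(all((idx$n - idx$m) %% 2 == 0))
  set.seed(1)
  z <- zernike_moments(matrix(runif(256, 0, 255), 16, 16))
  expect_length(z$magnitudes, 25)
  expect_true(all(is.finite(z$magnitudes)) && all(z$magnitudes >= 0))
  expect_error(zernike_moments(matrix(0, 4, 4)), "8x8")
})

test_that("order-(0,0) moment equals the disk mean and matches the brute-force oracle", {
  set.seed(3)
  m <- matrix(runif(256, 0, 255), 16, 16)
  z <- zernike_moments(m)
  oz <- oracle_zernike(m)
  expect_equal(unname(z$magnitudes), oz, tolerance = 1e-10)
  # R_{0,0} = 1, so |Z_00| = disk-mean intensity
  expect_equal(unname(z$magnitudes[1]), oz[1], tolerance = 1e-12)
  expect_gt(z$magnitudes[1], 0)
  # degenerate all-zero image: zero vector, no error
  expect_equal(max(zernike_moments(matrix(0, 16, 16))$magnitudes), 0)
})

test_that("Zernike magnitudes are rotation invariant", {
  set.seed(4)
  worst <- 0
  for (r in 1:20) {
    sp <- default_class_specs()[[1 + r %% 2]]
    g <- rgb_to_gray(generate_image(sp, c(32, 32), seed = r)$image)
    z0 <- zernike_moments(g)$magnitudes
    for (rot in 1:3) {
      g <- rot90m(g)
      zr <- zernike_moments(g)$magnitudes
      rel <- max(abs(zr - z0) / pmax(abs(z0), 1e-8))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-2)
})

test_that("GLCM matches enumerated pairs and the pixel-loop oracle", {
  # [[0,0],[1,1]]: two horizontal pairs, both within one level
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)   # rows: (0,0),(1,1)
  P <- glcm(q, levels = 2, d = 1, angle = 0)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # constant image: single nonzero diagonal entry = 1
  qc <- matrix(3L, 5, 5)
  Pc <- glcm(qc, levels = 8, d = 1, angle = 45)
  expect_equal(Pc[4, 4], 1)
  expect_equal(sum(Pc), 1)
  # oracle equivalence across distances and angles on a random image
  set.seed(9)
  qr <- quantize_gray(matrix(runif(256, 0, 255), 16, 16), 8)
  for (d in c(1, 2)) for (a in seq(0, 315, by = 45)) {
    expect_equal(glcm(qr, 8, d, a), oracle_glcm(qr, 8, d, a), tolerance = 1e-12)
  }
  # any normalized GLCM sums to one
  expect_equal(sum(glcm(qr, 8, 4, 135)), 1, tolerance = 1e-12)
  expect_error(glcm(qr, 8, d = 20, angle = 0), "displacement")
})

test_that("Haralick features match the brute-force oracle", {
  expect_length(haralick_features(matrix(100, 16, 16)), 13)
  # constant image: contrast 0, angular second moment 1
  hc <- haralick_features(matrix(100, 16, 16))
  expect_equal(unname(hc[2]), 0)
  expect_equal(unname(hc[1]), 1)
  # two-level checkerboard, d = 1, all 8 angles: against per-angle oracle
  chk <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  spec <- glcm_spec(levels = 2, distances = 1)
  mine <- haralick_features(chk, spec)
  q <- quantize_gray(chk, 2)
  acc <- sapply(seq(0, 315, by = 45), function(a)
    oracle_haralick_one(oracle_glcm(q, 2, 1, a)))
  expect_equal(unname(mine), rowMeans(acc), tolerance = 1e-10)
  # random image with the default multi-distance spec
  set.seed(2)
  g <- matrix(runif(256, 0, 255), 16, 16)
  spec <- glcm_spec(levels = 8, distances = c(1, 2))
  mine <- haralick_features(g, spec)
  qg <- quantize_gray(g, 8)
  acc <- c()
  for (d in c(1, 2)) for (a in seq(0, 315, by = 45))
    acc <- cbind(acc, oracle_haralick_one(oracle_glcm(qg, 8, d, a)))
  expect_equal(unname(mine), rowMeans(acc), tolerance = 1e-8)
})

test_that("Haralick means are invariant under transpose", {
  # the 8-angle set is closed under the transpose map
  set.seed(6)
  g <- matrix(runif(24 * 24, 0, 255), 24, 24)
  f1 <- haralick_features(g)
  f2 <- haralick_features(t(g))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("joint color histogram layout, mass and oracle equivalence", {
  expect_length(color_histogram(array(128, c(4, 4, 3))), 512)
  black <- array(0, c(4, 4, 3))
  hb <- color_histogram(black)
  expect_equal(unname(hb[1]), 1)
  expect_equal(sum(hb[-1]), 0)
  # 2x1 image, one black one white pixel: two bins with mass 0.5
  img <- array(0, c(2, 1, 3)); img[2, 1, ] <- 255
  h2 <- color_histogram(img)
  expect_equal(sort(h2[h2 > 0]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(unname(h2[1]), 0.5)      # (0,0,0) bin
  expect_equal(unname(h2[512]), 0.5)    # (7,7,7) bin
  set.seed(11)
  rnd <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  expect_equal(unname(color_histogram(rnd)), oracle_color_histogram(rnd),
               tolerance = 1e-12)
  expect_error(color_histogram(matrix(0, 4, 4)), "RGB")
})

test_that("fusion yields the fixed 550-d layout and slices back", {
  set.seed(5)
  z <- runif(25); h <- runif(13); ch <- runif(512)
  fv <- fuse_features(z, h, ch)
  expect_length(fv, 550)
  expect_equal(as.numeric(fv[1:25]), z)
  expect_equal(as.numeric(fv[26:38]), h)
  expect_equal(as.numeric(fv[39:550]), ch)
  expect_equal(as.numeric(fuse_features(rep(0, 25), rep(0, 13), rep(0, 512))),
               rep(0, 550))
  expect_error(fuse_features(z[-1], h, ch), "25")
  expect_error(fuse_features(z, h[-1], ch), "13")
  expect_error(fuse_features(z, h, ch[-1]), "512")
})

test_that("end-to-end extraction produces finite named 550-vectors", {
  g <- generate_image(default_class_specs()$malignant, c(48, 48), seed = 2)
  fv <- extract_feature_vector(g$image, resize_to = NULL)
  expect_length(fv, 550)
  expect_true(all(is.finite(fv)))
  expect_match(names(fv)[1], "^z_0_0$")
  expect_match(names(fv)[26], "^har_01$")
  expect_match(names(fv)[39], "^ch_0_0_0$")
  # resizing path gives the same layout
  fv2 <- extract_feature_vector(g$image, resize_to = 64)
  expect_length(fv2, 550)
  ds <- make_tiny_dataset(n_per_class = 2, seed = 3)
  tab <- extract_features(ds$manifest, ds$dir, resize_to = NULL)
  expect_equal(nrow(tab), 4)
  expect_equal(ncol(tab), 550 + 6)
})
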