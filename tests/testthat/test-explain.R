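test_that("pca_2d reproduces geometry, ranks variance and matches its oracle", {
  set.seed(1)
  # 2-D data: embedding preserves pairwise distances exactly
  X2 <- matrix(rnorm(20), 10, 2)
  e2 <- pca_2d(X2)
  expect_equal(as.matrix(dist(e2$points)), as.matrix(dist(X2)),
               tolerance = 1e-10)
  # collinear points: zero second variance
  X3 <- outer(1:3, c(1, 2, 3))
  e3 <- pca_2d(X3)
  expect_equal(e3$explained_variance[2], 0, tolerance = 1e-12)
  expect_gte(e3$explained_variance[1], e3$explained_variance[2])
  # oracle equivalence on a random 20 x 10 matrix
  X <- matrix(rnorm(200), 20, 10)
  e <- pca_2d(X)
  Xc <- scale(X, scale = FALSE)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  sc <- Xc %*% eg$vectors[, 1:2]
  for (j in 1:2) {
    d <- min(max(abs(e$points[, j] - sc[, j])),
             max(abs(e$points[, j] + sc[, j])))
    expect_lt(d, 1e-8)
  }
  # total variance conservation: eigenvalues sum to trace of covariance
  expect_equal(sum(eg$values), sum(diag(stats::cov(Xc))), tolerance = 1e-8)
  expect_error(pca_2d(matrix(1, 5, 3)), "rank-0")
})

test_that("kpca with a linear kernel equals pca up to sign", {
  set.seed(2)
  for (r in 1:10) {
    nr <- 15 + r %% 3; nc <- 4 + (5 * r) %% 3
    X <- matrix(rnorm(nr * nc), nr, nc)
    p <- pca_2d(X)
    k <- kpca_2d(X, "linear")
    for (j in 1:2) {
      d <- min(max(abs(p$points[, j] - k$points[, j])),
               max(abs(p$points[, j] + k$points[, j])))
      expect_lt(d, 1e-6)
    }
  }
})

test_that("kpca against an independent kernel-pca implementation", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6)
  mine <- kpca_2d(X, "rbf")
  ref <- kernlab::kpca(X, kernel = "rbfdot",
                       kpar = list(sigma = 1 / ncol(X)), features = 2)
  refp <- kernlab::rotated(ref)[, 1:2]
  # conventions differ by per-component scale and sign; directions agree
  for (j in 1:2) expect_gt(abs(stats::cor(mine$points[, j], refp[, j])),
                           0.999)
})

test_that("rbf kernel degenerates as gamma shrinks", {
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  # the uncentred kernel approaches the rank-one all-ones matrix, and the
  # centred spectrum vanishes proportionally to gamma
  e_small <- kpca_2d(X, "rbf", gamma = 1e-8)
  e_unit <- kpca_2d(X, "rbf", gamma = 1)
  expect_lt(e_small$explained_variance[2], 1e-5 * e_unit$explained_variance[2])
  K <- exp(-1e-8 * as.matrix(stats::dist(X))^2)
  ev <- eigen(K, symmetric = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-6)
})

test_that("well-separated clusters embed with high silhouette under rbf", {
  set.seed(5)
  X <- rbind(matrix(rnorm(25 * 6), 25, 6),
             matrix(rnorm(25 * 6, mean = 8), 25, 6))
  lab <- rep(1:2, each = 25)
  emb <- kpca_2d(X, "rbf", labels = lab)
  # silhouette computed directly from the 2-D embedding
  d <- as.matrix(dist(emb$points))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

# a hand-built single-conv network: one feature map, class score = mean(A)
single_map_net <- function(h = 8, w = 8, w_scale = 1) {
  conv <- list(type = "conv", W = matrix(0, 1, 9), b = 0,
               block = "B5", trainable = TRUE, name = "conv1")
  conv$W[1, 5] <- 1           # center tap: A = relu(x)
  fc1 <- list(type = "fc",
              W = rbind(rep(w_scale / (h * w), h * w), rep(0, h * w)),
              b = c(0, 0), block = "B6", trainable = TRUE, name = "fc1")
  structure(list(layers = list(conv, list(type = "relu"),
                               list(type = "flatten"), fc1),
                 num_classes = 2L, scale_factor = 1L,
                 input_size = as.integer(h), classes = c("on", "off"),
                 seed = 1L),
            class = "vgg_network")
}

test_that("grad_cam matches the closed-form single-feature-map case", {
  set.seed(6)
  x <- array(rnorm(64), c(8, 8, 1))
  net <- single_map_net()
  hm <- grad_cam(net, x, "on")
  # score = mean(A) with A = relu(x): alpha = 1/(HW), heat ~ relu(A) = A
  A <- pmax(x[, , 1], 0)
  expected <- if (max(A) > 0) A / max(A) else A
  expect_equal(hm$values, expected, tolerance = 1e-8)
  expect_equal(hm$source_layer, "conv1")
  # class with zero weight on every feature map: all-zero heatmap
  hm0 <- grad_cam(net, x, "off")
  expect_equal(hm0$values, matrix(0, 8, 8))
  expect_error(grad_cam(net, x, "nope"), "unknown class")
})

test_that("heatmap range invariant and upsampling keep the maximum in place", {
  set.seed(7)
  for (r in 1:5) {
    m <- matrix(runif(16), 4, 4)
    up <- histopatch:::bilinear_upsample(m, 32, 32)
    expect_gte(min(up), 0)
    src <- which(m == max(m), arr.ind = TRUE)[1, ]
    dst <- which(up == max(up), arr.ind = TRUE)[1, ]
    # maximum stays within one source-cell radius
    expect_lte(abs(dst[1] / 8 - (src[1] - 0.5)), 1.01)
    expect_lte(abs(dst[2] / 8 - (src[2] - 0.5)), 1.01)
  }
})

test_that("overlay endpoints: identity at alpha 0, blue floor, red peak", {
  set.seed(8)
  img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  hm <- matrix(0, 8, 8)
  expect_equal(overlay_heatmap(hm, img, alpha = 0), img)
  # constant-zero heatmap tints toward blue: blue channel rises
  tinted <- overlay_heatmap(hm, img, alpha = 1)
  expect_true(all(tinted[, , 3] == 255) && all(tinted[, , 1] == 0))
  # value 1 at one pixel maps to the red extreme there
  hm[3, 5] <- 1
  red <- overlay_heatmap(hm, img, alpha = 1)
  expect_equal(red[3, 5, ], c(255, 0, 0))
  expect_error(overlay_heatmap(matrix(0, 4, 4), img), "mismatch")
})
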