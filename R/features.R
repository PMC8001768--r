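# Handcrafted descriptors: Zernike moments (shape/margin), Haralick texture
# statistics from gray-level co-occurrence matrices, and a joint RGB color
# histogram, fused into a fixed 550-d layout:
#   [1:25]    Zernike magnitudes, orders 0-8, index (n, m) sorted by (n, m)
#   [26:38]   13 Haralick statistics averaged over all (distance, angle) GLCMs
#   [39:550]  8x8x8 joint color histogram, R-major flattening

#' Valid Zernike (n, m) index list up to a maximum order
#'
#' Indices with `0 <= n <= n_max`, `m >= 0`, `n - m` even and `m <= n`,
#' sorted by `(n, m)`. For `n_max = 8` there are 25 of them.
#'
#' @param n_max Maximum radial order.
#' @return Data.frame with columns `n` and `m`.
#' @export
zernike_index_list <- function(n_max = 8) {
  idx <- expand.grid(m = 0:n_max, n = 0:n_max)[, c("n", "m")]
  idx <- idx[idx$m <= idx$n & (idx$n - idx$m) %% 2 == 0, ]
  idx <- idx[order(idx$n, idx$m), ]
  rownames(idx) <- NULL
  idx
}

# Radial polynomial R_{n,m}(rho) by the standard factorial sum.
zernike_radial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

# Conjugate Zernike basis V*_{n,m} evaluated on the pixel grid mapped to the
# unit disk (center = image center, radius = min(H, W) / 2). Cached per
# (H, W, n_max); pixels outside the disk are dropped.
.zernike_cache <- new.env(parent = emptyenv())

zernike_basis <- function(h, w, n_max) {
  key <- paste(h, w, n_max, sep = "x")
  if (!is.null(.zernike_cache[[key]])) return(.zernike_cache[[key]])
  R <- min(h, w) / 2
  y <- (seq_len(h) - (h + 1) / 2) / R
  x <- (seq_len(w) - (w + 1) / 2) / R
  yy <- outer(y, rep(1, w)); xx <- outer(rep(1, h), x)
  rho <- sqrt(xx^2 + yy^2)
  inside <- which(rho <= 1)
  theta <- atan2(yy[inside], xx[inside])
  rho_in <- rho[inside]
  idx <- zernike_index_list(n_max)
  basis <- matrix(complex(real = 0), nrow(idx), length(inside))
  for (k in seq_len(nrow(idx))) {
    n <- idx$n[k]; m <- idx$m[k]
    basis[k, ] <- zernike_radial(n, m, rho_in) * exp(-1i * m * theta)
  }
  val <- list(inside = inside, basis = basis, idx = idx,
              alpha = length(inside))
  .zernike_cache[[key]] <- val
  val
}

#' Zernike moment magnitudes of a grayscale image
#'
#' Projects the image onto the conjugate Zernike basis over the inscribed
#' unit disk and scales by `(n + 1) / alpha_N`, where `alpha_N` is the number
#' of pixels inside the disk (so the order-(0,0) magnitude is the disk-mean
#' intensity). Magnitudes are rotation invariant.
#'
#' @param gray `H x W` numeric matrix (any intensity scale), at least 8x8.
#' @param n_max Maximum radial order (default 8, giving 25 moments).
#' @return Object of class `zernike_result`: list with `magnitudes` (named
#'   `z_n_m`), `index_list` and `alpha`.
#' @export
zernike_moments <- function(gray, n_max = 8) {
  if (!is.matrix(gray) || nrow(gray) < 8 || ncol(gray) < 8)
    stop("gray must be a matrix of at least 8x8")
  zb <- zernike_basis(nrow(gray), ncol(gray), n_max)
  f <- gray[zb$inside]
  z <- as.vector(zb$basis %*% f)
  mags <- Mod(z) * (zb$idx$n + 1) / zb$alpha
  names(mags) <- sprintf("z_%d_%d", zb$idx$n, zb$idx$m)
  structure(list(magnitudes = mags, index_list = zb$idx, alpha = zb$alpha),
            class = "zernike_result")
}

#' Quantize a grayscale image to a fixed number of levels
#'
#' Uniform bins over `[0, 255]`; output levels run `0 .. levels - 1`.
#'
#' @param gray `H x W` matrix in `[0, 255]`.
#' @param levels Number of gray levels.
#' @return Integer matrix of bin indices.
#' @export
quantize_gray <- function(gray, levels = 32) {
  q <- floor(pmin(pmax(gray, 0), 255) * levels / 256)
  matrix(as.integer(pmin(q, levels - 1)), nrow(gray), ncol(gray))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized levels at the displacement
#' `(dc, dr) = (round(d cos a), -round(d sin a))` in (column, row) steps.
#'
#' @param q Integer matrix of quantized levels in `0 .. levels - 1`
#'   (see [quantize_gray()]).
#' @param levels Number of gray levels.
#' @param d Displacement length in pixels.
#' @param angle Angle in degrees (0 is rightward, 90 upward).
#' @param symmetric Add the transpose (default TRUE).
#' @param normalized Divide by the total count (default TRUE).
#' @return `levels x levels` matrix.
#' @export
glcm <- function(q, levels = 32, d = 1, angle = 0, symmetric = TRUE,
                 normalized = TRUE) {
  h <- nrow(q); w <- ncol(q)
  a <- angle * pi / 180
  dc <- round(d * cos(a)); dr <- -round(d * sin(a))
  if (abs(dr) >= h || abs(dc) >= w)
    stop("displacement larger than image extent")
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  from <- q[r1, c1, drop = FALSE]
  to <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(as.vector(from) * levels + as.vector(to) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  if (normalized && sum(P) > 0) P <- P / sum(P)
  P
}

# The 13 Haralick statistics of one normalized GLCM. Entropies use log2 with
# an epsilon guard; correlation-type terms return 0 when a variance or
# entropy in the denominator vanishes (constant images). Sum variance is
# taken about the sum average (the statistically meaningful centring).
haralick_from_glcm <- function(P, eps = 1e-12) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  psum <- tapply(as.vector(P), as.vector(i + j), sum)
  pdiff <- tapply(as.vector(P), as.vector(abs(i - j)), sum)
  ksum <- as.numeric(names(psum)); kdiff <- as.numeric(names(pdiff))

  f1 <- sum(P^2)                                    # angular second moment
  f2 <- sum(kdiff^2 * pdiff)                        # contrast
  f3 <- if (sd_x * sd_y < eps) 0 else
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)  # correlation
  f4 <- sum((i - mu_x)^2 * P)                       # sum of squares: variance
  f5 <- sum(P / (1 + (i - j)^2))                    # inverse difference moment
  f6 <- sum(ksum * psum)                            # sum average
  f7 <- sum((ksum - f6)^2 * psum)                   # sum variance
  f8 <- -sum(psum * log2(psum + eps))               # sum entropy
  f9 <- -sum(P * log2(P + eps))                     # entropy
  mu_d <- sum(kdiff * pdiff)
  f10 <- sum((kdiff - mu_d)^2 * pdiff)              # difference variance
  f11 <- -sum(pdiff * log2(pdiff + eps))            # difference entropy
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxpy + eps))
  hxy2 <- -sum(pxpy * log2(pxpy + eps))
  hx <- -sum(px * log2(px + eps)); hy <- -sum(py * log2(py + eps))
  f12 <- if (max(hx, hy) < eps) 0 else (f9 - hxy1) / max(hx, hy)  # IMC 1
  f13 <- sqrt(pmax(1 - exp(-2 * (hxy2 - f9)), 0))                 # IMC 2
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

#' GLCM specification
#'
#' @param levels Gray quantization levels (default 32).
#' @param distances Integer displacement lengths (default `c(1, 2, 4)`).
#' @param angles Angles in degrees (default the eight multiples of 45).
#' @param symmetric,normalized GLCM accumulation options.
#' @return List of class `glcm_spec`.
#' @export
glcm_spec <- function(levels = 32, distances = c(1, 2, 4),
                      angles = seq(0, 315, by = 45),
                      symmetric = TRUE, normalized = TRUE) {
  stopifnot(levels >= 2, all(distances >= 1))
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 angles = as.numeric(angles),
                 symmetric = symmetric, normalized = normalized),
            class = "glcm_spec")
}

#' Mean Haralick texture features over multiple distances and angles
#'
#' Computes the first 13 Haralick statistics (the maximal correlation
#' coefficient is excluded for its numerical instability) on each
#' (distance, angle) GLCM and returns their element-wise mean.
#'
#' @param gray `H x W` matrix in `[0, 255]` (unquantized).
#' @param spec A [glcm_spec()].
#' @return Named numeric vector of length 13 (`har_01` .. `har_13`).
#' @export
haralick_features <- function(gray, spec = glcm_spec()) {
  if (!inherits(spec, "glcm_spec")) stop("spec must be a glcm_spec")
  q <- quantize_gray(gray, spec$levels)
  acc <- matrix(0, 13, 0)
  for (d in spec$distances) {
    for (a in spec$angles) {
      P <- glcm(q, spec$levels, d, a, spec$symmetric, spec$normalized)
      acc <- cbind(acc, haralick_from_glcm(P))
    }
  }
  out <- rowMeans(acc)
  names(out) <- sprintf("har_%02d", 1:13)
  out
}

#' Joint RGB color histogram
#'
#' 3-D histogram over (R, G, B) with `bins_per_channel` uniform bins per axis
#' on `[0, 255]`, flattened R-major (R slowest, then G, then B) and
#' normalized to sum 1.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param bins_per_channel Bins per channel (default 8, giving 512 entries).
#' @return Named numeric vector of length `bins_per_channel^3`.
#' @export
color_histogram <- function(image, bins_per_channel = 8) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an RGB (H x W x 3) array")
  b <- bins_per_channel
  qc <- function(ch) pmin(floor(pmin(pmax(ch, 0), 255) * b / 256), b - 1)
  r <- qc(image[, , 1]); g <- qc(image[, , 2]); bl <- qc(image[, , 3])
  idx <- r * b * b + g * b + bl + 1
  h <- tabulate(idx, nbins = b^3)
  h <- h / sum(h)
  grid <- expand.grid(b = 0:(b - 1), g = 0:(b - 1), r = 0:(b - 1))
  names(h) <- sprintf("ch_%d_%d_%d", grid$r, grid$g, grid$b)
  h
}

#' Fuse the three handcrafted descriptors into the 550-d layout
#'
#' @param z A `zernike_result` (25 magnitudes) or a length-25 vector.
#' @param h Length-13 Haralick vector.
#' @param c Length-512 color-histogram vector.
#' @return Named numeric vector of length 550 (class `feature_vector`).
#' @export
fuse_features <- function(z, h, c) {
  zv <- if (inherits(z, "zernike_result")) z$magnitudes else z
  if (length(zv) != 25) stop("Zernike component must have length 25")
  if (length(h) != 13) stop("Haralick component must have length 13")
  if (length(c) != 512) stop("color-histogram component must have length 512")
  out <- c(zv, h, c)
  if (any(!is.finite(out))) stop("non-finite feature values")
  structure(out, class = c("feature_vector", class(out)))
}

#' Extract the fused 550-d descriptor from one RGB image
#'
#' Images are resized (bilinear) to `resize_to` pixels square before
#' extraction so all inputs share one resolution; pass `resize_to = NULL`
#' to extract at native size.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param n_max Zernike maximum order.
#' @param gspec A [glcm_spec()].
#' @param bins_per_channel Color-histogram bins per channel.
#' @param resize_to Target square size in pixels, or NULL.
#' @return Named length-550 feature vector.
#' @export
extract_feature_vector <- function(image, n_max = 8, gspec = glcm_spec(),
                                   bins_per_channel = 8, resize_to = 224) {
  if (!is.null(resize_to)) image <- resize_rgb(image, resize_to, resize_to)
  gray <- rgb_to_gray(image)
  fuse_features(zernike_moments(gray, n_max),
                haralick_features(gray, gspec),
                color_histogram(image, bins_per_channel))
}

#' Extract fused features for every image of a manifest
#'
#' @param manifest Manifest data.frame.
#' @param base_dir Directory against which relative image paths resolve.
#' @param ... Passed to [extract_feature_vector()].
#' @return Data.frame: 550 feature columns with layout-stable names, then the
#'   manifest label columns.
#' @export
extract_features <- function(manifest, base_dir, ...) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image_rgb(file.path(base_dir, manifest$image_path[i]))
    extract_feature_vector(img, ...)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(feat, manifest[, intersect(manifest_cols, names(manifest)),
                       drop = FALSE])
}
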