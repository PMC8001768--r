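# Independent naive reference implementations used as oracles. These are
# deliberately written as explicit loops / direct formula transcriptions,
# sharing no code path with the package implementations they check.

# Zernike moments by direct double sum over the pixel grid.
oracle_zernike <- function(gray, n_max = 8) {
  h <- nrow(gray); w <- ncol(gray)
  R <- min(h, w) / 2
  radial <- function(n, m, rho) {
    out <- 0
    for (s in 0:((n - m) / 2)) {
      out <- out + (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + m) / 2 - s) *
           factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
    }
    out
  }
  idx <- list()
  for (n in 0:n_max) for (m in 0:n) if ((n - m) %% 2 == 0)
    idx[[length(idx) + 1]] <- c(n, m)
  # alpha_N: pixels inside the unit disk
  alpha <- 0
  for (r in 1:h) for (cc in 1:w) {
    y <- (r - (h + 1) / 2) / R; x <- (cc - (w + 1) / 2) / R
    if (sqrt(x^2 + y^2) <= 1) alpha <- alpha + 1
  }
  mags <- numeric(length(idx))
  for (k in seq_along(idx)) {
    n <- idx[[k]][1]; m <- idx[[k]][2]
    acc <- complex(real = 0)
    for (r in 1:h) for (cc in 1:w) {
      y <- (r - (h + 1) / 2) / R; x <- (cc - (w + 1) / 2) / R
      rho <- sqrt(x^2 + y^2)
      if (rho <= 1) {
        theta <- atan2(y, x)
        acc <- acc + gray[r, cc] * radial(n, m, rho) * exp(-1i * m * theta)
      }
    }
    mags[k] <- Mod(acc) * (n + 1) / alpha
  }
  mags
}

# GLCM by explicit pixel loop.
oracle_glcm <- function(q, levels, d, angle, symmetric = TRUE,
                        normalized = TRUE) {
  a <- angle * pi / 180
  dc <- round(d * cos(a)); dr <- -round(d * sin(a))
  P <- matrix(0, levels, levels)
  for (r in 1:nrow(q)) for (cc in 1:ncol(q)) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      P[q[r, cc] + 1, q[r2, c2] + 1] <- P[q[r, cc] + 1, q[r2, c2] + 1] + 1
    }
  }
  if (symmetric) P <- P + t(P)
  if (normalized && sum(P) > 0) P <- P / sum(P)
  P
}

# The 13 Haralick statistics by direct formula transcription.
oracle_haralick_one <- function(P, eps = 1e-12) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px)); sy <- sqrt(sum(((1:L) - muy)^2 * py))
  psum <- rep(0, 2 * L); pdif <- rep(0, L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  f <- numeric(13)
  f[1] <- sum(P^2)
  f[2] <- sum((0:(L - 1))^2 * pdif)
  cor_num <- 0
  for (i in 1:L) for (j in 1:L) cor_num <- cor_num + i * j * P[i, j]
  f[3] <- if (sx * sy < eps) 0 else (cor_num - mux * muy) / (sx * sy)
  f[4] <- 0
  for (i in 1:L) for (j in 1:L) f[4] <- f[4] + (i - mux)^2 * P[i, j]
  f[5] <- 0
  for (i in 1:L) for (j in 1:L) f[5] <- f[5] + P[i, j] / (1 + (i - j)^2)
  f[6] <- sum((2:(2 * L)) * psum[2:(2 * L)])
  f[7] <- sum(((2:(2 * L)) - f[6])^2 * psum[2:(2 * L)])
  f[8] <- -sum(psum * log2(psum + eps))
  f[9] <- -sum(P * log2(P + eps))
  mud <- sum((0:(L - 1)) * pdif)
  f[10] <- sum(((0:(L - 1)) - mud)^2 * pdif)
  f[11] <- -sum(pdif * log2(pdif + eps))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j] + eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
  }
  hx <- -sum(px * log2(px + eps)); hy <- -sum(py * log2(py + eps))
  f[12] <- if (max(hx, hy) < eps) 0 else (f[9] - hxy1) / max(hx, hy)
  f[13] <- sqrt(max(1 - exp(-2 * (hxy2 - f[9])), 0))
  f
}

# Joint color histogram by per-pixel loop.
oracle_color_histogram <- function(image, bins = 8) {
  h <- numeric(bins^3)
  for (r in 1:dim(image)[1]) for (cc in 1:dim(image)[2]) {
    ri <- min(floor(image[r, cc, 1] * bins / 256), bins - 1)
    gi <- min(floor(image[r, cc, 2] * bins / 256), bins - 1)
    bi <- min(floor(image[r, cc, 3] * bins / 256), bins - 1)
    k <- ri * bins^2 + gi * bins + bi + 1
    h[k] <- h[k] + 1
  }
  h / sum(h)
}

# Exact 90-degree rotation of a matrix grid (counter-clockwise).
rot90m <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

# Small synthetic two-class dataset written to a temp dir; returns manifest.
make_tiny_dataset <- function(n_per_class = 10, size = c(32, 32), seed = 1,
                              dir = tempfile("ds_")) {
  design <- data.frame(class = c("benign", "malignant"), n = n_per_class)
  man <- generate_dataset(design, dir, seed = seed, size = size)
  list(manifest = man, dir = dir)
}

quadrant_means <- function(hm) {
  h2 <- nrow(hm) / 2; w2 <- ncol(hm) / 2
  c(TL = mean(hm[1:h2, 1:w2]), TR = mean(hm[1:h2, (w2 + 1):ncol(hm)]),
    BL = mean(hm[(h2 + 1):nrow(hm), 1:w2]),
    BR = mean(hm[(h2 + 1):nrow(hm), (w2 + 1):ncol(hm)]))
}
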