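# Stain-color normalization by sparse non-negative stain separation.
#
# Working space is per-channel optical density, OD = -log10(I / I0), in which
# the Beer-Lambert law makes OD linear in stain concentration: V = W H with
# V the 3 x n pixel OD matrix, W the 3 x 2 unit-column stain-color matrix and
# H the 2 x n concentration matrix. W and H are estimated by seeded
# multiplicative-update NMF with an L1 penalty on H (sparse separation);
# normalization maps a source image onto a reference stain basis while
# preserving the concentration structure.

#' Convert an RGB image to optical density
#'
#' `OD = -log10(max(I, 1) / I0)` per channel; pure white maps to OD 0.
#'
#' @param image `H x W x 3` array with values in `[0, I0]`.
#' @param I0 Incident intensity (default 255).
#' @return List of class `od_image` with `od` (`H x W x 3`, non-negative)
#'   and `shape`.
#' @export
rgb_to_od <- function(image, I0 = 255) {
  img <- pmin(pmax(image, 0), I0)
  od <- -log10(pmax(img, 1) / I0)
  structure(list(od = od, shape = dim(img)[1:2]), class = "od_image")
}

#' Convert optical density back to RGB
#'
#' Inverse of [rgb_to_od()]: `I = round(I0 * 10^(-OD))`, clipped to `[0, I0]`.
#'
#' @param od An `od_image` or a bare `H x W x 3` OD array.
#' @param I0 Incident intensity.
#' @return `H x W x 3` integer-valued array.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  a <- if (inherits(od, "od_image")) od$od else od
  pmin(pmax(round(I0 * 10^(-a)), 0), I0)
}

# pixels x 3 -> 3 x n OD matrix of tissue pixels (max-channel OD > beta)
od_pixel_matrix <- function(od_arr) {
  t(matrix(od_arr, ncol = 3L))
}

# Exact L1-penalized non-negative least squares for the concentrations of
# every pixel given a fixed 3 x 2 stain basis. With two stains the per-pixel
# problem min_h ||v - W h||^2 + lambda * sum(h), h >= 0 has four candidate
# active sets ({}, {1}, {2}, {1,2}); all are solved in closed form and the
# best is kept, vectorized across pixels.
h_solve <- function(V, W, lambda) {
  G <- crossprod(W)
  braw <- crossprod(W, V)
  n <- ncol(V)
  detG <- G[1, 1] * G[2, 2] - G[1, 2]^2
  b <- braw - lambda / 2
  cands <- array(0, c(2, n, 4))
  cands[1, , 2] <- pmax(b[1, ] / G[1, 1], 0)
  cands[2, , 3] <- pmax(b[2, ] / G[2, 2], 0)
  h1 <- (G[2, 2] * b[1, ] - G[1, 2] * b[2, ]) / detG
  h2 <- (G[1, 1] * b[2, ] - G[1, 2] * b[1, ]) / detG
  ok <- (h1 > 0) & (h2 > 0)
  cands[1, , 4] <- ifelse(ok, h1, 0)
  cands[2, , 4] <- ifelse(ok, h2, 0)
  best <- matrix(0, 2, n)
  bestf <- rep(Inf, n)
  for (k in 1:4) {
    Hk <- cands[, , k]
    f <- G[1, 1] * Hk[1, ]^2 + 2 * G[1, 2] * Hk[1, ] * Hk[2, ] +
      G[2, 2] * Hk[2, ]^2 -
      2 * (braw[1, ] * Hk[1, ] + braw[2, ] * Hk[2, ]) +
      lambda * (Hk[1, ] + Hk[2, ])
    up <- f < bestf
    best[, up] <- Hk[, up]
    bestf[up] <- f[up]
  }
  best
}

# Sparse two-stain separation, min ||V - WH||^2 + lambda * sum(H) with
# W >= 0 (unit columns) and H >= 0, by block coordinate descent in the
# dictionary-learning style: exact active-set solves for H, and the
# projected atom update w_j = normalize(max(R_j h_j', 0)) for each column.
# Deterministic for a fixed seed (seeded random non-negative init).
nmf_stain <- function(V, lambda = 0.1, seed = 1, max_iter = 200, tol = 1e-6,
                      W_fixed = NULL) {
  set.seed(as.integer(seed))
  if (!is.null(W_fixed)) {
    return(list(W = W_fixed, H = h_solve(V, W_fixed, lambda)))
  }
  W <- matrix(stats::runif(6, 0.1, 1), 3, 2)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- h_solve(V, W, lambda)
    for (j in 1:2) {
      R <- V - W[, -j, drop = FALSE] %*% H[-j, , drop = FALSE]
      wj <- pmax(R %*% H[j, ], 0)
      nw <- sqrt(sum(wj^2))
      if (nw < 1e-10) {
        wj <- stats::runif(3, 0.1, 1)
        nw <- sqrt(sum(wj^2))
      }
      W[, j] <- wj / nw
    }
    obj <- sum((V - W %*% H)^2) + lambda * sum(H)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj_old, 1e-12))
      break
    obj_old <- obj
  }
  list(W = W, H = h_solve(V, W, lambda))
}

#' Estimate the stain-color matrix of an image
#'
#' Runs sparse NMF on the optical densities of tissue pixels (max-channel
#' OD above `beta`). The returned profile orders columns hematoxylin-first
#' (the column with the larger blue-channel OD loading) and records robust
#' (99th-percentile) concentration maxima per stain.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param lambda L1 sparsity weight on concentrations (default 0.1).
#' @param beta Tissue OD threshold (default 0.15).
#' @param seed Integer seed for the NMF initialization.
#' @param max_iter,tol Solver controls.
#' @return Object of class `stain_profile` with `W` (3 x 2, unit columns,
#'   hematoxylin first) and `c_max` (length-2 concentration maxima).
#' @export
estimate_stain_matrix <- function(image, lambda = 0.1, beta = 0.15, seed = 1,
                                  max_iter = 200, tol = 1e-6) {
  odi <- rgb_to_od(image)
  V_all <- od_pixel_matrix(odi$od)
  tissue <- pmax(V_all[1, ], V_all[2, ], V_all[3, ]) > beta
  if (sum(tissue) < 100) {
    stop(structure(class = c("no_tissue_error", "error", "condition"),
                   list(message = paste0(
                     "no tissue: fewer than 100 pixels exceed OD ", beta,
                     "; skip stain normalization for this image"),
                     call = sys.call())))
  }
  fit <- nmf_stain(V_all[, tissue, drop = FALSE], lambda = lambda,
                   seed = seed, max_iter = max_iter, tol = tol)
  # hematoxylin-first: larger blue-channel OD loading
  ord <- order(fit$W[3, ], decreasing = TRUE)
  W <- fit$W[, ord, drop = FALSE]
  H <- fit$H[ord, , drop = FALSE]
  c_max <- apply(H, 1, stats::quantile, probs = 0.99, names = FALSE)
  structure(list(W = W, c_max = c_max, lambda = lambda, beta = beta),
            class = "stain_profile")
}

#' Concentration maps of an image for a fixed stain basis
#'
#' Solves the non-negative, L1-penalized least-squares problem for H with W
#' held fixed, over every pixel of the image.
#'
#' @param image `H x W x 3` RGB array.
#' @param W 3 x 2 stain-color matrix (unit columns).
#' @param lambda L1 penalty.
#' @param seed Seed for the multiplicative-update initialization.
#' @return `2 x n` concentration matrix (pixels in column-major order).
#' @export
stain_concentrations <- function(image, W, lambda = 0.1, seed = 1) {
  odi <- rgb_to_od(image)
  V <- od_pixel_matrix(odi$od)
  fit <- nmf_stain(V, lambda = lambda, seed = seed, W_fixed = W,
                   max_iter = 100)
  fit$H
}

#' Normalize the stain colors of a source image to a reference profile
#'
#' Decomposes the source into its own stain basis and concentrations,
#' rescales each concentration row by `reference$c_max / source c_max`, and
#' recomposes with the reference stain matrix. Structure (the concentration
#' maps) is preserved; only the color basis and dynamic range change.
#' Background pixels with near-zero OD keep near-zero concentrations and
#' stay white.
#'
#' The L1 penalty serves identification of the stain basis; the
#' concentration maps used for recomposition are solved with
#' `lambda_reconstruct` (default 0, plain non-negative least squares) so the
#' shrinkage bias does not darken or lighten the output.
#'
#' @param source `H x W x 3` RGB array.
#' @param reference A `stain_profile` (from [estimate_stain_matrix()] on the
#'   reference/template image chosen by the operator).
#' @param lambda,beta,seed As in [estimate_stain_matrix()].
#' @param lambda_reconstruct L1 weight for the recomposition concentrations.
#' @return Normalized `H x W x 3` RGB array, same shape as `source`.
#' @export
normalize_stains <- function(source, reference, lambda = 0.1, beta = 0.15,
                             seed = 1, lambda_reconstruct = 0) {
  if (!inherits(reference, "stain_profile"))
    stop("reference must be a stain_profile")
  src_prof <- estimate_stain_matrix(source, lambda = lambda, beta = beta,
                                    seed = seed)
  H <- stain_concentrations(source, src_prof$W, lambda = lambda_reconstruct,
                            seed = seed)
  scale <- reference$c_max / pmax(src_prof$c_max, 1e-8)
  H <- H * scale
  od_new <- reference$W %*% H
  h <- dim(source)[1]; w <- dim(source)[2]
  od_arr <- array(t(od_new), dim = c(h, w, 3))
  od_to_rgb(od_arr)
}

#' Normalize every image of a manifest to one reference image
#'
#' Pipeline-mode wrapper: images whose tissue content is too low to estimate
#' a stain matrix are logged and passed through unchanged.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param base_dir Directory against which relative image paths resolve.
#' @param reference_path Path of the reference/template image.
#' @param out_dir Output directory for normalized PNGs.
#' @param lambda,beta,seed As in [estimate_stain_matrix()].
#' @return The manifest with `image_path` pointing into `out_dir`.
#' @export
normalize_manifest <- function(manifest, base_dir, reference_path, out_dir,
                               lambda = 0.1, beta = 0.15, seed = 1) {
  ref_img <- read_image_rgb(reference_path)
  ref <- estimate_stain_matrix(ref_img, lambda = lambda, beta = beta,
                               seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- manifest
  for (i in seq_len(nrow(manifest))) {
    src_path <- file.path(base_dir, manifest$image_path[i])
    img <- read_image_rgb(src_path)
    res <- tryCatch(
      normalize_stains(img, ref, lambda = lambda, beta = beta, seed = seed),
      no_tissue_error = function(e) {
        message("passing through unnormalized (", conditionMessage(e), "): ",
                manifest$image_path[i])
        img
      })
    write_image_rgb(res, file.path(out_dir, manifest$image_path[i]))
  }
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  invisible(out)
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("Stain profile (columns: hematoxylin-like, eosin-like)\n")
  print(round(x$W, 4))
  cat("robust concentration maxima:", round(x$c_max, 4), "\n")
  invisible(x)
}
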