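# Visual explanation: 2-D PCA / kernel-PCA embeddings of feature matrices,
# Grad-CAM class-activation heatmaps from the last convolutional layer, and
# blue-to-red heatmap overlays.

#' 2-D principal component embedding
#'
#' Mean-centred projection onto the top-2 covariance eigenvectors. The sign
#' of each component is fixed so its largest-magnitude loading is positive,
#' making plots reproducible.
#'
#' @param features `n x p` numeric matrix, `n >= 3`, `p >= 2`, finite.
#' @param labels Optional point labels carried through for coloring.
#' @return Object of class `embedding2d`: `points` (`n x 2`),
#'   `explained_variance` (top-2 eigenvalues), `method = "pca"`, `labels`.
#' @export
pca_2d <- function(features, labels = NULL) {
  X <- as.matrix(features)
  if (nrow(X) < 3 || ncol(X) < 2) stop("need at least 3 rows and 2 columns")
  if (any(!is.finite(X))) stop("non-finite feature values")
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(Xc^2) < 1e-24) stop("rank-0 input: all rows identical")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pr$rotation))
  rot <- pr$rotation[, 1:k, drop = FALSE]
  pts <- pr$x[, 1:k, drop = FALSE]
  ev <- pr$sdev[1:k]^2
  if (k < 2) {   # rank-1 data: second component is identically zero
    rot <- cbind(rot, 0); pts <- cbind(pts, 0); ev <- c(ev, 0)
  }
  for (j in 1:2) {
    if (any(rot[, j] != 0) && rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; pts[, j] <- -pts[, j]
    }
  }
  structure(list(points = unname(pts), explained_variance = unname(ev),
                 method = "pca", labels = labels, loadings = unname(rot)),
            class = "embedding2d")
}

kernel_matrix <- function(X, kernel, gamma, degree, coef0) {
  lin <- tcrossprod(X)
  switch(kernel,
    linear = lin,
    poly = (gamma * lin + coef0)^degree,
    rbf = {
      sq <- rowSums(X^2)
      exp(-gamma * pmax(outer(sq, sq, "+") - 2 * lin, 0))
    },
    sigmoid = tanh(gamma * lin + coef0))
}

#' 2-D kernel principal component embedding
#'
#' Eigendecomposition of the double-centred kernel matrix; the top-2
#' components are returned on the conventional scale `v_j * sqrt(lambda_j)`
#' (eigenvectors normalized so that `lambda * ||alpha||^2 = 1`), under which
#' the linear kernel reproduces [pca_2d()] up to per-component sign.
#'
#' @param features `n x p` matrix as in [pca_2d()].
#' @param kernel One of `"linear"`, `"poly"` (degree 3, coef 1), `"rbf"`,
#'   `"sigmoid"`.
#' @param gamma Kernel scale; default `1/p`.
#' @param degree,coef0 Polynomial/sigmoid parameters.
#' @param labels Optional labels carried through.
#' @return An `embedding2d` with `method = "kpca-<kernel>"`.
#' @export
kpca_2d <- function(features, kernel = c("linear", "poly", "rbf", "sigmoid"),
                    gamma = NULL, degree = 3, coef0 = 1, labels = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(features)
  if (nrow(X) < 3 || ncol(X) < 2) stop("need at least 3 rows and 2 columns")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  n <- nrow(X)
  K <- kernel_matrix(X, kernel, gamma, degree, coef0)
  J <- diag(n) - matrix(1 / n, n, n)
  Kc <- J %*% K %*% J
  Kc <- (Kc + t(Kc)) / 2
  eg <- eigen(Kc, symmetric = TRUE)
  if (eg$values[1] <= 1e-12)
    stop("kernel matrix is numerically rank-0; condition: largest eigenvalue ",
         format(eg$values[1]))
  pts <- matrix(0, n, 2)
  ev <- pmax(eg$values[1:2], 0)
  for (j in 1:2) {
    if (ev[j] > 1e-12) {
      v <- eg$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      pts[, j] <- v * sqrt(ev[j])
    }
  }
  structure(list(points = pts, explained_variance = ev,
                 method = paste0("kpca-", kernel), labels = labels),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("2-D embedding (%s), %d points\n", x$method, nrow(x$points)))
  if (x$method == "pca")
    cat("explained variance:", signif(x$explained_variance, 5), "\n")
  invisible(x)
}

#' @export
plot.embedding2d <- function(x, ...) {
  col <- if (!is.null(x$labels)) as.integer(factor(x$labels)) else 1
  graphics::plot(x$points, col = col, pch = 19,
                 xlab = "component 1", ylab = "component 2",
                 main = x$method, ...)
  invisible(x)
}

#' Grad-CAM heatmap for one image and target class
#'
#' Backpropagates the (pre-softmax) score of `target_class` to the
#' activations A_k of the last convolutional layer; channel weights are the
#' spatial means of the gradients, the raw map is
#' `relu(sum_k alpha_k A_k)`, bilinearly upsampled to the input size and
#' min-max normalized to `[0, 1]` (identically-zero maps are returned as
#' zeros).
#'
#' @param net A trained `vgg_network`.
#' @param image `H x W x 3` normalized input (as from
#'   [load_manifest_images()]).
#' @param target_class Class label (must be one of the network's classes).
#' @return Object of class `heatmap2d`: `values` (`H x W` in `[0, 1]`),
#'   `target_class`, `source_layer`.
#' @export
grad_cam <- function(net, image, target_class) {
  classes <- net$classes %||% as.character(seq_len(net$num_classes))
  ci <- match(as.character(target_class), classes)
  if (is.na(ci)) stop("unknown class: ", target_class)
  x <- array(image, c(dim(image)[1:3], 1))
  fw <- nn_forward(net, x, training = FALSE)
  dlogits <- matrix(0, net$num_classes, 1)
  dlogits[ci, 1] <- 1
  bw <- nn_backward(net, fw$cache, dlogits, record_dact = TRUE)
  conv_idx <- which(vapply(net$layers, function(l) l$type == "conv",
                           logical(1)))
  last_conv <- conv_idx[length(conv_idx)]
  relu_idx <- last_conv + 1          # activations: relu after the last conv
  A <- fw$cache[[relu_idx]]$out      # channels-first: K x h x w x 1
  # gradient w.r.t. the relu output = gradient into the layer that follows
  dA <- bw$dacts[[relu_idx + 1]]
  K <- dim(A)[1]; hh <- dim(A)[2]; ww <- dim(A)[3]
  alpha <- rowMeans(matrix(dA, K))
  raw <- matrix(crossprod(matrix(A, K), alpha), hh, ww)
  raw <- pmax(raw, 0)
  up <- bilinear_upsample(raw, dim(image)[1], dim(image)[2])
  mx <- max(up)
  values <- if (mx > 0) up / mx else up * 0
  structure(list(values = values, target_class = as.character(target_class),
                 source_layer = net$layers[[last_conv]]$name),
            class = "heatmap2d")
}

#' @export
print.heatmap2d <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap (%dx%d) for class '%s' from layer %s; max %.3f\n",
              nrow(x$values), ncol(x$values), x$target_class, x$source_layer,
              max(x$values)))
  invisible(x)
}

#' Blend a heatmap over an image with a blue-to-red colormap
#'
#' Relevance 0 maps to blue, 1 to red (through cyan and yellow); the colored
#' map is alpha-blended over the image.
#'
#' @param heatmap A `heatmap2d` or an `H x W` matrix in `[0, 1]`.
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param alpha Blend opacity in `[0, 1]`; 0 returns the image unchanged.
#' @return `H x W x 3` array in `[0, 255]`.
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.5) {
  hm <- if (inherits(heatmap, "heatmap2d")) heatmap$values else heatmap
  if (!all(dim(hm) == dim(image)[1:2])) stop("heatmap/image shape mismatch")
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(hm))     # n x 3 in 0..255
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image[, , ch] +
      alpha * matrix(cols[, ch], nrow(hm), ncol(hm))
  }
  out
}
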