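# Shared helpers: image I/O, manifests, seed fan-out.

#' Read an RGB image into a 0-255 numeric array
#'
#' @param path Path to a PNG (or, via EBImage, TIFF) file.
#' @return Numeric `H x W x 3` array with values in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write a 0-255 RGB array as PNG
#'
#' @param img Numeric `H x W x 3` array in `[0, 255]`.
#' @param path Output path; directories are created as needed.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Resize an RGB image (bilinear)
#'
#' Thin wrapper over [EBImage::resize()] applied per channel.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param height,width Target dimensions in pixels.
#' @return Resized `height x width x 3` array.
#' @export
resize_rgb <- function(img, height, width) {
  out <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) {
    out[, , ch] <- EBImage::resize(img[, , ch], w = height, h = width)
  }
  pmin(pmax(out, 0), 255)
}

#' Convert RGB to grayscale (ITU-R BT.601 luma)
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @return `H x W` matrix in `[0, 255]`.
#' @export
rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

manifest_cols <- c("image_path", "class", "subclass", "magnification",
                   "patient_id", "split_tag")

#' Read a dataset manifest CSV
#'
#' @param path CSV with header
#'   `image_path,class,subclass,magnification,patient_id,split_tag`.
#' @return A data.frame with those columns (missing optional columns are NA).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"image_path" %in% names(m) || !"class" %in% names(m)) {
    stop("manifest must contain image_path and class columns")
  }
  for (col in manifest_cols) if (!col %in% names(m)) m[[col]] <- NA
  m[, manifest_cols]
}

#' Write a dataset manifest CSV
#'
#' @param manifest Data.frame of records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Derive a child seed from a master seed and a stage tag
#'
#' One master seed fans out deterministically to per-stage seeds so a single
#' knob reproduces a whole experiment. Kept below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param tag Character stage tag.
#' @return Integer seed.
#' @export
derive_seed <- function(master, tag) {
  h <- as.integer(master) %% 2147483647L
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647L
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear upsampling of a matrix to (H, W), aligning pixel centres so the
# maximum stays within one source-cell radius of its original location.
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  yy <- (seq_len(H) - 0.5) / H * h + 0.5
  xx <- (seq_len(W) - 0.5) / W * w + 0.5
  y0 <- pmin(pmax(floor(yy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yy - y0, 0), 1); fx <- pmin(pmax(xx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, H), 1 - fx) + b * outer(rep(1, H), fx)
  bot <- c_ * outer(rep(1, H), 1 - fx) + d * outer(rep(1, H), fx)
  top * outer(1 - fy, rep(1, W)) + bot * outer(fy, rep(1, W))
}
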