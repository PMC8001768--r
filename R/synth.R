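# Seeded synthetic H&E-like patch generator.
#
# Images are composed in optical-density space under a two-stain
# Beer-Lambert model: RGB = 255 * 10^(-W %*% c), where W holds the unit-norm
# stain color vectors (hematoxylin-like, eosin-like) and c the per-pixel
# concentrations. Nuclei carry high hematoxylin concentration; stroma carries
# band-pass textured eosin. Class identity is encoded in nuclear count, size,
# eccentricity, margin irregularity, clustering and texture band, mirroring
# the morphology pathologists report: benign nuclei are smaller and rounder,
# malignant nuclei larger with irregular margins.

# Reference optical-density stain vectors (columns: hematoxylin, eosin),
# widely used literature values, normalized to unit Euclidean length.
default_stain_matrix <- function() {
  W <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

#' Specification of one synthetic tissue class
#'
#' Bundles the knobs that make classes visually distinct: how many nuclei, how
#' large, how elongated, how irregular their margins, how clustered they lie,
#' the spatial-frequency band of the background texture, and how much the
#' stain colors wobble from image to image.
#'
#' @param class_id Class label.
#' @param nucleus_count_range Integer pair, nuclei per patch (inclusive).
#' @param nucleus_radius_range Pixel pair, base nuclear radius before the
#'   magnification multiplier.
#' @param eccentricity_range Pair in `[0, 1)`; 0 is a circle.
#' @param margin_irregularity Amplitude `a >= 0` of the radial margin
#'   perturbation `r(theta) = r0 * (1 + a * sum of low-order sinusoids)`.
#' @param clustering In `[0, 1]`; 0 scatters nuclei uniformly, 1 packs them
#'   tightly around a few cluster seeds.
#' @param texture_band Spatial-frequency pair (cycles per image) of the
#'   band-pass background texture.
#' @param stain_jitter Standard deviation (>= 0) of the Gaussian perturbation
#'   applied to stain-matrix entries per image (columns renormalized after).
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(class_id,
                       nucleus_count_range = c(6, 12),
                       nucleus_radius_range = c(3, 5),
                       eccentricity_range = c(0, 0.4),
                       margin_irregularity = 0.05,
                       clustering = 0.2,
                       texture_band = c(4, 12),
                       stain_jitter = 0.02) {
  stopifnot(length(nucleus_count_range) == 2, length(nucleus_radius_range) == 2,
            length(eccentricity_range) == 2, length(texture_band) == 2)
  if (any(nucleus_count_range < 0) || diff(nucleus_count_range) < 0)
    stop("invalid nucleus_count_range")
  if (any(nucleus_radius_range <= 0) || diff(nucleus_radius_range) < 0)
    stop("invalid nucleus_radius_range")
  if (any(eccentricity_range < 0) || any(eccentricity_range >= 1) ||
      diff(eccentricity_range) < 0)
    stop("invalid eccentricity_range")
  if (margin_irregularity < 0) stop("margin_irregularity must be >= 0")
  if (clustering < 0 || clustering > 1) stop("clustering must lie in [0,1]")
  if (any(texture_band <= 0) || diff(texture_band) < 0)
    stop("invalid texture_band")
  if (stain_jitter < 0) stop("stain_jitter must be >= 0")
  structure(list(class_id = as.character(class_id),
                 nucleus_count_range = as.integer(round(nucleus_count_range)),
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 eccentricity_range = as.numeric(eccentricity_range),
                 margin_irregularity = as.numeric(margin_irregularity),
                 clustering = as.numeric(clustering),
                 texture_band = as.numeric(texture_band),
                 stain_jitter = as.numeric(stain_jitter)),
            class = "class_spec")
}

#' Default benign/malignant class specifications
#'
#' Benign patches carry fewer, smaller, rounder nuclei with smooth margins;
#' malignant patches carry more, larger, elongated nuclei with irregular
#' margins and coarser stromal texture.
#'
#' @return Named list of two `class_spec` objects (`benign`, `malignant`).
#' @export
default_class_specs <- function() {
  list(
    benign = class_spec("benign",
                        nucleus_count_range = c(5, 10),
                        nucleus_radius_range = c(2.5, 4.5),
                        eccentricity_range = c(0, 0.35),
                        margin_irregularity = 0.05,
                        clustering = 0.2,
                        texture_band = c(6, 16),
                        stain_jitter = 0.02),
    malignant = class_spec("malignant",
                           nucleus_count_range = c(9, 16),
                           nucleus_radius_range = c(6, 10),
                           eccentricity_range = c(0.3, 0.8),
                           margin_irregularity = 0.35,
                           clustering = 0.6,
                           texture_band = c(2, 8),
                           stain_jitter = 0.04)
  )
}

#' Default eight sub-class specifications
#'
#' Four benign-like (A, F, PT, TA) and four malignant-like (DC, LC, MC, PC)
#' sub-classes, interpolating morphology within each family so sub-classes
#' are separable but harder than the binary problem.
#'
#' @return Named list of eight `class_spec` objects.
#' @export
default_subclass_specs <- function() {
  benign_ids <- c("A", "F", "PT", "TA")
  malignant_ids <- c("DC", "LC", "MC", "PC")
  out <- list()
  for (i in seq_along(benign_ids)) {
    out[[benign_ids[i]]] <- class_spec(
      benign_ids[i],
      nucleus_count_range = c(4 + i, 8 + i),
      nucleus_radius_range = c(2 + 0.5 * i, 4 + 0.5 * i),
      eccentricity_range = c(0, 0.2 + 0.05 * i),
      margin_irregularity = 0.03 + 0.02 * i,
      clustering = 0.1 + 0.05 * i,
      texture_band = c(4 + i, 12 + 2 * i),
      stain_jitter = 0.02)
  }
  for (i in seq_along(malignant_ids)) {
    out[[malignant_ids[i]]] <- class_spec(
      malignant_ids[i],
      nucleus_count_range = c(8 + i, 14 + i),
      nucleus_radius_range = c(5 + 0.7 * i, 8 + 0.7 * i),
      eccentricity_range = c(0.25 + 0.05 * i, 0.7 + 0.02 * i),
      margin_irregularity = 0.25 + 0.05 * i,
      clustering = 0.4 + 0.1 * i,
      texture_band = c(1 + 0.5 * i, 6 + i),
      stain_jitter = 0.04)
  }
  out
}

# Magnification realized as a nucleus-scale multiplier at fixed patch size.
magnification_scale <- function(magnification) {
  scales <- c("40" = 1.0, "100" = 1.6, "200" = 2.5, "400" = 4.0)
  key <- as.character(magnification)
  if (!key %in% names(scales)) stop("magnification must be one of 40,100,200,400")
  scales[[key]]
}

# Band-pass filtered Gaussian noise, standardized to zero mean unit variance.
# Frequencies in cycles per image (relative to the smaller dimension).
bandpass_noise <- function(h, w, f_lo, f_hi) {
  z <- matrix(stats::rnorm(h * w), h, w)
  Z <- stats::fft(z)
  fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
  fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
  r <- sqrt(outer(fy^2, fx^2, "+")) * min(h, w)
  mask <- (r >= f_lo) & (r <= f_hi)
  if (!any(mask)) mask[which.min(abs(r - (f_lo + f_hi) / 2))] <- TRUE
  out <- Re(stats::fft(Z * mask, inverse = TRUE)) / (h * w)
  s <- stats::sd(out)
  if (s < 1e-12) matrix(0, h, w) else (out - mean(out)) / s
}

# Rasterize one nucleus with sinusoidally perturbed elliptical margin into
# the running mask; returns the logical pixel set of this nucleus.
render_nucleus <- function(h, w, cx, cy, r0, ecc, phi, amp) {
  ry <- r0
  rx <- r0 * sqrt(1 - ecc^2)
  pad <- ceiling(r0 * (1 + 2 * amp)) + 1
  rows <- max(1, floor(cy - pad)):min(h, ceiling(cy + pad))
  cols <- max(1, floor(cx - pad)):min(w, ceiling(cx + pad))
  if (!length(rows) || !length(cols)) return(NULL)
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  rho <- sqrt((u / rx)^2 + (v / ry)^2)
  theta <- atan2(v / ry, u / rx)
  # low-order sinusoidal margin perturbation with random phases
  kk <- 2:5
  coef <- stats::runif(length(kk)); coef <- coef / sum(coef)
  ph <- stats::runif(length(kk), 0, 2 * pi)
  lim <- 1
  for (j in seq_along(kk)) lim <- lim + amp * coef[j] * sin(kk[j] * theta + ph[j])
  inside <- rho <= lim
  list(rows = rows, cols = cols, inside = inside)
}

#' Generate one synthetic H&E-like image patch with ground truth
#'
#' Deterministic for fixed `(spec, size, seed)`. Pixels are composed as
#' `RGB = 255 * 10^(-W c)` (Beer-Lambert in optical density), with nuclei
#' carrying hematoxylin-like concentration and stroma eosin-like textured
#' concentration, then rounded and clipped to `[0, 255]`.
#'
#' @param spec A [class_spec()].
#' @param size Pixel pair `c(height, width)`, each >= 32.
#' @param seed Integer seed.
#' @param magnification One of 40, 100, 200, 400; scales nuclear radii.
#' @param signal_quadrant One of `"none"`, `"TL"`, `"TR"`, `"BL"`, `"BR"`;
#'   if not `"none"`, all nuclei are confined to that quadrant (used to plant
#'   localizable signal for heatmap checks).
#' @return List with `image` (`H x W x 3`, 0-255) and `truth` (list with
#'   `nucleus_centers` matrix, logical `nucleus_mask`, `signal_quadrant`).
#' @export
generate_image <- function(spec, size = c(96, 96), seed = 1,
                           magnification = 40, signal_quadrant = "none") {
  if (!inherits(spec, "class_spec")) stop("spec must be a class_spec")
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 32)) stop("size must be >= 32x32")
  signal_quadrant <- match.arg(signal_quadrant,
                               c("none", "TL", "TR", "BL", "BR"))
  h <- size[1]; w <- size[2]
  set.seed(as.integer(seed))

  # per-image stain matrix jitter
  W <- default_stain_matrix()
  if (spec$stain_jitter > 0) {
    W <- W + matrix(stats::rnorm(6, 0, spec$stain_jitter), 3, 2)
    W <- pmax(W, 1e-3)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  }

  # stromal eosin concentration: base + band-pass texture
  tex <- bandpass_noise(h, w, spec$texture_band[1], spec$texture_band[2])
  c_eos <- pmax(0.35 + 0.18 * tex, 0)
  # stroma is essentially pure eosin: a faint, independent hematoxylin wash
  # keeps the two concentration maps uncorrelated (identifiable separation)
  c_hem_bg <- pmax(0.015 + 0.01 * bandpass_noise(h, w, 2, 10), 0)

  # nucleus placement
  n_nuc <- if (spec$nucleus_count_range[2] == 0) 0L else
    sample(spec$nucleus_count_range[1]:spec$nucleus_count_range[2], 1)
  mscale <- magnification_scale(magnification)
  qlim <- switch(signal_quadrant,
                 none = c(1, h, 1, w),
                 TL = c(1, floor(h / 2), 1, floor(w / 2)),
                 TR = c(1, floor(h / 2), floor(w / 2) + 1, w),
                 BL = c(floor(h / 2) + 1, h, 1, floor(w / 2)),
                 BR = c(floor(h / 2) + 1, h, floor(w / 2) + 1, w))
  mask <- matrix(FALSE, h, w)
  centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (n_nuc > 0) {
    n_clust <- max(1L, round(1 + (1 - spec$clustering) * 3))
    clust_r <- c(stats::runif(n_clust, qlim[1], qlim[2]))
    clust_c <- c(stats::runif(n_clust, qlim[3], qlim[4]))
    spread_r <- (qlim[2] - qlim[1]) * (1 - 0.7 * spec$clustering) / 2
    spread_c <- (qlim[4] - qlim[3]) * (1 - 0.7 * spec$clustering) / 2
    for (i in seq_len(n_nuc)) {
      j <- sample.int(n_clust, 1)
      r0 <- stats::runif(1, spec$nucleus_radius_range[1],
                         spec$nucleus_radius_range[2]) * mscale
      # when signal is planted in a quadrant, the whole nucleus body must
      # stay inside it, so inset the center range by the outer radius
      inset <- if (signal_quadrant == "none") 0 else
        min(r0 * (1 + 2 * spec$margin_irregularity),
            (qlim[2] - qlim[1]) / 2, (qlim[4] - qlim[3]) / 2)
      cy <- min(max(clust_r[j] + stats::rnorm(1, 0, spread_r),
                    qlim[1] + inset), qlim[2] - inset)
      cx <- min(max(clust_c[j] + stats::rnorm(1, 0, spread_c),
                    qlim[3] + inset), qlim[4] - inset)
      ecc <- stats::runif(1, spec$eccentricity_range[1],
                          spec$eccentricity_range[2])
      phi <- stats::runif(1, 0, pi)
      nuc <- render_nucleus(h, w, cx, cy, r0, ecc, phi,
                            spec$margin_irregularity)
      if (is.null(nuc)) next
      mask[nuc$rows, nuc$cols] <- mask[nuc$rows, nuc$cols] | nuc$inside
      centers <- rbind(centers, c(cy, cx))
    }
  }

  # chromatin texture inside nuclei
  chrom <- bandpass_noise(h, w, 8, 24)
  c_hem <- c_hem_bg
  c_hem[mask] <- pmax(0.85 + 0.12 * chrom[mask], 0.3)
  # dense chromatin largely excludes eosin
  c_eos[mask] <- c_eos[mask] * 0.08

  od <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) od[, , ch] <- W[ch, 1] * c_hem + W[ch, 2] * c_eos
  img <- round(255 * 10^(-od))
  img <- pmin(pmax(img, 0), 255)

  list(image = img,
       truth = list(nucleus_centers = centers,
                    nucleus_mask = mask,
                    signal_quadrant = signal_quadrant))
}

#' Generate a synthetic dataset with a CSV manifest
#'
#' Writes one PNG per record plus a manifest CSV
#' (`image_path,class,subclass,magnification,patient_id,split_tag`) and a
#' JSON sidecar recording the generator parameters and seed.
#'
#' @param design Data.frame with columns `class`, `n`, and optionally
#'   `subclass` and `magnification`; one row per design cell.
#' @param out_dir Output directory (created).
#' @param seed Integer master seed.
#' @param specs Named list of `class_spec`s keyed by `subclass` when present,
#'   else by `class`. Defaults to the benign/malignant pair augmented with
#'   the eight sub-class specs.
#' @param size Patch size `c(height, width)`.
#' @param n_patients Number of synthetic patient IDs to cycle through.
#' @param signal_quadrant Passed through to [generate_image()].
#' @return The manifest data.frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(design, out_dir, seed = 1, specs = NULL,
                             size = c(96, 96), n_patients = 10,
                             signal_quadrant = "none") {
  if (!is.data.frame(design) || nrow(design) == 0)
    stop("design must be a non-empty data.frame")
  if (!all(c("class", "n") %in% names(design)))
    stop("design needs columns class and n")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (is.null(specs)) specs <- c(default_class_specs(), default_subclass_specs())

  recs <- list()
  for (r in seq_len(nrow(design))) {
    cls <- as.character(design$class[r])
    sub <- if ("subclass" %in% names(design)) as.character(design$subclass[r]) else NA
    mag <- if ("magnification" %in% names(design)) design$magnification[r] else 40
    key <- if (!is.na(sub) && sub %in% names(specs)) sub else cls
    if (!key %in% names(specs)) stop("no class_spec for design cell: ", key)
    for (i in seq_len(design$n[r])) {
      tag <- paste(key, mag, i, sep = "_")
      s_i <- derive_seed(seed, tag)
      gen <- generate_image(specs[[key]], size = size, seed = s_i,
                            magnification = mag,
                            signal_quadrant = signal_quadrant)
      rel <- file.path(cls, sprintf("%s_m%s_%03d.png", key, mag, i))
      write_image_rgb(gen$image, file.path(out_dir, rel))
      recs[[length(recs) + 1]] <- data.frame(
        image_path = rel, class = cls, subclass = sub,
        magnification = mag,
        patient_id = sprintf("P%02d", (s_i %% n_patients) + 1),
        split_tag = NA, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, recs)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(
    list(seed = seed, size = size, n_patients = n_patients,
         signal_quadrant = signal_quadrant,
         design = design,
         specs = lapply(specs, unclass)),
    file.path(out_dir, "generator_params.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a 20-class texture-patch fixture
#'
#' Emulates the structure of a magnification-free 20-class histology texture
#' benchmark: `n_per_class` patches of `308 x 168` pixels (width x height) per
#' class, classes labelled `A` through `T`, each class with distinct texture
#' band and stain parameters. Images are written as PNG (lossless; the
#' manifest records the format via the file extension).
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param n_per_class Patches per class (default 48, giving 960 records).
#' @return The manifest data.frame, also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_kimia_fixture <- function(out_dir, seed = 1, n_per_class = 48) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ids <- LETTERS[1:20]
  specs <- list()
  for (i in seq_along(ids)) {
    # sweep texture scale, nuclear density and stain balance across classes
    f_lo <- 1 + (i - 1) %% 5 * 2
    f_hi <- f_lo + 4 + (i - 1) %/% 5 * 6
    specs[[ids[i]]] <- class_spec(
      ids[i],
      nucleus_count_range = if (i %% 4 == 0) c(0, 0) else c(2 * (i %% 5), 4 + 2 * (i %% 5)),
      nucleus_radius_range = c(2 + (i %% 3), 4 + (i %% 3)),
      eccentricity_range = c(0, 0.3 + 0.02 * i),
      margin_irregularity = 0.02 * (i %% 6),
      clustering = (i %% 4) / 4,
      texture_band = c(f_lo, f_hi),
      stain_jitter = 0.01 + 0.002 * i)
  }
  design <- data.frame(class = ids, n = n_per_class)
  manifest <- generate_dataset(design, out_dir, seed = seed, specs = specs,
                               size = c(168, 308))
  manifest$magnification <- NA
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' @export
print.class_spec <- function(x, ...) {
  cat("Synthetic tissue class spec:", x$class_id, "\n")
  cat(sprintf("  nuclei %d-%d, radius %.1f-%.1f px, ecc %.2f-%.2f\n",
              x$nucleus_count_range[1], x$nucleus_count_range[2],
              x$nucleus_radius_range[1], x$nucleus_radius_range[2],
              x$eccentricity_range[1], x$eccentricity_range[2]))
  cat(sprintf("  margin irregularity %.2f, clustering %.2f, texture band %.1f-%.1f c/img, stain jitter %.3f\n",
              x$margin_irregularity, x$clustering,
              x$texture_band[1], x$texture_band[2], x$stain_jitter))
  invisible(x)
}
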