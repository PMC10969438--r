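# Image-quality report (PSNR / SSIM / MSE / MAD) and dataset class
# assessment (imbalance ratio, intra/inter-class distances, silhouette).

#' Image quality metrics between a reference and a processed image
#'
#' If the two images differ in geometry the reference is first resized onto
#' the processed geometry (bilinear), mirroring the usual difference-image
#' comparison.  PSNR uses `peak = 1` for unit-scaled images and `peak =
#' 255` for 8-bit-range inputs unless given explicitly; identical images
#' report `psnr = Inf`.  SSIM is the standard single-scale formulation with
#' an 11 x 11 Gaussian window (sd 1.5) and constants `K1 = 0.01`,
#' `K2 = 0.03`.
#'
#' @param reference,processed Matrices or `H x W x C` arrays.
#' @param peak Peak signal value; `NULL` to auto-detect.
#' @return List of class `quality_report` with `psnr`, `ssim`, `mse`,
#'   `mad`, `peak`.
#' @export
image_quality_metrics <- function(reference, processed, peak = NULL) {
  gray <- function(x) if (length(dim(x)) == 3L) luminance(x) else x
  ref <- gray(reference); prc <- gray(processed)
  if (!all(dim(ref) == dim(prc))) {
    if (nrow(prc) != ncol(prc)) stop("geometry mismatch: processed image is not square")
    ref <- resize_image(ref, nrow(prc))
  }
  if (!all(dim(ref) == dim(prc))) stop("shape mismatch after alignment")
  if (is.null(peak)) peak <- if (max(abs(ref), abs(prc)) > 1.5) 255 else 1
  d <- ref - prc
  mse <- mean(d^2)
  mad <- mean(abs(d))
  psnr <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  ssim <- ssim_index(ref, prc, peak = peak)
  structure(list(psnr = psnr, ssim = ssim, mse = mse, mad = mad, peak = peak),
            class = "quality_report")
}

# Single-scale SSIM with Gaussian window; mean over the SSIM map.
ssim_index <- function(x, y, peak = 1, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  w <- gaussian_kernel_1d(sigma, radius = 5L)  # 11-tap window
  f <- function(m) conv_separable(m, w)
  c1 <- (k1 * peak)^2; c2 <- (k2 * peak)^2
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2; syy <- f(y * y) - my^2; sxy <- f(x * y) - mx * my
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Class-assessment metrics for a labeled set of image vectors
#'
#' `imbr` is the majority/minority count ratio; `intrac` the mean pairwise
#' Euclidean distance between same-class vectors; `interc` the mean
#' pairwise distance between vectors of different classes; `distr` their
#' ratio `intrac / interc`; `silho` the mean silhouette width over all
#' vectors.  Classes with fewer than two members contribute no intra-class
#' pairs; if no intra-class pair exists at all, `intrac` and `distr` are
#' `NA`.
#'
#' @param vectors Numeric matrix, one row per image (flattened pixels or
#'   any feature vector).
#' @param labels Vector of class labels, one per row.
#' @return List of class `class_assessment`.
#' @export
class_assessment <- function(vectors, labels) {
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  stopifnot(nrow(vectors) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least two classes")
  D <- as.matrix(stats::dist(vectors))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  intra_pairs <- D[ut & same]
  inter_pairs <- D[ut & !same]
  intrac <- if (length(intra_pairs)) mean(intra_pairs) else NA_real_
  interc <- mean(inter_pairs)
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  structure(list(imbr = as.numeric(max(counts) / min(counts)),
                 intrac = intrac,
                 interc = interc,
                 distr = if (is.na(intrac)) NA_real_ else intrac / interc,
                 silho = mean(sil[, "sil_width"]),
                 class_counts = counts),
            class = "class_assessment")
}

#' Flatten manifest images into a vector matrix for class assessment
#'
#' Reads every image in the manifest, resizes to a common small side and
#' flattens to rows.
#'
#' @param manifest Data frame with `image` and `label` columns.
#' @param side Common resize side before flattening.
#' @return List with `vectors` (matrix) and `labels`.
#' @export
manifest_vectors <- function(manifest, side = 32L) {
  vecs <- lapply(manifest$image, function(p) {
    as.numeric(resize_image(png::readPNG(p), side))
  })
  list(vectors = do.call(rbind, vecs), labels = manifest$label)
}
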