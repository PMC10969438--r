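# Preprocessing: resizing, intensity normalization, augmentation, splits.

#' Intensity-normalization parameters
#'
#' Target mean `n0` and target variance `var0` of the normalized image.
#' The defaults (0 and 1) place most output intensities in `[-1, 1]`.
#'
#' @param n0 Target mean.
#' @param var0 Target variance (>= 0).
#' @export
norm_params <- function(n0 = 0, var0 = 1) {
  stopifnot(var0 >= 0)
  structure(list(n0 = n0, var0 = var0), class = "norm_params")
}

#' Resize an image with bilinear interpolation
#'
#' Half-pixel-center alignment: output pixel `(i, j)` samples the source at
#' `((i + 0.5) * H/side - 0.5, (j + 0.5) * W/side - 0.5)`, clamped to the
#' image domain.  An input already at the target size is returned
#' unchanged.
#'
#' @param img `H x W` matrix or `H x W x C` array, unit-scaled.
#' @param side Target side length in pixels (output is `side x side`).
#' @return Resized image of the same type.
#' @export
resize_image <- function(img, side = 299L) {
  if (side < 1) stop("side must be at least 1")
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (H == side && W == side) return(img)
  ys <- ((seq_len(side) - 0.5) * H / side) - 0.5
  xs <- ((seq_len(side) - 0.5) * W / side) - 0.5
  yy <- rep(ys, times = side); xx <- rep(xs, each = side)
  if (length(d) == 2L) {
    return(matrix(bilinear_sample(img, yy, xx), side, side))
  }
  out <- array(0, c(side, side, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], yy, xx), side, side)
  }
  out
}

#' Mean-variance intensity normalization
#'
#' Maps each pixel to `n0 + sqrt(var0 * (H - N)^2 / VAR)` when the pixel
#' exceeds the image mean `N` and to `n0 - sqrt(...)` otherwise, where `N`
#' and `VAR` are the population mean and variance of the input.  The output
#' therefore has population mean exactly `n0` and population variance
#' exactly `var0`.  A constant input (zero variance) maps to the constant
#' `n0`.  RGB arrays are normalized per channel independently.
#'
#' @param img `H x W` matrix or `H x W x C` array.
#' @param params A [norm_params()].
#' @return Normalized image, same shape.
#' @export
normalize_image <- function(img, params = norm_params()) {
  d <- dim(img)
  if (length(d) == 3L) {
    for (ch in seq_len(d[3])) img[, , ch] <- normalize_image(img[, , ch], params)
    return(img)
  }
  n <- length(img)
  N <- mean(img)
  VAR <- sum((img - N)^2) / n  # population variance
  if (VAR <= 0) {
    img[] <- params$n0
    return(img)
  }
  dev <- sqrt(params$var0 * (img - N)^2 / VAR)
  out <- ifelse(img > N, params$n0 + dev, params$n0 - dev)
  matrix(out, d[1], d[2])
}

#' Augmentation parameters
#'
#' Ranges follow common dermoscopy practice: rotations within +/-15
#' degrees, random horizontal/vertical flips, contrast factors in
#' `[0.7, 1.3]`, mild brightness scaling, random crop-and-resize, and
#' additive Gaussian noise.
#'
#' @param rotation_range Max absolute rotation in degrees (symmetric).
#' @param hflip_prob,vflip_prob Flip probabilities.
#' @param brightness_range Multiplicative brightness factor range.
#' @param contrast_range Contrast factor range (about the image mean).
#' @param crop_fraction_range Range of the linear crop fraction.
#' @param noise_sd Additive Gaussian noise sd (unit-scaled intensities).
#' @export
augment_params <- function(rotation_range = 15,
                           hflip_prob = 0.5,
                           vflip_prob = 0.5,
                           brightness_range = c(0.9, 1.1),
                           contrast_range = c(0.7, 1.3),
                           crop_fraction_range = c(0.85, 1.0),
                           noise_sd = 0.01) {
  stopifnot(rotation_range >= 0,
            hflip_prob >= 0, hflip_prob <= 1, vflip_prob >= 0, vflip_prob <= 1,
            all(contrast_range > 0))
  structure(list(rotation_range = rotation_range,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 crop_fraction_range = crop_fraction_range,
                 noise_sd = noise_sd), class = "augment_params")
}

rotate_channel <- function(m, angle_deg) {
  if (angle_deg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- angle_deg * pi / 180
  ys <- rep(0:(H - 1), times = W) - cy
  xs <- rep(0:(W - 1), each = H) - cx
  sy <- cy + cos(th) * ys - sin(th) * xs
  sx <- cx + sin(th) * ys + cos(th) * xs
  matrix(bilinear_sample(m, sy, sx), H, W)
}

apply_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- f(img[, , ch])
  img
}

#' Randomly augment an image
#'
#' Applies, in fixed order: rotation, flips, brightness/contrast scaling,
#' crop-and-resize, additive noise.  Degenerate ranges collapse to the
#' identity.  Draws come from the current RNG stream unless `seed` is
#' given.
#'
#' @param img `H x W` matrix or `H x W x C` array, unit-scaled.
#' @param params An [augment_params()].
#' @param seed Optional integer seed.
#' @return Augmented image, same shape; also carries the sampled draws as
#'   attribute `"draws"`.
#' @export
augment <- function(img, params = augment_params(), seed = NULL) {
  with_seed(seed, {
    H <- dim(img)[1]; W <- dim(img)[2]
    draws <- list(
      rotation = stats::runif(1, -params$rotation_range, params$rotation_range),
      hflip = stats::runif(1) < params$hflip_prob,
      vflip = stats::runif(1) < params$vflip_prob,
      brightness = stats::runif(1, params$brightness_range[1], params$brightness_range[2]),
      contrast = stats::runif(1, params$contrast_range[1], params$contrast_range[2]),
      crop = stats::runif(1, params$crop_fraction_range[1], params$crop_fraction_range[2]))
    out <- apply_channels(img, function(m) rotate_channel(m, draws$rotation))
    if (draws$hflip) out <- apply_channels(out, function(m) m[, ncol(m):1, drop = FALSE])
    if (draws$vflip) out <- apply_channels(out, function(m) m[nrow(m):1, , drop = FALSE])
    out <- out * draws$brightness
    mu <- mean(out)
    out <- (out - mu) * draws$contrast + mu
    if (draws$crop < 1) {
      ch <- max(2L, round(H * draws$crop)); cw <- max(2L, round(W * draws$crop))
      r0 <- sample.int(H - ch + 1L, 1L); c0 <- sample.int(W - cw + 1L, 1L)
      cropped <- if (is.matrix(out)) out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
                 else out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), , drop = FALSE]
      # restore the original geometry (assumes square targets for arrays)
      if (is.matrix(cropped)) {
        out <- resize_image(cropped, H)
      } else {
        out <- resize_image(cropped, H)
      }
    }
    if (params$noise_sd > 0) {
      out <- out + stats::rnorm(length(out), 0, params$noise_sd)
    }
    out <- clamp01(out)
    attr(out, "draws") <- draws
    out
  })
}

#' Train/validation/test split specification
#'
#' @param fractions Length-3 non-negative fractions summing to 1
#'   (train, validation, test).
#' @param seed Integer seed for the shuffle.
#' @param stratified Preserve per-class proportions (default `TRUE`).
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1L,
                       stratified = TRUE) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9)
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = stratified), class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to fracs.
apportion <- function(n, fracs) {
  exact <- n * fracs
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(exact - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a manifest into train/validation/test manifests
#'
#' Sizes follow largest-remainder apportionment of the fractions; with
#' `stratified = TRUE` the apportionment is applied per class, so per-split
#' class proportions match the overall proportions within one record.
#' Splitting is deterministic given the spec's seed.
#'
#' @param manifest Data frame with at least a `label` column.
#' @param spec A [split_spec()].
#' @return Named list of data frames `train`, `val`, `test`; each row of
#'   `manifest` appears in exactly one of them.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  n <- nrow(manifest)
  empty <- manifest[integer(0), , drop = FALSE]
  if (n == 0) return(list(train = empty, val = empty, test = empty))
  assign_split <- function(idx, k) {
    counts <- apportion(length(idx), spec$fractions)
    perm <- if (length(idx) == 1L) idx else with_seed(spec$seed + k, sample(idx))
    stats::setNames(rep(c("train", "val", "test"), counts), perm)
  }
  labels_for <- character(n)
  if (spec$stratified && "label" %in% names(manifest)) {
    classes <- unique(manifest$label)
    for (k in seq_along(classes)) {
      idx <- which(manifest$label == classes[k])
      s <- assign_split(idx, k)
      labels_for[as.integer(names(s))] <- s
    }
  } else {
    s <- assign_split(seq_len(n), 0L)
    labels_for[as.integer(names(s))] <- s
  }
  list(train = manifest[labels_for == "train", , drop = FALSE],
       val = manifest[labels_for == "val", , drop = FALSE],
       test = manifest[labels_for == "test", , drop = FALSE])
}
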