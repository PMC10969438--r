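# Synthetic dermoscopy-like image generator.
#
# Lesions are star-shaped regions with boundary radius
#   r(theta) = r0(theta) * (1 + sum_i a_i * sin(f_i * theta + phi_i)),
# where r0(theta) traces an axis-aligned ellipse with the requested
# major/minor radii.  The boundary is sampled at 720 angles and rasterized
# by even-odd polygon scan fill, so every ground-truth mask has an exact
# analytic polygon to check against.  Benign lesions keep all harmonic
# amplitudes at or below 0.05 (near-elliptical, border irregularity index
# close to 1); malignant lesions carry at least one harmonic of amplitude
# >= 0.25 at angular frequency >= 6, which pushes the irregularity index
# past the clinical 1.8 decision threshold by construction.  Hair strokes
# (dark, 1-3 px, anti-aliased quadratic Bezier) and bubbles (bright soft
# discs) emulate the acquisition artifacts the preprocessing and
# segmentation stages must tolerate.

N_BOUNDARY_SAMPLES <- 720L

#' Specification of one synthetic lesion
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param center Numeric `(y, x)` lesion center in 0-based pixel coordinates.
#' @param radii Numeric `(major, minor)` ellipse radii in pixels.
#' @param boundary_harmonics Matrix with columns `amplitude`, `frequency`,
#'   `phase`: sinusoidal radius perturbations. May have zero rows.
#' @param base_color Length-3 RGB triple in `[0, 1]`.
#' @param color_variegation Per-channel sd of the smooth intra-lesion color
#'   noise field.
#' @param hair_count,bubble_count Number of artifact strokes / bubbles.
#' @param rng_seed Integer seed; everything drawn for this lesion flows
#'   from it.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(class_label,
                        center,
                        radii,
                        boundary_harmonics = NULL,
                        base_color = c(0.45, 0.30, 0.24),
                        color_variegation = c(0.02, 0.02, 0.02),
                        hair_count = 0L,
                        bubble_count = 0L,
                        rng_seed = 1L) {
  class_label <- match.arg(class_label, c("benign", "malignant"))
  if (is.null(boundary_harmonics)) {
    boundary_harmonics <- matrix(numeric(0), 0, 3)
  }
  boundary_harmonics <- matrix(as.numeric(boundary_harmonics), ncol = 3,
                               dimnames = list(NULL, c("amplitude", "frequency", "phase")))
  amps <- boundary_harmonics[, "amplitude"]
  if (class_label == "malignant" &&
      !any(amps >= 0.25 & boundary_harmonics[, "frequency"] >= 2)) {
    stop("malignant specs need at least one boundary harmonic with amplitude >= 0.25")
  }
  if (class_label == "benign" && any(amps > 0.05)) {
    stop("benign specs must keep all harmonic amplitudes <= 0.05")
  }
  structure(list(class_label = class_label,
                 center = as.numeric(center),
                 radii = as.numeric(radii),
                 boundary_harmonics = boundary_harmonics,
                 base_color = as.numeric(base_color),
                 color_variegation = rep_len(as.numeric(color_variegation), 3L),
                 hair_count = as.integer(hair_count),
                 bubble_count = as.integer(bubble_count),
                 rng_seed = as.integer(rng_seed)),
            class = "lesion_spec")
}

#' Analytic boundary polygon of a lesion spec
#'
#' @param spec A [lesion_spec()].
#' @param n Number of angular samples.
#' @return `n x 2` matrix of `(y, x)` vertices.
#' @export
lesion_boundary <- function(spec, n = N_BOUNDARY_SAMPLES) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- spec$radii[1]; b <- spec$radii[2]
  r0 <- 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
  pert <- rep(1, n)
  h <- spec$boundary_harmonics
  if (nrow(h) > 0) {
    for (i in seq_len(nrow(h))) {
      pert <- pert + h[i, 1] * sin(h[i, 2] * theta + h[i, 3])
    }
  }
  r <- r0 * pert
  cbind(y = spec$center[1] + r * sin(theta), x = spec$center[2] + r * cos(theta))
}

max_lesion_radius <- function(spec) {
  b <- lesion_boundary(spec)
  max(sqrt((b[, 1] - spec$center[1])^2 + (b[, 2] - spec$center[2])^2))
}

# Render one anti-aliased quadratic Bezier stroke onto an H x W alpha map.
render_bezier_stroke <- function(H, W, p0, p1, p2, width) {
  t <- seq(0, 1, length.out = 4L * max(H, W))
  by <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  bx <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  alpha <- matrix(0, H, W)
  sigma <- width / 2
  rad <- ceiling(2 * sigma)
  for (k in seq_along(t)) {
    r0 <- round(by[k]); c0 <- round(bx[k])
    if (r0 + rad < 0 || r0 - rad > H - 1 || c0 + rad < 0 || c0 - rad > W - 1) next
    rr <- max(0, r0 - rad):min(H - 1, r0 + rad)
    cc <- max(0, c0 - rad):min(W - 1, c0 + rad)
    d2 <- outer((rr - by[k])^2, (cc - bx[k])^2, "+")
    a <- exp(-d2 / (2 * sigma^2))
    idx <- cbind(rep(rr + 1, length(cc)), rep(cc + 1, each = length(rr)))
    alpha[idx] <- pmax(alpha[idx], as.numeric(a))
  }
  alpha
}

# Smooth random field in [-1, 1]-ish range: white noise blurred by a
# Gaussian, then rescaled to unit sd.
smooth_noise_field <- function(H, W, sigma = 6) {
  z <- matrix(stats::rnorm(H * W), H, W)
  z <- conv_separable(z, gaussian_kernel_1d(sigma))
  s <- stats::sd(as.numeric(z))
  if (s < 1e-12) return(matrix(0, H, W))
  z / s
}

#' Render a synthetic dermoscopy image from a lesion spec
#'
#' Deterministic given `spec$rng_seed`.  Returns the 8-bit-quantized RGB
#' image together with the exact ground-truth lesion mask rasterized from
#' the analytic boundary polygon, plus the hair-stroke alpha mask used to
#' paint artifacts (useful as ground truth for the hair detector).
#'
#' @param spec A [lesion_spec()].
#' @param canvas `(height, width)` in pixels, each at least 64.
#' @return List with `image` (`H x W x 3` array in `[0,1]`), `mask`
#'   (`H x W` 0/1 matrix), `hair_mask` (`H x W` 0/1 matrix) and `spec`.
#' @export
generate_lesion_image <- function(spec, canvas = c(96L, 96L)) {
  H <- as.integer(canvas[1]); W <- as.integer(canvas[2])
  if (H < 64L || W < 64L) stop("canvas must be at least 64 x 64")
  rmax <- max_lesion_radius(spec)
  margin <- min(spec$center[1], H - 1 - spec$center[1],
                spec$center[2], W - 1 - spec$center[2])
  if (rmax > 0.9 * margin) {
    stop(sprintf("lesion (max radius %.1f px) exceeds the 10%% canvas margin (%.1f px available)",
                 rmax, 0.9 * margin))
  }
  seeds <- derive_seeds(spec$rng_seed, 4L)
  boundary <- lesion_boundary(spec)
  mask <- rasterize_polygon(boundary, c(H, W))

  img <- with_seed(seeds[1], {
    skin <- c(0.86, 0.70, 0.62)
    img <- array(0, c(H, W, 3))
    shade <- smooth_noise_field(H, W, sigma = 12) * 0.015
    for (ch in 1:3) img[, , ch] <- skin[ch] + shade + stats::rnorm(H * W, 0, 0.004)

    # anti-aliased lesion edge: per-pixel area coverage of the analytic
    # polygon, so thin border structures keep their true opacity
    soft <- rasterize_polygon_coverage(boundary, c(H, W))
    for (ch in 1:3) {
      tex <- smooth_noise_field(H, W, sigma = 3) * spec$color_variegation[ch]
      lesion_col <- clamp01(spec$base_color[ch] + tex)
      img[, , ch] <- img[, , ch] * (1 - soft) + lesion_col * soft
    }
    img
  })

  hair_mask <- matrix(0, H, W)
  if (spec$hair_count > 0) {
    hair_mask <- with_seed(seeds[2], {
      hm <- matrix(0, H, W)
      lesion_area <- sum(mask)
      edge_point <- function() {
        # random point on a random image edge, so strokes span the canvas
        side <- sample.int(4L, 1L)
        switch(side,
               c(0, stats::runif(1, 0, W - 1)),
               c(H - 1, stats::runif(1, 0, W - 1)),
               c(stats::runif(1, 0, H - 1), 0),
               c(stats::runif(1, 0, H - 1), W - 1))
      }
      for (i in seq_len(spec$hair_count)) {
        for (attempt in 1:10) {
          p0 <- edge_point(); p2 <- edge_point()
          if (sum((p0 - p2)^2) < (min(H, W) / 2)^2) next  # too short
          mid <- (p0 + p2) / 2 + stats::rnorm(2, 0, min(H, W) / 5)
          wdt <- stats::runif(1, 1, 3)
          a <- render_bezier_stroke(H, W, p0, mid, p2, wdt)
          cand <- pmax(hm, a)
          # keep hair coverage of the lesion below 30% so segmentation
          # stays well-posed
          if (sum((cand > 0.5) & (mask == 1)) <= 0.3 * lesion_area) {
            hm <- cand
            break
          }
        }
      }
      hm
    })
    hair_col <- c(0.12, 0.09, 0.07)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - hair_mask) + hair_col[ch] * hair_mask
    }
  }

  if (spec$bubble_count > 0) {
    img <- with_seed(seeds[3], {
      for (i in seq_len(spec$bubble_count)) {
        cy <- stats::runif(1, 0, H - 1); cx <- stats::runif(1, 0, W - 1)
        r <- stats::runif(1, 2, 5)
        rr <- max(0, floor(cy - 3 * r)):min(H - 1, ceiling(cy + 3 * r))
        cc <- max(0, floor(cx - 3 * r)):min(W - 1, ceiling(cx + 3 * r))
        d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
        a <- 0.35 * exp(-d2 / (2 * (r / 1.5)^2))
        for (ch in 1:3) {
          img[rr + 1, cc + 1, ch] <- img[rr + 1, cc + 1, ch] * (1 - a) + 1 * a
        }
      }
      img
    })
  }

  img <- clamp01(img)
  img <- round(img * 255) / 255  # 8-bit quantization, matches PNG round-trip
  list(image = img, mask = mask,
       hair_mask = (hair_mask > 0.5) + 0L,       # stroke cores
       hair_footprint = (hair_mask > 0.02) + 0L, # any pixel a stroke touched
       spec = spec)
}

# Draw a random spec of the given class.  Amplitude and frequency ranges
# implement the class contracts: benign all-harmonics <= 0.05, malignant
# at least one harmonic >= 0.25 (drawn in [0.28, 0.40], frequency 6-9).
random_lesion_spec <- function(class_label, canvas, seed,
                               hair_range = c(0L, 3L),
                               bubble_range = c(0L, 2L)) {
  with_seed(seed, {
    H <- canvas[1]; W <- canvas[2]
    short <- min(H, W)
    major <- stats::runif(1, 0.22, 0.30) * short
    minor <- stats::runif(1, 0.80, 1.00) * major
    if (class_label == "malignant") {
      harmonics <- rbind(
        c(stats::runif(1, 0.28, 0.40), sample(6:9, 1), stats::runif(1, 0, 2 * pi)),
        c(stats::runif(1, 0.02, 0.05), sample(3:5, 1), stats::runif(1, 0, 2 * pi)))
      base_color <- c(stats::runif(1, 0.28, 0.38), stats::runif(1, 0.16, 0.24),
                      stats::runif(1, 0.12, 0.20))
      varieg <- rep(stats::runif(1, 0.05, 0.09), 3)
    } else {
      harmonics <- rbind(
        c(stats::runif(1, 0.01, 0.05), sample(3:6, 1), stats::runif(1, 0, 2 * pi)))
      base_color <- c(stats::runif(1, 0.52, 0.62), stats::runif(1, 0.36, 0.44),
                      stats::runif(1, 0.28, 0.36))
      varieg <- rep(stats::runif(1, 0.01, 0.02), 3)
    }
    amp_sum <- sum(harmonics[, 1])
    rmax <- major * (1 + amp_sum)
    margin_needed <- rmax / 0.9 + 1
    cy <- stats::runif(1, margin_needed, H - 1 - margin_needed)
    cx <- stats::runif(1, margin_needed, W - 1 - margin_needed)
    draw_count <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    lesion_spec(class_label,
                center = c(cy, cx),
                radii = c(major, minor),
                boundary_harmonics = harmonics,
                base_color = base_color,
                color_variegation = varieg,
                hair_count = draw_count(hair_range),
                bubble_count = draw_count(bubble_range),
                rng_seed = derive_seeds(seed, 1L))
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n` PNG images (and their ground-truth masks) under `dir` plus a
#' `manifest.csv` with columns `image,label,mask,patient_id`.  Class counts
#' follow the rounding rule `minority = round(n / (1 + imbalance_ratio))`,
#' `majority = n - minority`; benign is the majority class.
#'
#' @param n Total number of images (>= 2).
#' @param imbalance_ratio Desired majority:minority count ratio (>= 1).
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param canvas `(height, width)` of each image.
#' @param hair_range,bubble_range Integer ranges for per-image artifact
#'   counts.
#' @return The manifest as a data frame (invisibly also written to
#'   `dir/manifest.csv`), with attribute `class_counts`.
#' @export
generate_dataset <- function(n, imbalance_ratio = 1, dir = tempfile("dermacaps_"),
                             seed = 1L, canvas = c(96L, 96L),
                             hair_range = c(0L, 3L), bubble_range = c(0L, 2L)) {
  if (n < 2) stop("n must be at least 2")
  if (imbalance_ratio < 1) stop("imbalance_ratio must be >= 1")
  minority <- round(n / (1 + imbalance_ratio))
  majority <- n - minority
  if (minority < 1) stop("n too small to realize the requested imbalance ratio")
  labels <- c(rep("benign", majority), rep("malignant", minority))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- random_lesion_spec(labels[i], canvas, seeds[i],
                               hair_range = hair_range, bubble_range = bubble_range)
    out <- generate_lesion_image(spec, canvas)
    img_path <- file.path(dir, sprintf("img_%04d.png", i))
    mask_path <- file.path(dir, sprintf("mask_%04d.png", i))
    png::writePNG(out$image, img_path)
    png::writePNG(out$mask + 0, mask_path)
    records[[i]] <- data.frame(image = img_path, label = labels[i],
                               mask = mask_path,
                               patient_id = sprintf("P%04d", i),
                               stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, records)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  counts <- table(manifest$label)
  attr(manifest, "class_counts") <- c(benign = as.integer(counts["benign"]),
                                      malignant = as.integer(counts["malignant"]))
  manifest
}

#' Read a dataset manifest CSV
#'
#' @param path Path to a manifest CSV with at least `image` and `label`
#'   columns.
#' @return Data frame with one row per image.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "label") %in% names(m))) {
    stop("manifest must have columns 'image' and 'label'")
  }
  m
}
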