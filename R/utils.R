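# Shared helpers: seeded RNG scopes, image conversions, polygon geometry.
#
# Coordinate convention used throughout: (row, col), 0-based, pixel centers
# at integer coordinates.  Contours and polygons are lists/matrices of
# sub-pixel (y, x) vertices.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not disturb the
#' caller's RNG stream.  All randomness in the package flows through this
#' helper so that every fixture is reproducible from a single integer seed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one parent seed.  Documented splitting
# scheme: child k is the k-th draw of a 31-bit integer from the parent
# stream, so generators nested at different depths never share a stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp01 <- function(x) clamp(x, 0, 1)

#' Luminance (grayscale) channel of an RGB image
#'
#' Rec. 601 weights, the convention used by the hair detector and the
#' segmentation front end.
#'
#' @param img `H x W x 3` numeric array, or an `H x W` matrix (returned
#'   unchanged).
#' @return `H x W` numeric matrix.
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# --- polygon geometry -------------------------------------------------------

# Shoelace area of a closed polygon given as (y, x) columns.
poly_area <- function(p) {
  y <- p[, 1]; x <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

poly_perimeter <- function(p) {
  y <- p[, 1]; x <- p[, 2]
  sum(sqrt(diff(c(y, y[1]))^2 + diff(c(x, x[1]))^2))
}

# Resample a closed polygon to (approximately) uniform arc-length spacing.
# Duplicate vertices are dropped before interpolation.
poly_resample <- function(p, spacing = 1, n = NULL) {
  y <- p[, 1]; x <- p[, 2]
  m <- length(y)
  if (m > 1 && y[1] == y[m] && x[1] == x[m]) { y <- y[-m]; x <- x[-m] }
  y <- c(y, y[1]); x <- c(x, x[1])
  seg <- sqrt(diff(y)^2 + diff(x)^2)
  keep <- c(TRUE, seg > 1e-12)
  y <- y[keep]; x <- x[keep]
  d <- c(0, cumsum(sqrt(diff(y)^2 + diff(x)^2)))
  L <- d[length(d)]
  if (is.null(n)) n <- max(16L, round(L / spacing))
  s <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(y = stats::approx(d, y, s)$y, x = stats::approx(d, x, s)$y)
}

# Circular moving-average smoothing of a closed polygon (odd window).
poly_smooth <- function(p, window = 3L) {
  if (window <= 1L) return(p)
  k <- (window - 1L) %/% 2L
  sm <- function(v) {
    n <- length(v)
    vv <- c(v[(n - k + 1L):n], v, v[1:k])
    as.numeric(stats::filter(vv, rep(1 / window, window))[(k + 1L):(k + n)])
  }
  cbind(y = sm(p[, 1]), x = sm(p[, 2]))
}

# Even-odd scanline rasterization of a closed polygon into a binary mask.
# A pixel (r, c) is set when its center lies inside the polygon; on a
# boundary exactly crossing a pixel center the half-open rule
# [x_left, x_right) applies, so an axis-aligned square with corners at
# integer coordinates (0,0)-(s,s) fills exactly s^2 pixels.
rasterize_polygon <- function(p, shape) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(0L, H, W)
  y <- p[, 1]; x <- p[, 2]
  n <- length(y)
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  for (r in 0:(H - 1L)) {
    crosses <- (y <= r & y2 > r) | (y2 <= r & y > r)
    if (!any(crosses)) next
    t <- (r - y[crosses]) / (y2[crosses] - y[crosses])
    xc <- sort(x[crosses] + t * (x2[crosses] - x[crosses]))
    np <- length(xc)
    if (np %% 2L == 1L) np <- np - 1L  # degenerate tangency: drop last
    if (np < 2L) next
    for (k in seq(1L, np, by = 2L)) {
      c0 <- ceiling(xc[k]); c1 <- ceiling(xc[k + 1L]) - 1L
      c0 <- max(c0, 0L); c1 <- min(c1, W - 1L)
      if (c0 <= c1) mask[r + 1L, (c0 + 1L):(c1 + 1L)] <- 1L
    }
  }
  mask
}

# Area-coverage rasterization: fraction of each pixel covered by the
# polygon, estimated by scan-filling at `factor`-times resolution and
# block-averaging.  Thin structures keep an opacity proportional to their
# true coverage instead of being washed out by blurring.
rasterize_polygon_coverage <- function(p, shape, factor = 3L) {
  H <- shape[1]; W <- shape[2]
  p_hi <- cbind(p[, 1] * factor + (factor - 1) / 2,
                p[, 2] * factor + (factor - 1) / 2)
  hi <- rasterize_polygon(p_hi, c(H * factor, W * factor))
  dim(hi) <- c(factor, H, factor, W)
  cov <- apply(hi, c(2, 4), sum) / factor^2
  cov
}

# Bilinear sampling of a matrix at sub-pixel (y, x) positions (0-based
# coordinates, clamped to the image domain).
bilinear_sample <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  ys <- clamp(ys, 0, H - 1); xs <- clamp(xs, 0, W - 1)
  y0 <- pmin(floor(ys), H - 2); x0 <- pmin(floor(xs), W - 2)
  y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fy <- ys - y0; fx <- xs - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

# Pad a matrix by reflection (used by separable filters and texture maps).
pad_reflect <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(min(k, H))), seq_len(H), H + 1 - rev(seq_len(min(k, H))))
  if (k > H) ri <- clamp(c(rev(seq_len(k)), seq_len(H), H + 1 - rev(seq_len(k))), 1, H)
  ci <- if (k > W) clamp(c(rev(seq_len(k)), seq_len(W), W + 1 - rev(seq_len(k))), 1, W)
        else c(rev(seq_len(min(k, W))), seq_len(W), W + 1 - rev(seq_len(min(k, W))))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1-D kernel along rows then columns,
# reflected borders, output size preserved.
conv_separable <- function(m, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  p <- pad_reflect(m, k)
  H <- nrow(p); W <- ncol(p)
  out <- matrix(0, H, W)
  for (i in seq_along(kernel)) {
    sh <- i - k - 1L
    out <- out + kernel[i] * p[clamp(seq_len(H) + sh, 1L, H), ]
  }
  p <- out
  out <- matrix(0, H, W)
  for (i in seq_along(kernel)) {
    sh <- i - k - 1L
    out <- out + kernel[i] * p[, clamp(seq_len(W) + sh, 1L, W)]
  }
  out[(k + 1L):(H - k), (k + 1L):(W - k), drop = FALSE]
}

# Otsu threshold: maximizes the between-class variance of the gray-level
# histogram; used to build the lesion/background region map.
otsu_threshold <- function(x, bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) return(lo)
  h <- tabulate(pmin(floor((x - lo) / (hi - lo) * bins) + 1L, bins), nbins = bins)
  p <- h / sum(h)
  centers <- lo + (seq_len(bins) - 0.5) * (hi - lo) / bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  centers[which.max(between)]
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Central-difference gradient with reflected borders; returns list(gy, gx).
central_gradient <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[clamp(seq_len(H) - 1L, 1L, H), , drop = FALSE]
  dn <- m[clamp(seq_len(H) + 1L, 1L, H), , drop = FALSE]
  lf <- m[, clamp(seq_len(W) - 1L, 1L, W), drop = FALSE]
  rt <- m[, clamp(seq_len(W) + 1L, 1L, W), drop = FALSE]
  list(gy = (dn - up) / 2, gx = (rt - lf) / 2)
}

# 5-point Laplacian with reflected (Neumann) borders.
laplacian5 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[clamp(seq_len(H) - 1L, 1L, H), , drop = FALSE]
  dn <- m[clamp(seq_len(H) + 1L, 1L, H), , drop = FALSE]
  lf <- m[, clamp(seq_len(W) - 1L, 1L, W), drop = FALSE]
  rt <- m[, clamp(seq_len(W) + 1L, 1L, W), drop = FALSE]
  up + dn + lf + rt - 4 * m
}
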