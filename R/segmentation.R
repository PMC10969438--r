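# Active-contour (snake) segmentation with a diffused external force field.
#
# The snake is a closed parametric curve Y(v) relaxed to equilibrium of
#   b * Y_vv - a * Y_vvvv + M(Y) = 0,
# where b weights tension, a weights rigidity, and M is an external force
# field derived from the image.  M solves the steady state of the
# spatially weighted diffusion
#   M_s = t(|grad g|) * lap(M) - B(|grad g|) * (M - grad g),
# with g the Gaussian-gradient edge map, t(r) = exp(-r / A),
# B(r) = 1 - t(r).  Near strong edges (B ~ 1) the field stays pinned to
# grad g; in flat regions (t ~ 1) it is the harmonic extension of the edge
# forces, which gives the snake long-range attraction.

#' Gaussian-gradient edge map
#'
#' `g = |grad(G_sigma * img)|`: the image is smoothed with an isotropic
#' Gaussian and the gradient magnitude taken with central differences and
#' reflected borders.
#'
#' @param img Grayscale matrix.
#' @param sigma Gaussian sd in pixels (> 0).
#' @return Non-negative matrix of the same size.
#' @export
compute_edge_map <- function(img, sigma = 2) {
  stopifnot(sigma > 0)
  sm <- conv_separable(img, gaussian_kernel_1d(sigma))
  gr <- central_gradient(sm)
  sqrt(gr$gy^2 + gr$gx^2)
}

#' Diffuse the edge-map gradient into an external force field
#'
#' Explicit iteration of the weighted diffusion reaction equation starting
#' from `M0 = grad g`.  `calibration_A` sets the edge-sensitivity scale of
#' the weights `t = exp(-|grad g| / A)`, `B = 1 - t`; the default is 10%
#' of the maximum gradient magnitude.  The explicit scheme requires
#' `dt <= 1/4` on the unit grid.
#'
#' @param g Edge map (matrix) from [compute_edge_map()].
#' @param calibration_A Edge-sensitivity parameter `A` (> 0), or `NULL`
#'   for `0.1 * max |grad g|`.
#' @param iters Number of iterations (>= 1).
#' @param dt Time step (<= 0.25).
#' @return List of class `force_field` with per-pixel components `my`,
#'   `mx` plus the parameters used.
#' @export
diffuse_force_field <- function(g, calibration_A = NULL, iters = 200L, dt = 0.2) {
  if (dt > 0.25) stop("dt must satisfy the explicit stability bound dt <= 1/4")
  if (iters < 1) stop("iters must be >= 1")
  gr <- central_gradient(g)
  fy <- gr$gy; fx <- gr$gx
  mag <- sqrt(fy^2 + fx^2)
  if (is.null(calibration_A)) calibration_A <- 0.1 * max(mag)
  if (calibration_A <= 0) calibration_A <- 1e-8
  tw <- exp(-mag / calibration_A)
  bw <- 1 - tw
  my <- fy; mx <- fx
  for (i in seq_len(iters)) {
    my <- my + dt * (tw * laplacian5(my) - bw * (my - fy))
    mx <- mx + dt * (tw * laplacian5(mx) - bw * (mx - fx))
  }
  structure(list(my = my, mx = mx, sigma = NA_real_,
                 calibration_A = calibration_A,
                 diffusion_iters = as.integer(iters), diffusion_dt = dt),
            class = "force_field")
}

# Dense direct solve of the steady-state field equations; oracle-grade,
# only sensible for small rasters.  Solves, per component,
#   (B + t * L_neumann) m = B * f
# where L_neumann is the 5-point graph Laplacian with reflected borders.
solve_force_field_dense <- function(g, calibration_A = NULL) {
  gr <- central_gradient(g)
  mag <- sqrt(gr$gy^2 + gr$gx^2)
  if (is.null(calibration_A)) calibration_A <- 0.1 * max(mag)
  tw <- as.numeric(exp(-mag / calibration_A))
  bw <- 1 - tw
  H <- nrow(g); W <- ncol(g); n <- H * W
  idx <- function(r, c) (c - 1L) * H + r
  A <- matrix(0, n, n)
  for (c in seq_len(W)) for (r in seq_len(H)) {
    i <- idx(r, c)
    A[i, i] <- A[i, i] + bw[i]
    for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      rr <- clamp(nb[1], 1L, H); cc <- clamp(nb[2], 1L, W)
      j <- idx(rr, cc)
      A[i, i] <- A[i, i] + tw[i]
      A[i, j] <- A[i, j] - tw[i]
    }
  }
  my <- matrix(solve(A, bw * as.numeric(gr$gy)), H, W)
  mx <- matrix(solve(A, bw * as.numeric(gr$gx)), H, W)
  structure(list(my = my, mx = mx, calibration_A = calibration_A),
            class = "force_field")
}

#' Closed snake contour
#'
#' @param points `n x 2` matrix of `(y, x)` sub-pixel vertices (n >= 8),
#'   implicitly closed.
#' @param tension_b,rigidity_a Non-negative internal-energy weights.
#' @param step_tau Evolution time step.
#' @return Object of class `snake`.
#' @export
snake <- function(points, tension_b = 0.5, rigidity_a = 0.5, step_tau = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 8L) stop("a snake needs at least 8 points")
  stopifnot(tension_b >= 0, rigidity_a >= 0, step_tau > 0)
  structure(list(points = points, tension_b = tension_b,
                 rigidity_a = rigidity_a, step_tau = step_tau),
            class = "snake")
}

#' Circle initialization for a snake
#'
#' Default initialization: a circle at the image center with radius
#' `0.45 * min(H, W)`.
#'
#' @param shape `(H, W)` of the image.
#' @param radius Circle radius; default `0.45 * min(shape)`.
#' @param n Number of contour points.
#' @param ... Passed to [snake()].
#' @export
snake_init_circle <- function(shape, radius = 0.45 * min(shape), n = 100L, ...) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cy <- (shape[1] - 1) / 2; cx <- (shape[2] - 1) / 2
  snake(cbind(y = cy + radius * sin(th), x = cx + radius * cos(th)), ...)
}

# Cyclic internal-energy operator K = -b D2 + a D4 (D2/D4: cyclic second /
# fourth difference matrices).  K annihilates constant contours.
snake_internal_operator <- function(n, b, a) {
  D2 <- matrix(0, n, n)
  i <- seq_len(n)
  D2[cbind(i, i)] <- -2
  D2[cbind(i, (i %% n) + 1L)] <- 1
  D2[cbind(i, ((i - 2L) %% n) + 1L)] <- 1
  D4 <- D2 %*% D2
  -b * D2 + a * D4
}

#' Evolve a snake to equilibrium in an external force field
#'
#' Semi-implicit update `Y_new = (I + tau K)^-1 (Y + tau * M(Y))` with `K`
#' the cyclic pentadiagonal internal-energy operator; the field is sampled
#' at the contour points by bilinear interpolation (and normalized to unit
#' vectors where its magnitude is appreciable, so attraction strength is
#' uniform along the capture range).  Points are redistributed to uniform
#' arc length every 10 iterations.  Stops when the mean point displacement
#' drops below `tol` or after `max_iters`.
#'
#' @param init A [snake()].
#' @param field A `force_field`.
#' @param max_iters,tol Stopping controls (maximum point displacement).
#' @param normalize_field Use unit-magnitude forces inside the capture
#'   range (default `TRUE`), so attraction strength is uniform.
#' @param balloon Pressure-force weight.  With a `region` map the
#'   pressure is signed by the local region score (inward over
#'   background, outward inside the lesion), so the contour is driven
#'   toward the appearance boundary from both sides and can enter deep
#'   border concavities; without one, an inward pressure is applied
#'   wherever the field magnitude is negligible (below `balloon_gate` of
#'   its maximum).  Set to 0 for the pressure-free evolution.
#' @param balloon_gate Fraction of the maximum field magnitude below
#'   which the gated (region-free) pressure is active.
#' @param region Optional matrix in `[-1, 1]`: positive where the pixel
#'   looks like background, negative inside the lesion (see
#'   [region_score()]).
#' @return The converged `snake`, with attribute `iterations`.
#' @export
evolve_snake <- function(init, field, max_iters = 500L, tol = 0.05,
                         normalize_field = TRUE, balloon = 0.3,
                         balloon_gate = 0.1, region = NULL) {
  pts <- init$points
  n <- nrow(pts)
  K <- snake_internal_operator(n, init$tension_b, init$rigidity_a)
  Ainv <- solve(diag(n) + init$step_tau * K)
  my <- field$my; mx <- field$mx
  mag <- sqrt(my^2 + mx^2)
  mmax <- max(mag, 1e-12)
  if (normalize_field) {
    scale <- 1 / pmax(mag, balloon_gate * mmax)
    myn <- my * scale; mxn <- mx * scale
  } else {
    myn <- my; mxn <- mx
  }
  # polygon orientation decides the inward normal direction
  orient_sign <- function(p) {
    y <- p[, 1]; x <- p[, 2]
    s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (s >= 0) 1 else -1
  }
  it <- 0L
  for (it in seq_len(max_iters)) {
    fy <- bilinear_sample(myn, pts[, 1], pts[, 2])
    fx <- bilinear_sample(mxn, pts[, 1], pts[, 2])
    if (balloon > 0) {
      w <- if (is.null(region)) {
        local_mag <- bilinear_sample(mag, pts[, 1], pts[, 2])
        pmax(0, 1 - local_mag / (balloon_gate * mmax))  # 1 far, 0 near edges
      } else {
        bilinear_sample(region, pts[, 1], pts[, 2])     # signed pressure
      }
      nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
      prv <- rbind(pts[n, , drop = FALSE], pts[-n, , drop = FALSE])
      tg <- nxt - prv
      tl <- sqrt(rowSums(tg^2)); tl[tl < 1e-12] <- 1
      nrm <- cbind(-tg[, 2], tg[, 1]) / tl * orient_sign(pts)
      fy <- fy - balloon * w * nrm[, 1]
      fx <- fx - balloon * w * nrm[, 2]
    }
    new_pts <- Ainv %*% (pts + init$step_tau * cbind(fy, fx))
    disp <- max(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    if (it %% 10L == 0L) {
      pts <- poly_resample(cbind(pts[, 1], pts[, 2]), n = n)
    }
    if (poly_perimeter(pts) < 8) {
      stop("snake collapsed below an 8 px perimeter; the internal forces ",
           "(tension/rigidity) likely overwhelm the external field")
    }
    if (disp < tol) break
  }
  out <- snake(pts, init$tension_b, init$rigidity_a, init$step_tau)
  attr(out, "iterations") <- it
  out
}

#' Lesion/background region score
#'
#' Smoothed luminance thresholded by Otsu's criterion and mapped to
#' `[-1, 1]`: +1 for clear background (bright skin), -1 inside the dark
#' lesion, ramping linearly over a `softness`-wide intensity band.  Used
#' as the signed pressure map of the region-driven snake.
#'
#' @param img Grayscale matrix or RGB array in `[0, 1]`.
#' @param sigma Gaussian sd of the pre-smoothing.
#' @param softness Intensity half-width of the linear ramp.
#' @return Matrix in `[-1, 1]`.
#' @export
region_score <- function(img, sigma = 2, softness = 0.08) {
  gray <- luminance(img)
  sm <- conv_separable(gray, gaussian_kernel_1d(sigma))
  thr <- otsu_threshold(sm)
  clamp((sm - thr) / softness, -1, 1)
}

#' Rasterize a snake contour to a binary lesion mask
#'
#' Even-odd polygon scan fill, then the largest connected component is
#' kept and interior holes are filled.
#'
#' @param snk A [snake()] (or an `n x 2` point matrix).
#' @param shape `(H, W)` of the target raster.
#' @return `H x W` 0/1 matrix of class `lesion_mask`.
#' @export
contour_to_mask <- function(snk, shape) {
  pts <- if (inherits(snk, "snake")) snk$points else as.matrix(snk)
  mask <- rasterize_polygon(pts, shape)
  if (sum(mask) == 0) stop("degenerate contour: the rasterized mask is empty")
  mask <- largest_component(mask)
  mask <- fill_holes(mask)
  structure(mask, class = c("lesion_mask", class(mask)))
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  # flood-fill the background from the border; unreached zero pixels are holes
  bg <- EBImage::bwlabel(1L - mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(bg %in% border_labels)
  out <- mask
  out[hole] <- 1L
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Segment a lesion image end to end
#'
#' Hair removal (optional), Gaussian-gradient edge map (floored to
#' suppress intra-lesion texture edges), force-field diffusion, snake
#' evolution from a centered circle with region-signed pressure, and
#' rasterization.
#'
#' @param img RGB array or grayscale matrix in `[0, 1]`.
#' @param sigma Edge-map Gaussian sd.
#' @param calibration_A Force-field sensitivity (`NULL` = auto).
#' @param tension_b,rigidity_a,step_tau Snake parameters.
#' @param diffusion_iters,diffusion_dt Force-field iteration controls.
#' @param edge_floor Fraction of the maximum edge response below which
#'   the edge map is zeroed before diffusion (suppresses variegation
#'   texture inside the lesion).
#' @param balloon Region-pressure weight (see [evolve_snake()]).
#' @param init_radius Initial circle radius (default `0.45 * min(H, W)`).
#' @param hair_removal Run [remove_hair()] first (RGB inputs only).
#' @param max_iters,tol Snake stopping controls.
#' @return List with `mask`, `snake`, `field`, `edge_map`, `region` and
#'   (when hair removal ran) `hair`.
#' @export
segment_lesion <- function(img, sigma = 2, calibration_A = NULL,
                           tension_b = 0.1, rigidity_a = 0.1, step_tau = 1,
                           diffusion_iters = 200L, diffusion_dt = 0.2,
                           edge_floor = 0.2, balloon = 0.3,
                           init_radius = NULL, hair_removal = TRUE,
                           max_iters = 600L, tol = 0.05) {
  hair <- NULL
  if (hair_removal && length(dim(img)) == 3L) {
    hair <- remove_hair(img)
    img <- hair$inpainted
  }
  gray <- luminance(img)
  g <- compute_edge_map(gray, sigma)
  if (edge_floor > 0) g[g < edge_floor * max(g)] <- 0
  field <- diffuse_force_field(g, calibration_A, diffusion_iters, diffusion_dt)
  region <- region_score(img, sigma = sigma)
  shape <- dim(gray)
  if (is.null(init_radius)) init_radius <- 0.45 * min(shape)
  init <- snake_init_circle(shape, radius = init_radius,
                            tension_b = tension_b, rigidity_a = rigidity_a,
                            step_tau = step_tau)
  snk <- evolve_snake(init, field, max_iters = max_iters, tol = tol,
                      balloon = balloon, region = region)
  mask <- contour_to_mask(snk, shape)
  list(mask = mask, snake = snk, field = field, edge_map = g,
       region = region, hair = hair)
}

#' Dice overlap between two binary masks
#'
#' @param a,b 0/1 matrices of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
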