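# Shared fixtures, generated in code.  Heavier fixtures are cached per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

# digital disk mask of radius r, centered
disk_mask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  cx <- (n - 1) / 2
  outer(0:(n - 1), 0:(n - 1), function(i, j) as.numeric((i - cx)^2 + (j - cx)^2 <= r^2))
}

# filled axis-aligned square mask of side s
square_mask <- function(s, pad = 6L) {
  n <- s + 2L * pad
  m <- matrix(0, n, n)
  m[(pad + 1L):(pad + s), (pad + 1L):(pad + s)] <- 1
  m
}

# star-shaped lesion spec (strongly irregular border)
star_spec <- function(amplitude = 0.35, frequency = 7, r0 = 30, seed = 1L) {
  lesion_spec("malignant",
              center = c(60, 60), radii = c(r0, r0),
              boundary_harmonics = rbind(c(amplitude, frequency, 0)),
              rng_seed = seed)
}

# polygon perimeter/area oracle straight from an analytic boundary r(theta)
analytic_shape_oracle <- function(r_fun, n = 4000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- r_fun(th)
  x <- r * cos(th); y <- r * sin(th)
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(perimeter = per, area = area,
       irregularity = per^2 / (4 * pi * area),
       convexity = NA)
}

# small labeled dataset on disk, cached across test files
small_dataset <- function(n = 16L, seed = 101L) {
  key <- sprintf("ds_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("dermacaps_fix_", key))
    .fixture_cache[[key]] <- generate_dataset(n, 1, dir = dir, seed = seed)
  }
  .fixture_cache[[key]]
}

# numerical gradient of f at x by central differences
num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
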