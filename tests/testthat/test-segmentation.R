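test_that("edge map vanishes on uniform images and peaks symmetrically on a step", {
  expect_true(all(compute_edge_map(matrix(0.5, 32, 32), 2) == 0))
  step <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  g <- compute_edge_map(step, 2)
  expect_true(all(g >= 0))
  peak_col <- which.max(g[16, ])
  expect_true(peak_col %in% c(16, 17))
  # symmetry about the edge
  expect_equal(g[16, 16 - 3], g[16, 17 + 3], tolerance = 1e-9)
})

test_that("step-edge response matches the Gaussian-derivative closed form", {
  # ideal 1-D step of height 1 smoothed at sigma = 2: the smoothed profile
  # is Phi(d / sigma), so the central-difference gradient at distance d
  # from the edge plane is (Phi((d+1)/sigma) - Phi((d-1)/sigma)) / 2
  n <- 64L
  step <- cbind(matrix(0, 32, n / 2), matrix(1, 32, n / 2))
  sigma <- 2
  g <- compute_edge_map(step, sigma)
  for (off in 0:3) {
    d <- off + 0.5  # pixel centers sit half a pixel from the edge plane
    expected <- (pnorm((d + 1) / sigma) - pnorm((d - 1) / sigma)) / 2
    expect_lt(abs(g[16, n / 2 - off] - expected) / expected, 0.03)
  }
})

test_that("force-field diffusion keeps the zero field and respects stability limits", {
  z <- matrix(0, 16, 16)
  f <- diffuse_force_field(z, calibration_A = 1, iters = 50)
  expect_true(all(f$my == 0) && all(f$mx == 0))
  expect_error(diffuse_force_field(z, dt = 0.3), "stability")
  expect_error(diffuse_force_field(z, iters = 0), "iters")
})

test_that("strong-edge pinning holds in the small-A limit", {
  g <- matrix(0, 16, 16)
  g[8, 8] <- 1
  gr <- dermacaps:::central_gradient(g)
  f <- diffuse_force_field(g, calibration_A = 1e-6, iters = 200)
  strong <- abs(gr$gy) > 0.2 | abs(gr$gx) > 0.2
  expect_lt(max(abs(f$my - gr$gy)[strong]), 0.05)
  expect_lt(max(abs(f$mx - gr$gx)[strong]), 0.05)
})

test_that("explicit diffusion converges to the dense steady-state solve", {
  # 16x16 single vertical edge fixture
  g <- cbind(matrix(0, 16, 8), matrix(0.5, 16, 8))
  g <- compute_edge_map(g, 1)
  fast <- diffuse_force_field(g, iters = 4000)
  dense <- dermacaps:::solve_force_field_dense(g)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rms(fast$my, dense$my), 1e-3)
  expect_lt(rms(fast$mx, dense$mx), 1e-3)
})

test_that("the internal operator annihilates constant contours", {
  K <- dermacaps:::snake_internal_operator(24, b = 0.7, a = 0.3)
  const <- cbind(rep(2, 24), rep(-3, 24))
  expect_lt(max(abs(K %*% const)), 1e-12)
  # semi-implicit solve maps the constant contour to itself
  Ainv <- solve(diag(24) + 1 * K)
  expect_equal(Ainv %*% const, const, tolerance = 1e-9)
})

test_that("pure tension shrinks a circle monotonically", {
  zero <- structure(list(my = matrix(0, 64, 64), mx = matrix(0, 64, 64)),
                    class = "force_field")
  init <- snake_init_circle(c(64, 64), radius = 25, tension_b = 0.5,
                            rigidity_a = 0)
  radii <- c()
  s <- init
  for (k in 1:5) {
    s <- evolve_snake(s, zero, max_iters = 20, tol = 0, balloon = 0)
    radii <- c(radii, mean(sqrt(rowSums(sweep(s$points, 2, c(31.5, 31.5))^2))))
  }
  expect_true(all(diff(radii) < 0))
})

test_that("the snake recovers a synthetic disk boundary", {
  spec <- lesion_spec("benign", center = c(48, 48), radii = c(30, 30), rng_seed = 5)
  out <- generate_lesion_image(spec, c(96, 96))
  seg <- segment_lesion(out$image, hair_removal = FALSE)
  pts <- seg$snake$points
  r <- sqrt(rowSums(sweep(pts, 2, c(48, 48))^2))
  expect_lt(mean(abs(r - 30)), 2)
  expect_gt(dice_overlap(seg$mask, out$mask), 0.95)
})

test_that("snake evolution is equivariant to image translation", {
  spec <- lesion_spec("benign", center = c(40, 40), radii = c(20, 20), rng_seed = 8)
  out <- generate_lesion_image(spec, c(96, 96))
  img <- luminance(out$image)
  dyx <- c(6L, -4L)
  shifted <- img
  shifted[] <- 0.86
  shifted[(1 + dyx[1]):96, 1:(96 + dyx[2])] <- img[1:(96 - dyx[1]), (1 - dyx[2]):96]
  run <- function(im, cy, cx) {
    g <- compute_edge_map(im, 2)
    g[g < 0.2 * max(g)] <- 0
    f <- diffuse_force_field(g, iters = 300)
    init <- snake_init_circle(c(96, 96), radius = 30, tension_b = 0.1, rigidity_a = 0.1)
    init$points <- sweep(init$points, 2, c(cy, cx) - c(47.5, 47.5), "+")
    evolve_snake(init, f, balloon = 0)$points
  }
  p1 <- run(img, 40, 40)
  p2 <- run(shifted, 40 + dyx[1], 40 + dyx[2])
  # compare centroids (point correspondence is arbitrary after resampling)
  expect_lt(max(abs(colMeans(p2) - colMeans(p1) - dyx)), 0.1)
})

test_that("contour_to_mask scan-fills with the documented half-open rule", {
  sq <- rbind(c(20, 20), c(20, 30), c(30, 30), c(30, 20))
  mask <- contour_to_mask(sq, c(50, 50))
  expect_equal(sum(mask), 100)
  expect_true(all(mask %in% c(0L, 1L)))
  expect_equal(mask[1, 1], 0L)
  expect_equal(mask[50, 50], 0L)
  # disk contour stays highly circular
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  disk <- cbind(32 + 20 * sin(th), 32 + 20 * cos(th))
  dm <- contour_to_mask(disk, c(64, 64))
  expect_gte(shape_descriptors(dm)$circularity, 0.95)
  # degenerate contour
  line <- cbind(c(10, 10, 10), c(5, 6, 7))
  expect_error(contour_to_mask(line, c(20, 20)), "empty")
})

test_that("median Dice across a mixed synthetic set stays high", {
  man <- small_dataset()
  d <- vapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(man$image[i])
    gt <- png::readPNG(man$mask[i])
    if (length(dim(gt)) == 3L) gt <- gt[, , 1]
    seg <- segment_lesion(img)
    dice_overlap(seg$mask, gt > 0.5)
  }, numeric(1))
  expect_gte(median(d), 0.9)
})
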