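test_that("disk and square masks hit their closed-form descriptors", {
  dd <- shape_descriptors(disk_mask(40))
  expect_gte(dd$convexity, 0.99)
  expect_gte(dd$circularity, 0.95)
  expect_lte(dd$circularity, 1)
  expect_false(dd$is_irregular)
  sq <- shape_descriptors(square_mask(40))
  expect_lt(abs(sq$circularity - pi / 4), 0.05)
  expect_lt(abs(sq$irregularity_index - 4 / pi), 0.1)
})

test_that("circularity and the irregularity index are exact reciprocals", {
  for (mask in list(disk_mask(25), square_mask(30),
                    generate_lesion_image(star_spec(), c(120, 120))$mask)) {
    sd_ <- shape_descriptors(mask)
    expect_equal(sd_$circularity * sd_$irregularity_index, 1, tolerance = 1e-9)
  }
})

test_that("a 7-pointed star is irregular and matches the analytic polygon oracle", {
  out <- generate_lesion_image(star_spec(amplitude = 0.35, frequency = 7, r0 = 30),
                               c(120, 120))
  sd_ <- shape_descriptors(out$mask)
  expect_true(sd_$is_irregular)
  expect_gt(sd_$irregularity_index, 1.8)
  # convexity against a brute-force hull oracle on the analytic boundary
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  r <- 30 * (1 + 0.35 * sin(7 * th))
  bx <- r * cos(th); by <- r * sin(th)
  hull <- grDevices::chull(bx, by)
  hx <- bx[hull]; hy <- by[hull]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  poly_area <- abs(sum(bx * c(by[-1], by[1]) - c(bx[-1], bx[1]) * by)) / 2
  expect_lt(abs(sd_$convexity - poly_area / hull_area) / (poly_area / hull_area), 0.03)
})

test_that("descriptors respect raster symmetries and scale covariance", {
  m <- generate_lesion_image(star_spec(seed = 4), c(120, 120))$mask
  a <- shape_descriptors(m)
  b <- shape_descriptors(t(m)[ncol(m):1, ])  # 90-degree rotation
  expect_lt(abs(a$circularity - b$circularity) / a$circularity, 0.03)
  expect_lt(abs(a$convexity - b$convexity) / a$convexity, 0.03)
  small <- disk_mask(15); big <- disk_mask(30)
  expect_lt(abs(shape_descriptors(small)$circularity -
                shape_descriptors(big)$circularity), 0.02)
})

test_that("multi-component and empty masks follow the error contract", {
  m <- disk_mask(10, pad = 25)
  m[2:4, 2:4] <- 1
  expect_warning(sd_ <- shape_descriptors(m), "largest")
  expect_equal(sd_$area, sum(disk_mask(10)))
  expect_error(shape_descriptors(matrix(0, 10, 10)), "empty")
})

test_that("texture map is local sd with the expected closed forms", {
  expect_true(all(texture_map(matrix(0.3, 20, 20)) == 0))
  cb <- outer(1:20, 1:20, function(i, j) (i + j) %% 2)
  tm <- texture_map(cb, window_radius = 1)
  # interior 3x3 windows mix 5:4 or 4:5 zeros and ones
  expect_equal(unique(round(as.numeric(tm[5:15, 5:15]), 10)),
               round(sqrt(20 / 81), 10))
  # shift invariance
  expect_equal(texture_map(cb + 3, window_radius = 1)[5:15, 5:15],
               tm[5:15, 5:15], tolerance = 1e-9)
})

test_that("co-occurrence statistics hit their degenerate closed forms", {
  # constant image: all mass on one diagonal cell
  g <- texture_glcm(matrix(0.4, 12, 12), levels = 8)
  expect_equal(g$contrast, 0)
  expect_equal(g$homogeneity, 1)
  expect_equal(g$energy, 1)
  # checkerboard at horizontal offset: every pair differs by the two
  # quantized levels -> contrast equals the squared level gap
  cb <- outer(1:12, 1:12, function(i, j) (i + j) %% 2) * 0.9
  g2 <- texture_glcm(cb, levels = 8, offset = c(0L, 1L))
  expect_equal(g2$contrast, (8 - 1)^2)
  expect_equal(g2$energy, 0.5)       # two equally likely level pairs
  expect_equal(g2$correlation, -1)   # perfectly anti-correlated
})

test_that("color features anchor on primary colors and circular hue", {
  mk <- function(rgb) {
    img <- array(0, c(8, 8, 3))
    for (ch in 1:3) img[, , ch] <- rgb[ch]
    img
  }
  mask <- matrix(1, 8, 8)
  red <- color_features(mk(c(1, 0, 0)), mask)
  expect_equal(red$hue$mean, 0)
  expect_equal(red$saturation$mean, 1)
  expect_equal(red$value$mean, 1)
  gray <- color_features(mk(c(0.5, 0.5, 0.5)), mask)
  expect_true(gray$hue$undefined)
  expect_true(is.na(gray$hue$mean))
  expect_equal(gray$saturation$mean, 0)
  # two-tone lesion: half hue 10 deg, half hue 350 deg -> circular mean 0
  img <- array(0, c(8, 8, 3))
  col1 <- grDevices::col2rgb(grDevices::hsv(10 / 360, 1, 1)) / 255
  col2 <- grDevices::col2rgb(grDevices::hsv(350 / 360, 1, 1)) / 255
  for (ch in 1:3) {
    img[, 1:4, ch] <- col1[ch]
    img[, 5:8, ch] <- col2[ch]
  }
  two <- color_features(img, mask)
  hue_deg <- two$hue$mean * 360
  expect_lt(min(hue_deg, 360 - hue_deg), 0.5)  # 8-bit hue quantization
  # histograms sum to the pixel count
  expect_equal(sum(two$saturation$hist), 64)
  expect_equal(sum(two$value$hist), 64)
})

test_that("the feature table has one row per manifest record", {
  man <- small_dataset()
  tab <- lesion_feature_table(man)
  expect_equal(nrow(tab), nrow(man))
  expect_true(all(tab$irregularity_index[tab$label == "malignant"] > 1.8))
  expect_true(all(tab$irregularity_index[tab$label == "benign"] < 1.3))
})
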