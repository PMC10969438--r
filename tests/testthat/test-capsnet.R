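test_that("zero-weight CBAM pins both attentions at one half", {
  set.seed(3)
  fmap <- array(rnorm(8 * 5 * 5 * 2), c(8, 5, 5, 2))
  out <- cbam(fmap, cbam_params(reduction_ratio = 4L), zero_weights = TRUE)
  expect_true(all(out$mc == 0.5))
  expect_true(all(out$ms == 0.5))
  expect_equal(out$refined, 0.25 * fmap, tolerance = 1e-12)
})

test_that("CBAM attentions stay strictly inside (0, 1)", {
  for (s in 1:10) {
    fmap <- dermacaps:::with_seed(s, array(rnorm(8 * 4 * 4 * 2), c(8, 4, 4, 2)))
    out <- cbam(fmap, cbam_params(reduction_ratio = 4L), seed = s)
    expect_true(all(out$mc > 0 & out$mc < 1))
    expect_true(all(out$ms > 0 & out$ms < 1))
  }
  # a channel count below the reduction ratio clips the hidden width
  expect_warning(cbam(array(rnorm(8 * 4 * 4), c(8, 4, 4, 1))), "clipping")
})

test_that("CBAM matches a by-hand evaluation on a small fixture", {
  # 2-channel 2x2 map, one sample; identity-like MLP (hidden width 1 with
  # unit weights), spatial kernel 1x1 summing mean and max maps.
  fmap <- array(c(1, 3, 2, 0, 0, 2, 4, 2), c(2, 2, 2, 1))
  out <- cbam(fmap, cbam_params(reduction_ratio = 2L, spatial_kernel = 1L),
              zero_weights = TRUE)
  store <- new.env()
  # rebuild with explicit weights
  ad <- function(nm) get(nm, envir = asNamespace("dermacaps"))
  st <- ad("new_param_store")()
  mod <- ad("make_cbam")(st, "c", 2L, cbam_params(reduction_ratio = 2L, spatial_kernel = 1L))
  st$params[["c.mlp1.W"]]$value[] <- matrix(c(1, 1), 1, 2)
  st$params[["c.mlp1.b"]]$value[] <- 0
  st$params[["c.mlp2.W"]]$value[] <- matrix(c(1, 1), 2, 1)
  st$params[["c.mlp2.b"]]$value[] <- 0
  st$params[["c.spatial.W"]]$value[] <- array(1, c(1, 2, 1, 1))
  st$params[["c.spatial.b"]]$value[] <- 0
  x <- ad("as_ad")(fmap)
  mc <- ad("ad_value")(mod$channel_attention(x))
  # by hand: channel means (1.5, 2), maxes (3, 4); shared MLP with unit
  # weights maps a 2-vector to rep(sum, 2); mc = sigmoid(3.5 + 7)
  expect_equal(as.numeric(mc), rep(1 / (1 + exp(-10.5)), 2), tolerance = 1e-9)
  x1 <- ad("ad_mul_channels")(x, ad("as_ad")(mc))
  ms <- ad("ad_value")(mod$spatial_attention(x1))
  v <- fmap * as.numeric(mc)[1]
  mean_map <- apply(v, c(2, 3), mean); max_map <- apply(v, c(2, 3), max)
  expect_equal(array(ms, c(2, 2)), 1 / (1 + exp(-(mean_map + max_map))),
               tolerance = 1e-9)
  refined <- ad("ad_value")(ad("ad_mul_spatial")(x1, ad("as_ad")(ms)))
  manual <- v * rep(as.numeric(1 / (1 + exp(-(mean_map + max_map)))), each = 2)
  expect_equal(as.numeric(refined), as.numeric(manual), tolerance = 1e-9)
})

test_that("fusion obeys its additive and identity-kernel contracts", {
  set.seed(8)
  a <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  zero <- array(0, dim(a))
  expect_equal(fuse_features(a, zero, mode = "sum"), a)
  # identity-initialized 1x1 kernel reproduces the first (backbone) block
  out <- fuse_features(a, a + 1, mode = "concat", identity_first = TRUE)
  expect_equal(out, a, tolerance = 1e-12)
  expect_error(fuse_features(a, array(0, c(4, 2, 3, 2))), "shape")
})

test_that("primary capsules have the documented layout and normalization", {
  set.seed(2)
  fused <- array(rnorm(16 * 3 * 3 * 4), c(16, 3, 3, 4))
  poses <- primary_capsules(fused, capsule_config())
  expect_equal(dim(poses), c(4, 4, 32, 4))
  flat <- matrix(poses, 16, 32 * 4)
  expect_lt(max(abs(colMeans(flat))), 1e-9)
  expect_lt(max(abs(colMeans(flat^2) * 16 / 15 - 16 / 15)), 1e-3)
})

test_that("routing coefficients sum to one per child at every iteration", {
  for (iters in 1:3) {
    for (s in 1:5) {
      ch <- dermacaps:::with_seed(s, array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3)))
      Z <- dermacaps:::with_seed(s + 100, array(rnorm(4 * 4 * 6 * 5, 0, 0.5), c(4, 4, 6, 5)))
      r <- attention_routing(ch, Z, iterations = iters)
      sums <- apply(r$coefficients, c(1, 3), sum)
      expect_lt(max(abs(sums - 1)), 1e-6)
    }
  }
})

test_that("first-iteration coefficients are uniform with zero agreements", {
  ch <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  Z <- array(rnorm(4 * 4 * 3 * 4, 0, 0.5), c(4, 4, 3, 4))
  r <- attention_routing(ch, Z, iterations = 1)
  expect_true(all(r$coefficients == 1 / 4))
  expect_true(all(r$agreements == 0))
})

test_that("a single parent absorbs every child with coefficient one", {
  ch <- array(rnorm(4 * 4 * 5 * 2), c(4, 4, 5, 2))
  Z <- array(rnorm(4 * 4 * 5 * 1, 0, 0.5), c(4, 4, 5, 1))
  r <- attention_routing(ch, Z, iterations = 2)
  expect_true(all(abs(r$coefficients - 1) < 1e-12))
  # parent equals LayerNorm of the plain vote sum
  V <- dermacaps:::ad_value(dermacaps:::ad_caps_votes(dermacaps:::as_ad(ch),
                                                      dermacaps:::as_ad(Z)))
  vote_sum <- apply(V, c(1, 2, 4, 5), sum)  # sum over children
  for (n in 1:2) {
    v <- as.numeric(vote_sum[, , 1, n])
    ln <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
    expect_equal(as.numeric(dermacaps:::ad_value(r$parents)[, , 1, n]), ln,
                 tolerance = 1e-9)
  }
})

test_that("routing matches a step-by-step small-tensor oracle", {
  # 2 children x 2 parents with hd = 2: transcribe the update rules
  # directly with explicit loops, then compare
  hd <- 2L; J <- 2L; I <- 2L
  ch <- array(c(1, 0, 0.5, -1,  0.2, 0.7, -0.3, 0.1), c(hd, hd, J, 1))
  Z <- array(c(0.5, 0, 0, 0.5,   1, 0, 0, -1,
               0.3, -0.2, 0.1, 0,  0, 1, 1, 0), c(hd, hd, J, I))
  r <- attention_routing(ch, Z, iterations = 2)
  # oracle
  votes <- array(0, c(hd, hd, J, I))
  for (j in 1:J) for (i in 1:I) votes[, , j, i] <- Z[, , j, i] %*% ch[, , j, 1]
  ln <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  # iteration 1: uniform coefficients
  P <- array(0, c(hd, hd, I))
  for (i in 1:I) {
    acc <- matrix(0, hd, hd)
    for (j in 1:J) acc <- acc + 0.5 * votes[, , j, i]
    P[, , i] <- array(ln(as.numeric(acc)), c(hd, hd))
  }
  # iteration 2
  Fji <- matrix(0, J, I)
  for (j in 1:J) for (i in 1:I) Fji[j, i] <- sum(votes[, , j, i] * P[, , i])
  H <- t(apply(Fji, 1, function(f) exp(f - max(f)) / sum(exp(f - max(f)))))
  P2 <- array(0, c(hd, hd, I))
  for (i in 1:I) {
    acc <- matrix(0, hd, hd)
    for (j in 1:J) acc <- acc + H[j, i] * votes[, , j, i]
    P2[, , i] <- array(ln(as.numeric(acc)), c(hd, hd))
  }
  expect_equal(dermacaps:::ad_value(r$parents)[, , , 1], P2, tolerance = 1e-6)
  expect_equal(r$coefficients[, , 1], H, tolerance = 1e-6)
})

test_that("routing is permutation-equivariant in the children", {
  set.seed(5)
  ch <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  Z <- array(rnorm(4 * 4 * 6 * 3, 0, 0.5), c(4, 4, 6, 3))
  perm <- c(4, 1, 6, 2, 5, 3)
  r1 <- attention_routing(ch, Z, iterations = 2)
  r2 <- attention_routing(ch[, , perm, , drop = FALSE],
                          Z[, , perm, , drop = FALSE], iterations = 2)
  expect_equal(dermacaps:::ad_value(r1$parents),
               dermacaps:::ad_value(r2$parents), tolerance = 1e-12)
})

test_that("class capsules produce one logit per class through a shared classifier", {
  set.seed(6)
  poses <- array(rnorm(4 * 4 * 8 * 3), c(4, 4, 8, 3))
  out <- class_capsules_and_logits(poses, capsule_config(), seed = 2)
  expect_equal(dim(out$logits), c(2L, 3L))
  # zero classifier: logits all equal the bias, softmax uniform
  z <- class_capsules_and_logits(poses, capsule_config(), seed = 2,
                                 zero_classifier = TRUE)
  expect_true(all(z$logits == z$logits[1, 1]))
  expect_equal(softmax(z$logits[, 1]), c(0.5, 0.5))
})

test_that("permuting class capsules permutes the logits identically", {
  set.seed(7)
  poses <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  Z <- array(rnorm(4 * 4 * 6 * 3, 0, 0.5), c(4, 4, 6, 3))
  w <- rnorm(16)
  logits_for <- function(Zc) {
    r <- attention_routing(poses, Zc, iterations = 2)
    cp <- dermacaps:::ad_value(r$parents)
    apply(cp, c(3, 4), function(p) sum(w * as.numeric(p)))
  }
  l1 <- logits_for(Z)
  perm <- c(3, 1, 2)
  l2 <- logits_for(Z[, , , perm, drop = FALSE])
  expect_equal(l2, l1[perm, ], tolerance = 1e-12)
})
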