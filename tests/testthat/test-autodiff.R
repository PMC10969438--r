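# Gradient correctness of the tape engine: every composite layer is
# checked against central-difference numerical gradients.

ad <- function(nm) get(nm, envir = asNamespace("dermacaps"))

test_that("convolution gradients match numerical differentiation", {
  set.seed(1)
  ad_param <- ad("ad_param"); ad_conv2d <- ad("ad_conv2d")
  ad_sum <- ad("ad_sum"); ad_mul <- ad("ad_mul")
  ad_backward <- ad("ad_backward"); as_ad <- ad("as_ad"); ad_value <- ad("ad_value")
  W <- ad_param(array(rnorm(2 * 3 * 3 * 3, 0, 0.3), c(2, 3, 3, 3)))
  b <- ad_param(rnorm(2))
  x <- ad_param(array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2)))
  loss <- function() {
    h <- ad_conv2d(x, W, b, stride = 2, pad = 1)
    ad_sum(ad_mul(h, h))
  }
  L <- loss()
  ad("ad_zero_grads")(list(W, b, x))
  ad_backward(L)
  for (p in list(W = W, b = b, x = x)) {
    idx <- sample(length(p$value), min(6, length(p$value)))
    ng <- vapply(idx, function(i) {
      e <- 1e-5; v0 <- p$value[i]
      p$value[i] <- v0 + e; l1 <- ad_value(loss())
      p$value[i] <- v0 - e; l2 <- ad_value(loss())
      p$value[i] <- v0
      (l1 - l2) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(ng - p$grad[idx]) / (abs(ng) + 1e-8)), 1e-5)
  }
})

test_that("softmax, layer norm and cross-entropy gradients are exact", {
  set.seed(2)
  ad_param <- ad("ad_param"); ad_backward <- ad("ad_backward")
  ad_value <- ad("ad_value")
  ln <- ad("ad_layernorm_cols"); sm <- ad("ad_softmax_cols")
  xent <- ad("ad_softmax_xent")
  x <- ad_param(matrix(rnorm(12), 4, 3))
  loss_ln <- function() xent(sm(ln(x)), c(1L, 3L, 2L))
  L <- loss_ln()
  ad("ad_zero_grads")(list(x))
  ad_backward(L)
  ng <- num_grad(function(v) {
    x2 <- ad_param(matrix(v, 4, 3))
    ad_value(xent(sm(ln(x2)), c(1L, 3L, 2L)))
  }, as.numeric(x$value))
  expect_lt(max(abs(ng - as.numeric(x$grad)) / (abs(ng) + 1e-8)), 1e-5)
})

test_that("batch-norm training-mode gradients are exact", {
  set.seed(3)
  ad_param <- ad("ad_param")
  x <- ad_param(array(rnorm(4 * 5 * 5 * 3), c(4, 5, 5, 3)))
  gam <- ad_param(runif(4, 0.5, 1.5))
  bet <- ad_param(rnorm(4))
  fresh_state <- function() {
    e <- new.env(); e$mean <- rep(0, 4); e$var <- rep(1, 4); e
  }
  loss <- function() {
    h <- ad("ad_batch_norm")(x, gam, bet, fresh_state(), train = TRUE)
    ad("ad_sum")(ad("ad_mul")(h, h))
  }
  L <- loss()
  ad("ad_zero_grads")(list(x, gam, bet))
  ad("ad_backward")(L)
  for (p in list(x, gam, bet)) {
    idx <- sample(length(p$value), min(5, length(p$value)))
    ng <- vapply(idx, function(i) {
      e <- 1e-5; v0 <- p$value[i]
      p$value[i] <- v0 + e; l1 <- ad("ad_value")(loss())
      p$value[i] <- v0 - e; l2 <- ad("ad_value")(loss())
      p$value[i] <- v0
      (l1 - l2) / (2 * e)
    }, numeric(1))
    # scale-aware criterion: tiny components of the projected gradient
    # carry finite-difference noise (a wrong backward rule errs at O(1))
    expect_lt(max(abs(ng - p$grad[idx])) / (max(abs(ng)) + 1e-6), 1e-3)
  }
})

test_that("routing gradients on a 2-child/2-parent fixture are exact to 1e-4", {
  set.seed(4)
  ad_param <- ad("ad_param")
  ch <- ad_param(array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  Z <- ad_param(array(rnorm(4 * 4 * 2 * 2, 0, 0.4), c(4, 4, 2, 2)))
  loss <- function() {
    r <- attention_routing(ch, Z, iterations = 2)
    ad("ad_sum")(ad("ad_mul")(r$parents, r$parents))
  }
  L <- loss()
  ad("ad_zero_grads")(list(ch, Z))
  ad("ad_backward")(L)
  for (p in list(ch, Z)) {
    ng <- vapply(seq_along(p$value), function(i) {
      e <- 1e-5; v0 <- p$value[i]
      p$value[i] <- v0 + e; l1 <- ad("ad_value")(loss())
      p$value[i] <- v0 - e; l2 <- ad("ad_value")(loss())
      p$value[i] <- v0
      (l1 - l2) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(ng - as.numeric(p$grad)) / (abs(ng) + 1e-6)), 1e-4)
  }
})

test_that("full classifier gradients agree with numerical differentiation", {
  set.seed(5)
  model <- build_capsnet(backbone_config("tiny", input_side = 16L),
                         capsule_config(capsules_per_layer = 8L), seed = 3)
  x <- array(rnorm(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  y <- c(1L, 2L)
  loss <- function() {
    out <- model$forward(ad("as_ad")(x), train = TRUE)
    ad("ad_softmax_xent")(out$logits, y)
  }
  L <- loss()
  ad("ad_zero_grads")(model$params)
  ad("ad_backward")(L)
  errs <- c()
  for (nm in c("stem.W", "s2b1.sc.W", "s3b2.c3.W", "cbam.mlp1.W",
               "fuse.mix.W", "primary.W", "caps.Z1", "caps.Zclass", "head.W")) {
    p <- model$params[[nm]]
    idx <- sample(length(p$value), min(4, length(p$value)))
    ng <- vapply(idx, function(i) {
      e <- 1e-5; v0 <- p$value[i]
      p$value[i] <- v0 + e; l1 <- ad("ad_value")(loss())
      p$value[i] <- v0 - e; l2 <- ad("ad_value")(loss())
      p$value[i] <- v0
      (l1 - l2) / (2 * e)
    }, numeric(1))
    errs <- c(errs, abs(ng - p$grad[idx]) / (abs(ng) + 1e-6))
  }
  # piecewise-linear kinks (relu, max-pooling) make isolated
  # finite-difference probes unreliable; the bulk must be exact
  expect_lt(median(errs), 1e-5)
  expect_gt(mean(errs < 1e-3), 0.85)
})
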