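test_that("sgd_step reproduces closed-form updates", {
  # quadratic L = theta^2: gradient 2 theta
  g <- function(theta, v) 2 * theta
  s <- sgd_step(1, list(1), g, sgd_config(step_size = 0.1, momentum = 0))
  expect_equal(s$theta, 0.8)
  # zero step size is the identity
  s0 <- sgd_step(1, list(1), g, sgd_config(step_size = 0, momentum = 0))
  expect_equal(s0$theta, 1)
  # the minibatch estimate is the mean of per-sample gradients
  gs <- function(theta, v) v * theta
  s2 <- sgd_step(c(2, 3), list(1, 3), function(theta, v) gs(theta, v),
                 sgd_config(step_size = 0.1, momentum = 0))
  expect_equal(s2$qhat, c(2, 3) * 2)  # mean of 1*theta and 3*theta
  expect_equal(s2$theta, c(2, 3) - 0.1 * c(4, 6))
  # momentum accumulates velocity
  s3 <- sgd_step(1, list(1), g, sgd_config(step_size = 0.1, momentum = 0.9))
  s4 <- sgd_step(s3$theta, list(1), g, sgd_config(step_size = 0.1, momentum = 0.9),
                 state = s3$state)
  expect_equal(s3$theta, 0.8)
  expect_equal(s4$theta, 0.8 - 0.9 * 0.2 - 0.1 * 1.6)
})

test_that("max_stable_step gives 2 / lambda_max and predicts divergence", {
  expect_equal(max_stable_step(diag(2))$max_stable_step, 2)
  r <- max_stable_step(diag(c(1, 4)))
  expect_equal(r$max_stable_step, 0.5)
  iterate <- function(mu, steps = 100) {
    theta <- c(1, 1)
    A <- diag(2) - mu * diag(c(1, 4))
    for (i in seq_len(steps)) theta <- A %*% theta
    sqrt(sum(theta^2))
  }
  expect_gt(iterate(0.6), 1e3)   # above the bound: diverges
  expect_lt(iterate(0.4), 1e-3)  # below the bound: contracts
  # spectral radius approaches 1 from below as mu -> 0
  rr <- vapply(c(0.1, 0.01, 0.001),
               function(mu) max_stable_step(diag(c(1, 4)), mu)$spectral_radius,
               numeric(1))
  expect_true(all(rr < 1))
  expect_true(all(diff(rr) > 0))
  expect_warning(max_stable_step(matrix(c(1, 2, 0, 1), 2)), "symmetr")
})

test_that("metrics match the hand-computed confusion matrix", {
  # counts T=8, f=2, C=5, P=5
  y_true <- rep(c(1, 0), c(10, 10))
  y_pred <- c(rep(1, 8), rep(0, 2), rep(0, 5), rep(1, 5))
  m <- compute_metrics(y_true, y_pred, positive = 1)
  expect_equal(m$accuracy, 0.65)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$rate_R, 8 / 13)
  expect_equal(m$f1, 2 * (8 / 13) * 0.8 / ((8 / 13) + 0.8))
  expect_equal(unname(m$counts[c("T", "f", "C", "P")]), c(8, 2, 5, 5))
})

test_that("perfect and uninformative classifiers hit the metric extremes", {
  y <- c(1, 1, 0, 0, 1)
  p <- compute_metrics(y, y, scores = y, positive = 1)
  for (nm in c("accuracy", "sensitivity", "specificity", "f1", "auc_roc")) {
    expect_equal(p[[nm]], 1)
  }
  flat <- compute_metrics(y, rep(1, 5), scores = rep(0.5, 5), positive = 1)
  expect_equal(flat$auc_roc, 0.5)   # tied scores trace the diagonal ROC
  expect_equal(flat$specificity, 0)
})

test_that("undefined ratios surface as NA sentinels", {
  m <- compute_metrics(c(0, 0), c(0, 0), positive = 1)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$rate_R))
  a <- auc_roc(c(0.2, 0.8), c(TRUE, TRUE))
  expect_true(is.na(a))
})

test_that("metrics equal brute-force enumeration on random fixtures", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 400
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(yt, yp, positive = 1)
    TP <- sum(yt == 1 & yp == 1); FN <- sum(yt == 1 & yp == 0)
    TN <- sum(yt == 0 & yp == 0); FP <- sum(yt == 0 & yp == 1)
    expect_equal(m$accuracy, (TP + TN) / n)
    expect_equal(m$sensitivity, TP / (TP + FN))
    expect_equal(m$specificity, TN / (TN + FP))
  }
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  set.seed(13)
  y <- sample(0:1, 200, replace = TRUE)
  s <- runif(200) + 0.3 * y
  a1 <- auc_roc(s, y)
  expect_equal(auc_roc(qlogis(pmin(pmax(s / 2, 1e-6), 1 - 1e-6)), y), a1,
               tolerance = 1e-12)
  skip_if_not_installed("pROC")
  a2 <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("training loss decreases across the first epochs for most seeds", {
  man <- small_dataset()
  drops <- vapply(1:6, function(s) {
    res <- train_pipeline(man,
                          sgd = sgd_config(epochs = 2L, minibatch = 8L, seed = s),
                          split = split_spec(fractions = c(0.8, 0, 0.2), seed = s),
                          segment = FALSE, augment_train = FALSE)
    diff(res$history$train_loss) <= 0
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("training with an identical seed reproduces identical metrics", {
  man <- small_dataset()
  cfg <- sgd_config(epochs = 2L, minibatch = 8L, seed = 4L)
  r1 <- train_pipeline(man, sgd = cfg, segment = FALSE)
  r2 <- train_pipeline(man, sgd = cfg, segment = FALSE)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$test_metrics$accuracy, r2$test_metrics$accuracy)
  expect_identical(r1$test_predictions$score, r2$test_predictions$score)
})
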