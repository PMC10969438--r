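# Minibatch SGD training and the end-to-end pipeline.

#' SGD configuration
#'
#' @param step_size Step size `mu` (> 0).
#' @param minibatch Minibatch size (>= 1).
#' @param momentum Momentum coefficient (0 = plain SGD; default 0.9,
#'   i.e. SGDM).
#' @param epochs Training epochs.
#' @param decay_factor Step-decay multiplier applied to the step size for
#'   the last `1 - decay_after` fraction of the epochs (1 = constant
#'   step size).
#' @param decay_after Fraction of the epochs run at the full step size.
#' @param seed Seed for shuffling and any stochastic draw during training.
#' @export
sgd_config <- function(step_size = 0.01, minibatch = 32L, momentum = 0.9,
                       epochs = 30L, decay_factor = 0.1, decay_after = 0.6,
                       seed = 1L) {
  stopifnot(step_size >= 0, minibatch >= 1, decay_factor > 0, decay_factor <= 1)
  structure(list(step_size = step_size, minibatch = as.integer(minibatch),
                 momentum = momentum, epochs = as.integer(epochs),
                 decay_factor = decay_factor, decay_after = decay_after,
                 seed = as.integer(seed)), class = "sgd_config")
}

#' One (momentum-filtered) SGD step on a parameter vector
#'
#' The gradient estimate is the sample average of per-sample gradients
#' over the minibatch; the update is `theta - mu * Qhat` for zero momentum
#' and velocity-filtered otherwise.
#'
#' @param theta Numeric parameter vector.
#' @param minibatch List (or vector) of samples.
#' @param grad_fn `function(theta, sample)` returning the per-sample
#'   gradient (same length as `theta`).
#' @param config A [sgd_config()].
#' @param state Optional momentum state from a previous call.
#' @return List with updated `theta`, the gradient estimate `qhat`, and
#'   `state`.
#' @export
sgd_step <- function(theta, minibatch, grad_fn, config = sgd_config(),
                     state = NULL) {
  if (!is.list(minibatch)) minibatch <- as.list(minibatch)
  grads <- vapply(minibatch, function(v) grad_fn(theta, v),
                  numeric(length(theta)))
  qhat <- if (length(theta) == 1L) mean(grads) else rowMeans(matrix(grads, length(theta)))
  if (any(!is.finite(qhat))) stop("non-finite gradient estimate; aborting step")
  if (config$momentum > 0) {
    v <- if (is.null(state)) numeric(length(theta)) else state
    v <- config$momentum * v - config$step_size * qhat
    theta <- theta + v
    state <- v
  } else {
    theta <- theta - config$step_size * qhat
  }
  list(theta = theta, qhat = qhat, state = state)
}

# in-place SGDM update over a model's ad_param list
optimizer_step <- function(params, velocities, lr, momentum) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (momentum > 0) {
      v <- velocities[[nm]]
      if (is.null(v)) v <- 0 * p$value
      v <- momentum * v - lr * g
      p$value <- p$value + v
      velocities[[nm]] <- v
    } else {
      p$value <- p$value - lr * g
    }
  }
  velocities
}

# margin loss (capsule-literature alternative to cross-entropy), built
# from tape ops so it is differentiable
margin_loss <- function(logits, labels, m_pos = 0.9, m_neg = 0.1, lambda = 0.5) {
  p <- ad_softmax_cols(logits)
  K <- nrow(ad_value(p)); N <- ncol(ad_value(p))
  Tk <- matrix(0, K, N); Tk[cbind(labels, seq_len(N))] <- 1
  pos <- ad_relu(ad_add(ad_scale(p, -1), m_pos))      # max(0, m+ - p)
  neg <- ad_relu(ad_add(p, -m_neg))                   # max(0, p - m-)
  term <- ad_add(ad_mul(as_ad(Tk), ad_mul(pos, pos)),
                 ad_scale(ad_mul(as_ad(1 - Tk), ad_mul(neg, neg)), lambda))
  ad_scale(ad_sum(term), 1 / N)
}

# --- image loading / preprocessing for the classifier -----------------------

load_and_preprocess <- function(paths, side, segment = FALSE,
                                segment_side = 96L, verbose = FALSE) {
  lapply(seq_along(paths), function(i) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (segment) {
      seg_in <- if (max(dim(img)[1:2]) > segment_side) resize_image(img, segment_side) else img
      seg <- try(segment_lesion(seg_in), silent = TRUE)
      if (!inherits(seg, "try-error")) {
        mask <- seg$mask
        bg <- apply(seg_in, 3, function(ch) mean(ch[mask == 0]))
        for (ch in 1:3) {
          m <- seg_in[, , ch]
          m[mask == 0] <- bg[ch]
          seg_in[, , ch] <- m
        }
        img <- seg_in
      }
    }
    resize_image(img, side)
  })
}

batch_tensor <- function(imgs, idx, augment_params = NULL) {
  side <- dim(imgs[[1]])[1]
  x <- array(0, c(3, side, side, length(idx)))
  for (k in seq_along(idx)) {
    im <- imgs[[idx[k]]]
    if (!is.null(augment_params)) im <- augment(im, augment_params)
    im <- normalize_image(im)
    x[, , , k] <- aperm(im, c(3, 1, 2))
  }
  x
}

#' Predict class probabilities with a capsule classifier
#'
#' @param model A `capsnet_model`.
#' @param imgs List of preprocessed `side x side x 3` images in `[0, 1]`
#'   (normalization is applied internally).
#' @param batch_size Forward batch size.
#' @return `N x classes` probability matrix (softmax over class logits).
#' @export
predict_capsnet <- function(model, imgs, batch_size = 32L) {
  n <- length(imgs)
  probs <- matrix(0, n, length(model$classes),
                  dimnames = list(NULL, model$classes))
  if (n == 0L) return(probs)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- batch_tensor(imgs, idx)
    out <- ad_no_grad(model$forward(as_ad(x)))
    probs[idx, ] <- t(softmax(ad_value(out$logits)))
  }
  colnames(probs) <- model$classes
  probs
}

#' Train the full pipeline on a dataset manifest
#'
#' Preprocess (optional snake segmentation + resize + normalization),
#' stratified 70/15/15 split, minibatch SGDM training of the
#' backbone + CBAM + capsule classifier with cross-entropy loss,
#' per-epoch validation metrics, and one final evaluation on the held-out
#' test split.  A leakage guard raises an error if any test record enters
#' a training minibatch.
#'
#' @param manifest Data frame with `image` and `label` columns (see
#'   [generate_dataset()]).
#' @param backbone_cfg,caps_cfg,cbam_cfg Model configuration.
#' @param sgd A [sgd_config()].
#' @param split A [split_spec()].
#' @param segment Mask out the background via [segment_lesion()] before
#'   training (slower, closer to the full pipeline).
#' @param augment_train Apply random augmentation to training minibatches.
#' @param loss `"cross_entropy"` (default) or `"margin"`.
#' @param verbose Print one line per epoch.
#' @return List of class `train_result` with the trained `model`, per
#'   epoch `history`, `test_metrics` (a `metrics_report`), the splits and
#'   per-image test predictions.
#' @export
train_pipeline <- function(manifest,
                           backbone_cfg = backbone_config("tiny"),
                           caps_cfg = capsule_config(),
                           cbam_cfg = cbam_params(),
                           sgd = sgd_config(),
                           split = split_spec(seed = sgd$seed),
                           segment = FALSE,
                           augment_train = TRUE,
                           loss = c("cross_entropy", "margin"),
                           verbose = FALSE) {
  loss <- match.arg(loss)
  splits <- split_dataset(manifest, split)
  classes <- sort(unique(manifest$label))
  lab_int <- function(m) match(m$label, classes)
  all_paths <- c(splits$train$image, splits$val$image, splits$test$image)
  imgs <- load_and_preprocess(all_paths, backbone_cfg$input_side, segment = segment)
  n_tr <- nrow(splits$train); n_va <- nrow(splits$val); n_te <- nrow(splits$test)
  idx_tr <- seq_len(n_tr)
  idx_va <- n_tr + seq_len(n_va)
  idx_te <- n_tr + n_va + seq_len(n_te)
  y_tr <- lab_int(splits$train); y_va <- lab_int(splits$val); y_te <- lab_int(splits$test)
  test_ids <- splits$test$image

  model <- build_capsnet(backbone_cfg, caps_cfg, cbam_cfg, seed = sgd$seed)
  model$classes <- classes
  velocities <- list()
  aug <- if (augment_train) augment_params() else NULL
  history <- data.frame()
  with_seed(sgd$seed + 7L, {
    for (epoch in seq_len(sgd$epochs)) {
      ord <- sample(idx_tr)
      if (any(all_paths[ord] %in% test_ids)) {
        stop("leakage guard: a test record appeared in the training stream")
      }
      lr <- sgd$step_size *
        if (epoch > ceiling(sgd$decay_after * sgd$epochs)) sgd$decay_factor else 1
      epoch_loss <- 0; nb <- 0L
      for (start in seq(1, n_tr, by = sgd$minibatch)) {
        bidx <- ord[start:min(start + sgd$minibatch - 1L, n_tr)]
        x <- batch_tensor(imgs, bidx, aug)
        yb <- y_tr[match(bidx, idx_tr)]
        out <- model$forward(as_ad(x), train = TRUE)
        l <- if (loss == "cross_entropy") ad_softmax_xent(out$logits, yb)
             else margin_loss(out$logits, yb)
        if (!is.finite(ad_value(l))) stop("non-finite loss; aborting training")
        ad_zero_grads(model$params)
        ad_backward(l)
        velocities <- optimizer_step(model$params, velocities,
                                     lr, sgd$momentum)
        epoch_loss <- epoch_loss + ad_value(l); nb <- nb + 1L
      }
      val_acc <- NA_real_
      if (n_va > 0) {
        pv <- predict_capsnet(model, imgs[idx_va])
        val_acc <- mean(classes[max.col(pv)] == splits$val$label)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epoch_loss / nb,
                                           val_accuracy = val_acc))
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  val acc %.3f",
                        epoch, epoch_loss / nb, val_acc))
      }
    }
  })
  pos <- classes[length(classes)]
  if (n_te > 0) {
    pt <- predict_capsnet(model, imgs[idx_te])
    pred_lab <- classes[max.col(pt)]
    test_metrics <- compute_metrics(splits$test$label, pred_lab,
                                    scores = pt[, pos], positive = pos)
  } else {
    pt <- matrix(numeric(0), 0, length(classes))
    pred_lab <- character(0)
    test_metrics <- NULL
  }
  structure(list(model = model, history = history,
                 test_metrics = test_metrics,
                 splits = splits,
                 test_predictions = data.frame(image = splits$test$image,
                                               label = splits$test$label,
                                               predicted = pred_lab,
                                               score = if (n_te > 0) pt[, pos] else numeric(0))),
            class = "train_result")
}

#' Evaluate a trained model on a manifest
#'
#' @param model A `capsnet_model`.
#' @param manifest Data frame with `image` and `label` columns.
#' @param segment Apply the same segmentation preprocessing used in
#'   training.
#' @return A `metrics_report`.
#' @export
evaluate_pipeline <- function(model, manifest, segment = FALSE) {
  side <- model$backbone$config$input_side
  imgs <- load_and_preprocess(manifest$image, side, segment = segment)
  p <- predict_capsnet(model, imgs)
  classes <- model$classes
  pos <- classes[length(classes)]
  compute_metrics(manifest$label, classes[max.col(p)],
                  scores = p[, pos], positive = pos)
}
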