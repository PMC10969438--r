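# Residual convolutional backbone.
#
# Two bottleneck residual block topologies are used, mirroring the classic
# deep-residual design: RBB-1 adds the three-convolution branch G to an
# identity shortcut, x = G(y) + y, and requires matching channel counts;
# RBB-2 replaces the shortcut with a projection (convolution + norm) F,
# x = G(y) + F(y), and is used wherever width or resolution changes.  The
# `resnet50` preset stacks 1 stem convolution + 16 bottleneck blocks x 3
# convolutions = 49 convolution layers on the main path and pools to a
# 2048-dimensional feature vector; the `tiny` preset (3 stages of widths
# 8/16/32, two blocks each) is a desk-scale companion that trains in
# minutes on a CPU.  Convolutions are followed by batch normalization;
# inference uses the exponentially averaged running statistics, so
# prediction is deterministic and batch-independent.

#' Rectified linear unit
#' @param x Numeric vector/array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable softmax
#' @param logits Numeric vector, or matrix with one column per sample.
#' @return Probabilities summing to 1 (per column for matrices).
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    e <- exp(sweep(logits, 2, apply(logits, 2, max)))
    return(sweep(e, 2, colSums(e), "/"))
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

# parameter collector: builders register ad_param tensors under unique names
new_param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$main_convs <- 0L
  e$shortcut_convs <- 0L
  e
}

store_param <- function(store, name, value) {
  p <- ad_param(value)
  store$params[[name]] <- p
  p
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# conv + batch norm + optional relu; counts toward the requested tally
make_conv_bn <- function(store, name, cin, cout, k, stride = 1L,
                         activation = TRUE, count = c("main", "shortcut")) {
  count <- match.arg(count)
  W <- store_param(store, paste0(name, ".W"), he_init(cin * k * k, c(cout, cin, k, k)))
  gamma <- store_param(store, paste0(name, ".gamma"), rep(1, cout))
  beta <- store_param(store, paste0(name, ".beta"), rep(0, cout))
  state <- new.env(parent = emptyenv())
  state$mean <- rep(0, cout)
  state$var <- rep(1, cout)
  if (count == "main") store$main_convs <- store$main_convs + 1L
  else store$shortcut_convs <- store$shortcut_convs + 1L
  pad <- (k - 1L) %/% 2L
  function(x, train = FALSE) {
    out <- ad_conv2d(x, W, b = NULL, stride = stride, pad = pad)
    out <- ad_batch_norm(out, gamma, beta, state, train = train)
    if (activation) out <- ad_relu(out)
    out
  }
}

#' Construct a residual bottleneck block
#'
#' @param store Internal parameter store (from the backbone builder); pass
#'   `NULL` to get a standalone block with its own store.
#' @param name Parameter name prefix.
#' @param cin,cout Input/output channel counts.
#' @param mid Bottleneck width of the 3 x 3 convolution.
#' @param stride Stride of the 3 x 3 convolution.
#' @param kind `"RBB1"` (identity shortcut; needs `cin == cout`,
#'   `stride == 1`) or `"RBB2"` (projection shortcut).
#' @return List with `forward` (tensor function) and `params`.
#' @export
residual_block <- function(store = NULL, name = "rbb", cin, cout, mid,
                           stride = 1L, kind = c("RBB1", "RBB2")) {
  kind <- match.arg(kind)
  if (is.null(store)) store <- new_param_store()
  if (kind == "RBB1" && (cin != cout || stride != 1L)) {
    stop("RBB1 requires matching channels and unit stride; use RBB2")
  }
  c1 <- make_conv_bn(store, paste0(name, ".c1"), cin, mid, 1L, 1L, TRUE)
  c2 <- make_conv_bn(store, paste0(name, ".c2"), mid, mid, 3L, stride, TRUE)
  c3 <- make_conv_bn(store, paste0(name, ".c3"), mid, cout, 1L, 1L, FALSE)
  sc <- if (kind == "RBB2") {
    make_conv_bn(store, paste0(name, ".sc"), cin, cout, 1L, stride, FALSE,
                 count = "shortcut")
  } else NULL
  forward <- function(x, train = FALSE) {
    g <- c3(c2(c1(x, train), train), train)
    s <- if (is.null(sc)) x else sc(x, train)
    ad_relu(ad_add(g, s))
  }
  list(forward = forward, params = store$params, store = store)
}

#' Backbone configuration
#'
#' @param preset `"resnet50"` (49 main-path convolutions, 2048-d pooled
#'   feature) or `"tiny"` (3 stages of widths 8/16/32, two blocks each,
#'   under 100k parameters).
#' @param input_side Expected input side; defaults to 299 (resnet50) or
#'   32 (tiny).
#' @param seed Seed for the random weight initialization.
#' @export
backbone_config <- function(preset = c("tiny", "resnet50"), input_side = NULL,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(input_side)) input_side <- if (preset == "resnet50") 299L else 32L
  structure(list(preset = preset, input_side = as.integer(input_side),
                 seed = as.integer(seed)), class = "backbone_config")
}

#' Build a residual backbone
#'
#' Weights are randomly initialized (He-normal, seeded); the architecture,
#' not any trained weight, is the contract.
#'
#' @param config A [backbone_config()].
#' @return List of class `backbone` with `forward(x)` mapping a
#'   `(3, side, side, N)` tensor to `list(map, features)` (final pre-pool
#'   feature map and globally pooled feature vector), `params`, `config`
#'   and conv-layer counts.
#' @export
build_backbone <- function(config = backbone_config()) {
  store <- new_param_store()
  with_seed(config$seed, {
    if (config$preset == "resnet50") {
      stem <- make_conv_bn(store, "stem", 3L, 64L, 7L, 2L, TRUE)
      blocks_per_stage <- c(3L, 4L, 6L, 3L)
      mids <- c(64L, 128L, 256L, 512L)
      outs <- c(256L, 512L, 1024L, 2048L)
      use_maxpool <- TRUE
      cin <- 64L
    } else {
      stem <- make_conv_bn(store, "stem", 3L, 8L, 3L, 2L, TRUE)
      blocks_per_stage <- c(2L, 2L, 2L)
      mids <- c(4L, 8L, 16L)
      outs <- c(8L, 16L, 32L)
      use_maxpool <- FALSE
      cin <- 8L
    }
    stage_fns <- list()
    for (s in seq_along(blocks_per_stage)) {
      for (b in seq_len(blocks_per_stage[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        kind <- if (b == 1L && (cin != outs[s] || stride != 1L)) "RBB2" else "RBB1"
        blk <- residual_block(store, sprintf("s%db%d", s, b), cin, outs[s],
                              mids[s], stride, kind)
        stage_fns[[length(stage_fns) + 1L]] <- blk$forward
        cin <- outs[s]
      }
    }
    feature_dim <- cin
    forward <- function(x, train = FALSE) {
      x <- as_ad(x)
      side <- dim(x$value)[2]
      if (side != config$input_side) {
        stop(sprintf("input side %d does not match the configured side %d",
                     side, config$input_side))
      }
      h <- stem(x, train)
      if (use_maxpool) h <- ad_maxpool(h, 3L, 2L, 1L)
      for (f in stage_fns) h <- f(h, train)
      list(map = h, features = ad_global_pool(h, "mean"))
    }
    structure(list(forward = forward, params = store$params, config = config,
                   feature_dim = feature_dim,
                   conv_layers = store$main_convs,
                   shortcut_convs = store$shortcut_convs),
              class = "backbone")
  })
}

#' Convert a list of H x W x 3 images to a channels-first batch
#'
#' @param imgs List of `side x side x 3` arrays (or one array).
#' @return `(3, side, side, N)` array.
#' @export
images_to_batch <- function(imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  d <- dim(imgs[[1]])
  out <- array(0, c(3, d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- aperm(imgs[[i]], c(3, 1, 2))
  out
}

#' Extract pooled features and the final feature map for a batch
#'
#' @param model A `backbone` (from [build_backbone()]).
#' @param batch `(3, side, side, N)` array or a list of images.
#' @return List with `features` (`feature_dim x N` matrix) and `map`
#'   (final pre-pool feature-map array).
#' @export
extract_features <- function(model, batch) {
  if (is.list(batch)) batch <- images_to_batch(batch)
  out <- ad_no_grad(model$forward(as_ad(batch)))
  list(features = ad_value(out$features), map = ad_value(out$map))
}

#' Architecture summary of a backbone or full classifier
#'
#' Reports the number of convolution layers on the main path (stem +
#' 3 per bottleneck block), projection-shortcut convolutions, pooled
#' feature dimension and parameter count; for a full capsule classifier
#' also the capsule layout.
#'
#' @param model A `backbone` or `capsnet_model`.
#' @return Named list of class `model_summary`.
#' @export
model_summary <- function(model) {
  if (inherits(model, "capsnet_model")) {
    bb <- model$backbone
    caps <- model$caps_config
    s <- list(preset = bb$config$preset,
              conv_layers = bb$conv_layers,
              shortcut_convs = bb$shortcut_convs,
              feature_dim = bb$feature_dim,
              conv_capsule_layers = caps$conv_capsule_layers,
              capsules_per_layer = caps$capsules_per_layer,
              total_conv_capsules = caps$conv_capsule_layers * caps$capsules_per_layer,
              pose_side = caps$pose_side,
              class_capsules = caps$class_capsules,
              class_capsule_size = caps$class_capsule_size,
              n_params = sum(vapply(model$params, function(p) length(p$value), numeric(1))))
  } else {
    s <- list(preset = model$config$preset,
              conv_layers = model$conv_layers,
              shortcut_convs = model$shortcut_convs,
              feature_dim = model$feature_dim,
              n_params = sum(vapply(model$params, function(p) length(p$value), numeric(1))))
  }
  structure(s, class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
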