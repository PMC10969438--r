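# CBAM attention, feature fusion, and the matrix-capsule head with
# inverted dot-product attention routing.
#
# Channel attention: Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))), a
# shared two-layer bottleneck MLP over the spatially pooled descriptors.
# Spatial attention: Ms = sigmoid(conv_kxk([channel-mean; channel-max])).
# The refined map is F' = Ms(Mc(F) (x) F) (x) F with broadcast
# multiplication.
#
# Capsule head: a primary convolution standardizes (layer-normalizes) the
# fused features and reshapes them into matrix capsules of size
# pose_side x pose_side.  Routing between consecutive capsule layers:
# votes M_ji = Z_ji . N_j (a learned pose transform per child-parent
# pair); agreements F_ji = <N_i, M_ji> (dot product of flattened poses);
# coefficients H_ji = softmax over parents of F_ji (each child's
# coefficients sum to 1); parent poses N_i = LayerNorm(sum_j H_ji M_ji).
# Parents start at zero, so the first iteration has all agreements 0 and
# uniform coefficients 1/(number of parents); later iterations re-score
# the votes against the current parents.

#' CBAM parameters
#' @param reduction_ratio Channel-MLP bottleneck ratio (clipped so the
#'   hidden width is at least 1).
#' @param spatial_kernel Odd kernel size of the spatial-attention
#'   convolution.
#' @export
cbam_params <- function(reduction_ratio = 16L, spatial_kernel = 7L) {
  stopifnot(spatial_kernel %% 2L == 1L)
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "cbam_params")
}

#' Capsule head configuration
#'
#' Defaults follow the reference layout: two convolutional capsule layers
#' of 32 matrix capsules of size 4 x 4 each (64 in total), two class
#' capsules of size 16 (= 4 x 4 flattened), two routing iterations.
#'
#' @param pose_side Pose matrix side `hd` (>= 2).
#' @param capsules_per_layer Capsules per convolutional capsule layer.
#' @param conv_capsule_layers Number of convolutional capsule layers.
#' @param class_capsules Number of class capsules (>= 2).
#' @param class_capsule_size Flattened class-capsule size (must equal
#'   `pose_side^2`).
#' @param routing_iterations Routing iterations (>= 1).
#' @param softmax_over Softmax axis of the routing coefficients:
#'   `"parents"` (inverted dot-product attention, default) or
#'   `"children"` (classic capsule convention).
#' @export
capsule_config <- function(pose_side = 4L, capsules_per_layer = 32L,
                           conv_capsule_layers = 2L, class_capsules = 2L,
                           class_capsule_size = 16L, routing_iterations = 2L,
                           softmax_over = c("parents", "children")) {
  softmax_over <- match.arg(softmax_over)
  stopifnot(pose_side >= 2L, routing_iterations >= 1L, class_capsules >= 2L)
  if (class_capsule_size != pose_side^2) {
    stop("class_capsule_size must equal pose_side^2 (flattened pose)")
  }
  structure(list(pose_side = as.integer(pose_side),
                 capsules_per_layer = as.integer(capsules_per_layer),
                 conv_capsule_layers = as.integer(conv_capsule_layers),
                 class_capsules = as.integer(class_capsules),
                 class_capsule_size = as.integer(class_capsule_size),
                 routing_iterations = as.integer(routing_iterations),
                 softmax_over = softmax_over),
            class = "capsule_config")
}

# --- CBAM -------------------------------------------------------------------

make_cbam <- function(store, name, channels, params = cbam_params()) {
  hidden <- max(1L, channels %/% params$reduction_ratio)
  if (channels < params$reduction_ratio) {
    warning("channel count below reduction ratio; clipping hidden width to 1")
  }
  W1 <- store_param(store, paste0(name, ".mlp1.W"), he_init(channels, c(hidden, channels)))
  b1 <- store_param(store, paste0(name, ".mlp1.b"), rep(0, hidden))
  W2 <- store_param(store, paste0(name, ".mlp2.W"), he_init(hidden, c(channels, hidden)))
  b2 <- store_param(store, paste0(name, ".mlp2.b"), rep(0, channels))
  k <- params$spatial_kernel
  Ws <- store_param(store, paste0(name, ".spatial.W"), he_init(2 * k * k, c(1, 2, k, k)))
  bs <- store_param(store, paste0(name, ".spatial.b"), 0)
  mlp <- function(v) {
    ad_add_colvec(ad_matmul(W2, ad_relu(ad_add_colvec(ad_matmul(W1, v), b1))), b2)
  }
  channel_attention <- function(x) {
    ad_sigmoid(ad_add(mlp(ad_global_pool(x, "mean")), mlp(ad_global_pool(x, "max"))))
  }
  spatial_attention <- function(x) {
    ad_sigmoid(ad_conv2d(ad_channel_pool(x), Ws, bs, stride = 1L, pad = (k - 1L) %/% 2L))
  }
  forward <- function(x) {
    x <- as_ad(x)
    mc <- channel_attention(x)
    x1 <- ad_mul_channels(x, mc)
    ms <- spatial_attention(x1)
    ad_mul_spatial(x1, ms)
  }
  list(forward = forward, channel_attention = channel_attention,
       spatial_attention = spatial_attention)
}

#' Apply CBAM attention to a feature map (standalone)
#'
#' Convenience wrapper building a seeded one-off CBAM module; returns the
#' refined map and the attention maps as plain arrays.
#'
#' @param fmap `(C, H, W, N)` array.
#' @param params A [cbam_params()].
#' @param seed Weight-initialization seed.
#' @param zero_weights Use all-zero weights (attention pinned at 0.5).
#' @return List with `refined`, `mc` (`C x N`), `ms` (`1 x H x W x N`).
#' @export
cbam <- function(fmap, params = cbam_params(), seed = 1L, zero_weights = FALSE) {
  store <- new_param_store()
  mod <- with_seed(seed, make_cbam(store, "cbam", dim(fmap)[1], params))
  if (zero_weights) for (p in store$params) p$value[] <- 0
  x <- as_ad(fmap)
  mc <- mod$channel_attention(x)
  x1 <- ad_mul_channels(x, mc)
  ms <- mod$spatial_attention(x1)
  refined <- ad_mul_spatial(x1, ms)
  list(refined = ad_value(refined), mc = ad_value(mc), ms = ad_value(ms))
}

# --- fusion -----------------------------------------------------------------

make_fusion <- function(store, name, c_backbone, c_attended, c_out,
                        mode = c("concat", "sum")) {
  mode <- match.arg(mode)
  if (mode == "sum") {
    return(list(forward = function(a, b) ad_add(a, b), out_channels = c_backbone))
  }
  Wm <- store_param(store, paste0(name, ".mix.W"),
                    he_init(c_backbone + c_attended, c(c_out, c_backbone + c_attended, 1, 1)))
  bm <- store_param(store, paste0(name, ".mix.b"), rep(0, c_out))
  list(forward = function(a, b) {
    ad_conv2d(ad_concat_channels(a, b), Wm, bm, stride = 1L, pad = 0L)
  }, out_channels = c_out)
}

#' Fuse the backbone map with the attended map
#'
#' Default: channel-wise concatenation followed by a 1 x 1 mixing
#' convolution; `mode = "sum"` adds the maps elementwise.
#'
#' @param backbone_map,attended `(C, H, W, N)` arrays of equal spatial
#'   shape.
#' @param mode `"concat"` or `"sum"`.
#' @param out_channels Output channels for concat mode.
#' @param seed Weight seed for the mixing convolution.
#' @param identity_first Initialize the mixing kernel so the output equals
#'   the first (backbone) block of the concatenation.
#' @return Fused `(C', H, W, N)` array.
#' @export
fuse_features <- function(backbone_map, attended, mode = c("concat", "sum"),
                          out_channels = dim(backbone_map)[1], seed = 1L,
                          identity_first = FALSE) {
  mode <- match.arg(mode)
  if (!all(dim(backbone_map)[2:4] == dim(attended)[2:4])) {
    stop("spatial shapes of the fused maps must match")
  }
  if (mode == "sum" && dim(backbone_map)[1] != dim(attended)[1]) {
    stop("sum fusion requires equal channel counts")
  }
  store <- new_param_store()
  fus <- with_seed(seed, make_fusion(store, "fuse", dim(backbone_map)[1],
                                     dim(attended)[1], out_channels, mode))
  if (identity_first && mode == "concat") {
    W <- store$params[["fuse.mix.W"]]
    W$value[] <- 0
    for (c0 in seq_len(min(out_channels, dim(backbone_map)[1]))) {
      W$value[c0, c0, 1, 1] <- 1
    }
    store$params[["fuse.mix.b"]]$value[] <- 0
  }
  ad_value(fus$forward(as_ad(backbone_map), as_ad(attended)))
}

# --- capsule ops ------------------------------------------------------------

# votes: children (hd,hd,J,N), Z (hd,hd,J,I) -> votes (hd,hd,J,I,N)
ad_caps_votes <- function(children, Z) {
  children <- as_ad(children); Z <- as_ad(Z)
  ch <- children$value; Zv <- Z$value
  dc <- dim(ch); hd <- dc[1]; J <- dc[3]; N <- dc[4]
  I <- dim(Zv)[4]
  V <- array(0, c(hd, hd, J, I, N))
  Zmats <- vector("list", J); Cmats <- vector("list", J)
  for (j in seq_len(J)) {
    Zj <- matrix(aperm(array(Zv[, , j, ], c(hd, hd, I)), c(1, 3, 2)), hd * I, hd)
    Cj <- matrix(ch[, , j, ], hd, hd * N)
    Vj <- Zj %*% Cj  # (hd*I, hd*N)
    Zmats[[j]] <- Zj; Cmats[[j]] <- Cj
    V[, , j, , ] <- aperm(array(Vj, c(hd, I, hd, N)), c(1, 3, 2, 4))
  }
  if (!any(is.finite(V))) stop("non-finite votes")
  new_ad(V, list(children, Z), function(g) {
    dch <- array(0, dc)
    dZ <- array(0, dim(Zv))
    for (j in seq_len(J)) {
      gj <- matrix(aperm(array(g[, , j, , ], c(hd, hd, I, N)), c(1, 3, 2, 4)),
                   hd * I, hd * N)
      dZj <- gj %*% t(Cmats[[j]])
      dZ[, , j, ] <- aperm(array(dZj, c(hd, I, hd)), c(1, 3, 2))
      dch[, , j, ] <- array(crossprod(Zmats[[j]], gj), c(hd, hd, N))
    }
    list(dch, dZ)
  })
}

# weighted vote sum: V (d,J,I,N) flattened votes, H (J,I,N) coefficients
# -> parents (d,I,N)
ad_caps_wsum <- function(V, H) {
  V <- as_ad(V); H <- as_ad(H)
  Vv <- V$value; Hv <- H$value
  d <- dim(Vv)[1]; J <- dim(Vv)[2]; I <- dim(Vv)[3]; N <- dim(Vv)[4]
  Hb <- array(rep(as.numeric(Hv), each = d), dim(Vv))
  VH <- Vv * Hb
  dim(VH) <- c(d, J, I * N)
  P <- array(0, c(d, I * N))
  for (j in seq_len(J)) P <- P + matrix(VH[, j, ], d, I * N)
  P <- array(P, c(d, I, N))
  new_ad(P, list(V, H), function(g) {
    dV <- array(0, dim(Vv))
    dH <- array(0, dim(Hv))
    for (j in seq_len(J)) {
      Hj <- Hb[, j, , , drop = FALSE]; dim(Hj) <- c(d, I, N)
      Vj <- Vv[, j, , , drop = FALSE]; dim(Vj) <- c(d, I, N)
      dV[, j, , ] <- g * Hj
      dH[j, , ] <- colSums(matrix(g * Vj, d, I * N))
    }
    list(dV, dH)
  })
}

# agreements: F[j,i,n] = <V[,j,i,n], P[,i,n]>
ad_caps_agree <- function(V, P) {
  V <- as_ad(V); P <- as_ad(P)
  Vv <- V$value; Pv <- P$value
  d <- dim(Vv)[1]; J <- dim(Vv)[2]; I <- dim(Vv)[3]; N <- dim(Vv)[4]
  Fv <- array(0, c(J, I, N))
  for (j in seq_len(J)) {
    Vj <- Vv[, j, , , drop = FALSE]; dim(Vj) <- c(d, I, N)
    Fv[j, , ] <- colSums(matrix(Vj * Pv, d, I * N))
  }
  new_ad(Fv, list(V, P), function(g) {
    dV <- array(0, dim(Vv))
    dP <- array(0, c(d, I, N))
    for (j in seq_len(J)) {
      gj <- array(rep(g[j, , ], each = d), c(d, I, N))
      Vj <- Vv[, j, , , drop = FALSE]; dim(Vj) <- c(d, I, N)
      dV[, j, , ] <- gj * Pv
      dP <- dP + gj * Vj
    }
    list(dV, dP)
  })
}

# layer normalization of poses: (d, I, N) standardized over d per capsule
caps_layernorm <- function(P) {
  d <- dim(ad_value(P))
  ad_reshape(ad_layernorm_cols(ad_reshape(P, c(d[1], d[2] * d[3]))), d)
}

# softmax of agreements over the chosen axis; F (J, I, N)
routing_softmax <- function(F_, over = "parents") {
  d <- dim(ad_value(F_))
  if (over == "parents") {
    Fp <- ad_aperm(F_, c(2, 1, 3))
    S <- ad_softmax_cols(ad_reshape(Fp, c(d[2], d[1] * d[3])))
    ad_aperm(ad_reshape(S, c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    S <- ad_softmax_cols(ad_reshape(F_, c(d[1], d[2] * d[3])))
    ad_reshape(S, d)
  }
}

#' Inverted dot-product attention routing between capsule layers
#'
#' @param children `(hd, hd, J, N)` child pose tensor (array or
#'   `ad_tensor`).
#' @param Z `(hd, hd, J, I)` pose-transform weights.
#' @param iterations Routing iterations (>= 1).
#' @param softmax_over `"parents"` (default) or `"children"`.
#' @return List with `parents` (`(hd, hd, I, N)` tensor), `coefficients`
#'   (`(J, I, N)` array, final iteration) and `agreements`.
#' @export
attention_routing <- function(children, Z, iterations = 2L,
                              softmax_over = "parents") {
  children <- as_ad(children); Z <- as_ad(Z)
  dc <- dim(children$value)
  hd <- dc[1]; J <- dc[3]; N <- dc[4]
  I <- dim(Z$value)[4]
  V <- ad_caps_votes(children, Z)
  Vf <- ad_reshape(V, c(hd * hd, J, I, N))
  # iteration 1: parents are zero, agreements vanish, coefficients uniform
  H1 <- array(1 / I, c(J, I, N))
  P <- caps_layernorm(ad_caps_wsum(Vf, as_ad(H1)))
  Hlast <- H1; Flast <- array(0, c(J, I, N))
  if (iterations >= 2L) {
    for (it in 2:iterations) {
      F_ <- ad_caps_agree(Vf, P)
      H <- routing_softmax(F_, softmax_over)
      P <- caps_layernorm(ad_caps_wsum(Vf, H))
      Hlast <- ad_value(H); Flast <- ad_value(F_)
    }
  }
  list(parents = ad_reshape(P, c(hd, hd, I, N)),
       coefficients = Hlast, agreements = Flast)
}

# --- primary capsules and the full model ------------------------------------

make_primary_capsules <- function(store, name, cin, config) {
  hd <- config$pose_side
  cap_ch <- config$capsules_per_layer * hd * hd
  W <- store_param(store, paste0(name, ".W"), he_init(cin, c(cap_ch, cin, 1, 1)))
  b <- store_param(store, paste0(name, ".b"), rep(0, cap_ch))
  function(fused) {
    # 1x1 conv -> global spatial pooling -> standardize -> matrix capsules
    h <- ad_conv2d(fused, W, b, stride = 1L, pad = 0L)
    v <- ad_global_pool(h, "mean")  # (cap_ch, N)
    N <- dim(ad_value(v))[2]
    poses <- ad_reshape(v, c(hd * hd, config$capsules_per_layer, N))
    poses <- ad_reshape(ad_layernorm_cols(
      ad_reshape(poses, c(hd * hd, config$capsules_per_layer * N))),
      c(hd, hd, config$capsules_per_layer, N))
    poses
  }
}

#' Primary matrix capsules from a fused feature map (standalone)
#'
#' One 1 x 1 convolution, global spatial pooling, layer normalization
#' ("standardize"), and a reshape into `capsules_per_layer` matrix poses
#' of size `pose_side x pose_side`.
#'
#' @param fused `(C, H, W, N)` array.
#' @param config A [capsule_config()].
#' @param seed Weight seed.
#' @return `(hd, hd, J, N)` pose array.
#' @export
primary_capsules <- function(fused, config = capsule_config(), seed = 1L) {
  store <- new_param_store()
  f <- with_seed(seed, make_primary_capsules(store, "primary", dim(fused)[1], config))
  ad_value(f(as_ad(fused)))
}

#' Build the full attention-capsule classifier
#'
#' Backbone -> CBAM -> fusion -> primary capsules -> conv capsule layers
#' with attention routing -> class capsules -> shared linear classifier
#' producing one logit per class.
#'
#' @param backbone_cfg A [backbone_config()].
#' @param caps_cfg A [capsule_config()].
#' @param cbam_cfg A [cbam_params()].
#' @param fusion_mode `"concat"` or `"sum"`.
#' @param seed Weight-initialization seed.
#' @return List of class `capsnet_model` with `forward(x, collect =
#'   FALSE)`, `params`, configs.
#' @export
build_capsnet <- function(backbone_cfg = backbone_config("tiny"),
                          caps_cfg = capsule_config(),
                          cbam_cfg = cbam_params(),
                          fusion_mode = "concat",
                          seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  bb <- build_backbone(backbone_config(backbone_cfg$preset,
                                       backbone_cfg$input_side, seeds[1]))
  store <- new_param_store()
  store$params <- bb$params
  C <- bb$feature_dim
  with_seed(seeds[2], {
    cbam_mod <- make_cbam(store, "cbam", C, cbam_cfg)
    fus <- make_fusion(store, "fuse", C, C, C, fusion_mode)
    primary <- make_primary_capsules(store, "primary", fus$out_channels, caps_cfg)
    hd <- caps_cfg$pose_side
    J <- caps_cfg$capsules_per_layer
    Zs <- list()
    for (l in seq_len(caps_cfg$conv_capsule_layers)) {
      Zs[[l]] <- store_param(store, sprintf("caps.Z%d", l),
                             he_init(hd * hd, c(hd, hd, J, J)))
    }
    Zclass <- store_param(store, "caps.Zclass",
                          he_init(hd * hd, c(hd, hd, J, caps_cfg$class_capsules)))
    Wcls <- store_param(store, "head.W",
                        matrix(stats::rnorm(caps_cfg$class_capsule_size,
                                            0, 1 / sqrt(caps_cfg$class_capsule_size)),
                               1, caps_cfg$class_capsule_size))
    bcls <- store_param(store, "head.b", 0)
  })
  forward <- function(x, train = FALSE, collect = FALSE) {
    x <- as_ad(x)
    bb_out <- bb$forward(x, train = train)
    attended <- cbam_mod$forward(bb_out$map)
    fused <- fus$forward(bb_out$map, attended)
    poses <- primary(fused)
    routing_info <- list()
    for (l in seq_len(caps_cfg$conv_capsule_layers)) {
      r <- attention_routing(poses, Zs[[l]], caps_cfg$routing_iterations,
                             caps_cfg$softmax_over)
      poses <- r$parents
      if (collect) routing_info[[l]] <- r[c("coefficients", "agreements")]
    }
    rc <- attention_routing(poses, Zclass, caps_cfg$routing_iterations,
                            caps_cfg$softmax_over)
    N <- dim(ad_value(x))[4]
    class_poses <- ad_reshape(rc$parents,
                              c(caps_cfg$class_capsule_size,
                                caps_cfg$class_capsules * N))
    logits <- ad_reshape(ad_add_colvec(ad_matmul(Wcls, class_poses), bcls),
                         c(caps_cfg$class_capsules, N))
    out <- list(logits = logits, features = bb_out$features)
    if (collect) {
      out$routing <- routing_info
      out$class_routing <- rc[c("coefficients", "agreements")]
      out$class_poses <- ad_value(rc$parents)
    }
    out
  }
  structure(list(forward = forward, params = store$params, backbone = bb,
                 caps_config = caps_cfg, cbam_config = cbam_cfg,
                 fusion_mode = fusion_mode, seed = seed,
                 classes = c("benign", "malignant")),
            class = "capsnet_model")
}

#' Class capsules and logits from child poses (standalone)
#'
#' Routes `(hd, hd, J, N)` child poses into `class_capsules` class
#' capsules and applies a shared linear classifier (the same weight vector
#' for every class capsule) to the flattened poses.
#'
#' @param poses Child pose array.
#' @param config A [capsule_config()].
#' @param seed Weight seed.
#' @param zero_classifier Zero the shared classifier weights (logits then
#'   all equal the bias).
#' @return List with `logits` (`classes x N`), `class_poses`,
#'   `coefficients`.
#' @export
class_capsules_and_logits <- function(poses, config = capsule_config(),
                                      seed = 1L, zero_classifier = FALSE) {
  hd <- config$pose_side
  J <- dim(poses)[3]; N <- dim(poses)[4]
  ps <- with_seed(seed, list(
    Z = he_init(hd * hd, c(hd, hd, J, config$class_capsules)),
    W = matrix(stats::rnorm(config$class_capsule_size,
                            0, 1 / sqrt(config$class_capsule_size)),
               1, config$class_capsule_size),
    b = 0))
  if (zero_classifier) { ps$W[] <- 0 }
  r <- attention_routing(poses, ps$Z, config$routing_iterations,
                         config$softmax_over)
  class_poses <- ad_value(r$parents)
  flat <- matrix(class_poses, config$class_capsule_size,
                 config$class_capsules * N)
  logits <- matrix(ps$W %*% flat + ps$b, config$class_capsules, N)
  list(logits = logits, class_poses = class_poses,
       coefficients = r$coefficients)
}
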