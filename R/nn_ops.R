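# Neural-network layer operations on channels-first feature maps.
#
# Feature maps are numeric arrays with dim (C, H, W, N): channels first,
# batch last.  Convolutions are computed as a sum over kernel offsets of
# (Cout x Cin) matrix products against shifted input slices, which maps
# the whole layer onto BLAS-level matrix multiplies.

# pad (C,H,W,N) spatially with zeros
pad_spatial <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

conv_out_len <- function(len, k, stride, pad) (len + 2 * pad - k) %/% stride + 1L

# 2-D convolution: x (Cin,H,W,N), W (Cout,Cin,kh,kw), b (Cout) or NULL.
ad_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  x <- as_ad(x); W <- as_ad(W)
  xv <- x$value; Wv <- W$value
  dx <- dim(xv); dW <- dim(Wv)
  Cin <- dx[1]; H <- dx[2]; Wd <- dx[3]; N <- dx[4]
  Cout <- dW[1]; kh <- dW[3]; kw <- dW[4]
  stopifnot(dW[2] == Cin)
  Ho <- conv_out_len(H, kh, stride, pad)
  Wo <- conv_out_len(Wd, kw, stride, pad)
  xp <- pad_spatial(xv, pad)
  acc <- matrix(0, Cout, Ho * Wo * N)
  slices <- vector("list", kh * kw)
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    ri <- seq.int(ki, by = stride, length.out = Ho)
    ci <- seq.int(kj, by = stride, length.out = Wo)
    Xs <- xp[, ri, ci, , drop = FALSE]
    dim(Xs) <- c(Cin, Ho * Wo * N)
    slices[[(ki - 1L) * kw + kj]] <- Xs
    Wk <- Wv[, , ki, kj]
    dim(Wk) <- c(Cout, Cin)
    acc <- acc + Wk %*% Xs
  }
  out <- array(acc, c(Cout, Ho, Wo, N))
  parents <- list(x, W)
  if (!is.null(b)) {
    b <- as_ad(b)
    out <- out + array(rep(b$value, Ho * Wo * N), c(Cout, Ho, Wo, N))
    parents <- list(x, W, b)
  }
  new_ad(out, parents, function(g) {
    G <- matrix(g, Cout, Ho * Wo * N)
    dWv <- array(0, dW)
    dxp <- array(0, dim(xp))
    tG <- t(G)
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      s <- (ki - 1L) * kw + kj
      dWv[, , ki, kj] <- tcrossprod(G, slices[[s]])
      ri <- seq.int(ki, by = stride, length.out = Ho)
      ci <- seq.int(kj, by = stride, length.out = Wo)
      Wk <- Wv[, , ki, kj]
      dim(Wk) <- c(Cout, Cin)
      dxs <- crossprod(Wk, G)
      dim(dxs) <- c(Cin, Ho, Wo, N)
      dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + dxs
    }
    dxv <- if (pad > 0) {
      dxp[, pad + seq_len(H), pad + seq_len(Wd), , drop = FALSE]
    } else dxp
    dim(dxv) <- dx
    out <- list(dxv, dWv)
    if (length(parents) == 3L) out[[3]] <- rowSums(matrix(G, Cout))
    out
  })
}

# Batch normalization: each channel standardized over its (H, W, batch)
# extent during training, then scaled/shifted by per-channel gamma/beta.
# Inference uses the exponentially averaged running statistics held in
# `state`, so prediction is deterministic and batch-independent.  The
# channels-first layout makes every reduction a plain rowMeans and every
# broadcast a length-C vector recycled along the first dimension.
ad_batch_norm <- function(x, gamma, beta, state, train = FALSE,
                          momentum = 0.1, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$value)
  C <- d[1]; m <- prod(d[-1])
  xm <- x$value
  dim(xm) <- c(C, m)
  if (train) {
    mu <- rowMeans(xm)
    vr <- rowMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * vr
  } else {
    mu <- state$mean
    vr <- state$var
  }
  inv <- 1 / sqrt(vr + eps)
  xh <- (x$value - mu) * inv       # length-C vectors recycle along dim 1
  out <- xh * gamma$value + beta$value
  gv <- gamma$value
  new_ad(out, list(x, gamma, beta), function(g) {
    gmat <- g; dim(gmat) <- c(C, m)
    xhm <- xh; dim(xhm) <- c(C, m)
    dgamma <- rowSums(gmat * xhm)
    dbeta <- rowSums(gmat)
    if (train) {
      dxh_m1 <- dgamma / m          # rowMeans(dxh * xh) / gamma folded below
      gmean <- dbeta / m
      dx <- ((g - gmean) * gv - xh * (gv * dxh_m1)) * inv
    } else {
      dx <- g * gv * inv
    }
    list(dx, dgamma, dbeta)
  })
}

# Global spatial pooling: (C,H,W,N) -> (C,N).
ad_global_pool <- function(x, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- matrix(aperm(x$value, c(2, 3, 1, 4)), HW, C * N)
  if (mode == "mean") {
    out <- matrix(colMeans(xm), C, N)
    new_ad(out, list(x), function(g) {
      gm <- matrix(rep(as.numeric(g), each = HW) / HW, HW, C * N)
      list(aperm(array(gm, c(d[2], d[3], C, N)), c(3, 1, 2, 4)))
    })
  } else {
    amax <- max.col(t(xm), ties.method = "first")
    out <- matrix(xm[cbind(amax, seq_len(C * N))], C, N)
    new_ad(out, list(x), function(g) {
      gm <- matrix(0, HW, C * N)
      gm[cbind(amax, seq_len(C * N))] <- as.numeric(g)
      list(aperm(array(gm, c(d[2], d[3], C, N)), c(3, 1, 2, 4)))
    })
  }
}

# Channel pooling for spatial attention: (C,H,W,N) -> (2,H,W,N)
# (row 1 = channel mean, row 2 = channel max).
ad_channel_pool <- function(x) {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; M <- d[2] * d[3] * d[4]
  xm <- matrix(x$value, C, M)
  amax <- max.col(t(xm), ties.method = "first")
  out <- array(0, c(2, d[2], d[3], d[4]))
  out[1, , , ] <- colMeans(xm)
  out[2, , , ] <- xm[cbind(amax, seq_len(M))]
  new_ad(out, list(x), function(g) {
    gm <- matrix(g, 2, M)
    dx <- matrix(rep(gm[1, ], each = C) / C, C, M)
    dx[cbind(amax, seq_len(M))] <- dx[cbind(amax, seq_len(M))] + gm[2, ]
    dim(dx) <- d
    list(dx)
  })
}

# Broadcast multiplications for attention maps.
# s: (C,N) channel attention applied over all spatial sites.
ad_mul_channels <- function(x, s) {
  x <- as_ad(x); s <- as_ad(s)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  sb <- array(0, d)
  for (n in seq_len(N)) sb[, , , n] <- s$value[, n]
  out <- x$value * sb
  xv <- x$value
  new_ad(out, list(x, s), function(g) {
    ds_mat <- matrix(aperm(g * xv, c(1, 4, 2, 3)), C * N, H * Wd)
    list(g * sb, matrix(rowSums(ds_mat), C, N))
  })
}

# m: (1,H,W,N) spatial attention applied over all channels.
ad_mul_spatial <- function(x, m) {
  x <- as_ad(x); m <- as_ad(m)
  d <- dim(x$value)
  C <- d[1]
  mv <- array(m$value, c(d[2], d[3], d[4]))
  mb <- aperm(array(rep(mv, each = C), c(C, d[2], d[3], d[4])), c(1, 2, 3, 4))
  out <- x$value * mb
  xv <- x$value
  new_ad(out, list(x, m), function(g) {
    dm <- colSums(matrix(g * xv, C, d[2] * d[3] * d[4]))
    list(g * mb, array(dm, c(1, d[2], d[3], d[4])))
  })
}

ad_concat_channels <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a$value
  out[da[1] + seq_len(db[1]), , , ] <- b$value
  new_ad(out, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

# Max pooling with square window.
ad_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- as_ad(x)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  Ho <- conv_out_len(H, k, stride, pad)
  Wo <- conv_out_len(Wd, k, stride, pad)
  xp <- pad_spatial(x$value, pad)  # zero padding (inputs are post-ReLU)
  best <- array(-Inf, c(C, Ho, Wo, N))
  which_off <- array(0L, c(C, Ho, Wo, N))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    ri <- seq.int(ki, by = stride, length.out = Ho)
    ci <- seq.int(kj, by = stride, length.out = Wo)
    sl <- array(xp[, ri, ci, , drop = FALSE], c(C, Ho, Wo, N))
    upd <- sl > best
    best[upd] <- sl[upd]
    which_off[upd] <- (ki - 1L) * k + kj
  }
  new_ad(best, list(x), function(g) {
    dxp <- array(0, dim(xp))
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      off <- (ki - 1L) * k + kj
      mask <- which_off == off
      if (!any(mask)) next
      ri <- seq.int(ki, by = stride, length.out = Ho)
      ci <- seq.int(kj, by = stride, length.out = Wo)
      dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] +
        array(g * mask, c(C, Ho, Wo, N))
    }
    dxv <- if (pad > 0) dxp[, pad + seq_len(H), pad + seq_len(Wd), , drop = FALSE] else dxp
    dim(dxv) <- d
    list(dxv)
  })
}
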