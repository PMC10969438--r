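# Minimal reverse-mode automatic differentiation on numeric arrays.
#
# Every differentiable operation returns an `ad_tensor`: an environment
# holding the forward value, its parents, and a backward closure mapping
# the output gradient to the parents' gradients.  `ad_backward()` runs the
# reverse sweep over the topologically sorted tape.  The engine is
# deliberately small: only the operations the backbone, attention and
# capsule layers need are implemented, and each backward rule is verified
# end-to-end against numerical gradients in the test suite.

ad_env <- new.env(parent = emptyenv())
ad_env$counter <- 0L
ad_env$no_grad <- FALSE

new_ad <- function(value, parents = list(), backfn = NULL, requires = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  if (ad_env$no_grad) {
    e$parents <- list()
    e$backfn <- NULL
    e$requires <- FALSE
  } else {
    e$parents <- parents
    e$backfn <- backfn
    if (is.null(requires)) {
      requires <- any(vapply(parents, function(p) p$requires, logical(1)))
    }
    e$requires <- requires
  }
  e$grad <- NULL
  ad_env$counter <- ad_env$counter + 1L
  e$id <- ad_env$counter
  class(e) <- "ad_tensor"
  e
}

# evaluate expr without recording the tape (inference mode): intermediate
# values become garbage-collectable and no backward closures are kept
ad_no_grad <- function(expr) {
  old <- ad_env$no_grad
  ad_env$no_grad <- TRUE
  on.exit(ad_env$no_grad <- old)
  expr
}

#' Trainable tensor (leaf with gradient)
#' @param value Numeric array/matrix/vector.
#' @return An `ad_tensor` that accumulates gradients.
#' @keywords internal
ad_param <- function(value) new_ad(value, requires = TRUE)

as_ad <- function(x) if (inherits(x, "ad_tensor")) x else new_ad(x, requires = FALSE)

ad_value <- function(x) if (inherits(x, "ad_tensor")) x$value else x

# Topological order by DFS (iterative, to keep deep tapes safe).
ad_topo <- function(root) {
  order <- vector("list", 256L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L)); nstack <- 1L
  while (nstack > 0L) {
    fr <- stack[[nstack]]
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) { nstack <- nstack - 1L; next }
      seen[[key]] <- TRUE
      stack[[nstack]]$stage <- 2L
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          nstack <- nstack + 1L
          stack[[nstack]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
      nstack <- nstack - 1L
    }
  }
  order[seq_len(norder)]
}

accumulate_grad <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Reverse sweep: fill `$grad` on every tensor reachable from `root`
#' @param root Scalar-valued `ad_tensor` (typically the loss).
#' @keywords internal
ad_backward <- function(root) {
  order <- ad_topo(root)
  if (length(root$value) != 1L) stop("backward expects a scalar root")
  root$grad <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  for (k in rev(seq_along(order))) {
    node <- order[[k]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(node$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

keep_dim <- function(template, x) {
  dim(x) <- dim(template)
  x
}

# --- elementwise and shape ops ---------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  new_ad(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  new_ad(a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  mask <- a$value > 0
  new_ad(a$value * mask, list(a), function(g) list(g * mask))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  s <- 1 / (1 + exp(-a$value))
  new_ad(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_reshape <- function(a, dims) {
  a <- as_ad(a)
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  new_ad(v, list(a), function(g) { dim(g) <- old; list(g) })
}

ad_aperm <- function(a, perm) {
  a <- as_ad(a)
  inv <- order(perm)
  new_ad(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  new_ad(av %*% bv, list(a, b),
         function(g) list(g %*% t(bv), t(av) %*% g))
}

# column-vector bias broadcast over the columns of a (d x N) matrix
ad_add_colvec <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad(a$value + b$value, list(a, b),
         function(g) list(g, rowSums(g)))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  dims <- dim(a$value)
  new_ad(sum(a$value), list(a),
         function(g) list(keep_dim(a$value, array(as.numeric(g), dim = c(length(a$value))))))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

ad_concat_rows <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- nrow(a$value)
  new_ad(rbind(a$value, b$value), list(a, b),
         function(g) list(g[seq_len(na), , drop = FALSE],
                          g[-seq_len(na), , drop = FALSE]))
}

# --- column-wise softmax / normalization ------------------------------------

# softmax over the rows of each column of a (d x M) matrix
ad_softmax_cols <- function(a) {
  a <- as_ad(a)
  v <- a$value
  m <- v[cbind(max.col(t(v), ties.method = "first"), seq_len(ncol(v)))]
  e <- exp(sweep(v, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  new_ad(p, list(a), function(g) {
    list(p * sweep(g, 2, colSums(p * g)))
  })
}

# per-column standardization (layer normalization without affine terms)
ad_layernorm_cols <- function(a, eps = 1e-5) {
  a <- as_ad(a)
  v <- a$value
  d <- nrow(v)
  mu <- colMeans(v)
  xc <- sweep(v, 2, mu)
  vr <- colMeans(xc^2)
  inv <- 1 / sqrt(vr + eps)
  xh <- sweep(xc, 2, inv, "*")
  new_ad(xh, list(a), function(g) {
    gm <- colMeans(g)
    gx <- colMeans(g * xh)
    list(sweep(sweep(g, 2, gm) - sweep(xh, 2, gx, "*"), 2, inv, "*"))
  })
}

# cross-entropy of softmax(logits) against integer labels; mean over batch
ad_softmax_xent <- function(logits, labels) {
  logits <- as_ad(logits)
  v <- logits$value
  N <- ncol(v)
  m <- apply(v, 2, max)
  e <- exp(sweep(v, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  new_ad(loss, list(logits), function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    list(d * (as.numeric(g) / N))
  })
}
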