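# Differentiable operations used to assemble the segmentation networks.
# Values are plain R arrays: feature maps are (H, W, C) arrays, prototypes
# are channel vectors, attention intermediates are (positions x channels)
# matrices. Each op returns a tape node.

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# 3x3 same-padding convolution; kernel k is (9*Cin) x Cout, bias length
# Cout. The im2col matrix is kept from the forward pass for reuse in the
# backward pass; the input gradient is skipped when the input is a
# constant leaf (e.g. the image patch itself).
ad_conv3 <- function(x, k, b) {
  r <- conv3_fwd_cols(x$v, k$v, b$v)
  need_gx <- !(is.null(x$bk) && is.null(x$is_param) && !length(x$parents))
  tp_node(r$y, list(x, k, b), function(g) {
    bw <- conv3_bwd(r$cols, k$v, g, need_gx)
    list(bw$gx, bw$gk, as.numeric(bw$gb))
  })
}

# 1x1 convolution: k is Cin x Cout.
ad_conv1 <- function(x, k, b) {
  d <- dim(x$v)
  xm <- matrix(x$v, d[1] * d[2], d[3])
  y <- xm %*% k$v
  y <- sweep(y, 2, b$v, "+")
  dim(y) <- c(d[1], d[2], ncol(k$v))
  tp_node(y, list(x, k, b), function(g) {
    gm <- matrix(g, d[1] * d[2], ncol(k$v))
    gx <- gm %*% t(k$v)
    dim(gx) <- d
    list(gx, crossprod(xm, gm), colSums(gm))
  })
}

ad_relu <- function(x) {
  pos <- x$v > 0
  tp_node(x$v * pos, list(x), function(g) list(g * pos))
}

ad_maxpool2 <- function(x) {
  r <- maxpool2_fwd(x$v)
  d <- dim(x$v)
  tp_node(r$y, list(x), function(g) list(maxpool2_bwd(g, r$idx, d[1], d[2])))
}

ad_avgpool <- function(x, s) {
  d <- dim(x$v)
  tp_node(avgpool_fwd(x$v, s), list(x),
          function(g) list(avgpool_bwd(g, s, d[1], d[2])))
}

ad_bilinear <- function(x, h_out, w_out) {
  d <- dim(x$v)
  tp_node(bilinear_fwd(x$v, h_out, w_out), list(x),
          function(g) list(bilinear_bwd(g, d[1], d[2])))
}

# Channel concatenation of (H, W, C_i) nodes.
ad_concat <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cc <- vapply(dims, function(d) d[3], 0L)
  y <- array(0, c(dims[[1]][1], dims[[1]][2], sum(cc)))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, , at + seq_len(cc[i])] <- xs[[i]]$v
    at <- at + cc[i]
  }
  tp_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , at + seq_len(cc[i]), drop = FALSE]
      at <- at + cc[i]
    }
    out
  })
}

ad_add <- function(a, b) {
  tp_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

ad_scale <- function(x, s) {
  tp_node(x$v * s, list(x), function(g) list(g * s))
}

# Mask average pooling: prototype[c] = sum_{h,w} feat[h,w,c] * mask[h,w]
# normalised by the FULL spatial area H*W (not the mask sum). `mask` is a
# constant 0/1 matrix already resized to the feature-map grid.
ad_mask_avg_pool <- function(x, mask) {
  d <- dim(x$v)
  if (!identical(dim(mask), d[1:2])) stop("mask/feature shape mismatch")
  area <- d[1] * d[2]
  xm <- matrix(x$v, area, d[3])
  p <- as.numeric(crossprod(xm, as.numeric(mask))) / area
  tp_node(p, list(x), function(g) {
    gx <- outer(as.numeric(mask), g) / area
    dim(gx) <- d
    list(gx)
  })
}

# Element-wise mean of a list of equally shaped nodes (multi-shot merge).
ad_mean_nodes <- function(xs) {
  k <- length(xs)
  v <- xs[[1]]$v
  if (k > 1) for (i in 2:k) v <- v + xs[[i]]$v
  tp_node(v / k, xs, function(g) rep(list(g / k), k))
}

# Inner product of a prototype with every spatial position of a query
# feature map (the prototype tiled and applied as a 1x1 kernel).
ad_proto_dot <- function(x, p) {
  d <- dim(x$v)
  if (length(p$v) != d[3]) stop("prototype/feature channel mismatch")
  xm <- matrix(x$v, d[1] * d[2], d[3])
  y <- xm %*% p$v
  dim(y) <- c(d[1], d[2], 1L)
  tp_node(y, list(x, p), function(g) {
    gm <- as.numeric(g)
    gx <- outer(gm, p$v)
    dim(gx) <- d
    list(gx, as.numeric(crossprod(xm, gm)))
  })
}

ad_reshape_mat <- function(x) {
  d <- dim(x$v)
  tp_node(matrix(x$v, d[1] * d[2], d[3]), list(x), function(g) {
    dim(g) <- d
    list(g)
  })
}

ad_reshape_cube <- function(m, h, w) {
  cc <- ncol(m$v)
  tp_node(array(m$v, c(h, w, cc)), list(m), function(g) {
    dim(g) <- c(h * w, cc)
    list(g)
  })
}

ad_matmul <- function(a, b, transb = FALSE) {
  v <- if (transb) tcrossprod(a$v, b$v) else a$v %*% b$v
  tp_node(v, list(a, b), function(g) {
    if (transb) list(g %*% b$v, crossprod(g, a$v))
    else list(tcrossprod(g, b$v), crossprod(a$v, g))
  })
}

ad_softmax_rows <- function(a) {
  m <- a$v - apply(a$v, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  tp_node(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Numerically stable pixel-mean binary cross-entropy from logits:
# per pixel max(x,0) - x*y + log1p(exp(-|x|)); gradient (sigmoid(x) - y)/n.
ad_bce_logits <- function(logits, y) {
  x <- logits$v
  n <- length(x)
  val <- sum(pmax(x, 0) - x * y + log1p(exp(-abs(x)))) / n
  tp_node(val, list(logits), function(g) {
    gx <- g * (1 / (1 + exp(-x)) - y) / n
    list(gx)
  })
}

ad_mean_scalars <- function(xs) {
  k <- length(xs)
  tp_node(mean(vapply(xs, function(x) x$v, 0)), xs,
          function(g) rep(list(g / k), k))
}
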