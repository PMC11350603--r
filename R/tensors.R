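# Minimal dense-tensor layer primitives used by the counting network.
#
# Feature maps are plain 3-D arrays dim = c(H, W, C).  Convolutions are
# computed by im2col gather + one BLAS matrix product; the backward pass
# is the exact adjoint (rowsum scatter).  Everything is stride 1.
#
# A convolution weight is a matrix (C_out x k*k*C_in) whose columns are
# ordered tap-fastest, then input channel; bias is length C_out.

conv_geom_cache <- new.env(parent = emptyenv())

# Geometry (gather indices) for a stride-1 convolution.
# pad = "same" (odd k) or "valid".
conv_geom <- function(h, w, k, dilation = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  key <- paste(h, w, k, dilation, pad, sep = "_")
  g <- conv_geom_cache[[key]]
  if (!is.null(g)) return(g)
  eff <- (k - 1L) * dilation + 1L
  p <- if (pad == "same") {
    if (eff %% 2L == 0L) stop_cfg("'same' padding needs odd effective kernel")
    (eff - 1L) %/% 2L
  } else 0L
  hp <- h + 2L * p; wp <- w + 2L * p
  ho <- hp - eff + 1L; wo <- wp - eff + 1L
  if (ho < 1L || wo < 1L)
    stop_cfg("kernel (effective ", eff, ") exceeds input ", h, "x", w)
  # linear index (1-based, column-major in padded grid) of each output
  # pixel's top-left tap
  base <- as.vector(outer(seq_len(ho), (seq_len(wo) - 1L) * hp, "+"))
  off <- as.vector(outer((seq_len(k) - 1L) * dilation,
                         (seq_len(k) - 1L) * dilation * hp, "+"))
  idx <- outer(off, base, "+")                      # k^2 x (ho*wo)
  inner <- as.vector(outer(p + seq_len(h), (p + seq_len(w) - 1L) * hp, "+"))
  g <- list(h = h, w = w, k = k, k2 = k * k, p = p, hp = hp, wp = wp,
            ho = ho, wo = wo, np = ho * wo, idx = as.vector(idx),
            inner = inner)
  conv_geom_cache[[key]] <- g
  g
}

# x: array (H, W, C) -> list(y = array (Ho, Wo, Cout), cache)
conv_fwd <- function(x, W, b, k, dilation = 1L, pad = "same") {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  g <- conv_geom(h, w, k, dilation, pad)
  xm <- x; dim(xm) <- c(h * w, cin)
  if (g$p > 0L || g$k > 1L) {
    P <- matrix(0, g$hp * g$wp, cin)
    P[g$inner, ] <- xm
    A <- P[g$idx, , drop = FALSE]                   # (k2*np) x cin
    dim(A) <- c(g$k2, g$np, cin)
    A <- aperm(A, c(1, 3, 2))
    dim(A) <- c(g$k2 * cin, g$np)
  } else {
    A <- t(xm)                                      # 1x1 conv fast path
  }
  Y <- W %*% A + b                                  # (cout, np)
  y <- t(Y)
  dim(y) <- c(g$ho, g$wo, nrow(W))
  list(y = y, cache = list(A = A, g = g, W = W, cin = cin))
}

# dy: array (Ho, Wo, Cout) -> list(dx, dW, db)
conv_bwd <- function(cache, dy) {
  g <- cache$g; cin <- cache$cin
  cout <- dim(dy)[3]
  dY <- dy; dim(dY) <- c(g$np, cout); dY <- t(dY)
  dW <- dY %*% t(cache$A)
  db <- rowSums(dY)
  dA <- crossprod(cache$W, dY)                      # (k2*cin) x np
  if (g$p > 0L || g$k > 1L) {
    dim(dA) <- c(g$k2, cin, g$np)
    dA <- aperm(dA, c(1, 3, 2))
    dim(dA) <- c(g$k2 * g$np, cin)
    agg <- rowsum(dA, group = g$idx)
    dP <- matrix(0, g$hp * g$wp, cin)
    dP[as.integer(rownames(agg)), ] <- agg
    dxm <- dP[g$inner, , drop = FALSE]
  } else {
    dxm <- t(dA)
  }
  dx <- dxm; dim(dx) <- c(g$h, g$w, cin)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling, stride 2; even dims required.
maxpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop_cfg("max pooling needs even dimensions")
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  a <- x[ri, ci, , drop = FALSE];      b <- x[ri + 1L, ci, , drop = FALSE]
  cc <- x[ri, ci + 1L, , drop = FALSE]; dd <- x[ri + 1L, ci + 1L, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  which4 <- ifelse(a == y, 1L, ifelse(b == y, 2L, ifelse(cc == y, 3L, 4L)))
  list(y = y, cache = list(which4 = which4, dims = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$dims; w4 <- cache$which4
  dx <- array(0, d)
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  put <- function(sel, dr, dc) {
    sub <- dx[ri + dr, ci + dc, , drop = FALSE]
    sub[sel] <- dy[sel]
    dx[ri + dr, ci + dc, ] <<- sub
  }
  put(w4 == 1L, 0L, 0L); put(w4 == 2L, 1L, 0L)
  put(w4 == 3L, 0L, 1L); put(w4 == 4L, 1L, 1L)
  dx
}

# 2x2 average pooling, stride 2 (used for the structural-loss pyramid).
avgpool2 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_cfg("avgpool2 expects a matrix or array")
  if (d[1] %% 2L || d[2] %% 2L) stop_cfg("average pooling needs even dimensions")
  ri <- seq(1L, d[1], 2L); ci <- seq(1L, d[2], 2L)
  if (length(d) == 2L)
    (x[ri, ci] + x[ri + 1L, ci] + x[ri, ci + 1L] + x[ri + 1L, ci + 1L]) / 4
  else
    (x[ri, ci, , drop = FALSE] + x[ri + 1L, ci, , drop = FALSE] +
       x[ri, ci + 1L, , drop = FALSE] + x[ri + 1L, ci + 1L, , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, dims) {
  dy[ceiling(seq_len(dims[1]) / 2), ceiling(seq_len(dims[2]) / 2)] / 4
}

# Global average pooling: (H, W, C) -> length-C vector.
gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  list(y = colMeans(xm), cache = d)
}
gap_bwd <- function(dims, dv) {
  n <- dims[1] * dims[2]
  array(rep(dv / n, each = n), dims)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Jacobian-vector product of softmax: given probs p and dL/dp, return dL/dz.
softmax_bwd <- function(p, dp) p * (dp - sum(dp * p))

# He-scaled Gaussian initialization for a conv weight matrix.
init_conv <- function(cout, cin, k) {
  fan_in <- cin * k * k
  list(W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                  cout, fan_in),
       b = rep(0.01, cout))
}
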