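# The counting network: a VGG19-style multiscale extractor whose last
# three stages all sit at 1/8 resolution (pooling retained through stage
# 3, stages 4-5 dilated instead of pooled), multiscale channel-attention
# feature fusion, and regression / classification heads built on parallel
# dilated convolutions. Forward and backward passes are written
# explicitly on the primitives in tensors.R; there is no autograd.

#' Network architecture configuration
#'
#' The `"full"` profile mirrors the VGG19 convolutional layout
#' (stage depths 2,2,4,4,4; channels 64,128,256,512,512) so the last
#' three stages emit H/8 x W/8 maps with 256, 512 and 512 channels. The
#' `"reduced"` profile keeps the identical topology with thin channels
#' and shallow stages so the whole pipeline trains on CPU at desk scale.
#'
#' @param profile `"reduced"` or `"full"`.
#' @param n_classes number of density classes for the classification head.
#' @param mscam_reduction channel reduction factor inside the attention
#'   bottleneck.
#' @param mdc_dilations dilation rates of the parallel columns; (1, 2, 3)
#'   is the smallest set whose union of taps covers a contiguous window
#'   with no gridding holes.
#' @return a `mtsc_config` list.
#' @export
mtsc_config <- function(profile = c("reduced", "full"), n_classes = 5L,
                        mscam_reduction = 4L, mdc_dilations = c(1L, 2L, 3L)) {
  profile <- match.arg(profile)
  ch <- if (profile == "full") c(64L, 128L, 256L, 512L, 512L)
  else c(4L, 8L, 16L, 32L, 32L)
  nc <- if (profile == "full") c(2L, 2L, 4L, 4L, 4L) else c(1L, 1L, 2L, 2L, 2L)
  structure(list(profile = profile,
                 stage_channels = ch,
                 stage_convs = nc,
                 stage_dilations = c(1L, 1L, 1L, 2L, 2L),
                 mscam_reduction = as.integer(mscam_reduction),
                 mdc_dilations = as.integer(mdc_dilations),
                 n_classes = as.integer(n_classes)),
            class = "mtsc_config")
}

init_mscam <- function(channels, reduction) {
  cm <- max(1L, channels %/% reduction)
  list(l1 = init_conv(cm, channels, 1L), l2 = init_conv(channels, cm, 1L),
       g1 = init_conv(cm, channels, 1L), g2 = init_conv(channels, cm, 1L))
}

#' Initialize network parameters
#'
#' He-scaled Gaussian initialization under a fixed seed; biases start at
#' a small positive value so rectified units are active from the first
#' step.
#'
#' @param cfg a [mtsc_config()].
#' @param seed integer seed.
#' @return a named flat list of `list(W, b)` parameter blocks (attention
#'   blocks are nested lists of those).
#' @export
init_mtsc_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    p <- list()
    cin <- 3L
    for (s in 1:5) {
      for (i in seq_len(cfg$stage_convs[s])) {
        p[[sprintf("s%dc%d", s, i)]] <- init_conv(cfg$stage_channels[s], cin, 3L)
        cin <- cfg$stage_channels[s]
      }
    }
    c3 <- cfg$stage_channels[3]; c5 <- cfg$stage_channels[5]
    p$aff1 <- init_mscam(c5, cfg$mscam_reduction)
    p$proj45 <- init_conv(c3, c5, 1L)
    p$aff2 <- init_mscam(c3, cfg$mscam_reduction)
    mid <- max(1L, c3 %/% 4L)
    for (j in 1:3) p[[paste0("mdc.c", j)]] <- init_conv(mid, c3, 3L)
    p$mdc.proj <- init_conv(c3, 3L * mid, 1L)
    hm <- max(1L, c3 %/% 2L)
    p$reg1 <- init_conv(hm, c3, 3L)
    p$reg2 <- init_conv(1L, hm, 1L)
    p$cls1 <- init_conv(hm, c3, 1L)
    p$cls2 <- init_conv(cfg$n_classes, hm, 1L)
    p
  })
}

# ---- backbone -------------------------------------------------------------

backbone_fwd <- function(params, image, cfg) {
  d <- dim(image)
  check_div8(d[1], d[2])
  x <- image
  caches <- list()
  feats <- list()
  for (s in 1:5) {
    dil <- cfg$stage_dilations[s]
    for (i in seq_len(cfg$stage_convs[s])) {
      nm <- sprintf("s%dc%d", s, i)
      cv <- conv_fwd(x, params[[nm]]$W, params[[nm]]$b, 3L, dil)
      rl <- relu_fwd(cv$y)
      caches[[nm]] <- list(conv = cv$cache, relu = rl$cache)
      x <- rl$y
    }
    if (s <= 3) {
      mp <- maxpool2_fwd(x)
      caches[[paste0("pool", s)]] <- mp$cache
      x <- mp$y
    }
    if (s >= 3) feats[[paste0("f", s)]] <- x
  }
  list(f3 = feats$f3, f4 = feats$f4, f5 = feats$f5, caches = caches)
}

backbone_bwd <- function(params, caches, df3, df4, df5, cfg, grads) {
  stage_bwd <- function(s, dx, grads) {
    for (i in rev(seq_len(cfg$stage_convs[s]))) {
      nm <- sprintf("s%dc%d", s, i)
      dx <- relu_bwd(caches[[nm]]$relu, dx)
      bw <- conv_bwd(caches[[nm]]$conv, dx)
      grads[[nm]]$W <- grads[[nm]]$W + bw$dW
      grads[[nm]]$b <- grads[[nm]]$b + bw$db
      dx <- bw$dx
    }
    list(dx = dx, grads = grads)
  }
  r5 <- stage_bwd(5, df5, grads)
  r4 <- stage_bwd(4, df4 + r5$dx, r5$grads)
  dx <- maxpool2_bwd(caches$pool3, df3 + r4$dx)
  r3 <- stage_bwd(3, dx, r4$grads)
  dx <- maxpool2_bwd(caches$pool2, r3$dx)
  r2 <- stage_bwd(2, dx, r3$grads)
  dx <- maxpool2_bwd(caches$pool1, r2$dx)
  r1 <- stage_bwd(1, dx, r2$grads)
  r1$grads
}

#' Multiscale feature extraction
#'
#' Runs the dilated VGG-style backbone and returns the three 1/8
#' resolution feature maps (channels 256/512/512 in the full profile).
#'
#' @param params parameters from [init_mtsc_params()].
#' @param image (H, W, 3) array; H and W must be divisible by 8.
#' @param cfg a [mtsc_config()].
#' @return `list(f3, f4, f5)` of (H/8, W/8, C) arrays.
#' @export
backbone_forward <- function(params, image, cfg) {
  out <- backbone_fwd(params, image, cfg)
  out[c("f3", "f4", "f5")]
}

# ---- multiscale channel attention ----------------------------------------

mscam_gate_fwd <- function(x, pl) {
  cin <- dim(x)[3]
  if (ncol(pl$l1$W) != cin)
    stop_cfg("attention weights expect ", ncol(pl$l1$W), " channels, got ", cin)
  c1 <- conv_fwd(x, pl$l1$W, pl$l1$b, 1L)
  r1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(r1$y, pl$l2$W, pl$l2$b, 1L)       # local branch L(F)
  gp <- gap_fwd(x)
  gz1 <- drop(pl$g1$W %*% gp$y) + pl$g1$b
  gr1 <- pmax(gz1, 0)
  gz2 <- drop(pl$g2$W %*% gr1) + pl$g2$b           # global branch G(F)
  s <- sweep(c2$y, 3L, gz2, "+")
  gate <- sigmoid(s)
  list(gate = gate,
       cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    gdims = gp$cache, g = gp$y, gz1 = gz1, gr1 = gr1,
                    gate = gate, pl = pl))
}

mscam_gate_bwd <- function(cache, dgate) {
  pl <- cache$pl
  ds <- dgate * cache$gate * (1 - cache$gate)
  # local branch
  b2 <- conv_bwd(cache$c2, ds)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- conv_bwd(cache$c1, dr1)
  # global branch
  dgz2 <- apply(ds, 3L, sum)
  dW_g2 <- outer(dgz2, cache$gr1); db_g2 <- dgz2
  dgr1 <- drop(crossprod(pl$g2$W, dgz2))
  dgz1 <- dgr1 * (cache$gz1 > 0)
  dW_g1 <- outer(dgz1, cache$g); db_g1 <- dgz1
  dg <- drop(crossprod(pl$g1$W, dgz1))
  dx <- b1$dx + gap_bwd(cache$gdims, dg)
  list(dx = dx,
       grads = list(l1 = list(W = b1$dW, b = b1$db),
                    l2 = list(W = b2$dW, b = b2$db),
                    g1 = list(W = dW_g1, b = db_g1),
                    g2 = list(W = dW_g2, b = db_g2)))
}

#' Multiscale channel attention (MS-CAM)
#'
#' Refines a feature map by an elementwise sigmoid gate combining a local
#' pointwise-convolution branch with a global average-pooling branch:
#' `F_m = F * sigmoid(L(F) + G(F))`, where both branches are
#' pointwise-conv -> ReLU -> pointwise-conv stacks.
#'
#' @param x (H, W, C) feature array.
#' @param weights attention block (`l1`, `l2`, `g1`, `g2` conv params),
#'   e.g. `init_mtsc_params(cfg)$aff1`.
#' @return the gated feature array, same shape as `x`.
#' @export
ms_cam <- function(x, weights) {
  g <- mscam_gate_fwd(x, weights)
  x * g$gate
}

#' Attentional feature fusion (AFF)
#'
#' Blends a low-level map `low` with a high-level map `high` through a
#' learned gate `M = sigmoid(L(low + high) + G(low + high))`:
#' `W = M * low + (1 - M) * high`. Both inputs must share shape.
#'
#' @param low,high (H, W, C) feature arrays of identical shape.
#' @param weights attention block as in [ms_cam()].
#' @return the fused feature array.
#' @export
aff_fuse <- function(low, high, weights) {
  aff_fwd(low, high, weights)$y
}

aff_fwd <- function(low, high, pl) {
  if (!all(dim(low) == dim(high)))
    stop_cfg("fusion inputs must share shape: ",
             paste(dim(low), collapse = "x"), " vs ",
             paste(dim(high), collapse = "x"))
  g <- mscam_gate_fwd(low + high, pl)
  y <- g$gate * low + (1 - g$gate) * high
  list(y = y, cache = list(gate_cache = g$cache, gate = g$gate,
                           low = low, high = high))
}

aff_bwd <- function(cache, dy) {
  gate <- cache$gate
  dgate <- dy * (cache$low - cache$high)
  gb <- mscam_gate_bwd(cache$gate_cache, dgate)
  list(dlow = dy * gate + gb$dx,
       dhigh = dy * (1 - gate) + gb$dx,
       grads = gb$grads)
}

# ---- multiscale dilated convolution block ---------------------------------

mdc_fwd <- function(x, params, cfg) {
  d <- dim(x)
  cols <- list(); caches <- list()
  mid <- nrow(params$mdc.c1$W)
  cat_arr <- array(0, c(d[1], d[2], 3L * mid))
  for (j in 1:3) {
    pj <- params[[paste0("mdc.c", j)]]
    cv <- conv_fwd(x, pj$W, pj$b, 3L, cfg$mdc_dilations[j])
    rl <- relu_fwd(cv$y)
    caches[[j]] <- list(conv = cv$cache, relu = rl$cache)
    cat_arr[, , ((j - 1L) * mid + 1L):(j * mid)] <- rl$y
  }
  pr <- conv_fwd(cat_arr, params$mdc.proj$W, params$mdc.proj$b, 1L)
  y <- x + pr$y                                      # shortcut path
  list(y = y, cache = list(cols = caches, proj = pr$cache, mid = mid))
}

mdc_bwd <- function(cache, dy, cfg) {
  pb <- conv_bwd(cache$proj, dy)
  dx <- dy                                           # shortcut gradient
  grads <- list(mdc.proj = list(W = pb$dW, b = pb$db))
  mid <- cache$mid
  for (j in 1:3) {
    dcol <- pb$dx[, , ((j - 1L) * mid + 1L):(j * mid), drop = FALSE]
    dcol <- relu_bwd(cache$cols[[j]]$relu, dcol)
    cb <- conv_bwd(cache$cols[[j]]$conv, dcol)
    grads[[paste0("mdc.c", j)]] <- list(W = cb$dW, b = cb$db)
    dx <- dx + cb$dx
  }
  list(dx = dx, grads = grads)
}

#' Multiscale dilated convolution block
#'
#' Three parallel 3x3 dilated-convolution columns (dilations 1, 2, 3 by
#' default) are concatenated, projected back by a pointwise convolution,
#' and added to an identity shortcut, enlarging the receptive field at
#' constant resolution without gridding holes.
#'
#' @param x (H, W, C) feature array.
#' @param params full parameter list (uses `mdc.c1..3` and `mdc.proj`).
#' @param cfg a [mtsc_config()].
#' @return feature array with the same shape as `x`.
#' @export
mdc_block <- function(x, params, cfg = mtsc_config()) {
  mdc_fwd(x, params, cfg)$y
}

# ---- full model -----------------------------------------------------------

#' Full network forward pass
#'
#' Fuses the two deepest feature maps, projects to the stage-3 width,
#' fuses with the stage-3 map, refines with the dilated block, and emits
#' a nonnegative density map at 1/8 resolution plus a density-class
#' probability distribution.
#'
#' @param params parameters from [init_mtsc_params()].
#' @param image (H, W, 3) array, dims divisible by 8.
#' @param cfg a [mtsc_config()].
#' @param with_cache keep intermediate activations for [model_backward()].
#' @return list with `density` (a [density_map()] at scale 8),
#'   `class_logits`, `class_probs`, and (optionally) `cache`.
#' @export
model_forward <- function(params, image, cfg, with_cache = FALSE) {
  bb <- backbone_fwd(params, image, cfg)
  a1 <- aff_fwd(bb$f4, bb$f5, params$aff1)
  pj <- conv_fwd(a1$y, params$proj45$W, params$proj45$b, 1L)
  a2 <- aff_fwd(bb$f3, pj$y, params$aff2)
  md <- mdc_fwd(a2$y, params, cfg)
  r1 <- conv_fwd(md$y, params$reg1$W, params$reg1$b, 3L)
  rr1 <- relu_fwd(r1$y)
  r2 <- conv_fwd(rr1$y, params$reg2$W, params$reg2$b, 1L)
  rr2 <- relu_fwd(r2$y)
  dens <- rr2$y[, , 1]
  c1 <- conv_fwd(md$y, params$cls1$W, params$cls1$b, 1L)
  cr1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(cr1$y, params$cls2$W, params$cls2$b, 1L)
  gp <- gap_fwd(c2$y)
  logits <- gp$y
  out <- list(density = density_map(dens, 8L),
              class_logits = logits,
              class_probs = softmax(logits))
  if (with_cache)
    out$cache <- list(bb = bb, a1 = a1, pj = pj$cache, a2 = a2, md = md,
                      r1 = r1$cache, rr1 = rr1$cache, r2 = r2$cache,
                      rr2 = rr2$cache, c1 = c1$cache, cr1 = cr1$cache,
                      c2 = c2$cache, gdims = gp$cache)
  out
}

zero_like_params <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

#' Full network backward pass
#'
#' Accumulates parameter gradients given upstream gradients of the loss
#' with respect to the predicted density map and the class logits.
#'
#' @param params parameter list.
#' @param cache `cache` element from `model_forward(..., with_cache = TRUE)`.
#' @param d_density matrix gradient w.r.t. the density output (H/8 x W/8);
#'   `NULL` for zero.
#' @param d_logits vector gradient w.r.t. the class logits; `NULL` for zero.
#' @param cfg a [mtsc_config()].
#' @return named gradient list mirroring `params`.
#' @export
model_backward <- function(params, cache, d_density = NULL, d_logits = NULL,
                           cfg = mtsc_config()) {
  grads <- zero_like_params(params)
  hw <- dim(cache$rr2)[1:2]
  dmd <- 0
  if (!is.null(d_density)) {
    dd <- array(d_density, c(hw, 1L))
    dd <- relu_bwd(cache$rr2, dd)
    b2 <- conv_bwd(cache$r2, dd)
    grads$reg2$W <- grads$reg2$W + b2$dW; grads$reg2$b <- grads$reg2$b + b2$db
    dr1 <- relu_bwd(cache$rr1, b2$dx)
    b1 <- conv_bwd(cache$r1, dr1)
    grads$reg1$W <- grads$reg1$W + b1$dW; grads$reg1$b <- grads$reg1$b + b1$db
    dmd <- dmd + b1$dx
  }
  if (!is.null(d_logits)) {
    dc2 <- gap_bwd(cache$gdims, d_logits)
    b2 <- conv_bwd(cache$c2, dc2)
    grads$cls2$W <- grads$cls2$W + b2$dW; grads$cls2$b <- grads$cls2$b + b2$db
    dc1 <- relu_bwd(cache$cr1, b2$dx)
    b1 <- conv_bwd(cache$c1, dc1)
    grads$cls1$W <- grads$cls1$W + b1$dW; grads$cls1$b <- grads$cls1$b + b1$db
    dmd <- dmd + b1$dx
  }
  if (is.null(d_density) && is.null(d_logits)) return(grads)
  mb <- mdc_bwd(cache$md$cache, dmd, cfg)
  for (nm in names(mb$grads)) {
    grads[[nm]]$W <- grads[[nm]]$W + mb$grads[[nm]]$W
    grads[[nm]]$b <- grads[[nm]]$b + mb$grads[[nm]]$b
  }
  ab2 <- aff_bwd(cache$a2$cache, mb$dx)
  for (nm in names(ab2$grads)) {
    grads$aff2[[nm]]$W <- grads$aff2[[nm]]$W + ab2$grads[[nm]]$W
    grads$aff2[[nm]]$b <- grads$aff2[[nm]]$b + ab2$grads[[nm]]$b
  }
  pb <- conv_bwd(cache$pj, ab2$dhigh)
  grads$proj45$W <- grads$proj45$W + pb$dW
  grads$proj45$b <- grads$proj45$b + pb$db
  ab1 <- aff_bwd(cache$a1$cache, pb$dx)
  for (nm in names(ab1$grads)) {
    grads$aff1[[nm]]$W <- grads$aff1[[nm]]$W + ab1$grads[[nm]]$W
    grads$aff1[[nm]]$b <- grads$aff1[[nm]]$b + ab1$grads[[nm]]$b
  }
  backbone_bwd(params, cache$bb$caches, df3 = ab2$dlow, df4 = ab1$dlow,
               df5 = ab1$dhigh, cfg = cfg, grads = grads)
}
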