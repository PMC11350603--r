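test_that("backbone emits three 1/8-resolution maps with the configured channels", {
  tm <- tiny_model()
  f <- backbone_forward(tm$params, random_image(64, 64), tm$cfg)
  expect_equal(dim(f$f3), c(8, 8, tm$cfg$stage_channels[3]))
  expect_equal(dim(f$f4), c(8, 8, tm$cfg$stage_channels[4]))
  expect_equal(dim(f$f5), c(8, 8, tm$cfg$stage_channels[5]))
  # full profile: channel widths 256/512/512 at 1/8 resolution
  cfg_full <- mtsc_config("full")
  pf <- init_mtsc_params(cfg_full, seed = 2)
  ff <- backbone_forward(pf, random_image(32, 32), cfg_full)
  expect_equal(dim(ff$f3), c(4, 4, 256))
  expect_equal(dim(ff$f4), c(4, 4, 512))
  expect_equal(dim(ff$f5), c(4, 4, 512))
})

test_that("inputs not divisible by 8 are rejected", {
  tm <- tiny_model()
  expect_error(backbone_forward(tm$params, array(0, c(100, 100, 3)), tm$cfg),
               "divisible by 8")
})

test_that("zero attention weights gate at exactly one half", {
  tm <- tiny_model()
  w <- rapply(tm$params$aff1, function(x) x * 0, how = "replace")
  x <- array(rnorm(4 * 4 * tm$cfg$stage_channels[5]),
             c(4, 4, tm$cfg$stage_channels[5]))
  expect_equal(ms_cam(x, w), 0.5 * x, tolerance = 1e-12)
  # and fusion becomes the elementwise mean
  y <- array(rnorm(length(x)), dim(x))
  expect_equal(aff_fuse(x, y, w), (x + y) / 2, tolerance = 1e-12)
})

test_that("spatially constant inputs give a spatially constant gate", {
  tm <- tiny_model()
  ch <- tm$cfg$stage_channels[5]
  x <- array(rep(rnorm(ch), each = 16), c(4, 4, ch))
  g <- shootcount:::mscam_gate_fwd(x, tm$params$aff1)$gate
  spread <- apply(g, 3, function(m) diff(range(m)))
  expect_lt(max(spread), 1e-12)
})

test_that("pointwise convolution on a 1x1 input is a plain matrix product", {
  set.seed(3)
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(4)
  x <- array(rnorm(3), c(1, 1, 3))
  got <- shootcount:::conv_fwd(x, W, b, 1L)$y
  expect_equal(as.numeric(got), as.numeric(W %*% x[1, 1, ] + b),
               tolerance = 1e-6)
})

test_that("attention gates stay strictly inside (0, 1) and steer fusion", {
  tm <- tiny_model()
  ch <- tm$cfg$stage_channels[5]
  x <- array(rnorm(4 * 4 * ch, sd = 2), c(4, 4, ch))
  g <- shootcount:::mscam_gate_fwd(x, tm$params$aff1)$gate
  expect_true(all(g > 0 & g < 1))
  # saturating the biases forces the gate to 1 (fusion returns `low`)
  w1 <- rapply(tm$params$aff1, function(v) v * 0, how = "replace")
  w1$l2$b <- w1$l2$b + 50
  low <- array(rnorm(length(x)), dim(x)); high <- array(rnorm(length(x)), dim(x))
  expect_equal(aff_fuse(low, high, w1), low, tolerance = 1e-8)
  w0 <- rapply(tm$params$aff1, function(v) v * 0, how = "replace")
  w0$l2$b <- w0$l2$b - 50
  expect_equal(aff_fuse(low, high, w0), high, tolerance = 1e-8)
})

test_that("the dilated block preserves shape and reduces to its shortcut", {
  tm <- tiny_model()
  ch <- tm$cfg$stage_channels[3]
  x <- array(rnorm(8 * 8 * ch), c(8, 8, ch))
  y <- mdc_block(x, tm$params, tm$cfg)
  expect_equal(dim(y), dim(x))
  p0 <- tm$params
  for (nm in c("mdc.c1", "mdc.c2", "mdc.c3", "mdc.proj")) {
    p0[[nm]]$W <- p0[[nm]]$W * 0; p0[[nm]]$b <- p0[[nm]]$b * 0
  }
  expect_equal(mdc_block(x, p0, tm$cfg), x, tolerance = 1e-12)
})

test_that("stacked dilations 1,2,3 cover a contiguous tap window", {
  taps <- sort(unique(unlist(lapply(c(1, 2, 3), function(d) d * (-1:1)))))
  expect_equal(taps, -3:3)  # no gridding holes
})

test_that("the full forward pass satisfies its output contracts", {
  tm <- tiny_model()
  img <- random_image(64, 64, seed = 5)
  out <- model_forward(tm$params, img, tm$cfg)
  expect_equal(dim(out$density), c(8L, 8L))
  expect_equal(attr(out$density, "scale"), 8L)
  expect_true(all(out$density >= 0))
  expect_equal(length(out$class_probs), 5)
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-6)
  out2 <- model_forward(tm$params, img, tm$cfg)
  expect_identical(density_values(out$density), density_values(out2$density))
  expect_identical(out$class_probs, out2$class_probs)
  # shape covariance at another size
  out3 <- model_forward(tm$params, random_image(32, 48, seed = 6), tm$cfg)
  expect_equal(dim(out3$density), c(4L, 6L))
})

test_that("every parameter block receives gradient on a random batch", {
  tm <- tiny_model(seed = 4)
  img <- random_image(32, 32, seed = 7)
  out <- model_forward(tm$params, img, tm$cfg, with_cache = TRUE)
  set.seed(8)
  g <- model_backward(tm$params, out$cache,
                      d_density = matrix(rnorm(16), 4, 4),
                      d_logits = rnorm(5), cfg = tm$cfg)
  maxabs <- function(x, nm = "") {
    if (is.list(x) && !identical(names(x), c("W", "b")))
      return(unlist(mapply(maxabs, x, paste0(nm, names(x), "."))))
    c(max(abs(x$W)), max(abs(x$b)))
  }
  expect_true(all(maxabs(g) > 0))
})

test_that("model gradients match finite differences at sampled weights", {
  tm <- tiny_model(seed = 9)
  img <- random_image(16, 16, seed = 10)
  R <- matrix(rnorm(4), 2, 2); q <- rnorm(5)
  loss <- function(pp) {
    o <- model_forward(pp, img, tm$cfg)
    sum(density_values(o$density) * R) + sum(o$class_logits * q)
  }
  out <- model_forward(tm$params, img, tm$cfg, with_cache = TRUE)
  g <- model_backward(tm$params, out$cache, d_density = R, d_logits = q,
                      cfg = tm$cfg)
  set.seed(11)
  for (nm in c("s1c1", "proj45", "mdc.c3", "reg2")) {
    j <- sample(length(tm$params[[nm]]$W), 1)
    e <- 1e-5
    pp <- tm$params; pp[[nm]]$W[j] <- pp[[nm]]$W[j] + e
    pm <- tm$params; pm[[nm]]$W[j] <- pm[[nm]]$W[j] - e
    num <- (loss(pp) - loss(pm)) / (2 * e)
    expect_equal(g[[nm]]$W[j], num, tolerance = 1e-4)
  }
})
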