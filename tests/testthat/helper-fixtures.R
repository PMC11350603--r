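# Shared fixtures: tiny scenes, models and batches built in code.

tiny_spec <- function(count_range = c(8, 8), h = 64, w = 64, ...) {
  scene_spec(h, w, count_range = count_range, ...)
}

tiny_model <- function(seed = 1L, n_classes = 5L) {
  cfg <- mtsc_config("reduced", n_classes = n_classes)
  params <- init_mtsc_params(cfg, seed = seed)
  list(cfg = cfg, params = params)
}

random_image <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# Independent brute-force oracle for the adaptive-kernel density map:
# evaluates every truncated Gaussian on the full canvas.
dense_gaussian_oracle <- function(pts, h, w, k = 3L, beta = 0.3,
                                  single_sigma = 4, sigma_min = 0.25) {
  dm <- matrix(0, h, w)
  n <- nrow(pts)
  if (n == 0) return(dm)
  sig <- if (n == 1) single_sigma else sapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    d <- sort(d[-i])
    beta * mean(d[seq_len(min(k, n - 1))])
  })
  sig <- pmax(sig, sigma_min)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  for (i in seq_len(n)) {
    g <- exp(-((xs - pts[i, 1])^2 + (ys - pts[i, 2])^2) / (2 * sig[i]^2))
    g[abs(xs - pts[i, 1]) > 4 * sig[i] | abs(ys - pts[i, 2]) > 4 * sig[i]] <- 0
    dm <- dm + g / sum(g)
  }
  dm
}

# Independent plain-loop SSIM oracle (valid windows, Gaussian weights).
ssim_oracle <- function(X, Y, z1 = 0.01, z2 = 0.03, window = 11, sigma = 1.5) {
  h <- nrow(X); w <- ncol(X)
  wn <- max(1, min(window, h, w))
  off <- seq_len(wn) - (wn + 1) / 2
  ker <- exp(-off^2 / (2 * sigma^2))
  ker <- outer(ker, ker); ker <- ker / sum(ker)
  vals <- c()
  for (r in 1:(h - wn + 1)) for (cl in 1:(w - wn + 1)) {
    px <- X[r:(r + wn - 1), cl:(cl + wn - 1)]
    py <- Y[r:(r + wn - 1), cl:(cl + wn - 1)]
    ux <- sum(ker * px); uy <- sum(ker * py)
    sxx <- sum(ker * px^2) - ux^2; syy <- sum(ker * py^2) - uy^2
    sxy <- sum(ker * px * py) - ux * uy
    vals <- c(vals, ((2 * ux * uy + z1) * (2 * sxy + z2)) /
                ((ux^2 + uy^2 + z1) * (sxx + syy + z2)))
  }
  mean(vals)
}

num_grad <- function(f, x, idx, eps = 1e-6) {
  sapply(idx, function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  })
}
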