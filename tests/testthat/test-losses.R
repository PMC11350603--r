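test_that("SSIM closed forms hold", {
  set.seed(1)
  X <- matrix(runif(64), 8, 8)
  expect_equal(ssim_score(X, X), 1, tolerance = 1e-10)
  expect_equal(ssim_score(matrix(0, 8, 8), matrix(1, 8, 8)),
               0.01 / 1.01, tolerance = 1e-6)
  Y <- matrix(runif(64), 8, 8)
  expect_equal(ssim_score(X, Y), ssim_score(Y, X), tolerance = 1e-12)
})

test_that("SSIM matches an independent plain-loop oracle", {
  set.seed(2)
  for (i in 1:3) {
    X <- matrix(runif(144), 12, 12); Y <- matrix(runif(144), 12, 12)
    expect_equal(ssim_score(X, Y), ssim_oracle(X, Y), tolerance = 1e-6)
  }
})

test_that("structural loss vanishes on perfect or fully masked inputs", {
  set.seed(3)
  G <- matrix(runif(64), 8, 8)
  M <- segmentation_mask(G, 0.5)
  expect_equal(structural_loss(G, G, M), 0, tolerance = 1e-10)
  expect_equal(structural_loss(matrix(runif(64), 8, 8), G, matrix(0, 8, 8)),
               0, tolerance = 1e-10)
})

test_that("structural loss equals an independent level-by-level computation", {
  set.seed(4)
  P <- matrix(runif(64), 8, 8); G <- matrix(runif(64), 8, 8)
  M <- segmentation_mask(G, 0.4)
  want <- 0
  X <- P * M; Y <- G * M
  for (j in 1:3) {
    want <- want + (1 - ssim_oracle(X, Y)) / 3
    if (j < 3) {
      pool <- function(A) {
        o <- matrix(0, nrow(A) / 2, ncol(A) / 2)
        for (r in seq_len(nrow(o))) for (cl in seq_len(ncol(o)))
          o[r, cl] <- mean(A[(2 * r - 1):(2 * r), (2 * cl - 1):(2 * cl)])
        o
      }
      X <- pool(X); Y <- pool(Y)
    }
  }
  expect_equal(structural_loss(P, G, M), want, tolerance = 1e-6)
})

test_that("infeasible pyramid depth is an error and SL stays within [0, 2]", {
  expect_error(structural_loss(matrix(0, 6, 6), matrix(0, 6, 6),
                               matrix(1, 6, 6)), "infeasible")
  set.seed(5)
  for (i in 1:10) {
    P <- matrix(runif(64, 0, 5), 8, 8); G <- matrix(runif(64, 0, 5), 8, 8)
    sl <- structural_loss(P, G, matrix(1, 8, 8))
    expect_gte(sl, 0); expect_lte(sl, 2)
  }
})

test_that("TV loss closed forms and invariances hold", {
  set.seed(6)
  G <- matrix(runif(64), 8, 8); P <- matrix(runif(64), 8, 8)
  expect_equal(tv_loss(3 * G, G), 0, tolerance = 1e-12)
  expect_equal(tv_loss(2.7 * P, G), tv_loss(P, G), tolerance = 1e-12)
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  expect_equal(tv_loss(a, b), 1)
  expect_equal(tv_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 0)
  expect_error(tv_loss(-a, b), "nonnegative")
})

test_that("labeled regression loss composes SL and weighted TV", {
  set.seed(7)
  G <- matrix(runif(64), 8, 8); P <- matrix(runif(64), 8, 8)
  expect_equal(labeled_regression_loss(G, G), 0, tolerance = 1e-10)
  expect_equal(labeled_regression_loss(P, G, lambda1 = 0),
               structural_loss(P, G, segmentation_mask(G)), tolerance = 1e-12)
  expect_equal(labeled_regression_loss(P, G, lambda1 = 0.01),
               structural_loss(P, G, segmentation_mask(G)) +
                 0.01 * tv_loss(P, G), tolerance = 1e-12)
})

test_that("classification cross-entropy behaves like -log p", {
  expect_equal(classification_cross_entropy(1, c(0, 1, 0)), 0)
  expect_equal(classification_cross_entropy(2, rep(0.2, 5)), log(5),
               tolerance = 1e-12)
  expect_error(classification_cross_entropy(0, c(0.5, 0.6)), "probability")
  # floored at 1e-12, never infinite
  expect_lt(classification_cross_entropy(0, c(0, 1)), 28)
})

test_that("smooth L1 branch values are exact", {
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(2, 0), 1.5)
  expect_equal(smooth_l1(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
})

test_that("consistency losses are restricted to the masked footprint", {
  tm <- tiny_model()
  mk <- random_patch_mask(64, 64, mask_spec(16, 0.25), seed = 3)
  m8 <- shootcount:::mask_at_scale(mk, 8)
  mkout <- function(d, p = rep(0.2, 5)) list(density = density_map(d, 8L),
                                             class_probs = p)
  base <- matrix(0.3, 8, 8)
  t_out <- mkout(base)
  expect_equal(unsupervised_losses(mkout(base), t_out, mk)$l_ru, 0)
  expect_equal(unsupervised_losses(mkout(base), t_out, mk)$l_cu, 0)
  # perturbing the student only OUTSIDE masked patches changes nothing
  pert <- base; pert[!m8] <- pert[!m8] + 5
  expect_equal(unsupervised_losses(mkout(pert), t_out, mk)$l_ru, 0)
  # a constant unit discrepancy inside the footprint matches by hand:
  # sum over masked patches of per-patch smooth-L1 (= 0.5 per unit, beta 1)
  inside <- base; inside[m8] <- inside[m8] + 1
  got <- unsupervised_losses(mkout(inside), t_out, mk)
  expect_equal(got$l_ru, 0.5 * mk$masked_patch_count, tolerance = 1e-12)
  # empty mask with positive ratio intent is an error
  mk0 <- random_patch_mask(64, 64, mask_spec(16, 0), seed = 1)
  expect_error(unsupervised_losses(mkout(base), t_out, mk0), "zero masked")
})

test_that("the loss breakdown respects its arithmetic invariants", {
  b <- total_loss(1, 2, 3, 4)
  expect_equal(b$l_l, 3); expect_equal(b$l_u, 7); expect_equal(b$total, 10)
  z <- total_loss(0, 0)
  expect_equal(z$total, 0)
  expect_error(total_loss(NaN, 1, 1, 1), "l_rl")
  expect_error(total_loss(1, 1, Inf, 1), "l_ru")
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(8)
  P <- matrix(runif(64, 0.1, 1), 8, 8)
  G <- matrix(runif(64, 0.1, 1), 8, 8)
  M <- segmentation_mask(G, 0.4)
  sl <- shootcount:::structural_loss_impl(P, G, M, ssim_params(), grad = TRUE)
  idx <- sample(64, 8)
  num <- num_grad(function(x) structural_loss(matrix(x, 8, 8), G, M),
                  as.numeric(P), idx)
  expect_equal(sl$grad[idx], num, tolerance = 1e-4)
  tv <- shootcount:::tv_loss_impl(P, G, grad = TRUE)
  numtv <- num_grad(function(x) tv_loss(matrix(x, 8, 8), G),
                    as.numeric(P), idx, eps = 1e-7)
  expect_equal(tv$grad[idx], numtv, tolerance = 1e-4)
  a <- rnorm(20); b <- rnorm(20)
  sm <- shootcount:::smooth_l1_impl(a, b, 1, grad = TRUE)
  numsm <- num_grad(function(x) smooth_l1(x, b), a, 1:20)
  expect_equal(sm$grad, numsm, tolerance = 1e-4)
})
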