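# Loss stack: segmentation-masked multiscale structural (SSIM) loss plus
# a weighted total-variation term for labeled density regression,
# cross-entropy for the density class, and smooth-L1 teacher-student
# consistency on masked patches for unlabeled images. Every term has an
# analytic gradient (checked against finite differences in the tests)
# because the network is trained without autograd.

#' Parameters of the structural similarity measure
#'
#' @param z1,z2 stabilizing constants of the luminance and
#'   contrast/structure terms (defaults 0.01 and 0.03).
#' @param window local-statistics window edge; Gaussian-weighted with
#'   sigma 1.5, shrunk to the grid when the grid is smaller.
#' @param k_levels pyramid depth of the structural loss (default 3).
#' @return an `ssim_params` list.
#' @export
ssim_params <- function(z1 = 0.01, z2 = 0.03, window = 11L, k_levels = 3L) {
  if (z1 <= 0 || z2 <= 0) stop_cfg("z1 and z2 must be > 0")
  if (k_levels < 1) stop_cfg("k_levels must be >= 1")
  structure(list(z1 = z1, z2 = z2, window = as.integer(window),
                 k_levels = as.integer(k_levels)), class = "ssim_params")
}

gaussian_window <- function(n, sigma = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Local SSIM statistics via valid Gaussian-window convolution; returns
# the mean SSIM map value and a cache sufficient for the adjoint.
ssim_fwd <- function(X, Y, z1, z2, window) {
  if (!all(dim(X) == dim(Y))) stop_cfg("SSIM inputs must share shape")
  h <- nrow(X); w <- ncol(X)
  wn <- max(1L, min(window, h, w))
  ker <- gaussian_window(wn)
  Wk <- matrix(as.vector(ker), 1L, wn * wn)
  cv <- function(M) conv_fwd(array(M, c(h, w, 1L)), Wk, 0, wn, pad = "valid")
  cX <- cv(X); cY <- cv(Y); cX2 <- cv(X^2); cY2 <- cv(Y^2); cXY <- cv(X * Y)
  ux <- cX$y[, , 1]; uy <- cY$y[, , 1]
  sxx <- cX2$y[, , 1] - ux^2
  syy <- cY2$y[, , 1] - uy^2
  sxy <- cXY$y[, , 1] - ux * uy
  A1 <- 2 * ux * uy + z1; A2 <- 2 * sxy + z2
  B1 <- ux^2 + uy^2 + z1; B2 <- sxx + syy + z2
  S <- (A1 * A2) / (B1 * B2)
  list(value = mean(S),
       cache = list(X = X, Y = Y, ux = ux, uy = uy, A1 = A1, A2 = A2,
                    B1 = B1, B2 = B2, S = S, conv_cache = cX$cache,
                    np = length(S), h = h, w = w))
}

# Gradient of mean SSIM w.r.t. X; convT is the adjoint of the valid
# window convolution (reuses the conv backward scatter).
ssim_bwd_X <- function(cache) {
  cc <- cache
  gS <- 1 / cc$np
  dS_dux <- 2 * cc$uy * cc$A2 / (cc$B1 * cc$B2) - cc$S * 2 * cc$ux / cc$B1
  dS_dsxx <- -cc$S / cc$B2
  dS_dsxy <- 2 * cc$A1 / (cc$B1 * cc$B2)
  convT <- function(G) {
    d <- dim(cc$S)
    if (is.null(d)) d <- c(1L, 1L)
    conv_bwd(cc$conv_cache, array(G, c(d, 1L)))$dx[, , 1]
  }
  gux <- gS * (dS_dux - 2 * cc$ux * dS_dsxx - cc$uy * dS_dsxy)
  dX <- convT(gux) + 2 * cc$X * convT(gS * dS_dsxx) +
    cc$Y * convT(gS * dS_dsxy)
  dX
}

#' Structural similarity between two grids
#'
#' Mean over window positions of
#' `[(2 mu_x mu_y + Z1)(2 sigma_xy + Z2)] /
#'  [(mu_x^2 + mu_y^2 + Z1)(sigma_x^2 + sigma_y^2 + Z2)]`
#' with Gaussian-weighted local statistics. Equal inputs score exactly 1.
#'
#' @param X,Y numeric matrices of equal shape.
#' @param params an [ssim_params()].
#' @return scalar in (-1, 1].
#' @export
ssim_score <- function(X, Y, params = ssim_params()) {
  ssim_fwd(as.matrix(X), as.matrix(Y), params$z1, params$z2,
           params$window)$value
}

pyramid_feasible <- function(h, w, k) {
  f <- 2^(k - 1)
  h %% f == 0 && w %% f == 0 && h >= f && w >= f
}

structural_loss_impl <- function(dm_pred, dm_gt, mask, params, grad = FALSE) {
  P <- density_values(as.matrix(dm_pred)); G <- density_values(as.matrix(dm_gt))
  M <- density_values(as.matrix(mask))
  if (!all(dim(P) == dim(G)) || !all(dim(P) == dim(M)))
    stop_cfg("density maps and mask must share shape")
  K <- params$k_levels
  if (!pyramid_feasible(nrow(P), ncol(P), K))
    stop_cfg("pyramid depth K=", K, " infeasible for grid ",
             nrow(P), "x", ncol(P))
  DM <- P * M; DHM <- G * M
  value <- 0
  dP <- if (grad) matrix(0, nrow(P), ncol(P)) else NULL
  X <- DM; Y <- DHM
  for (j in seq_len(K)) {
    fw <- ssim_fwd(X, Y, params$z1, params$z2, params$window)
    value <- value + (1 - fw$value) / K
    if (grad) {
      g <- -ssim_bwd_X(fw$cache) / K
      # chain back through j-1 average poolings
      if (j > 1) for (l in (j - 1):1) {
        dims_up <- c(nrow(g) * 2L, ncol(g) * 2L)
        g <- avgpool2_bwd(g, dims_up)
      }
      dP <- dP + g
    }
    if (j < K) { X <- avgpool2(X); Y <- avgpool2(Y) }
  }
  list(value = value, grad = if (grad) dP * M else NULL)
}

#' Segmentation-masked multiscale structural loss
#'
#' Restricts predicted and ground-truth density maps to the dense region
#' (Hadamard product with the binary mask), then averages `1 - SSIM`
#' over a `k_levels`-deep average-pooling pyramid (each level halves the
#' resolution).
#'
#' @param dm_pred,dm_gt density maps (matrices) of equal shape.
#' @param mask binary segmentation mask (see [segmentation_mask()]).
#' @param params an [ssim_params()].
#' @return scalar loss in `[0, 2]`; 0 iff the masked maps agree at all
#'   pyramid levels.
#' @export
structural_loss <- function(dm_pred, dm_gt, mask, params = ssim_params()) {
  structural_loss_impl(dm_pred, dm_gt, mask, params)$value
}

tv_loss_impl <- function(d_pred, d_gt, grad = FALSE) {
  P <- density_values(as.matrix(d_pred)); G <- density_values(as.matrix(d_gt))
  if (!all(dim(P) == dim(G))) stop_cfg("density maps must share shape")
  if (any(P < 0) || any(G < 0)) stop_cfg("total-variation loss needs ",
                                         "nonnegative inputs")
  sg <- sum(G); sp <- sum(P)
  if (sg == 0 && sp == 0)
    return(list(value = 0, grad = if (grad) P * 0 else NULL))
  u <- if (sg > 0) G / sg else G
  v <- if (sp > 0) P / sp else P
  value <- 0.5 * sg * sum(abs(u - v))
  g <- NULL
  if (grad) {
    if (sp > 0) {
      gv <- 0.5 * sg * sign(v - u)
      g <- (gv - sum(gv * v)) / sp
    } else g <- P * 0
  }
  list(value = value, grad = g)
}

#' Normalized total-variation counting loss
#'
#' `0.5 * sum(d_gt) * || d_gt / ||d_gt||_1 - d_pred / ||d_pred||_1 ||_1`:
#' the L1 distance between the two maps as probability distributions,
#' weighted by the ground-truth count. Invariant to positive rescaling of
#' the prediction; defined as 0 when both maps are empty.
#'
#' @param d_pred,d_gt nonnegative density maps of equal shape.
#' @return scalar loss.
#' @export
tv_loss <- function(d_pred, d_gt) tv_loss_impl(d_pred, d_gt)$value

#' Labeled regression loss
#'
#' Structural loss on the epsilon-thresholded dense region plus
#' `lambda1` times the total-variation loss on the full maps.
#'
#' @param d_pred,d_gt density maps at head resolution.
#' @param epsilon segmentation threshold (default 1e-3).
#' @param lambda1 total-variation weight (default 0.01).
#' @param params an [ssim_params()].
#' @return scalar loss.
#' @export
labeled_regression_loss <- function(d_pred, d_gt, epsilon = 1e-3,
                                    lambda1 = 0.01, params = ssim_params()) {
  labeled_regression_impl(d_pred, d_gt, epsilon, lambda1, params)$value
}

labeled_regression_impl <- function(d_pred, d_gt, epsilon = 1e-3,
                                    lambda1 = 0.01, params = ssim_params(),
                                    grad = FALSE) {
  mask <- segmentation_mask(d_gt, epsilon)
  sl <- structural_loss_impl(d_pred, d_gt, mask, params, grad = grad)
  tv <- tv_loss_impl(d_pred, d_gt, grad = grad)
  list(value = sl$value + lambda1 * tv$value,
       grad = if (grad) sl$grad + lambda1 * tv$grad else NULL)
}

#' Cross-entropy of a density-class prediction
#'
#' `-log p[y_gt]` for a single image; the probability at the true class
#' is floored at 1e-12 for numerical stability. Batch averaging is the
#' caller's responsibility.
#'
#' @param y_gt 0-based true class index.
#' @param y_probs probability vector (must sum to 1 within 1e-6).
#' @return scalar loss.
#' @export
classification_cross_entropy <- function(y_gt, y_probs) {
  if (abs(sum(y_probs) - 1) > 1e-6 || any(y_probs < -1e-12))
    stop_cfg("y_probs is not a probability distribution")
  if (y_gt < 0 || y_gt >= length(y_probs))
    stop_cfg("class index out of range")
  -log(max(y_probs[y_gt + 1L], 1e-12))
}

#' Smooth L1 (Huber) discrepancy
#'
#' Elementwise `0.5 (a-b)^2 / beta` where `|a-b| < beta`, else
#' `|a-b| - 0.5 beta`, averaged over elements.
#'
#' @param a,b numeric arrays of equal shape.
#' @param beta quadratic/linear transition point (default 1).
#' @return scalar loss.
#' @export
smooth_l1 <- function(a, b, beta = 1) {
  smooth_l1_impl(a, b, beta)$value
}

smooth_l1_impl <- function(a, b, beta = 1, grad = FALSE) {
  if (length(a) != length(b)) stop_cfg("smooth_l1 inputs must share shape")
  d <- a - b
  ad <- abs(d)
  quad <- ad < beta
  v <- ifelse(quad, 0.5 * d^2 / beta, ad - 0.5 * beta)
  g <- NULL
  if (grad) g <- ifelse(quad, d / beta, sign(d)) / length(d)
  list(value = mean(v), grad = g)
}

#' Teacher-student consistency losses on masked patches
#'
#' The regression term compares student and teacher density maps only
#' inside the masked-patch footprint (the pixel mask downsampled to the
#' 1/8 head grid): each masked patch contributes the smooth-L1 between
#' its student and teacher contents, and patch contributions are summed
#' over the masked set. The classification term sums, over the same
#' masked set, the smooth-L1 between the two class probability
#' distributions. Teacher outputs are treated as constants; per-batch
#' normalization is the caller's responsibility.
#'
#' @param student_out,teacher_out outputs of [model_forward()] (lists with
#'   `density` and `class_probs`).
#' @param mask the `patch_mask` applied to the student's input.
#' @param beta smooth-L1 transition point.
#' @return list with `l_ru`, `l_cu` and (for the trainer) gradients
#'   `grad_density` and `grad_probs` w.r.t. the student outputs.
#' @export
unsupervised_losses <- function(student_out, teacher_out, mask, beta = 1) {
  if (mask$masked_patch_count == 0)
    stop_cfg("mask has zero masked patches; consistency loss undefined ",
             "(masking ratio too small for this grid)")
  sd <- density_values(as.matrix(student_out$density))
  td <- density_values(as.matrix(teacher_out$density))
  if (!all(dim(sd) == dim(td))) stop_cfg("student/teacher shapes differ")
  m8 <- mask_at_scale(mask, dim(mask$pixel_mask)[1] %/% nrow(sd))
  if (!all(dim(m8) == dim(sd)))
    stop_cfg("mask footprint does not align with the head grid")
  idx <- which(m8)
  omega <- mask$masked_patch_count
  # every patch covers the same number of head cells, so the sum of
  # per-patch smooth-L1 means equals omega times the mean over all
  # masked cells
  ru <- smooth_l1_impl(sd[idx], td[idx], beta, grad = TRUE)
  gd <- matrix(0, nrow(sd), ncol(sd))
  gd[idx] <- ru$grad * omega
  cu <- smooth_l1_impl(student_out$class_probs, teacher_out$class_probs,
                       beta, grad = TRUE)
  list(l_ru = ru$value * omega, l_cu = cu$value * omega,
       grad_density = gd, grad_probs = cu$grad * omega)
}

#' Assemble the loss breakdown
#'
#' Supervised total `l_l = l_rl + l_cl`, unsupervised total
#' `l_u = l_ru + l_cu`, overall `total = l_l + l_u`. Any non-finite part
#' aborts with the offending term named.
#'
#' @param l_rl,l_cl,l_ru,l_cu component losses (unsupervised parts default
#'   to 0 for supervised-only training).
#' @return a `loss_breakdown` list.
#' @export
total_loss <- function(l_rl, l_cl, l_ru = 0, l_cu = 0) {
  parts <- c(l_rl = l_rl, l_cl = l_cl, l_ru = l_ru, l_cu = l_cu)
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad))
    stop_cfg("non-finite loss component(s): ", paste(bad, collapse = ", "),
             "; aborting training")
  structure(list(l_rl = l_rl, l_cl = l_cl, l_l = l_rl + l_cl,
                 l_ru = l_ru, l_cu = l_cu, l_u = l_ru + l_cu,
                 total = l_rl + l_cl + l_ru + l_cu),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total=%.5f  [labeled %.5f = rl %.5f + cl %.5f]  [unlab %.5f = ru %.5f + cu %.5f]\n",
    x$total, x$l_l, x$l_rl, x$l_cl, x$l_u, x$l_ru, x$l_cu))
  invisible(x)
}
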