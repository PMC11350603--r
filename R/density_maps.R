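# Ground-truth construction: point annotations -> density maps, binary
# segmentation masks, sum-preserving downsampling, and density-class labels.

#' Attach a resolution scale to a density map
#'
#' A density map is a nonnegative numeric matrix whose sum equals the
#' number of annotated objects. The `scale` attribute records the
#' downsampling factor relative to the source image (1 = full resolution,
#' 8 = regression-head resolution).
#'
#' @param values nonnegative numeric matrix.
#' @param scale integer downsampling factor.
#' @return the matrix with a `scale` attribute and class `density_map`.
#' @export
density_map <- function(values, scale = 1L) {
  values <- as.matrix(values)
  validate_density(values)
  attr(values, "scale") <- as.integer(scale)
  class(values) <- c("density_map", class(values))
  values
}

density_values <- function(x) {
  x <- unclass(x)
  attr(x, "scale") <- NULL
  x
}

validate_density <- function(values) {
  if (!all(is.finite(values))) stop_cfg("density map contains non-finite values")
  if (any(values < 0)) stop_cfg("density map contains negative values")
  invisible(TRUE)
}

#' Build a density map with geometric adaptive Gaussian kernels
#'
#' Each annotated point contributes a unit-mass 2-D Gaussian whose
#' bandwidth adapts to local crowding: `sigma_i = beta *` (mean distance
#' from point *i* to its `k` nearest annotated neighbours). Kernels are
#' evaluated on a square window truncated at +/- 4 sigma, clipped to the
#' canvas, and renormalized to unit mass, so border points still count
#' fully and the map's sum equals the point count.
#'
#' Images with a single point fall back to a fixed bandwidth
#' (`single_sigma`), since no neighbour distance exists. Bandwidths are
#' floored at `sigma_min` to keep coincident points well defined.
#'
#' @param points a `point_set` (see [point_set()]) or an n x 2 matrix of
#'   (x, y) coordinates, 0-based, origin top-left.
#' @param height,width canvas size in pixels.
#' @param k number of nearest neighbours (default 3).
#' @param beta bandwidth factor on the mean neighbour distance (default 0.3).
#' @param single_sigma fixed bandwidth (px) when fewer than 2 points exist.
#' @param sigma_min lower bound on any bandwidth, in pixels.
#' @return a [density_map()] at scale 1 whose sum equals `nrow(points)`.
#' @export
geometric_adaptive_density <- function(points, height, width, k = 3L,
                                       beta = 0.3, single_sigma = 4,
                                       sigma_min = 0.25) {
  if (height < 1 || width < 1) stop_cfg("zero-size canvas")
  if (k < 1) stop_cfg("k must be >= 1")
  if (beta <= 0) stop_cfg("beta must be > 0")
  pts <- as_points_matrix(points)
  dm <- matrix(0, height, width)
  n <- nrow(pts)
  if (n == 0) return(density_map(dm, 1L))
  sigmas <- if (n == 1) single_sigma else {
    dmat <- as.matrix(stats::dist(pts))
    diag(dmat) <- Inf
    kk <- min(k, n - 1L)
    apply(dmat, 1L, function(row) beta * mean(sort(row)[seq_len(kk)]))
  }
  sigmas <- pmax(sigmas, sigma_min)
  for (i in seq_len(n)) {
    dm <- add_gaussian_bump(dm, pts[i, 1], pts[i, 2], sigmas[i])
  }
  density_map(dm, 1L)
}

# Add a unit-mass truncated Gaussian centred at 0-based (x, y).
# Pixel (r, c) of the matrix (1-based) sits at 0-based coords (c-1, r-1).
add_gaussian_bump <- function(dm, x, y, sigma) {
  h <- nrow(dm); w <- ncol(dm)
  r0 <- max(1L, floor(y - 4 * sigma) + 1L)
  r1 <- min(h, ceiling(y + 4 * sigma) + 1L)
  c0 <- max(1L, floor(x - 4 * sigma) + 1L)
  c1 <- min(w, ceiling(x + 4 * sigma) + 1L)
  if (r0 > r1 || c0 > c1) return(dm)
  ry <- (r0:r1) - 1; cx <- (c0:c1) - 1
  gy <- exp(-((ry - y)^2) / (2 * sigma^2))
  gx <- exp(-((cx - x)^2) / (2 * sigma^2))
  gy[abs(ry - y) > 4 * sigma] <- 0
  gx[abs(cx - x) > 4 * sigma] <- 0
  bump <- outer(gy, gx)
  s <- sum(bump)
  if (s > 0) dm[r0:r1, c0:c1] <- dm[r0:r1, c0:c1] + bump / s
  dm
}

#' Binary segmentation mask of a density map
#'
#' Thresholds a density map at `epsilon` to separate dense areas (where
#' shoots contribute mass) from background; used to restrict the
#' structural loss to regions that carry signal.
#'
#' @param density a density map (matrix).
#' @param epsilon threshold; cells strictly greater are marked 1.
#' @return a 0/1 matrix of the same shape.
#' @export
segmentation_mask <- function(density, epsilon = 1e-3) {
  m <- density_values(as.matrix(density))
  validate_density(m)
  (m > epsilon) * 1
}

#' Sum-preserving block downsampling
#'
#' Each output cell is the sum of its `factor` x `factor` input block, so
#' the count semantics of the density map survive the resolution change
#' to the regression head's 1/8 grid.
#'
#' @param density density map (matrix).
#' @param factor integer block size; must divide both dimensions.
#' @return a [density_map()] whose `scale` is multiplied by `factor`.
#' @export
downsample_sum_preserving <- function(density, factor) {
  m <- as.matrix(density)
  scale0 <- attr(density, "scale") %||% 1L
  m <- density_values(m)
  h <- nrow(m); w <- ncol(m)
  if (h %% factor != 0 || w %% factor != 0)
    stop_cfg("factor ", factor, " does not divide dimensions ", h, "x", w)
  ho <- h %/% factor; wo <- w %/% factor
  dim(m) <- c(factor, ho, factor, wo)
  out <- apply(m, c(2, 4), sum)
  density_map(out, scale0 * as.integer(factor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Density-class label from a per-image count
#'
#' Maps a shoot count to one of `length(bin_edges)` density classes using
#' right-open bins: the class is the 0-based index of the first edge
#' exceeding the count; counts at or above the last edge fall in the last
#' class.
#'
#' @param count nonnegative per-image count.
#' @param bin_edges strictly increasing numeric thresholds.
#' @return integer class index in `[0, length(bin_edges) - 1]`.
#' @export
density_class_label <- function(count, bin_edges) {
  if (length(bin_edges) < 1 || any(diff(bin_edges) <= 0))
    stop_cfg("bin_edges must be strictly increasing")
  cls <- sum(bin_edges <= count)
  min(cls, length(bin_edges) - 1L)
}

#' Quantile bin edges for density classes
#'
#' Places class boundaries at the quantiles of the labeled training
#' counts so every class is populated on any dataset; the last edge is
#' the maximum count (its class is closed above by convention).
#'
#' @param counts labeled-train per-image counts.
#' @param n_classes desired number of classes (default 5).
#' @return strictly increasing numeric edges (possibly fewer than
#'   `n_classes` when counts carry ties).
#' @export
count_bin_edges <- function(counts, n_classes = 5L) {
  if (length(counts) < 1) stop_cfg("need at least one count")
  probs <- seq_len(n_classes) / n_classes
  edges <- unname(stats::quantile(counts, probs = probs, type = 7))
  edges <- unique(edges)
  if (length(edges) == 1L) edges <- c(edges, edges + 1)
  edges
}
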