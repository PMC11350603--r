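# Patch-aligned random masking of unlabeled images (masked image
# modeling as an augmentation) plus photometric/geometric augmentation
# with consistent point-coordinate transforms.

#' Masking specification
#'
#' @param patch_size square patch edge in pixels (default 16).
#' @param ratio fraction of patches masked, in `[0, 1]` (default 0.1).
#' @param fill_value intensity written into masked pixels; the default
#'   0.5 approximates the mean intensity of natural crown imagery (a
#'   mean fill avoids injecting spurious dark "objects").
#' @param rng_seed base seed folded with per-call seeds.
#' @return a `mask_spec` list.
#' @export
mask_spec <- function(patch_size = 16L, ratio = 0.1, fill_value = 0.5,
                      rng_seed = 0L) {
  if (patch_size < 1) stop_cfg("patch_size must be >= 1")
  if (ratio < 0 || ratio > 1) stop_cfg("ratio must be in [0, 1]")
  structure(list(patch_size = as.integer(patch_size), ratio = ratio,
                 fill_value = fill_value, rng_seed = as.integer(rng_seed)),
            class = "mask_spec")
}

round_half_up_int <- function(x) as.integer(floor(x + 0.5))

#' Draw a patch-aligned random mask
#'
#' Divides the canvas into `patch_size` squares and masks exactly
#' `round(ratio * n_patches)` of them (half-up rounding keeps the
#' realized ratio closest to the nominal one), chosen uniformly without
#' replacement under the given seed.
#'
#' @param height,width canvas size; must be multiples of `patch_size`.
#' @param spec a [mask_spec()].
#' @param seed integer seed for this draw.
#' @return a `patch_mask`: list with `grid` (logical patch matrix),
#'   `pixel_mask` (logical H x W raster, the nearest-neighbour expansion
#'   of `grid`), `masked_patch_count` and `patch_size`.
#' @export
random_patch_mask <- function(height, width, spec = mask_spec(), seed = 1L) {
  p <- spec$patch_size
  if (height %% p != 0 || width %% p != 0)
    stop_cfg("patch size ", p, " does not divide ", height, "x", width)
  gh <- height %/% p; gw <- width %/% p
  n_patches <- gh * gw
  n_mask <- round_half_up_int(spec$ratio * n_patches)
  chosen <- if (n_mask > 0)
    with_seed(combine_seeds(spec$rng_seed, seed),
              sample.int(n_patches, n_mask))
  else integer(0)
  grid <- matrix(FALSE, gh, gw)
  grid[chosen] <- TRUE
  pixel_mask <- grid[rep(seq_len(gh), each = p), rep(seq_len(gw), each = p)]
  structure(list(grid = grid, pixel_mask = pixel_mask,
                 masked_patch_count = n_mask, patch_size = p),
            class = "patch_mask")
}

#' Apply a patch mask to an image
#'
#' Pixels under the mask are set to `fill_value` in all channels; all
#' other pixels pass through unchanged.
#'
#' @param image (H, W, 3) array.
#' @param mask a `patch_mask` from [random_patch_mask()].
#' @param fill_value masked-pixel intensity (defaults to 0.5).
#' @return the masked image.
#' @export
apply_mask <- function(image, mask, fill_value = 0.5) {
  stopifnot(inherits(mask, "patch_mask"))
  d <- dim(image)
  if (!all(dim(mask$pixel_mask) == d[1:2]))
    stop_cfg("mask shape ", paste(dim(mask$pixel_mask), collapse = "x"),
             " does not match image ", paste(d[1:2], collapse = "x"))
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    plane[mask$pixel_mask] <- fill_value
    image[, , ch] <- plane
  }
  image
}

# Downsample a pixel mask to the head grid: a head cell is masked when
# any of its factor x factor pixels is masked (patch sizes >= 8 make this
# exact patch alignment).
mask_at_scale <- function(mask, factor) {
  pm <- mask$pixel_mask * 1
  down <- downsample_sum_preserving(density_map(pm), factor)
  density_values(down) > 0
}

#' Photometric and geometric augmentation with point tracking
#'
#' Applies, in order: brightness scaling (clamped to `[0, 1]`), optional
#' horizontal flip, bilinear rescaling, and cropping. Point coordinates
#' are transformed consistently with the pixels (flip maps `x` to
#' `W - 1 - x`; scaling multiplies coordinates by the realized scale
#' factor; cropping subtracts the origin and drops points that leave the
#' crop). Photometric changes never move points.
#'
#' @param image (H, W, 3) array in `[0, 1]`.
#' @param points a [point_set()] or `NULL` for unlabeled images.
#' @param brightness multiplicative brightness factor.
#' @param flip logical; horizontal flip.
#' @param scale isotropic rescale factor (bilinear).
#' @param crop_origin 0-based `(x0, y0)` of the crop, or `NULL`.
#' @param crop_size crop edge in pixels (square), or `NULL` for no crop.
#' @return `list(image, points)` with `points` `NULL` when unlabeled.
#' @export
augment <- function(image, points = NULL, brightness = 1, flip = FALSE,
                    scale = 1, crop_origin = NULL, crop_size = NULL) {
  pts <- if (!is.null(points)) as_points_matrix(points) else NULL
  img <- image
  if (brightness != 1) img <- clamp01(img * brightness)
  if (flip) {
    w <- dim(img)[2]
    img <- img[, w:1, , drop = FALSE]
    if (!is.null(pts) && nrow(pts)) pts[, 1] <- w - 1 - pts[, 1]
  }
  if (scale != 1) {
    h0 <- dim(img)[1]; w0 <- dim(img)[2]
    h1 <- max(1L, round(h0 * scale)); w1 <- max(1L, round(w0 * scale))
    ei <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    ei <- EBImage::resize(ei, w = w1, h = h1)
    img <- aperm(EBImage::imageData(ei), c(2, 1, 3))
    if (!is.null(pts) && nrow(pts)) {
      pts[, 1] <- pts[, 1] * (w1 / w0)
      pts[, 2] <- pts[, 2] * (h1 / h0)
    }
  }
  if (!is.null(crop_size)) {
    if (is.null(crop_origin)) crop_origin <- c(0, 0)
    x0 <- crop_origin[1]; y0 <- crop_origin[2]
    h <- dim(img)[1]; w <- dim(img)[2]
    if (x0 < 0 || y0 < 0 || x0 + crop_size > w || y0 + crop_size > h)
      stop_cfg("crop [", x0, ",", y0, "]+", crop_size,
               " exceeds image ", h, "x", w)
    img <- img[(y0 + 1):(y0 + crop_size), (x0 + 1):(x0 + crop_size), ,
               drop = FALSE]
    if (!is.null(pts) && nrow(pts)) {
      pts[, 1] <- pts[, 1] - x0
      pts[, 2] <- pts[, 2] - y0
      keep <- pts[, 1] >= 0 & pts[, 1] < crop_size &
        pts[, 2] >= 0 & pts[, 2] < crop_size
      pts <- pts[keep, , drop = FALSE]
    }
  }
  out_pts <- if (!is.null(points))
    point_set(pts, image_id = if (inherits(points, "point_set"))
      points$image_id else "")
  else NULL
  list(image = img, points = out_pts)
}

# Sample augmentation parameters for one training crop.
sample_augment_params <- function(h, w, cfg) {
  s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  h1 <- round(h * s); w1 <- round(w * s)
  cs <- min(cfg$crop_size, h1, w1)
  list(brightness = stats::runif(1, 1 - cfg$brightness_jitter,
                                 1 + cfg$brightness_jitter),
       flip = stats::runif(1) < cfg$flip_prob,
       scale = s,
       crop_origin = c(sample.int(w1 - cs + 1L, 1L) - 1L,
                       sample.int(h1 - cs + 1L, 1L) - 1L),
       crop_size = cs)
}
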