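# Synthetic crown scenes: dense small bright blobs ("new shoots") over
# procedural road/soil/grass backgrounds, with exact point annotations.
# These scenes emulate the statistical structure of top-down single-tree
# shoot imagery (per-image counts, small-object density, background
# classes) so the full pipeline is testable without real data.

REF_AREA <- 1024 * 768  # reference canvas of the real single-tree imagery

#' Specification of a synthetic crown scene
#'
#' @param image_height,image_width canvas size in pixels; must be
#'   divisible by 8 (the backbone stride).
#' @param count_range closed integer interval for the per-image shoot
#'   count. The default `NULL` uses 80--246 (the observed range of the
#'   real imagery at 1024 x 768) scaled linearly by canvas area for
#'   smaller canvases, floored at 1, to keep local density realistic.
#' @param blob_sigma_range Gaussian bump scale range (px) for shoot size.
#' @param background_class `"road"`, `"soil"` or `"grass"`, rendered as
#'   distinct procedural textures.
#' @param brightness_jitter per-image multiplicative brightness jitter
#'   fraction.
#' @param rng_seed base seed folded with the per-call seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_height = 768, image_width = 1024,
                       count_range = NULL, blob_sigma_range = c(1.2, 2.5),
                       background_class = c("grass", "soil", "road"),
                       brightness_jitter = 0.1, rng_seed = 0L) {
  background_class <- match.arg(background_class)
  check_div8(image_height, image_width)
  if (is.null(count_range)) {
    scale <- min(1, (image_height * image_width) / REF_AREA)
    count_range <- pmax(1, round(c(80, 246) * scale))
  }
  if (length(count_range) != 2 || count_range[1] < 0 ||
      count_range[1] > count_range[2])
    stop_cfg("count_range must be 0 <= min <= max")
  if (any(blob_sigma_range <= 0) || blob_sigma_range[1] > blob_sigma_range[2])
    stop_cfg("blob_sigma_range must be positive and ordered")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 count_range = as.integer(round(count_range)),
                 blob_sigma_range = blob_sigma_range,
                 background_class = background_class,
                 brightness_jitter = brightness_jitter,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Smooth random field: coarse uniform grid upsampled bilinearly.
smooth_field <- function(h, w, cells = 8L, amplitude = 1) {
  gh <- max(2L, ceiling(h / cells)); gw <- max(2L, ceiling(w / cells))
  g <- matrix(stats::runif(gh * gw, -1, 1), gh, gw)
  ry <- seq(1, gh, length.out = h)
  cx <- seq(1, gw, length.out = w)
  r0 <- pmin(floor(ry), gh - 1L); c0 <- pmin(floor(cx), gw - 1L)
  fy <- ry - r0; fx <- cx - c0
  a <- g[cbind(rep(r0, w), rep(c0, each = h))]
  b <- g[cbind(rep(r0 + 1L, w), rep(c0, each = h))]
  cc <- g[cbind(rep(r0, w), rep(c0 + 1L, each = h))]
  d <- g[cbind(rep(r0 + 1L, w), rep(c0 + 1L, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  v <- a * (1 - fyv) * (1 - fxv) + b * fyv * (1 - fxv) +
    cc * (1 - fyv) * fxv + d * fyv * fxv
  amplitude * matrix(v, h, w)
}

render_background <- function(h, w, class) {
  base <- switch(class,
                 road = c(0.45, 0.44, 0.43),
                 soil = c(0.42, 0.30, 0.18),
                 grass = c(0.18, 0.34, 0.12))
  img <- array(0, c(h, w, 3))
  coarse <- smooth_field(h, w, cells = 16L, amplitude = 0.08)
  fine <- matrix(stats::runif(h * w, -0.04, 0.04), h, w)
  streak <- if (class == "road") {
    matrix(rep(smooth_field(h, 1, cells = 4L, amplitude = 0.05), w), h, w)
  } else 0
  for (ch in 1:3) img[, , ch] <- base[ch] + coarse + fine + streak
  clamp01(img)
}

# Render one anisotropic bright Gaussian bump (a "shoot") additively.
render_blob <- function(img, x, y, sigma, ratio, theta, amp, tint) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ext <- ceiling(3 * sigma * max(1, ratio))
  r0 <- max(1L, floor(y) - ext + 1L); r1 <- min(h, ceiling(y) + ext + 1L)
  c0 <- max(1L, floor(x) - ext + 1L); c1 <- min(w, ceiling(x) + ext + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  ry <- (r0:r1) - 1 - y; cx <- (c0:c1) - 1 - x
  ct <- cos(theta); st <- sin(theta)
  u <- outer(ry * st, cx * ct, "+")          # rotated major axis
  v <- outer(ry * ct, -cx * st, "+")         # rotated minor axis
  s_major <- sigma * ratio; s_minor <- sigma
  bump <- amp * exp(-(u^2 / (2 * s_major^2) + v^2 / (2 * s_minor^2)))
  for (ch in 1:3)
    img[r0:r1, c0:c1, ch] <- img[r0:r1, c0:c1, ch] + bump * tint[ch]
  img
}

#' Generate one synthetic crown scene
#'
#' Draws a per-image count uniformly from the spec's `count_range`,
#' scatters that many anisotropic bright Gaussian bumps over a procedural
#' background, and returns the rendered RGB raster together with the
#' exact point annotations. Identical `(spec, seed)` pairs reproduce
#' identical outputs.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed for this scene.
#' @param image_id identifier recorded in the returned `point_set`.
#' @return `list(image = H x W x 3 array in [0, 1], points = point_set)`.
#' @export
generate_scene <- function(spec, seed = 1L, image_id = "scene") {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_height; w <- spec$image_width
  check_div8(h, w)
  with_seed(combine_seeds(spec$rng_seed, seed), {
    img <- render_background(h, w, spec$background_class)
    n <- if (spec$count_range[1] == spec$count_range[2]) spec$count_range[1]
    else sample(spec$count_range[1]:spec$count_range[2], 1L)
    margin <- 1.5
    pts <- cbind(x = stats::runif(n, margin, w - 1 - margin),
                 y = stats::runif(n, margin, h - 1 - margin))
    if (n > 0) {
      sig <- stats::runif(n, spec$blob_sigma_range[1], spec$blob_sigma_range[2])
      ratio <- stats::runif(n, 1, 2.2)
      theta <- stats::runif(n, 0, pi)
      amp <- stats::runif(n, 0.35, 0.7)
      for (i in seq_len(n)) {
        tint <- c(0.75, 0.95, 0.45) * stats::runif(1, 0.85, 1.1)
        img <- render_blob(img, pts[i, 1], pts[i, 2], sig[i], ratio[i],
                           theta[i], amp[i], tint)
      }
    }
    bj <- spec$brightness_jitter
    if (bj > 0) img <- img * stats::runif(1, 1 - bj, 1 + bj)
    img <- clamp01(img)
    list(image = img, points = point_set(pts, image_id = image_id))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG scenes with JSON point annotations, splits them
#' into train/val/test and writes a `manifest.csv` referencing every file
#' (paths relative to `out_dir`).
#'
#' @param n_images number of scenes (at least 3, one per split).
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if missing).
#' @param seed integer base seed (scene i uses `seed + i`).
#' @param ratios train/val/test ratios passed to [split_dataset()].
#' @return the manifest `data.frame`, invisibly; attribute `dir` holds
#'   `out_dir`.
#' @export
generate_dataset <- function(n_images, spec, out_dir, seed = 1L,
                             ratios = c(0.7, 0.2, 0.1)) {
  if (!is_count(n_images) || n_images < 3)
    stop_cfg("n_images must be an integer >= 3 (one image per split)")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_cfg("cannot create output directory ", out_dir)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  ids <- sprintf("img_%04d", seq_len(n_images))
  img_paths <- file.path("images", paste0(ids, ".png"))
  ann_paths <- file.path("annotations", paste0(ids, ".json"))
  for (i in seq_len(n_images)) {
    sc <- generate_scene(spec, seed = seed + i, image_id = ids[i])
    png::writePNG(sc$image, file.path(out_dir, img_paths[i]))
    write_points(sc$points, file.path(out_dir, ann_paths[i]))
  }
  man <- split_dataset(ids, ratios = ratios, seed = seed)
  ord <- match(man$image_path, ids)
  man$annotation_path <- ann_paths[ord]
  man$image_path <- img_paths[ord]
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  attr(man, "dir") <- out_dir
  invisible(man)
}

#' Read an RGB image as an (H, W, 3) array
#'
#' Grayscale PNGs are expanded to three channels; an alpha channel is
#' dropped.
#'
#' @param path PNG file.
#' @return numeric array (H, W, 3) in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
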