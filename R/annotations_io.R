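# Reading/writing point annotations, dataset manifests and density-map
# containers, plus the train/val/test split and labeled-subset protocol.

#' Point annotations for one image
#'
#' Coordinates are real-valued pixels, 0-based, origin at the top-left
#' corner, `x` indexing columns and `y` indexing rows. The number of
#' points is the image's ground-truth shoot count.
#'
#' @param points n x 2 numeric matrix (columns x, y); may have 0 rows.
#' @param image_id identifier string.
#' @return an object of class `point_set`.
#' @export
point_set <- function(points, image_id = "") {
  points <- as_points_matrix(points)
  structure(list(image_id = image_id, points = points), class = "point_set")
}

as_points_matrix <- function(points) {
  if (inherits(points, "point_set")) points <- points$points
  if (is.null(points) || length(points) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  points <- as.matrix(points)
  if (ncol(points) != 2) stop_cfg("points must have two columns (x, y)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

#' @export
print.point_set <- function(x, ...) {
  cat("<point_set> image_id=", x$image_id, ", ", nrow(x$points),
      " points\n", sep = "")
  invisible(x)
}

#' Number of points in a point set
#' @param x a `point_set`.
#' @param ... ignored.
#' @export
length.point_set <- function(x) nrow(x$points)

validate_points <- function(points, path = "<memory>") {
  bad <- which(!is.finite(points[, 1]) | !is.finite(points[, 2]) |
                 points[, 1] < 0 | points[, 2] < 0)
  if (length(bad))
    stop_cfg("invalid coordinates in ", path, " at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "),
             ": coordinates must be finite and nonnegative")
  invisible(TRUE)
}

#' Read point annotations (JSON or CSV)
#'
#' JSON files carry `{"image_id": ..., "points": [[x, y], ...]}`; CSV
#' files carry columns `x,y` with a header. A header-only CSV or an empty
#' JSON points list yields a valid zero-count image.
#'
#' @param path annotation file, dialect chosen by extension.
#' @return a [point_set()].
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop_cfg("annotation file not found: ", path)
  ext <- tolower(file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    pts <- obj$points
    if (is.null(pts) || length(pts) == 0) pts <- matrix(numeric(0), 0, 2)
    if (!is.numeric(as.matrix(pts)))
      stop_cfg("non-numeric coordinates in ", path)
    pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
    validate_points(pts, path)
    point_set(pts, image_id = obj$image_id %||% "")
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop_cfg("CSV annotations need columns x,y: ", path)
    if (nrow(df) == 0) return(point_set(NULL, image_id = strip_ext(basename(path))))
    if (!is.numeric(df$x) || !is.numeric(df$y)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$x))) |
                     is.na(suppressWarnings(as.numeric(df$y))))
      stop_cfg("non-numeric coordinates in ", path, " at row(s) ",
               paste(utils::head(bad, 5), collapse = ", "))
    }
    pts <- cbind(df$x, df$y)
    validate_points(pts, path)
    point_set(pts, image_id = strip_ext(basename(path)))
  } else stop_cfg("unsupported annotation format: .", ext)
}

#' Write point annotations (JSON or CSV)
#'
#' @param points a [point_set()].
#' @param path destination; `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  stopifnot(inherits(points, "point_set"))
  ext <- tolower(file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(image_id = points$image_id,
           points = unname(points$points)),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(points$points), path, row.names = FALSE)
  } else stop_cfg("unsupported annotation format: .", ext)
  invisible(path)
}

file_ext <- function(path) sub(".*\\.", "", basename(path))
strip_ext <- function(path) sub("\\.[^.]*$", "", path)

#' Split image ids into train/val/test
#'
#' Ids are sorted, shuffled with the given seed, and assigned
#' `floor(n * ratio)` images to train and to val with the remainder going
#' to test, so split sizes are deterministic for any n.
#'
#' @param image_ids character or numeric ids (one per image).
#' @param ratios length-3 positive vector (train, val, test) summing to 1.
#' @param seed integer shuffle seed.
#' @return a manifest `data.frame` with columns `image_path`,
#'   `annotation_path`, `split`, `labeled` (all entries labeled).
#' @export
split_dataset <- function(image_ids, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0))
    stop_cfg("ratios must be three positive numbers")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_cfg("ratios must sum to 1, got ", sum(ratios))
  ids <- sort(as.character(image_ids))
  n <- length(ids)
  if (n < 1) stop_cfg("no image ids supplied")
  shuffled <- with_seed(seed, sample(ids))
  n_train <- floor(n * ratios[1])
  n_val <- floor(n * ratios[2])
  split <- c(rep("train", n_train), rep("val", n_val),
             rep("test", n - n_train - n_val))
  man <- data.frame(image_path = shuffled,
                    annotation_path = NA_character_,
                    split = split,
                    labeled = TRUE,
                    stringsAsFactors = FALSE)
  man <- man[order(man$image_path), ]
  rownames(man) <- NULL
  attr(man, "split_seed") <- as.integer(seed)
  class(man) <- c("shoot_manifest", "data.frame")
  man
}

#' Flag a labeled subset of the training split
#'
#' Exactly `floor(percentage * n_train)` training entries keep their
#' labels (seeded sampling without replacement); the remaining training
#' entries become the unlabeled pool. Validation and test entries are
#' always labeled, since metrics need ground truth.
#'
#' @param manifest a manifest `data.frame` (see [split_dataset()]).
#' @param percentage fraction of training images kept labeled, in (0, 1].
#' @param seed integer sampling seed.
#' @return the manifest with its `labeled` column updated and a
#'   `labeled_percentage` attribute.
#' @export
select_labeled <- function(manifest, percentage, seed = 1L) {
  if (percentage <= 0 || percentage > 1)
    stop_cfg("percentage must be in (0, 1]")
  tr <- which(manifest$split == "train")
  n_lab <- floor(percentage * length(tr))
  if (n_lab < 1)
    stop_cfg("percentage ", percentage, " yields zero labeled training ",
             "images; training is impossible")
  tr_sorted <- tr[order(manifest$image_path[tr])]
  keep <- with_seed(seed, sample(tr_sorted, n_lab))
  manifest$labeled[tr] <- FALSE
  manifest$labeled[keep] <- TRUE
  attr(manifest, "labeled_percentage") <- percentage
  attr(manifest, "label_seed") <- as.integer(seed)
  manifest
}

#' Write / read a dataset manifest (CSV)
#'
#' @param manifest manifest `data.frame`.
#' @param path CSV file with columns
#'   `image_path, annotation_path, split, labeled`.
#' @return `path` / the manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("image_path", "annotation_path",
                                               "split", "labeled")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "annotation_path", "split", "labeled")
  if (!all(need %in% names(man)))
    stop_cfg("manifest is missing columns: ",
             paste(setdiff(need, names(man)), collapse = ", "))
  man$labeled <- as.logical(man$labeled)
  class(man) <- c("shoot_manifest", "data.frame")
  man
}

#' Write a density map to an HDF5 container
#'
#' Stores the grid as a float32 dataset `density` along with `height`,
#' `width` and `scale` datasets.
#'
#' @param map density map (matrix, optionally from [density_map()]).
#' @param path destination `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_density <- function(map, path) {
  m <- as.matrix(map)
  scale <- attr(map, "scale") %||% 1L
  m <- density_values(m)
  validate_density(m)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "density", dims = dim(m),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(m, path, "density")
  rhdf5::h5write(nrow(m), path, "height")
  rhdf5::h5write(ncol(m), path, "width")
  rhdf5::h5write(as.integer(scale), path, "scale")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop_cfg("density file not found: ", path)
  out <- tryCatch({
    vals <- rhdf5::h5read(path, "density")
    scale <- tryCatch(as.integer(rhdf5::h5read(path, "scale")),
                      error = function(e) 1L)
    rhdf5::h5closeAll()
    density_map(vals, scale)
  }, error = function(e) {
    rhdf5::h5closeAll()
    stop_cfg("failed to read density container ", path, ": ",
             conditionMessage(e))
  })
  out
}
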