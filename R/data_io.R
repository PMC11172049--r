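#' Read an image manifest
#'
#' Loads a CSV in the EyePACS label dialect (`image,level`), optionally
#' extended with `path`, `provenance` and `transform` columns as written
#' by [write_manifest()].  Grades must lie in 0..4 and image ids must be
#' unique; every violation is collected and reported with its row number
#' in a single itemized error.
#'
#' @param path CSV file path.
#' @param check_paths If `TRUE`, also verify that every referenced image
#'   file exists (relative paths are resolved against the CSV directory).
#' @return A manifest data.frame with columns `image_id`, `path`, `grade`,
#'   `provenance`, `transform`, carrying the CSV directory as attribute
#'   `root`.
#' @export
read_manifest <- function(path, check_paths = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "level") %in% names(df)))
    stop("manifest CSV must have `image` and `level` columns", call. = FALSE)
  m <- data.frame(
    image_id = as.character(df$image),
    path = if ("path" %in% names(df)) as.character(df$path) else as.character(df$image),
    grade = suppressWarnings(as.integer(df$level)),
    provenance = if ("provenance" %in% names(df)) as.character(df$provenance) else "original",
    transform = if ("transform" %in% names(df)) as.character(df$transform) else NA_character_,
    stringsAsFactors = FALSE)
  m$transform[m$transform %in% c("", "NA")] <- NA_character_
  root <- dirname(normalizePath(path, mustWork = FALSE))
  issues <- character(0)
  bad_grade <- which(is.na(m$grade) | m$grade < 0L | m$grade > 4L)
  if (length(bad_grade))
    issues <- c(issues, sprintf("row %d: grade `%s` outside 0..4",
                                bad_grade, df$level[bad_grade]))
  dup <- which(duplicated(m$image_id))
  if (length(dup))
    issues <- c(issues, sprintf("row %d: duplicate image id `%s`", dup, m$image_id[dup]))
  if (check_paths) {
    full <- resolve_paths(m$path, root)
    miss <- which(!file.exists(full))
    if (length(miss))
      issues <- c(issues, sprintf("row %d: missing file `%s`", miss, full[miss]))
  }
  if (length(issues))
    stop("manifest load failed:\n", paste("  -", issues, collapse = "\n"), call. = FALSE)
  attr(m, "root") <- root
  m
}

resolve_paths <- function(paths, root) {
  abs <- grepl("^(/|[A-Za-z]:)", paths)
  ifelse(abs, paths, file.path(root, paths))
}

#' Write an image manifest
#'
#' Writes the EyePACS-compatible CSV (`image,level` first, extra columns
#' after).  `read_manifest(write_manifest(m, f))` reproduces `m`.
#'
#' @param manifest A manifest data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(image = manifest$image_id, level = manifest$grade,
                    path = manifest$path, provenance = manifest$provenance,
                    transform = manifest$transform, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Contrast enhancement configuration
#'
#' @param method `"clahe"` (contrast-limited adaptive histogram
#'   equalization of the luminance channel; the default, standard for the
#'   low vessel/background contrast of fundus images) or `"stretch"`
#'   (global linear rescale of each channel to the full range).
#' @param clip_limit CLAHE clip limit.
#' @param tiles CLAHE tile grid per axis.
#' @return A `contrast_config` list.
#' @export
contrast_config <- function(method = c("clahe", "stretch"), clip_limit = 2,
                            tiles = 8L) {
  structure(list(method = match.arg(method), clip_limit = clip_limit,
                 tiles = as.integer(tiles)), class = "contrast_config")
}

#' Enhance image contrast
#'
#' Deterministically adjusts pixel brightness/darkness.  With
#' `method = "clahe"` the luminance channel is equalized and the RGB
#' channels rescaled by the per-pixel luminance gain; with `"stretch"`
#' each channel is linearly mapped to span `[0, 1]`.  Output is always
#' clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array (or matrix) with intensities in
#'   `[0, 1]`.
#' @param config A [contrast_config()].
#' @return An image of the same shape in `[0, 1]`.
#' @export
enhance_contrast <- function(image, config = contrast_config()) {
  gray <- is.matrix(image)
  if (config$method == "stretch") {
    out <- if (gray) stretch_plane(image) else {
      for (c3 in seq_len(dim(image)[3])) image[, , c3] <- stretch_plane(image[, , c3])
      image
    }
    return(clip01(out))
  }
  y <- if (gray) image else
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  # tile counts must divide the image dimensions
  nx <- best_tile_count(nrow(y), config$tiles)
  ny <- best_tile_count(ncol(y), config$tiles)
  ye <- EBImage::imageData(EBImage::clahe(EBImage::as.Image(clip01(y)),
                                          nx = nx, ny = ny,
                                          limit = config$clip_limit))
  if (gray) return(clip01(ye))
  gain <- ye / pmax(y, 1e-6)
  out <- image
  for (c3 in 1:3) out[, , c3] <- image[, , c3] * gain
  clip01(out)
}

# largest divisor of n not exceeding `want` (at least 1); each CLAHE tile
# should still hold a few pixels
best_tile_count <- function(n, want) {
  want <- max(1L, min(want, n %/% 4L))
  for (k in want:1L) if (n %% k == 0L) return(k)
  1L
}

stretch_plane <- function(p) {
  r <- range(p)
  if (diff(r) <= 0) p else (p - r[1]) / diff(r)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Preprocessing configuration
#'
#' @param resize_side Side of the intermediate square resize, in pixels.
#' @param crop_side Side of the crop fed to the network; must not exceed
#'   `resize_side` and must be divisible by `2^T` of the model it feeds.
#' @param hflip_prob Probability of a horizontal flip in training mode.
#' @param contrast A [contrast_config()], or `NULL` to skip enhancement.
#' @param seed Base seed for the training-mode crop/flip draws.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(resize_side = 256L, crop_side = 224L,
                              hflip_prob = 0.5, contrast = contrast_config(),
                              seed = 1L) {
  if (crop_side > resize_side)
    stop("crop_side must not exceed resize_side", call. = FALSE)
  structure(list(resize_side = as.integer(resize_side),
                 crop_side = as.integer(crop_side),
                 hflip_prob = hflip_prob, contrast = contrast,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Preprocess one image for the network
#'
#' Contrast enhancement, bilinear resize to `resize_side`, then either a
#' seeded random crop to `crop_side` with a random horizontal flip
#' (training mode) or a deterministic centre crop without flip
#' (evaluation mode).
#'
#' @param image `H x W x 3` RGB array in `[0, 1]` (a grayscale matrix is
#'   replicated to 3 channels).
#' @param config A [preprocess_config()].
#' @param training Logical; enables the random crop/flip.
#' @param seed Seed for this image's random draws (training mode);
#'   defaults to `config$seed`.
#' @return A `crop_side x crop_side x 3` array with attributes `offset`
#'   (row/col of the crop origin in the resized image, 0-based) and
#'   `flipped`.
#' @export
preprocess_image <- function(image, config = preprocess_config(),
                             training = FALSE, seed = config$seed) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("expected an RGB image (H x W x 3)", call. = FALSE)
  image <- image[, , 1:3, drop = FALSE]
  if (!is.null(config$contrast)) image <- enhance_contrast(image, config$contrast)
  r <- config$resize_side; cs <- config$crop_side
  img <- EBImage::imageData(EBImage::resize(EBImage::as.Image(image), w = r, h = r))
  slack <- r - cs
  if (training) {
    restore <- local_rng(seed)
    on.exit(restore(), add = TRUE)
    oy <- sample.int(slack + 1L, 1L) - 1L
    ox <- sample.int(slack + 1L, 1L) - 1L
    flip <- stats::runif(1) < config$hflip_prob
  } else {
    oy <- ox <- slack %/% 2L
    flip <- FALSE
  }
  out <- img[(oy + 1L):(oy + cs), (ox + 1L):(ox + cs), , drop = FALSE]
  if (flip) out <- out[, cs:1L, , drop = FALSE]
  structure(out, offset = c(oy, ox), flipped = flip)
}

#' Augmentation configuration for class balancing
#'
#' @param width_shift,height_shift Maximum shift as a fraction of the
#'   image side, drawn uniformly from `[-shift, shift]`; must lie in
#'   `[0, 0.5]`.
#' @param zoom_range Scale interval containing 1, drawn uniformly.
#' @param fill_mode Boundary policy for pixels mapped from outside the
#'   image; only `"nearest"` (clamp to the border) is implemented.
#' @param horizontal_flip Allow a random horizontal flip.
#' @param seed Seed for transform sampling in [balance_classes()].
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(width_shift = 0.1, height_shift = 0.1,
                                zoom_range = c(0.9, 1.1), fill_mode = "nearest",
                                horizontal_flip = TRUE, seed = 1L) {
  if (width_shift < 0 || width_shift > 0.5 || height_shift < 0 || height_shift > 0.5)
    stop("shift fractions must lie in [0, 0.5]", call. = FALSE)
  if (zoom_range[1] > 1 || zoom_range[2] < 1)
    stop("zoom_range must contain 1", call. = FALSE)
  fill_mode <- match.arg(fill_mode, "nearest")
  structure(list(width_shift = width_shift, height_shift = height_shift,
                 zoom_range = zoom_range, fill_mode = fill_mode,
                 horizontal_flip = horizontal_flip, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Balance class counts by augmentation records
#'
#' Up-samples every minority class to the majority-class count by adding
#' augmented copies of its records: each copy references the original
#' image and stores a replayable transform descriptor (flip, width/height
#' shift, zoom) sampled from `aug`.  Original records are never touched
#' and the majority class is never down-sampled.  A manifest that is
#' already balanced is returned unchanged.
#'
#' @param manifest A manifest data.frame.
#' @param aug An [augmentation_config()].
#' @return The balanced manifest (attribute `root` preserved).
#' @export
balance_classes <- function(manifest, aug = augmentation_config()) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  counts <- table(factor(manifest$grade, levels = sort(unique(manifest$grade))))
  if (any(counts == 0L))
    stop("empty class(es): ", paste(names(counts)[counts == 0], collapse = ", "),
         call. = FALSE)
  target <- max(counts)
  if (all(counts == target)) return(manifest)
  restore <- local_rng(aug$seed)
  on.exit(restore(), add = TRUE)
  extra <- list()
  for (g in as.integer(names(counts))) {
    need <- target - counts[[as.character(g)]]
    if (need == 0L) next
    base <- manifest[manifest$grade == g & manifest$provenance == "original", , drop = FALSE]
    if (nrow(base) == 0L) base <- manifest[manifest$grade == g, , drop = FALSE]
    pick <- base[sample.int(nrow(base), need, replace = TRUE), , drop = FALSE]
    desc <- replicate(need, sample_transform(aug))
    pick$image_id <- sprintf("%s_aug%03d", pick$image_id, seq_len(need))
    pick$provenance <- "augmented"
    pick$transform <- desc
    extra[[length(extra) + 1L]] <- pick
  }
  out <- rbind(manifest, do.call(rbind, extra))
  rownames(out) <- NULL
  attr(out, "root") <- attr(manifest, "root")
  out
}

sample_transform <- function(aug) {
  flip <- aug$horizontal_flip && stats::runif(1) < 0.5
  sprintf("flip=%d;sx=%.6f;sy=%.6f;zoom=%.6f;fill=%s",
          as.integer(flip),
          stats::runif(1, -aug$width_shift, aug$width_shift),
          stats::runif(1, -aug$height_shift, aug$height_shift),
          stats::runif(1, aug$zoom_range[1], aug$zoom_range[2]),
          aug$fill_mode)
}

parse_transform <- function(descriptor) {
  kv <- strsplit(strsplit(descriptor, ";")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  list(flip = vals[["flip"]] == "1", sx = as.numeric(vals[["sx"]]),
       sy = as.numeric(vals[["sy"]]), zoom = as.numeric(vals[["zoom"]]),
       fill = vals[["fill"]])
}

#' Replay an augmentation transform
#'
#' Applies the deterministic transform stored in an augmented manifest
#' record: horizontal flip, zoom about the image centre, then a
#' horizontal/vertical shift, with nearest-border fill and
#' nearest-neighbour sampling.  Re-rendering from the same descriptor is
#' bit-exact.
#'
#' @param image `H x W x C` array or matrix.
#' @param descriptor Transform string from [balance_classes()], or the
#'   parsed list.
#' @return The transformed image, same shape.
#' @export
render_augmented <- function(image, descriptor) {
  tr <- if (is.character(descriptor)) parse_transform(descriptor) else descriptor
  gray <- is.matrix(image)
  d <- if (gray) dim(image) else dim(image)[1:2]
  h <- d[1]; w <- d[2]
  # inverse mapping: source coords for each output pixel
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  i <- seq_len(h); j <- seq_len(w)
  si <- round((i - ci) / tr$zoom + ci - tr$sy * h)
  sj <- round((j - cj) / tr$zoom + cj - tr$sx * w)
  si <- pmin(pmax(si, 1L), h)            # "nearest" fill: clamp to border
  sj <- pmin(pmax(sj, 1L), w)
  if (tr$flip) sj <- rev(sj)
  if (gray) image[si, sj, drop = FALSE] else image[si, sj, , drop = FALSE]
}

#' Train/test split configuration
#'
#' @param train_fraction Fraction of records assigned to training.
#' @param stratified Split each grade separately so all grades appear in
#'   both partitions.
#' @param seed Seed for the shuffles.
#' @return A `split_config` list.
#' @export
split_config <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)), class = "split_config")
}

#' Split a manifest into train and test partitions
#'
#' Disjoint and exhaustive; records are sorted by id before the seeded
#' shuffle so the split is invariant to input order.  With stratification
#' each grade contributes `round(train_fraction * n_g)` training records;
#' otherwise `round(train_fraction * n)` records are drawn overall.
#'
#' @param manifest A manifest data.frame with at least 5 records.
#' @param config A [split_config()].
#' @return A list with elements `train` and `test`.
#' @export
split_manifest <- function(manifest, config = split_config()) {
  if (nrow(manifest) < 5L) stop("need at least 5 records to split", call. = FALSE)
  m <- manifest[order(manifest$image_id), , drop = FALSE]
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)
  take_train <- logical(nrow(m))
  if (config$stratified) {
    for (g in sort(unique(m$grade))) {
      idx <- which(m$grade == g)
      if (length(idx) < 2L) {
        warning(sprintf("grade %d has fewer than 2 records; assigning to train", g),
                call. = FALSE)
        take_train[idx] <- TRUE
        next
      }
      k <- round(config$train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      take_train[sample(idx, k)] <- TRUE
    }
  } else {
    k <- round(config$train_fraction * nrow(m))
    take_train[sample.int(nrow(m), k)] <- TRUE
  }
  train <- m[take_train, , drop = FALSE]; rownames(train) <- NULL
  test <- m[!take_train, , drop = FALSE]; rownames(test) <- NULL
  attr(train, "root") <- attr(manifest, "root")
  attr(test, "root") <- attr(manifest, "root")
  list(train = train, test = test)
}

#' Load and preprocess the images of a manifest
#'
#' Reads each record's PNG/JPEG, replays the stored augmentation
#' transform for augmented records, and applies [preprocess_image()]
#' (per-record seeds derived from `config$seed` keep training crops
#' reproducible).
#'
#' @param manifest A manifest data.frame.
#' @param config A [preprocess_config()].
#' @param training Passed to [preprocess_image()].
#' @return A list with `x` (`crop x crop x 3 x N` array) and `y` (integer
#'   grades).
#' @export
load_images <- function(manifest, config = preprocess_config(), training = FALSE) {
  n <- nrow(manifest)
  cs <- config$crop_side
  x <- array(0, c(cs, cs, 3L, n))
  root <- attr(manifest, "root") %||% "."
  paths <- resolve_paths(manifest$path, root)
  for (i in seq_len(n)) {
    img <- png::readPNG(paths[i])
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]
    if (!is.na(manifest$transform[i]))
      img <- render_augmented(img, manifest$transform[i])
    x[, , , i] <- preprocess_image(img, config, training = training,
                                   seed = config$seed + i)
  }
  list(x = x, y = manifest$grade)
}
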