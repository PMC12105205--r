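# Image and mask preparation: resizing to the model grid, train-time flip
# augmentation, mask hole filling and [0, 1] normalization. Evaluation
# pipelines apply resize + normalize only; flips are a training-time
# augmentation.

#' Preprocessing configuration
#'
#' @param target_height,target_width Model grid in pixels (128 x 192).
#' @param flip_prob Probability of each of the horizontal and vertical
#'   flips at train time.
#' @param fill_holes Fill enclosed background holes in annotation masks.
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(target_height = 128L, target_width = 192L,
                              flip_prob = 0.5, fill_holes = TRUE) {
  stopifnot(target_height > 0, target_width > 0,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 flip_prob = flip_prob, fill_holes = fill_holes),
            class = "preprocess_config")
}

#' Resize an image/mask pair to the model grid
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour so it stays strictly binary. Per-axis pixel spacing is
#' rescaled by original/target so measurements in mm survive the resize.
#'
#' @param image Matrix (H x W) or array (H x W x C) of intensities.
#' @param mask Binary H x W matrix.
#' @param cfg A [preprocess_config()].
#' @param pixel_spacing Optional scalar or per-axis `c(sy, sx)` spacing in
#'   mm/px of the input.
#' @return List with `image`, `mask` and `pixel_spacing` (per-axis
#'   `c(sy, sx)`, or `NULL` if none supplied).
#' @export
resize_pair <- function(image, mask, cfg = preprocess_config(),
                        pixel_spacing = NULL) {
  if (length(dim(image)) < 2 || any(dim(image)[1:2] == 0) ||
      is.null(dim(mask)) || any(dim(mask) == 0))
    stop("dimension error: empty image or mask")
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask must share height and width")
  h0 <- dim(image)[1]; w0 <- dim(image)[2]
  th <- cfg$target_height; tw <- cfg$target_width

  img2 <- EBImage::resize(image, w = th, h = tw, filter = "bilinear")
  msk2 <- EBImage::resize(mask, w = th, h = tw, filter = "none")
  storage.mode(msk2) <- "integer"

  spacing <- NULL
  if (!is.null(pixel_spacing)) {
    sp <- rep_len(pixel_spacing, 2)  # (sy, sx)
    spacing <- c(sy = sp[1] * h0 / th, sx = sp[2] * w0 / tw)
  }
  list(image = img2, mask = msk2, pixel_spacing = spacing)
}

#' Random horizontal/vertical flip of an image/mask pair
#'
#' Each flip is applied independently with probability `flip_prob`, and the
#' image and mask always receive the identical transform. Draws come from
#' the current RNG stream so a seeded caller reproduces the augmented
#' stream exactly. Train-time only.
#'
#' @param image Matrix or H x W x C array.
#' @param mask Binary matrix.
#' @param flip_prob Per-flip probability in \[0, 1\].
#' @return List with `image`, `mask`, and logicals `flipped_h`,
#'   `flipped_v`.
#' @export
random_flip_pair <- function(image, mask, flip_prob = 0.5) {
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  fh <- runif(1) < flip_prob  # horizontal flip: reverse columns
  fv <- runif(1) < flip_prob  # vertical flip: reverse rows
  flip <- function(x) {
    d <- dim(x)
    if (fh) x <- if (length(d) == 3) x[, d[2]:1, , drop = FALSE] else x[, d[2]:1, drop = FALSE]
    if (fv) x <- if (length(d) == 3) x[d[1]:1, , , drop = FALSE] else x[d[1]:1, , drop = FALSE]
    x
  }
  list(image = flip(image), mask = flip(mask), flipped_h = fh, flipped_v = fv)
}

#' Fill enclosed holes in a binary mask
#'
#' Every background region not connected to the image border becomes
#' foreground; foreground pixels are never removed. Turns hollow rim
#' annotations into solid head discs.
#'
#' @param mask Binary 0/1 matrix.
#' @return Integer 0/1 matrix of the same shape.
#' @export
fill_mask_holes <- function(mask) {
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    stop("validation error: mask must be binary 0/1")
  out <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  out <- matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
  out
}

#' Normalize an image to [0, 1] and replicate to three channels
#'
#' 8-bit inputs (integer storage or values above 1) are divided by 255;
#' float inputs already in \[0, 1\] pass through. Grayscale input is
#' replicated to three channels to match the model's H x W x 3 input.
#'
#' @param image Matrix or H x W x C array, integer 0-255 or float.
#' @return H x W x 3 array with values in \[0, 1\].
#' @export
normalize_image <- function(image) {
  x <- image
  if (is.integer(x) || max(x, na.rm = TRUE) > 1) x <- x / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  d <- dim(x)
  if (length(d) == 2) {
    array(x, dim = c(d, 3))
  } else if (d[3] == 1) {
    array(x[, , 1], dim = c(d[1], d[2], 3))
  } else if (d[3] == 3) {
    x
  } else stop("expected grayscale or 3-channel input")
}

#' Binarize a mask read from an 8-bit PNG
#'
#' Values above 127/255 map to foreground.
#'
#' @param mask_img Matrix of intensities in \[0, 1\] (as read by
#'   [png::readPNG()]) or 0-255.
#' @return Integer 0/1 matrix.
#' @export
binarize_mask <- function(mask_img) {
  if (length(dim(mask_img)) == 3) mask_img <- mask_img[, , 1]
  thr <- if (max(mask_img) > 1) 127 else 127 / 255
  matrix(as.integer(mask_img > thr), nrow(mask_img), ncol(mask_img))
}

#' Write a side-by-side inspection panel
#'
#' Writes a PNG with three panels: the image, the mask, and the image with
#' the mask boundary overlaid, mirroring the visual cross-checks used when
#' validating preprocessing.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param mask Binary matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_inspection_panel <- function(image, mask, path) {
  stopifnot(identical(dim(image)[1:2], dim(mask)))
  if (length(dim(image)) == 3) image <- image[, , 1]
  boundary <- mask_boundary(mask)
  overlay_r <- pmin(1, image + boundary)
  overlay_g <- image * (1 - boundary)
  panel <- array(0, dim = c(nrow(image), 3 * ncol(image), 3))
  w <- ncol(image)
  for (ch in 1:3) {
    panel[, 1:w, ch] <- image
    panel[, w + 1:w, ch] <- mask
  }
  panel[, 2 * w + 1:w, 1] <- overlay_r
  panel[, 2 * w + 1:w, 2] <- overlay_g
  panel[, 2 * w + 1:w, 3] <- overlay_g
  png::writePNG(panel, path)
  invisible(path)
}

# Boundary = foreground pixels with at least one 4-neighbour background.
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  matrix(as.integer(mask & !inner), h, w)
}
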