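#' Image and mask containers
#'
#' The pipeline works on plain numeric arrays and matrices so every
#' operation stays transparent and testable:
#'
#' * an *RGB image* is an `H x W x 3` numeric array of 8-bit channel
#'   values in `[0, 255]`, class `"rgb_image"`;
#' * color-space transforms return `H x W x 3` arrays of class
#'   `"hsv_image"`, `"ycbcr_image"` or `"lab_image"`;
#' * a *mask* is a logical `H x W` matrix;
#' * a *grayscale image* is a numeric `H x W` matrix normalized to
#'   `[0, 1]`.
#'
#' `as_rgb_image()` validates and tags an array; `read_skin_image()` and
#' `write_mask()` wrap [EBImage::readImage()] / [EBImage::writeImage()]
#' (which store images as width x height, so both functions transpose).
#'
#' @param x numeric array `H x W x 3` with values in `[0, 255]`.
#' @return `as_rgb_image()` returns the array with class `"rgb_image"`.
#' @examples
#' img <- as_rgb_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("an RGB image must be an H x W x 3 array", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop("RGB channel values must be numeric in [0, 255]", call. = FALSE)
  }
  structure(unclass(x), class = "rgb_image")
}

#' @rdname as_rgb_image
#' @param path file path of a PNG/JPEG/TIFF image (8-bit color).
#' @export
read_skin_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) stop("expected a color image, got a single plane", call. = FALSE)
  if (d[3] > 3L) img <- img[, , 1:3]  # drop alpha
  if (d[3] < 3L) stop("expected 3 color channels, got ", d[3], call. = FALSE)
  # EBImage is x,y (width, height) in [0,1]; we use row = image row
  arr <- aperm(EBImage::imageData(img), c(2, 1, 3)) * 255
  as_rgb_image(pmin(pmax(arr, 0), 255))
}

#' @rdname as_rgb_image
#' @param mask logical `H x W` matrix.
#' @param img an `rgb_image` to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' @rdname as_rgb_image
#' @export
write_rgb_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(unclass(img) / 255, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

# shared shape checks ------------------------------------------------------

check_mask <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || !(is.logical(m) || all(m %in% c(0, 1)))) {
    stop(name, " must be a binary H x W matrix", call. = FALSE)
  }
  matrix(as.logical(m), nrow(m), ncol(m))
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("shape mismatch: ", paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

check_planes <- function(x, class, op) {
  if (!inherits(x, class)) {
    stop(op, " expects a ", class, " (see colorspace transforms)", call. = FALSE)
  }
  invisible(TRUE)
}

# extract plane k of an H x W x 3 array as a matrix (dims never dropped)
plane <- function(x, k) {
  d <- dim(x)
  matrix(x[, , k], d[1], d[2])
}
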