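#' Pixel-wise color-space transforms
#'
#' The segmentation stages rely on three color-space views of the raw
#' 8-bit RGB photograph.
#'
#' `rgb_to_hsv()` implements the hexcone HSV model on channels normalized
#' to `[0, 1]`: `V = max(r, g, b)`, `S = (V - X) / V` with
#' `X = min(r, g, b)`, and a six-sector hue rule divided by 6 so
#' `H` lies in `[0, 1]` (pure red at `H = 0`). Degenerate pixels follow
#' the usual convention: `S = 0` when `V = 0`, and `H = 0` for
#' achromatic pixels (`V = X`).
#'
#' `rgb_to_ycbcr()` is the affine luma/chroma transform
#' `[Y; Cb; Cr] = [0; 128; 128] + M [r; g; b]` applied to the raw 8-bit
#' values, with
#' `M = [0.299 0.587 0.114; -0.169 -0.331 0.500; 0.500 -0.419 -0.081]`,
#' clipped to `[0, 255]`. A gray pixel maps exactly to `Cb = Cr = 128`.
#'
#' `rgb_to_lab()` converts channels normalized to `[0, 1]` through the
#' linear XYZ matrix
#' `[0.4125 0.3576 0.1804; 0.2127 0.7152 0.0722; 0.0193 0.1192 0.9502]`
#' and then to CIE 1976 L*a*b*, using the two-branch lightness rule
#' (`L = 116 (Y/Yn)^(1/3) - 16` above `Y/Yn = 0.008856`, else
#' `L = 903.3 Y/Yn`) and cube-root chroma differences
#' (`a = 500 (f(X/Xn) - f(Y/Yn))`, `b = 200 (f(Y/Yn) - f(Z/Zn))`).
#' The white point `(Xn, Yn, Zn)` is the image of `r = g = b = 1` under
#' the matrix (its row sums), so `(255,255,255)` maps exactly to
#' `L = 100, a = b = 0`. No gamma decoding is applied: the formulas act
#' on the raw channel values.
#'
#' @param img an [as_rgb_image()] array (`H x W x 3`, values in 0..255).
#' @return An `H x W x 3` array of class `"hsv_image"` (planes H, S, V
#'   each in `[0, 1]`), `"ycbcr_image"` (planes Y, Cb, Cr in
#'   `[0, 255]`), or `"lab_image"` (planes L in `[0, 100]`, a, b).
#' @examples
#' px <- as_rgb_image(array(c(200, 150, 100), dim = c(1, 1, 3)))
#' rgb_to_hsv(px)[1, 1, ]   # H = 1/12, S = 0.5, V = 200/255
#' @export
rgb_to_hsv <- function(img) {
  img <- as_rgb_image(img)
  r <- plane(img, 1) / 255; g <- plane(img, 2) / 255; b <- plane(img, 3) / 255
  v <- pmax(r, g, b)
  x <- pmin(r, g, b)
  c_ <- v - x
  s <- ifelse(v > 0, c_ / v, 0)

  # six-sector hue, expressed per dominant channel; achromatic -> 0
  h6 <- matrix(0, nrow(r), ncol(r))
  nz <- c_ > 0
  rmax <- nz & r >= g & r >= b
  gmax <- nz & !rmax & g >= b
  bmax <- nz & !rmax & !gmax
  h6[rmax] <- ((g - b)[rmax] / c_[rmax]) %% 6
  h6[gmax] <- 2 + (b - r)[gmax] / c_[gmax]
  h6[bmax] <- 4 + (r - g)[bmax] / c_[bmax]

  out <- array(c(h6 / 6, s, v), dim = dim(img))
  structure(out, class = "hsv_image")
}

ycbcr_matrix <- matrix(c(0.299,  0.587,  0.114,
                         -0.169, -0.331,  0.500,
                         0.500, -0.419, -0.081),
                       nrow = 3, byrow = TRUE)

#' @rdname rgb_to_hsv
#' @export
rgb_to_ycbcr <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  px <- matrix(unclass(img), ncol = 3)           # n x (r,g,b)
  out <- px %*% t(ycbcr_matrix)
  out[, 2] <- out[, 2] + 128
  out[, 3] <- out[, 3] + 128
  out <- pmin(pmax(out, 0), 255)
  structure(array(out, dim = d), class = "ycbcr_image")
}

xyz_matrix <- matrix(c(0.4125, 0.3576, 0.1804,
                       0.2127, 0.7152, 0.0722,
                       0.0193, 0.1192, 0.9502),
                     nrow = 3, byrow = TRUE)

#' @rdname rgb_to_hsv
#' @export
rgb_to_lab <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  px <- matrix(unclass(img), ncol = 3) / 255
  xyz <- px %*% t(xyz_matrix)
  wp <- rowSums(xyz_matrix)                      # image of r = g = b = 1
  ratio <- sweep(xyz, 2, wp, "/")

  f <- ratio^(1 / 3)
  L <- ifelse(ratio[, 2] > 0.008856,
              116 * f[, 2] - 16,
              903.3 * ratio[, 2])
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])

  structure(array(c(L, a, b), dim = d), class = "lab_image")
}
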