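#' Stage 2: lesion-region segmentation
#'
#' Within the skin region, candidate lesions are darker than the
#' surrounding skin once luminosity is saturated. The stage is a
#' four-step composition:
#'
#' 1. [saturate_luminosity()] — linearly stretch the CIELAB L plane so
#'    the `p_lo`/`p_hi` percentiles of L over skin pixels map to 0/100
#'    (clipped outside); healthy and damaged pixels are pushed apart.
#' 2. [pca_grayscale()] — project every pixel's `(L, a, b)` triplet onto
#'    the first principal component of the skin-pixel cloud. The
#'    component sign is chosen so the score correlates positively with
#'    L (lesions land in the low tail) and scores are affinely rescaled
#'    so skin pixels span `[0, 1]`.
#' 3. [threshold_lesions()] — flag the dark tail: skin pixels whose
#'    grayscale value is `<=` the `fraction` quantile (default 0.10) of
#'    grayscale over skin pixels. The selected interval `[a, b]` on the
#'    grayscale axis is reported alongside the mask. The threshold
#'    adapts to each image because it is a quantile of that image's own
#'    histogram.
#' 4. [damage_percentage()] — lesion pixels as a percentage of skin
#'    pixels, the per-image damage summary.
#'
#' All histogram statistics (stretch percentiles, PCA, quantile) are
#' computed over skin pixels only, so the background cannot distort
#' them; this restriction can be relaxed by passing an all-`TRUE` skin
#' mask.
#'
#' @param lab a `"lab_image"` from [rgb_to_lab()].
#' @param p_lo,p_hi stretch percentiles in `[0, 100]`.
#' @param skin logical skin mask (`TRUE` = skin).
#' @param gray numeric `H x W` grayscale matrix in `[0, 1]`.
#' @param fraction quantile fraction in `(0, 1)`; the flagged dark tail.
#' @param lesion logical lesion mask, a subset of `skin`.
#' @param img an [as_rgb_image()] array.
#' @param config a [pipeline_config()] list.
#' @return `threshold_lesions()` returns a list with elements `mask`
#'   (logical matrix) and `threshold` (list `fraction`, `a`, `b`).
#'   `segment_lesions()` returns a list with `mask`, `threshold`,
#'   `gray`, and `damage_percent`.
#' @examples
#' scene <- make_scene(scene_spec(seed = 3))
#' skin <- segment_skin(scene$image)
#' les <- segment_lesions(scene$image, skin)
#' les$damage_percent
#' @export
saturate_luminosity <- function(lab, skin = NULL, p_lo = 2, p_hi = 98) {
  check_planes(lab, "lab_image", "saturate_luminosity")
  L <- plane(lab, 1)
  sel <- if (is.null(skin)) rep(TRUE, length(L)) else as.vector(check_mask(skin))
  q <- stats::quantile(L[sel], c(p_lo, p_hi) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant L plane; returning input unchanged")
    return(lab)
  }
  Ls <- pmin(pmax((L - q[1]) / (q[2] - q[1]) * 100, 0), 100)
  out <- lab
  out[, , 1] <- Ls
  out
}

#' @rdname saturate_luminosity
#' @export
pca_grayscale <- function(lab, skin) {
  check_planes(lab, "lab_image", "pca_grayscale")
  skin <- check_mask(skin)
  check_same_shape(lab, skin)
  px <- cbind(as.vector(plane(lab, 1)), as.vector(plane(lab, 2)), as.vector(plane(lab, 3)))
  sk <- as.vector(skin)
  skin_px <- px[sk, , drop = FALSE]
  if (nrow(unique(skin_px)) < 2) {
    stop("pca_grayscale needs at least 2 distinct skin-pixel colors", call. = FALSE)
  }
  ctr <- colMeans(skin_px)
  cv <- stats::cov(skin_px)
  dir <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  score <- (px - matrix(ctr, nrow(px), 3, byrow = TRUE)) %*% dir
  # orient so the score tracks lightness: dark lesions land in the low tail
  ori <- suppressWarnings(stats::cor(score[sk], skin_px[, 1]))
  if (is.na(ori)) ori <- dir[1]
  if (ori < 0) score <- -score
  rng <- range(score[sk])
  g <- (score - rng[1]) / (rng[2] - rng[1])
  matrix(pmin(pmax(g, 0), 1), nrow(skin), ncol(skin))
}

#' @rdname saturate_luminosity
#' @export
threshold_lesions <- function(gray, skin, fraction = 0.10) {
  skin <- check_mask(skin)
  check_same_shape(gray, skin)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)", call. = FALSE)
  if (!any(skin)) stop("empty skin mask", call. = FALSE)
  vals <- gray[skin]
  thr <- stats::quantile(vals, fraction, names = FALSE)
  mask <- skin & gray <= thr
  sel <- vals[vals <= thr]
  list(mask = mask,
       threshold = list(fraction = fraction, a = min(sel), b = thr))
}

#' @rdname saturate_luminosity
#' @export
damage_percentage <- function(lesion, skin) {
  lesion <- check_mask(lesion); skin <- check_mask(skin)
  check_same_shape(lesion, skin)
  if (!any(skin)) stop("empty skin mask", call. = FALSE)
  if (any(lesion & !skin)) stop("lesion mask must lie inside the skin mask", call. = FALSE)
  100 * sum(lesion) / sum(skin)
}

#' @rdname saturate_luminosity
#' @export
segment_lesions <- function(img, skin, config = pipeline_config()) {
  img <- as_rgb_image(img)
  skin <- check_mask(skin)
  check_same_shape(img, skin)
  lab <- rgb_to_lab(img)
  lab <- saturate_luminosity(lab, skin, config$stretch_lo, config$stretch_hi)
  gray <- pca_grayscale(lab, skin)
  thr <- threshold_lesions(gray, skin, config$lesion_fraction)
  list(mask = thr$mask,
       threshold = thr$threshold,
       gray = gray,
       damage_percent = damage_percentage(thr$mask, skin))
}
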