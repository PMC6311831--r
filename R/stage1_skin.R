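#' Stage 1: skin-region segmentation
#'
#' The skin region is the logical AND of two masks computed in different
#' color spaces, followed by morphological cleanup:
#'
#' 1. **Hue mask** — pixels whose hexcone hue falls in a fixed
#'    red-orange band, `0.01 <= H <= 0.1` by default (closed interval).
#' 2. **Dynamic chroma mask** — pixels whose Cb/Cr chroma falls in a
#'    per-image *dynamic range*: `min(Cb) <= Cb <= mean(Cb)` and
#'    `mean(Cr) <= Cr <= max(Cr)`, the statistics taken over the whole
#'    image. Because the range is recomputed per photograph it
#'    self-tunes to the subject's skin tone and the scene illumination.
#'
#' The raw conjunction is cleaned with morphological closing, removal of
#' small connected components, and hole filling — plumbing that removes
#' background speckle without changing which tones are considered skin.
#'
#' @param hsv an `"hsv_image"` from [rgb_to_hsv()].
#' @param lo,hi closed hue-band endpoints, fractions in `[0, 1]`.
#' @param ycbcr a `"ycbcr_image"` from [rgb_to_ycbcr()].
#' @param range a `dynamic_range` from [compute_dynamic_range()].
#' @param exclude_black if `TRUE`, exact-black pixels are left out of
#'   the dynamic-range statistics (useful when the photograph carries a
#'   black border).
#' @param m,m1,m2 logical masks of identical shape.
#' @param min_object smallest connected component kept, in pixels.
#' @param close_radius radius of the disc structuring element for
#'   morphological closing, in pixels (0 disables closing).
#' @param img an [as_rgb_image()] array.
#' @param config a [pipeline_config()] list; only its Stage 1 entries
#'   are used.
#' @return Masks are logical `H x W` matrices (`TRUE` = skin).
#'   `compute_dynamic_range()` returns a `dynamic_range` list with
#'   elements `cb_low`, `cb_high`, `cr_low`, `cr_high`.
#' @examples
#' spec <- scene_spec(seed = 1, macules = list())
#' scene <- make_scene(spec)
#' skin <- segment_skin(scene$image)
#' mean(skin[scene$truth$skin_mask])   # recall on the true leg
#' @export
skin_mask_hue <- function(hsv, lo = 0.01, hi = 0.1) {
  check_planes(hsv, "hsv_image", "skin_mask_hue")
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("hue band requires 0 <= lo < hi <= 1", call. = FALSE)
  }
  h <- plane(hsv, 1)
  h >= lo & h <= hi
}

#' @rdname skin_mask_hue
#' @export
compute_dynamic_range <- function(ycbcr, exclude_black = FALSE) {
  check_planes(ycbcr, "ycbcr_image", "compute_dynamic_range")
  if (length(ycbcr) == 0) stop("empty image", call. = FALSE)
  cb <- plane(ycbcr, 2)
  cr <- plane(ycbcr, 3)
  if (exclude_black) {
    keep <- plane(ycbcr, 1) > 0
    if (!any(keep)) stop("all pixels excluded as black", call. = FALSE)
    cb <- cb[keep]; cr <- cr[keep]
  }
  structure(list(cb_low = min(cb), cb_high = mean(cb),
                 cr_low = mean(cr), cr_high = max(cr)),
            class = "dynamic_range")
}

#' @rdname skin_mask_hue
#' @export
skin_mask_ycbcr <- function(ycbcr, range) {
  check_planes(ycbcr, "ycbcr_image", "skin_mask_ycbcr")
  stopifnot(inherits(range, "dynamic_range"))
  cb <- plane(ycbcr, 2)
  cr <- plane(ycbcr, 3)
  cb >= range$cb_low & cb <= range$cb_high &
    cr >= range$cr_low & cr <= range$cr_high
}

#' @rdname skin_mask_hue
#' @export
combine_masks <- function(m1, m2) {
  m1 <- check_mask(m1); m2 <- check_mask(m2)
  check_same_shape(m1, m2)
  m1 & m2
}

#' @rdname skin_mask_hue
#' @export
clean_skin_mask <- function(m, min_object = 0, close_radius = 0) {
  m <- check_mask(m)
  if (!any(m)) return(m)
  em <- EBImage::Image(t(m * 1))
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    em <- EBImage::closing(em, brush)
  }
  if (min_object > 0) {
    lab <- EBImage::bwlabel(em)
    sizes <- tabulate(as.integer(lab))
    drop <- which(sizes < min_object)
    if (length(drop)) em <- EBImage::rmObjects(lab, drop) > 0
  }
  em <- EBImage::fillHull(em > 0)
  t(EBImage::imageData(em) > 0)
}

#' @rdname skin_mask_hue
#' @export
segment_skin <- function(img, config = pipeline_config()) {
  img <- as_rgb_image(img)
  hsv <- rgb_to_hsv(img)
  ycbcr <- rgb_to_ycbcr(img)
  rng <- compute_dynamic_range(ycbcr, exclude_black = config$exclude_black)
  raw <- combine_masks(
    skin_mask_hue(hsv, config$hue_lo, config$hue_hi),
    skin_mask_ycbcr(ycbcr, rng)
  )
  min_obj <- ceiling(config$min_object_frac * length(raw))
  clean_skin_mask(raw, min_object = min_obj, close_radius = config$close_radius)
}
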