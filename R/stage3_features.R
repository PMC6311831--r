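#' Stage 3: macule labeling and characterization
#'
#' Candidate lesions are split into connected macule regions and each
#' region is summarized by eleven features in a fixed order: five
#' morphologic (`area`, `major_axis`, `minor_axis`, `perimeter`,
#' `solidity`), two intensity (`max_intensity`, `min_intensity` on the
#' Stage 2 PCA grayscale), and four *Shade Indices* (`shi_r`, `shi_g`,
#' `shi_b`, `shi_br`).
#'
#' A Shade Index is the mean of a raw 8-bit channel inside the macule
#' divided by the mean of the same channel over a ring of healthy skin
#' around it:
#' \deqn{ShI_R = mean(M_{red}) / mean(HS_{red})}
#' and analogously for green and blue; the brown index combines red and
#' blue, \eqn{ShI_{BR} = (mean(M_{red}) + mean(M_{blue})) /
#' (mean(HS_{red}) + mean(HS_{blue}))}. Because macule and reference are
#' read from the same neighborhood, the indices cancel global
#' illumination and skin-tone differences: a macule identical to its
#' surroundings scores exactly 1 in every index.
#'
#' Conventions (documented because several are discretization choices):
#' regions are 8-connected; the healthy ring is the dilation of the
#' region by `ring_width` pixels, minus all lesion pixels, restricted to
#' skin; axis lengths are those of the ellipse with the same normalized
#' second central moments as the pixel set (a single pixel is treated as
#' a unit square); the perimeter is the total length of exposed pixel
#' edges (the boundary of the union of unit squares); solidity is 100
#' times area over the area of the convex hull of the pixel corners.
#'
#' @param lesion,skin logical masks, `lesion` inside `skin`.
#' @param min_area smallest region kept, in pixels.
#' @param ring_width healthy-ring width, in pixels.
#' @param region a `macule_region` as returned by [label_macules()].
#' @param gray Stage 2 PCA grayscale matrix in `[0, 1]`.
#' @param img the raw [as_rgb_image()] array.
#' @param config a [pipeline_config()] list.
#' @return `label_macules()` returns a list of `macule_region` objects,
#'   each with `label`, `pixels` and `ring` (integer matrices of
#'   0-based `row`,`col` coordinates). `characterize()` returns a
#'   tibble with one row per macule: `label`, `centroid_row`,
#'   `centroid_col`, then the eleven features in the order above.
#' @examples
#' lesion <- matrix(FALSE, 20, 20); lesion[5:10, 5:10] <- TRUE
#' skin <- matrix(TRUE, 20, 20)
#' regs <- label_macules(lesion, skin)
#' morph_features(regs[[1]])$area   # 36
#' @export
label_macules <- function(lesion, skin, min_area = 5, ring_width = 5) {
  lesion <- check_mask(lesion); skin <- check_mask(skin)
  check_same_shape(lesion, skin)
  if (any(lesion & !skin)) stop("lesion mask must lie inside the skin mask", call. = FALSE)
  lab <- label_components8(lesion)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  regions <- list()
  H <- nrow(lesion); W <- ncol(lesion)
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < min_area) next
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    ring_idx <- ring_pixels(rows, cols, H, W, ring_width, lesion, skin)
    regions[[length(regions) + 1L]] <- structure(
      list(label = length(regions) + 1L,
           pixels = cbind(row = rows - 1L, col = cols - 1L),
           ring = ring_idx),
      class = "macule_region")
  }
  regions
}

# 8-connected labeling: 4-connected pass, then union labels across diagonals
label_components8 <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  nmax <- max(lab)
  if (nmax < 2) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  for (dc in c(-1L, 1L)) {
    a <- lab[-H, , drop = FALSE]
    b <- if (dc == 1L) lab[-1, -1, drop = FALSE] else lab[-1, -W, drop = FALSE]
    a <- if (dc == 1L) a[, -W, drop = FALSE] else a[, -1, drop = FALSE]
    hit <- which(a > 0 & b > 0 & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# dilation ring around one component, clipped to skin, excluding all lesion px
ring_pixels <- function(rows, cols, H, W, ring_width, lesion, skin) {
  r0 <- max(1L, min(rows) - ring_width); r1 <- min(H, max(rows) + ring_width)
  c0 <- max(1L, min(cols) - ring_width); c1 <- min(W, max(cols) + ring_width)
  sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  brush <- EBImage::makeBrush(2 * ring_width + 1, shape = "disc")
  dil <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(sub * 1)), brush))) > 0
  ring <- dil & !lesion[r0:r1, c0:c1] & skin[r0:r1, c0:c1]
  idx <- which(ring)
  rr <- ((idx - 1L) %% nrow(ring)) + r0
  cc <- ((idx - 1L) %/% nrow(ring)) + c0
  cbind(row = rr - 1L, col = cc - 1L)
}

#' @rdname label_macules
#' @export
morph_features <- function(region) {
  stopifnot(inherits(region, "macule_region"), nrow(region$pixels) >= 1)
  r <- region$pixels[, "row"]; c <- region$pixels[, "col"]
  n <- length(r)

  # ellipse with identical normalized second central moments;
  # the 1/12 terms are the moments of a unit-square pixel
  urr <- sum((r - mean(r))^2) / n + 1 / 12
  ucc <- sum((c - mean(c))^2) / n + 1 / 12
  urc <- sum((r - mean(r)) * (c - mean(c))) / n
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  major <- 2 * sqrt(2) * sqrt(urr + ucc + common)
  minor <- 2 * sqrt(2) * sqrt(urr + ucc - common)

  list(area = n,
       major_axis = major,
       minor_axis = minor,
       perimeter = region_perimeter(r, c),
       solidity = 100 * n / corner_hull_area(r, c))
}

# exposed-edge perimeter of the union of unit pixel squares
region_perimeter <- function(r, c) {
  keys <- r * (max(c) + 2) + c
  inset <- function(rr, cc) (rr * (max(c) + 2) + cc) %in% keys
  4 * length(r) - sum(inset(r - 1, c)) - sum(inset(r + 1, c)) -
    sum(inset(r, c - 1)) - sum(inset(r, c + 1))
}

# area of the convex hull of pixel corner points (shoelace)
corner_hull_area <- function(r, c) {
  pts <- unique(cbind(
    c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
    c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)))
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' @rdname label_macules
#' @export
intensity_features <- function(region, gray) {
  stopifnot(inherits(region, "macule_region"))
  idx <- region$pixels[, "row"] + 1L + region$pixels[, "col"] * nrow(gray)
  v <- gray[idx]
  list(max_intensity = max(v), min_intensity = min(v))
}

#' @rdname label_macules
#' @export
shade_indices <- function(region, img) {
  stopifnot(inherits(region, "macule_region"))
  img <- as_rgb_image(img)
  if (nrow(region$ring) == 0) stop("empty healthy-skin ring", call. = FALSE)
  H <- dim(img)[1]
  ch_mean <- function(coords, k) {
    mean(img[coords[, "row"] + 1L + coords[, "col"] * H + (k - 1L) * H * dim(img)[2]])
  }
  m_r <- ch_mean(region$pixels, 1); m_g <- ch_mean(region$pixels, 2); m_b <- ch_mean(region$pixels, 3)
  h_r <- ch_mean(region$ring, 1);   h_g <- ch_mean(region$ring, 2);   h_b <- ch_mean(region$ring, 3)
  if (min(h_r, h_g, h_b) == 0 || (h_r + h_b) == 0) {
    stop("zero mean in the healthy-skin reference ring", call. = FALSE)
  }
  list(shi_r = m_r / h_r, shi_g = m_g / h_g, shi_b = m_b / h_b,
       shi_br = (m_r + m_b) / (h_r + h_b))
}

#' @rdname label_macules
#' @export
characterize <- function(img, gray, lesion, skin, config = pipeline_config()) {
  img <- as_rgb_image(img)
  check_same_shape(img, lesion)
  regions <- label_macules(lesion, skin,
                           min_area = config$min_area,
                           ring_width = config$ring_width)
  rows <- purrr::map(regions, function(reg) {
    tibble::tibble(
      label = reg$label,
      centroid_row = mean(reg$pixels[, "row"]),
      centroid_col = mean(reg$pixels[, "col"]),
      !!!morph_features(reg),
      !!!intensity_features(reg, gray),
      !!!shade_indices(reg, img))
  })
  if (length(rows) == 0) return(empty_feature_tibble())
  dplyr::bind_rows(rows)
}

empty_feature_tibble <- function() {
  tibble::tibble(
    label = integer(), centroid_row = double(), centroid_col = double(),
    area = double(), major_axis = double(), minor_axis = double(),
    perimeter = double(), solidity = double(),
    max_intensity = double(), min_intensity = double(),
    shi_r = double(), shi_g = double(), shi_b = double(), shi_br = double())
}

#' Names of the eleven macule features, in canonical order
#' @return character vector of length 11.
#' @export
feature_names <- function() {
  c("area", "major_axis", "minor_axis", "perimeter", "solidity",
    "max_intensity", "min_intensity", "shi_r", "shi_g", "shi_b", "shi_br")
}
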