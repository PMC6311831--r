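#' Reference feature distributions for the four macule classes
#'
#' Per-class means and standard deviations of the eleven macule
#' features (five morphologic, two intensity, four Shade Indices) for
#' vascular, petechiae, trophic-change and trauma macules, as
#' characterized from clinically assessed lower-limb lesions. These
#' distributions parameterize the synthetic feature sampler
#' ([sample_feature_vectors()]) and the default macule phenotypes of
#' the scene generator.
#'
#' @return A tibble with columns `class`, `feature`, `mean`, `sd`, `n`.
#' @examples
#' macule_feature_params() |> dplyr::filter(class == "petechiae")
#' @export
macule_feature_params <- function() {
  cls <- c("vascular", "petechiae", "trophic", "trauma")
  n <- c(47, 10, 10, 15)
  vals <- list(
    area          = list(c(1010.29, 1893.99), c(18.50, 5.99), c(2152.90, 1541.85), c(2133.60, 3684.09)),
    major_axis    = list(c(46.97, 48.96),     c(6.48, 1.60),  c(109.97, 54.13),    c(59.08, 63.30)),
    minor_axis    = list(c(23.76, 17.75),     c(3.88, 1.08),  c(30.67, 13.49),     c(29.85, 24.87)),
    perimeter     = list(c(143.90, 154.46),   c(15.83, 4.76), c(289.46, 116.72),   c(166.16, 173.27)),
    solidity      = list(c(72.56, 12.76),     c(88.00, 12.97), c(70.40, 11.96),    c(79.87, 9.31)),
    max_intensity = list(c(0.55, 0.18),       c(0.61, 0.14),  c(0.47, 0.16),       c(0.62, 0.13)),
    min_intensity = list(c(0.35, 0.18),       c(0.55, 0.14),  c(0.28, 0.19),       c(0.31, 0.21)),
    shi_r         = list(c(0.90, 0.06),       c(0.95, 0.03),  c(0.88, 0.07),       c(0.86, 0.08)),
    shi_g         = list(c(0.84, 0.08),       c(0.90, 0.07),  c(0.84, 0.09),       c(0.74, 0.14)),
    shi_b         = list(c(0.82, 0.11),       c(0.87, 0.09),  c(0.84, 0.08),       c(0.68, 0.15)),
    shi_br        = list(c(0.87, 0.11),       c(0.92, 0.04),  c(0.87, 0.07),       c(0.79, 0.10)))
  purrr::imap_dfr(vals, function(v, f) {
    tibble::tibble(class = cls, feature = f,
                   mean = vapply(v, `[`, double(1), 1),
                   sd = vapply(v, `[`, double(1), 2),
                   n = n)
  }) |> dplyr::arrange(match(class, cls), match(feature, feature_names()))
}

#' Nominal skin-tone palette of the scene generator
#'
#' Six base skin tones from light to dark brown. Every tone satisfies
#' the Stage 1 hue band (hexcone hue in `[0.01, 0.1]`) and, rendered
#' over the default non-skin background, places leg chroma on the skin
#' side of the per-image dynamic Cb/Cr range.
#'
#' @return A 6 x 3 integer matrix of RGB rows, lightest first.
#' @export
skin_palette <- function() {
  matrix(c(241, 194, 177,
           224, 172, 150,
           198, 144, 118,
           172, 118,  90,
           141,  93,  70,
           105,  66,  46),
         ncol = 3, byrow = TRUE,
         dimnames = list(paste0("tone", 1:6), c("r", "g", "b")))
}

# per-type defaults for painted macules: area distribution (mean, sd,
# truncation), elongation (major/minor), boundary roughness, and the
# per-channel shade factors relative to local skin
macule_type_defaults <- function() {
  list(
    vascular  = list(area = c(1010, 600), area_range = c(50, 2500), elong = 1.3,
                     rough = 0.20, factors = c(0.90, 0.84, 0.82)),
    petechiae = list(area = c(18.5, 5.99), area_range = c(5, 60), elong = 1.67,
                     rough = 0.15, factors = c(0.95, 0.90, 0.87)),
    trophic   = list(area = c(2152.9, 1541.85), area_range = c(300, 6000), elong = 3.0,
                     rough = 0.25, factors = c(0.88, 0.84, 0.84)),
    trauma    = list(area = c(2133.6, 1800), area_range = c(150, 6000), elong = 2.0,
                     rough = 0.35, factors = c(0.86, 0.74, 0.68)))
}

#' Synthetic lower-limb scenes with ground truth
#'
#' `scene_spec()` describes a synthetic photograph: a leg-shaped skin
#' region (vertical ellipse) of one base skin tone over a non-skin
#' fabric-blue background, an optional smooth multiplicative
#' illumination gradient, additive Gaussian pixel noise, and a list of
#' macules. `macule_spec()` describes one macule: a roughened ellipse
#' of a target pixel area whose color is the local skin color scaled by
#' per-channel shade factors. `add_random_macules()` scatters macules
#' of one type inside the leg with a minimum separation.
#' `make_scene()` renders the image and returns it together with the
#' ground truth (skin mask, per-macule masks/labels/areas/factors).
#' Rendering is fully deterministic for a given spec.
#'
#' The renderer paints each macule as exactly `area` pixels: pixel
#' elliptical radii (jittered by the boundary-roughness harmonics) are
#' sorted and the `area` smallest are selected. Shade factors multiply
#' the illuminated local skin color, so the pre-noise macule/ring
#' channel ratio equals the painted factor. A macule whose pixels fall
#' outside the leg is a placement error.
#'
#' @param width,height scene size in pixels.
#' @param tone palette row index 1..6 ([skin_palette()]) or an RGB
#'   triplet.
#' @param background RGB triplet of the non-skin background.
#' @param illumination peak-to-peak amplitude of the multiplicative
#'   illumination gradient (0 = uniform lighting).
#' @param noise_sd additive Gaussian noise SD, 8-bit counts.
#' @param macules list of `macule_spec()` entries.
#' @param allow_overlap if `FALSE` (default) overlapping macules are an
#'   error.
#' @param seed integer seed; the same spec renders bit-identically.
#' @param type macule type, one of `"vascular"`, `"petechiae"`,
#'   `"trophic"`, `"trauma"`.
#' @param center `c(row, col)` macule center (1-based pixel units).
#' @param area target pixel area (`NULL` = draw from the type's
#'   reference area distribution when the spec is rendered).
#' @param elong major/minor axis ratio; `rough` boundary roughness
#'   amplitude as a fraction of the radius; `factors` per-channel
#'   `(f_r, f_g, f_b)` shade factors in `(0, 1]`.
#' @param spec a `scene_spec`.
#' @param n number of macules to place.
#' @param min_sep minimum center separation in pixels (`NULL` = derived
#'   from the expected macule radius).
#' @return `make_scene()` returns a list with `image` (an
#'   [as_rgb_image()]) and `truth`: `skin_mask`, and `macules`, a list
#'   of per-macule records (`type`, `area`, `factors`, `center`,
#'   `mask`).
#' @examples
#' spec <- scene_spec(seed = 1) |> add_random_macules(5, "petechiae")
#' scene <- make_scene(spec)
#' length(scene$truth$macules)
#' @export
scene_spec <- function(width = 150, height = 200, tone = 3,
                       background = c(70, 90, 160), illumination = 0.10,
                       noise_sd = 3, macules = list(),
                       allow_overlap = FALSE, seed = 0) {
  tone_rgb <- if (length(tone) == 1) skin_palette()[tone, ] else as.numeric(tone)
  stopifnot(length(tone_rgb) == 3, length(background) == 3,
            illumination >= 0, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 tone = unname(tone_rgb), background = unname(background),
                 illumination = illumination, noise_sd = noise_sd,
                 macules = macules, allow_overlap = allow_overlap,
                 leg_a = 0.44, leg_b = 0.30,   # leg semi-axes, fractions of H / W
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
macule_spec <- function(type, center, area = NULL, elong = NULL,
                        rough = NULL, factors = NULL) {
  defs <- macule_type_defaults()
  type <- match.arg(type, names(defs))
  d <- defs[[type]]
  factors <- if (is.null(factors)) d$factors else factors
  stopifnot(length(center) == 2, all(factors > 0), all(factors <= 1))
  structure(list(type = type, center = as.numeric(center), area = area,
                 elong = if (is.null(elong)) d$elong else elong,
                 rough = if (is.null(rough)) d$rough else rough,
                 factors = as.numeric(factors)),
            class = "macule_spec")
}

#' @rdname scene_spec
#' @export
add_random_macules <- function(spec, n, type, min_sep = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"), n >= 1)
  d <- macule_type_defaults()[[match.arg(type, names(macule_type_defaults()))]]
  exp_radius <- sqrt(d$area[1] * d$elong / pi) * (1 + d$rough)
  if (is.null(min_sep)) min_sep <- ceiling(2 * exp_radius + 4)
  H <- spec$height; W <- spec$width
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  a <- spec$leg_a * H * 0.78 - exp_radius   # inner placement ellipse
  b <- spec$leg_b * W * 0.78 - exp_radius
  if (a <= 0 || b <= 0) stop("macules too large for the leg", call. = FALSE)
  centers <- withr::with_seed(seed + 211L, {
    got <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(got) < n && tries < 20000) {
      tries <- tries + 1
      u <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      cand <- c(cr + a * u * sin(th), cc + b * u * cos(th))
      if (nrow(got) == 0 ||
          min(sqrt(rowSums(sweep(got, 2, cand)^2))) >= min_sep) {
        got <- rbind(got, cand)
      }
    }
    if (nrow(got) < n) stop("could not place ", n, " macules with separation ",
                            min_sep, call. = FALSE)
    got
  })
  spec$macules <- c(spec$macules, lapply(seq_len(n), function(i) {
    macule_spec(type, center = centers[i, ])
  }))
  spec
}

#' @rdname scene_spec
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  withr::with_seed(spec$seed, {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    cr <- (H + 1) / 2; ccen <- (W + 1) / 2
    leg <- ((rr - cr) / (spec$leg_a * H))^2 + ((cc - ccen) / (spec$leg_b * W))^2 <= 1

    img <- array(0, dim = c(H, W, 3))
    for (k in 1:3) {
      plane <- matrix(spec$background[k], H, W)
      plane[leg] <- spec$tone[k]
      img[, , k] <- plane
    }

    if (spec$illumination > 0) {
      u <- ((rr - 1) / (H - 1) + (cc - 1) / (W - 1)) / 2
      illum <- 1 + spec$illumination * (u - 0.5)
      for (k in 1:3) img[, , k] <- img[, , k] * illum
    }

    painted <- matrix(FALSE, H, W)
    truth_mac <- list()
    for (m in spec$macules) {
      area <- m$area
      if (is.null(area)) {
        d <- macule_type_defaults()[[m$type]]
        repeat {
          area <- stats::rnorm(1, d$area[1], d$area[2])
          if (area >= d$area_range[1] && area <= d$area_range[2]) break
        }
        area <- round(area)
      }
      px <- render_macule_pixels(m, area, H, W)
      sel <- matrix(FALSE, H, W)
      sel[px] <- TRUE
      if (any(sel & !leg)) {
        stop("macule at (", m$center[1], ", ", m$center[2],
             ") extends outside the leg", call. = FALSE)
      }
      if (!spec$allow_overlap && any(sel & painted)) {
        stop("macules overlap at (", m$center[1], ", ", m$center[2], ")",
             call. = FALSE)
      }
      for (k in 1:3) {
        plane <- img[, , k]
        plane[sel] <- plane[sel] * m$factors[k]
        img[, , k] <- plane
      }
      painted <- painted | sel
      truth_mac[[length(truth_mac) + 1L]] <-
        list(type = m$type, area = sum(sel), factors = m$factors,
             center = m$center, mask = sel)
    }

    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 255)

    list(image = as_rgb_image(img),
         truth = list(skin_mask = leg, macules = truth_mac))
  })
}

# pixel indices (n x 2, 1-based) of a roughened ellipse of exactly `area`
# pixels; consumes RNG for orientation and boundary harmonics
render_macule_pixels <- function(m, area, H, W) {
  a <- sqrt(area * m$elong / pi)
  b <- sqrt(area / (m$elong * pi))
  theta <- stats::runif(1, 0, pi)
  rad <- ceiling(a * (1 + m$rough) * 1.6 + 2)
  r0 <- round(m$center[1]); c0 <- round(m$center[2])
  rs <- max(1, r0 - rad):min(H, r0 + rad)
  cs <- max(1, c0 - rad):min(W, c0 + rad)
  dr <- matrix(rs - m$center[1], length(rs), length(cs))
  dc <- matrix(cs - m$center[2], length(rs), length(cs), byrow = TRUE)
  xr <- (dr * cos(theta) + dc * sin(theta)) / a
  yr <- (-dr * sin(theta) + dc * cos(theta)) / b
  R <- sqrt(xr^2 + yr^2)
  if (m$rough > 0) {
    k <- 2:4
    amp <- stats::runif(3); amp <- amp / sum(amp)
    phase <- stats::runif(3, 0, 2 * pi)
    phi <- atan2(yr, xr)
    w <- Reduce(`+`, lapply(1:3, function(i) amp[i] * cos(k[i] * phi + phase[i])))
    R <- R / (1 + m$rough * w)
  }
  ord <- order(R)[seq_len(min(area, length(R)))]
  cbind(rs[((ord - 1L) %% length(rs)) + 1L],
        cs[((ord - 1L) %/% length(rs)) + 1L])
}

#' Sample labeled feature vectors from the reference distributions
#'
#' Draws `n_per_class` eleven-feature vectors for each macule class
#' from independent Gaussians with the per-class means and SDs of
#' [macule_feature_params()], truncated to validity: `area >= 1`, axes
#' and perimeter positive with `major_axis >= minor_axis`, solidity in
#' `(0, 100]`, intensities in `[0, 1]` with
#' `min_intensity <= max_intensity`, Shade Indices positive. Truncation
#' and ordering are enforced by resampling. Features are drawn
#' independently within a class: between-feature correlations of real
#' macules are not represented.
#'
#' @param n_per_class vectors per class (>= 1).
#' @param seed integer seed; a fixed seed reproduces the table exactly.
#' @param classes subset of classes to sample (default all four).
#' @return tibble with the 11 [feature_names()] columns and `class`.
#' @examples
#' sample_feature_vectors(2, seed = 1)
#' @export
sample_feature_vectors <- function(n_per_class, seed = 0,
                                   classes = c("vascular", "petechiae",
                                               "trophic", "trauma")) {
  stopifnot(n_per_class >= 1)
  params <- macule_feature_params()
  withr::with_seed(seed, {
    purrr::map_dfr(classes, function(cl) {
      p <- dplyr::filter(params, class == cl)
      get <- function(f) p$mean[p$feature == f] + p$sd[p$feature == f] *
        stats::rnorm(n_per_class)
      draw_trunc <- function(f, lo, hi) {
        x <- get(f)
        bad <- x < lo | x > hi
        while (any(bad)) {
          x[bad] <- get(f)[bad]
          bad <- x < lo | x > hi
        }
        x
      }
      area <- draw_trunc("area", 1, Inf)
      major <- draw_trunc("major_axis", 1e-6, Inf)
      minor <- draw_trunc("minor_axis", 1e-6, Inf)
      swap <- minor > major   # enforce axis ordering
      if (any(swap)) { tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp }
      mx <- draw_trunc("max_intensity", 0, 1)
      mn <- draw_trunc("min_intensity", 0, 1)
      bad <- mn > mx
      while (any(bad)) {
        mx[bad] <- draw_trunc("max_intensity", 0, 1)[bad]
        mn[bad] <- draw_trunc("min_intensity", 0, 1)[bad]
        bad <- mn > mx
      }
      tibble::tibble(
        area = area, major_axis = major, minor_axis = minor,
        perimeter = draw_trunc("perimeter", 1e-6, Inf),
        solidity = draw_trunc("solidity", 1e-6, 100),
        max_intensity = mx, min_intensity = mn,
        shi_r = draw_trunc("shi_r", 1e-6, Inf),
        shi_g = draw_trunc("shi_g", 1e-6, Inf),
        shi_b = draw_trunc("shi_b", 1e-6, Inf),
        shi_br = draw_trunc("shi_br", 1e-6, Inf),
        class = cl)
    }) |> as_macule_features()
  })
}

#' Match detected macule regions to ground-truth macules
#'
#' A detected region matches a true macule when more than half of its
#' pixels lie inside that macule's ground-truth mask. Used to separate
#' genuinely detected macules from noise clusters when measuring
#' feature recovery on synthetic scenes.
#'
#' @param regions list of `macule_region` from [label_macules()].
#' @param truth the `truth` element of a [make_scene()] result.
#' @return integer vector, one entry per region: index of the matching
#'   true macule, or `NA` if none claims a majority of the pixels.
#' @export
match_macules <- function(regions, truth) {
  vapply(regions, function(reg) {
    idx <- reg$pixels[, "row"] + 1L + reg$pixels[, "col"] * nrow(truth$skin_mask)
    ov <- vapply(truth$macules, function(m) mean(m$mask[idx]), double(1))
    if (length(ov) && max(ov) > 0.5) which.max(ov) else NA_integer_
  }, integer(1))
}

as_macule_features <- function(x) {
  class(x) <- unique(c("macule_features", class(x)))
  x
}
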