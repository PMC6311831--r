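# programmatic fixtures shared across test files

# single-pixel image from an RGB triplet
px_img <- function(r, g, b) as_rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))

# H x W image of one flat color
flat_img <- function(rgb, h = 8, w = 8) {
  as_rgb_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

# n random RGB colors as an n x 1 image (continuous values exercise
# the transforms away from the 8-bit lattice)
random_colors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    as_rgb_image(array(stats::runif(n * 3, 0, 255), dim = c(n, 1, 3)))
  })
}

# cached default scenes (rendering is deterministic, caching is safe)
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key, spec_fun) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- make_scene(spec_fun())
  .scene_cache[[key]]
}

plain_scene <- function() cached_scene("plain", function() scene_spec(seed = 0))

petechiae_scene <- function() {
  cached_scene("petechiae", function() {
    scene_spec(seed = 11, illumination = 0) |> add_random_macules(12, "petechiae")
  })
}

mixed_scene <- function() {
  cached_scene("mixed", function() {
    scene_spec(seed = 21, illumination = 0) |>
      add_random_macules(4, "petechiae") |>
      add_random_macules(1, "vascular")
  })
}

# macule region built directly from a pixel-coordinate matrix (0-based)
region_from_pixels <- function(pixels, ring = NULL) {
  structure(list(label = 1L, pixels = pixels,
                 ring = if (is.null(ring)) matrix(integer(0), 0, 2,
                                                  dimnames = list(NULL, c("row", "col")))
                        else ring),
            class = "macule_region")
}
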