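test_that("labeling splits components, filters small ones, and is 8-connected", {
  lesion <- matrix(FALSE, 20, 20)
  lesion[2:4, 2:4] <- TRUE
  lesion[10:12, 10:12] <- TRUE
  skin <- matrix(TRUE, 20, 20)
  regs <- label_macules(lesion, skin, min_area = 5)
  expect_length(regs, 2)
  expect_equal(vapply(regs, function(r) nrow(r$pixels), integer(1)), c(9L, 9L))

  # a 2-px speck is dropped at min_area = 5
  speck <- matrix(FALSE, 20, 20); speck[5, 5:6] <- TRUE
  expect_length(label_macules(speck, skin, min_area = 5), 0)

  # diagonal touch merges under 8-connectivity
  diagm <- matrix(FALSE, 10, 10)
  diagm[cbind(2:5, 2:5)] <- TRUE; diagm[cbind(2:5, 3:6)] <- TRUE
  expect_length(label_macules(diagm, skin[1:10, 1:10], min_area = 1), 1)
})

test_that("healthy ring excludes lesion pixels and clips to skin", {
  lesion <- matrix(FALSE, 20, 20); lesion[8:11, 1:4] <- TRUE  # touches border
  skin <- matrix(FALSE, 20, 20); skin[4:16, 1:10] <- TRUE
  regs <- label_macules(lesion, skin, min_area = 5, ring_width = 3)
  ring <- regs[[1]]$ring
  expect_gt(nrow(ring), 0)
  ring_idx <- ring[, "row"] + 1L + ring[, "col"] * 20L
  expect_true(all(skin[ring_idx]))
  expect_false(any(lesion[ring_idx]))
  # ring within the dilation distance of the component
  expect_true(all(ring[, "row"] >= 7 - 3 & ring[, "row"] <= 10 + 3))
})

test_that("morphologic features match hand-computed shapes", {
  single <- region_from_pixels(cbind(row = 5L, col = 5L))
  m1 <- morph_features(single)
  expect_equal(m1$area, 1)
  expect_equal(m1$solidity, 100)
  expect_equal(m1$perimeter, 4)
  expect_equal(m1$major_axis, m1$minor_axis)

  sq <- expand.grid(row = 0:9, col = 0:9)
  m2 <- morph_features(region_from_pixels(cbind(row = sq$row, col = sq$col)))
  expect_equal(m2$area, 100)
  expect_equal(m2$solidity, 100)
  expect_equal(m2$major_axis, m2$minor_axis)
  expect_equal(m2$perimeter, 40)

  # plus-sign pentomino: corner hull area 7 by hand => solidity 500/7
  plus <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, 2), c(2, 1))
  m3 <- morph_features(region_from_pixels(cbind(row = plus[, 1], col = plus[, 2])))
  expect_equal(m3$area, 5)
  expect_equal(m3$solidity, 500 / 7, tolerance = 1e-9)
})

test_that("solidity of convex regions is 100 within hull-discretization tolerance", {
  # axis-aligned convex regions: the pixel union equals its hull exactly
  for (dims in list(c(1, 1), c(3, 12), c(10, 10))) {
    g <- expand.grid(row = seq_len(dims[1]) - 1L, col = seq_len(dims[2]) - 1L)
    m <- morph_features(region_from_pixels(cbind(row = g$row, col = g$col)))
    expect_equal(m$solidity, 100)
  }
  # a discretized disc converges to 100 as the boundary-jaggedness share
  # of the corner hull shrinks (~1/r): within 2% at r = 50
  r <- 50
  g <- expand.grid(row = -r:r, col = -r:r)
  g <- g[g$row^2 + g$col^2 <= r^2, ]
  m <- morph_features(region_from_pixels(cbind(row = g$row + r, col = g$col + r)))
  expect_gte(m$solidity, 98)
  expect_lte(m$solidity, 100)
})

test_that("intensity features are order statistics of the grayscale", {
  gray <- matrix(0, 10, 10)
  reg <- region_from_pixels(cbind(row = c(2L, 3L), col = c(2L, 2L)))
  gray[3, 3] <- 0    # unused pixel
  gray[2 + 1, 2 + 1] <- 0  # 0-based coords map to [row+1, col+1]
  gray[3, 3] <- 0.28; gray[4, 3] <- 0.47
  f <- intensity_features(reg, gray)
  expect_equal(f$max_intensity, 0.47)
  expect_equal(f$min_intensity, 0.28)

  const <- region_from_pixels(cbind(row = 0:2, col = rep(0L, 3)))
  g2 <- matrix(0.4, 10, 10)
  expect_equal(intensity_features(const, g2),
               list(max_intensity = 0.4, min_intensity = 0.4))

  # adding a pixel never shrinks the range
  reg3 <- region_from_pixels(cbind(row = c(2L, 3L, 4L), col = c(2L, 2L, 2L)))
  gray[5, 3] <- 0.9
  f3 <- intensity_features(reg3, gray)
  expect_gte(f3$max_intensity, f$max_intensity)
  expect_lte(f3$min_intensity, f$min_intensity)
})

test_that("shade indices are channel-mean ratios against the ring", {
  img <- array(0, dim = c(10, 10, 3))
  mac <- cbind(row = rep(2:3, each = 2), col = rep(2:3, 2))
  ring <- cbind(row = rep(5:6, each = 2), col = rep(5:6, 2))
  set_px <- function(arr, coords, k, v) {
    arr[coords[, 1] + 1 + coords[, 2] * 10 + (k - 1) * 100] <- v
    arr
  }
  img <- set_px(img, mac, 1, 80);  img <- set_px(img, mac, 2, 50)
  img <- set_px(img, mac, 3, 40)
  img <- set_px(img, ring, 1, 100); img <- set_px(img, ring, 2, 60)
  img <- set_px(img, ring, 3, 60)
  reg <- region_from_pixels(mac, ring)
  s <- shade_indices(reg, as_rgb_image(img))
  expect_equal(s$shi_r, 0.80)
  expect_equal(s$shi_g, 50 / 60)
  expect_equal(s$shi_b, 40 / 60)
  expect_equal(s$shi_br, (80 + 40) / (100 + 60))   # = 0.75

  # identity macule: all indices exactly 1
  img_id <- set_px(set_px(set_px(img, mac, 1, 100), mac, 2, 60), mac, 3, 60)
  s_id <- shade_indices(reg, as_rgb_image(img_id))
  expect_equal(unlist(s_id), c(shi_r = 1, shi_g = 1, shi_b = 1, shi_br = 1))

  # invariance to a global multiplicative illumination change
  s_dim <- shade_indices(reg, as_rgb_image(unclass(img) * 0.6))
  expect_equal(unlist(s_dim), unlist(s), tolerance = 1e-12)

  expect_error(shade_indices(region_from_pixels(mac), as_rgb_image(img)), "ring")
})

test_that("characterize returns one ordered feature row per macule", {
  sc <- mixed_scene()
  skin <- segment_skin(sc$image)
  les <- segment_lesions(sc$image, skin)
  feats <- characterize(sc$image, les$gray, les$mask, skin)
  expect_true(all(c("label", "centroid_row", "centroid_col",
                    feature_names()) %in% names(feats)))
  expect_gte(nrow(feats), length(sc$truth$macules))

  # determinism
  feats2 <- characterize(sc$image, les$gray, les$mask, skin)
  expect_identical(feats, feats2)

  # empty lesion mask: empty table with the full schema
  empty <- characterize(sc$image, les$gray,
                        matrix(FALSE, nrow(skin), ncol(skin)), skin)
  expect_equal(nrow(empty), 0)
  expect_true(all(feature_names() %in% names(empty)))
})

test_that("painted shade factors are recovered through the full pipeline", {
  sc <- petechiae_scene()
  skin <- segment_skin(sc$image)
  les <- segment_lesions(sc$image, skin)
  cfg <- pipeline_config()
  regs <- label_macules(les$mask, skin, cfg$min_area, cfg$ring_width)
  feats <- characterize(sc$image, les$gray, les$mask, skin, cfg)
  match <- match_macules(regs, sc$truth)
  matched <- feats[!is.na(match), ]
  expect_gte(nrow(matched), 10)
  target <- sc$truth$macules[[1]]$factors
  big <- matched$area >= 30
  shi <- matched[, c("shi_r", "shi_g", "shi_b")]
  err <- abs(sweep(as.matrix(shi), 2, target))
  # per-region recovery for large regions; mean recovery overall
  if (any(big)) expect_lt(max(err[big, ]), 0.05)
  expect_lt(max(abs(colMeans(as.matrix(shi)) - target)), 0.05)
})
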