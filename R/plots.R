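#' Visual summaries of pipeline results
#'
#' `plot_scene()` shows an RGB image (optionally with mask outlines)
#' using base raster graphics; `plot_mask()` shows a binary mask.
#' `autoplot()` methods cover the tabular results: feature tables
#' (per-class feature distributions) and fitted classifiers (confusion
#' matrix).
#'
#' @param img an [as_rgb_image()] array.
#' @param skin,lesion optional masks overlaid as tinted regions.
#' @param mask a logical matrix.
#' @param main plot title.
#' @param object a feature tibble from [characterize()] /
#'   [sample_feature_vectors()] (with a `class` column) or a
#'   `"macule_net"`.
#' @param ... unused.
#' @return `autoplot()` methods return a ggplot object.
#' @export
plot_scene <- function(img, skin = NULL, lesion = NULL, main = "") {
  img <- unclass(as_rgb_image(img)) / 255
  if (!is.null(skin)) {
    edge <- skin & !erode_once(skin)
    img[, , 1][edge] <- 0; img[, , 2][edge] <- 1; img[, , 3][edge] <- 0
  }
  if (!is.null(lesion)) {
    img[, , 1][lesion] <- 1; img[, , 2][lesion] <- 0; img[, , 3][lesion] <- 1
  }
  op <- graphics::par(mar = c(0.5, 0.5, if (nzchar(main)) 2 else 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, ncol(img)), c(0, nrow(img)), asp = 1)
  graphics::rasterImage(img, 0, 0, ncol(img), nrow(img))
  if (nzchar(main)) graphics::title(main)
  invisible(NULL)
}

erode_once <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  p[1:H, 2:(W + 1)] & p[3:(H + 2), 2:(W + 1)] &
    p[2:(H + 1), 1:W] & p[2:(H + 1), 3:(W + 2)] & m
}

#' @rdname plot_scene
#' @export
plot_mask <- function(mask, main = "") {
  img <- array(rep(mask * 1, 3), dim = c(dim(mask), 3))
  plot_scene(as_rgb_image(img * 255), main = main)
}

#' @rdname plot_scene
#' @export
autoplot.macule_features <- function(object, ...) {
  stopifnot("class" %in% names(object))
  long <- tidyr::pivot_longer(object, dplyr::any_of(feature_names()),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Macule feature distributions by class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scene
#' @export
autoplot.macule_net <- function(object, ...) {
  conf <- as.data.frame(object$report$confusion)
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$Freq)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2b8cbe") +
    ggplot2::labs(title = sprintf("Held-out confusion matrix (accuracy %.1f%%)",
                                  object$report$accuracy),
                  x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}
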