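#' Per-feature t-test comparison between macule classes
#'
#' For every unordered pair of macule classes and every one of the 11
#' features, a two-sided two-sample Student's t-test with pooled
#' variance is computed (Welch's unequal-variance form available via
#' `var_equal = FALSE`). No multiple-testing correction is applied; the
#' significance flag is simply `p < alpha`.
#'
#' Degenerate inputs are resolved explicitly: when both groups are
#' constant and equal the test is reported as `t = 0, p = 1`; when both
#' are constant but different, `t = +/-Inf, p = 0`.
#'
#' @param features tibble with the 11 [feature_names()] columns and a
#'   `class` column.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance Student's test if `TRUE` (default),
#'   Welch otherwise.
#' @return A tibble with one row per feature x class pair: `feature`,
#'   `group1`, `group2`, `n1`, `n2`, `statistic` (t), `df`, `p_value`,
#'   `significant`. Pairs where either class has fewer than 2 examples
#'   are skipped with a warning.
#' @examples
#' feats <- sample_feature_vectors(10, seed = 7)
#' cmp <- compare_groups(feats)
#' dplyr::filter(cmp, feature == "area")
#' @export
compare_groups <- function(features, alpha = 0.05, var_equal = TRUE) {
  features <- tibble::as_tibble(features)
  stopifnot("class" %in% names(features))
  cls <- factor(features$class)
  counts <- table(cls)
  usable <- names(counts)[counts >= 2]
  if (length(usable) < length(counts)) {
    warning("skipping classes with < 2 examples: ",
            paste(setdiff(names(counts), usable), collapse = ", "))
  }
  if (length(usable) < 2) stop("need at least two classes with >= 2 examples",
                               call. = FALSE)
  pairs <- utils::combn(usable, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(feature_names(), function(f) {
      x <- features[[f]][cls == pr[1]]
      y <- features[[f]][cls == pr[2]]
      res <- safe_t_test(x, y, var_equal)
      tibble::tibble(feature = f, group1 = pr[1], group2 = pr[2],
                     n1 = length(x), n2 = length(y),
                     statistic = res$statistic, df = res$df,
                     p_value = res$p_value,
                     significant = res$p_value < alpha)
    })
  })
  structure(out, class = c("macuseg_comparison", class(out)))
}

safe_t_test <- function(x, y, var_equal) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) return(list(statistic = 0, df = df, p_value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' @rdname compare_groups
#' @param object a `compare_groups()` result.
#' @param ... unused.
#' @export
autoplot.macuseg_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = paste(.data$group1, "vs", .data$group2),
                               y = .data$feature, fill = .data$p_value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_gradient(low = "#67000d", high = "#fee8c8",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "p value",
                  title = "Feature differences between macule classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
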