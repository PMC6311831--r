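#' Measure feature recovery for painted macules through the full pipeline
#'
#' Renders uniform-lighting synthetic legs carrying macules of one
#' type, runs skin segmentation, lesion segmentation and
#' characterization at the given configuration, matches detected
#' regions to the ground truth ([match_macules()]), and returns the
#' measured features of the matched regions together with the painted
#' truth. This is the harness behind the shade-index and area recovery
#' checks.
#'
#' @param type macule type to paint (default `"petechiae"`).
#' @param n_scenes number of scenes; `per_scene` macules per scene.
#' @param seed base seed; scene seeds and tones are derived from it.
#' @param config a [pipeline_config()].
#' @return tibble: one row per detected-and-matched macule with the 11
#'   measured features plus `true_area`, `true_f_r`, `true_f_g`,
#'   `true_f_b`, `scene` and `n_painted` (total macules painted, for
#'   computing detection rates).
#' @export
measure_macule_recovery <- function(type = "petechiae", n_scenes = 3,
                                    per_scene = 12, seed = 0,
                                    config = pipeline_config()) {
  tones <- 2:4
  n_painted <- 0L
  rows <- purrr::map_dfr(seq_len(n_scenes), function(i) {
    spec <- scene_spec(seed = seed + i * 1000L, illumination = 0,
                       tone = tones[(i - 1L) %% length(tones) + 1L]) |>
      add_random_macules(per_scene, type)
    sc <- make_scene(spec)
    n_painted <<- n_painted + length(sc$truth$macules)
    skin <- segment_skin(sc$image, config)
    les <- segment_lesions(sc$image, skin, config)
    regs <- label_macules(les$mask, skin, config$min_area, config$ring_width)
    feats <- characterize(sc$image, les$gray, les$mask, skin, config)
    hit <- match_macules(regs, sc$truth)
    keep <- which(!is.na(hit))
    if (length(keep) == 0) return(NULL)
    truth <- sc$truth$macules[hit[keep]]
    dplyr::mutate(feats[keep, ],
                  true_area = vapply(truth, `[[`, double(1), "area"),
                  true_f_r = vapply(truth, function(m) m$factors[1], double(1)),
                  true_f_g = vapply(truth, function(m) m$factors[2], double(1)),
                  true_f_b = vapply(truth, function(m) m$factors[3], double(1)),
                  scene = i)
  })
  rows$n_painted <- n_painted
  rows
}
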