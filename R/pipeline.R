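#' Pipeline configuration and the end-to-end run
#'
#' `pipeline_config()` gathers every stage parameter with its default:
#' the Stage 1 hue band `[0.01, 0.1]` and cleanup settings, the Stage 2
#' luminosity-stretch percentiles and 10% lesion fraction, the Stage 3
#' labeling parameters, and the classifier train split (60/40).
#' Configurations serialize to JSON and round-trip exactly
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' `run_pipeline()` chains the three stages on one photograph and
#' writes a report bundle to `outdir`: `skin_mask.png`,
#' `lesion_mask.png`, `features.csv` (one row per macule: label,
#' centroid, the eleven features, and — when a trained model is given —
#' the predicted class), and `report.json` with the damage percentage
#' and every auto-tuned threshold (dynamic chroma range, grayscale
#' threshold interval) so the self-tuning behavior is auditable.
#' Coordinates in outputs are 0-based `(row, col)`; masks are written
#' as 8-bit 0/255 PNG.
#'
#' @param hue_lo,hue_hi Stage 1 hue band (closed interval, fractions).
#' @param exclude_black drop exact-black pixels from the dynamic-range
#'   statistics.
#' @param close_radius,min_object_frac Stage 1 cleanup: closing radius
#'   in pixels and minimum object size as a fraction of image area.
#' @param stretch_lo,stretch_hi Stage 2 luminosity-stretch percentiles.
#' @param lesion_fraction Stage 2 dark-tail fraction (default 0.10).
#' @param min_area,ring_width Stage 3 labeling parameters, pixels.
#' @param train_split classifier train fraction (default 0.60).
#' @param config a `pipeline_config` list; `path` a JSON file path.
#' @param image path of the input photograph (PNG/JPEG/TIFF) or an
#'   [as_rgb_image()] array.
#' @param model optional `"macule_net"` from [train_network()].
#' @param outdir output directory, created if missing.
#' @return `run_pipeline()` (invisibly) returns a list with `skin`,
#'   `lesion`, `gray`, `features`, `damage_percent`, `threshold`, and
#'   the paths written.
#' @examples
#' scene <- make_scene(scene_spec(seed = 5) |> add_random_macules(3, "vascular"))
#' out <- run_pipeline(scene$image, outdir = tempfile("bundle"))
#' out$damage_percent
#' @export
pipeline_config <- function(hue_lo = 0.01, hue_hi = 0.1,
                            exclude_black = FALSE,
                            close_radius = 5, min_object_frac = 0.001,
                            stretch_lo = 2, stretch_hi = 98,
                            lesion_fraction = 0.10,
                            min_area = 5, ring_width = 5,
                            train_split = 0.60) {
  stopifnot(hue_lo >= 0, hue_lo < hue_hi, hue_hi <= 1,
            lesion_fraction > 0, lesion_fraction < 1,
            train_split > 0, train_split < 1)
  list(hue_lo = as.numeric(hue_lo), hue_hi = as.numeric(hue_hi),
       exclude_black = isTRUE(exclude_black),
       close_radius = as.numeric(close_radius),
       min_object_frac = as.numeric(min_object_frac),
       stretch_lo = as.numeric(stretch_lo), stretch_hi = as.numeric(stretch_hi),
       lesion_fraction = as.numeric(lesion_fraction),
       min_area = as.numeric(min_area), ring_width = as.numeric(ring_width),
       train_split = as.numeric(train_split))
}

#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @export
run_pipeline <- function(image, config = pipeline_config(), model = NULL,
                         outdir = NULL) {
  img <- if (is.character(image)) read_skin_image(image) else as_rgb_image(image)

  skin <- segment_skin(img, config)
  if (!any(skin)) {
    warning("no skin region found; outputs are empty")
    features <- empty_feature_tibble()
    res <- list(skin = skin, lesion = skin, gray = NULL,
                features = features, damage_percent = NA_real_,
                threshold = NULL)
  } else {
    les <- segment_lesions(img, skin, config)
    features <- characterize(img, les$gray, les$mask, skin, config)
    if (!is.null(model) && nrow(features) > 0) {
      features$predicted_class <- predict(model, features)$.pred
    }
    res <- list(skin = skin, lesion = les$mask, gray = les$gray,
                features = features, damage_percent = les$damage_percent,
                threshold = les$threshold)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      skin = file.path(outdir, "skin_mask.png"),
      lesion = file.path(outdir, "lesion_mask.png"),
      features = file.path(outdir, "features.csv"),
      report = file.path(outdir, "report.json"))
    write_mask(res$skin, paths$skin)
    write_mask(res$lesion, paths$lesion)
    utils::write.csv(res$features, paths$features, row.names = FALSE)
    jsonlite::write_json(
      list(damage_percent = res$damage_percent,
           threshold = res$threshold,
           n_macules = nrow(res$features),
           config = config),
      paths$report, auto_unbox = TRUE, digits = NA, null = "null")
    res$paths <- paths
  }
  invisible(res)
}
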