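# End-to-end pipeline and standard-format readers/writers.
#
# Stages communicate through a manifest CSV (image path, landmark path,
# tcb, label, subject id) so each stage can be re-run independently; images
# are PNG, landmarks and card geometry are JSON, features and reports are
# CSV.

log_msg <- function(level, ..., threshold = getOption("neojaundice.log_level", "INFO")) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels[[level]] >= levels[[threshold]])
    message("[", level, "] ", ...)
}

#' Write / read an image as PNG
#'
#' @param image H x W x 3 array of intensities in 0-255.
#' @param path File path.
#' @return `read_image_png()` returns an integer 0-255 array.
#' @export
write_image_png <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  out <- round_half_up(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write / read a landmark set as JSON
#'
#' The JSON holds `points` (68 `[col, row]` pairs, in the standard 0-based
#' 68-point index order), `image_height`, and `image_width`.
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @return `read_landmarks_json()` returns a [landmark_set()].
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(list(points = unname(landmarks$points),
                            image_height = landmarks$image_height,
                            image_width = landmarks$image_width),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(obj$points, obj$image_height, obj$image_width)
}

rect_to_list <- function(b) b[c("row_min", "row_max", "col_min", "col_max")]
rect_from_list <- function(l) rect_box(l$row_min, l$row_max, l$col_min, l$col_max)

#' Write / read card geometry as JSON
#'
#' @param geometry A [card_geometry()].
#' @param path File path.
#' @return `read_card_geometry_json()` returns a [card_geometry()].
#' @export
write_card_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "card_geometry"))
  jsonlite::write_json(list(
    card_bbox = rect_to_list(geometry$card_bbox),
    patch_bboxes = lapply(geometry$patch_bboxes, rect_to_list),
    patch_reference_colors = geometry$patch_reference_colors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_card_geometry_json
#' @export
read_card_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  card_geometry(rect_from_list(as.list(obj$card_bbox)),
                lapply(obj$patch_bboxes, function(b) rect_from_list(as.list(b))),
                lapply(obj$patch_reference_colors, as.numeric))
}

#' Pipeline configuration
#'
#' @param output_dir Directory receiving every artifact.
#' @param n Cohort size.
#' @param jaundiced_fraction Proportion of jaundiced subjects.
#' @param noise_sigma Pixel noise of the generated scenes.
#' @param feature_sets Feature sets to evaluate.
#' @param models Traditional models to evaluate.
#' @param k Cross-validation folds.
#' @param alpha Significance level of the paired tests.
#' @param seed Master seed; every stochastic choice across stages derives
#'   from it.
#' @param stages Stage toggles, subset of
#'   `c("simulate", "calibrate", "segment", "featurize", "evaluate")`.
#' @param log_level `"DEBUG"`, `"INFO"`, or `"WARN"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, n = 68L, jaundiced_fraction = 24 / 68,
                            noise_sigma = 5, feature_sets = c("skin", "eye", "fusion"),
                            models = c("mlp", "svm", "dt", "rf"), k = 5L,
                            alpha = 0.05, seed = 1L,
                            stages = c("simulate", "calibrate", "segment",
                                       "featurize", "evaluate"),
                            log_level = "INFO") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(output_dir = output_dir, n = as.integer(n),
                 jaundiced_fraction = jaundiced_fraction,
                 noise_sigma = noise_sigma, feature_sets = feature_sets,
                 models = models, k = as.integer(k), alpha = alpha,
                 seed = as.integer(seed), stages = stages,
                 log_level = log_level),
            class = "pipeline_config")
}

manifest_path <- function(dir) file.path(dir, "manifest.csv")

stage_simulate <- function(config) {
  dir.create(file.path(config$output_dir, "scenes"), recursive = TRUE,
             showWarnings = FALSE)
  params <- scene_params(noise_sigma = config$noise_sigma)
  scenes <- generate_cohort(config$n, config$jaundiced_fraction, params,
                            seed = config$seed)
  rows <- lapply(scenes, function(sc) {
    base <- file.path(config$output_dir, "scenes", sc$subject_id)
    write_image_png(sc$image, paste0(base, ".png"))
    write_landmarks_json(sc$landmarks, paste0(base, "_landmarks.json"))
    write_card_geometry_json(sc$params$card_geometry, paste0(base, "_card.json"))
    data.frame(subject_id = sc$subject_id,
               image = paste0(base, ".png"),
               landmarks = paste0(base, "_landmarks.json"),
               card = paste0(base, "_card.json"),
               tcb = sc$tcb, label = as.character(sc$label))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path(config$output_dir), row.names = FALSE)
  log_msg("INFO", "simulate: wrote ", nrow(manifest), " scenes")
  manifest
}

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (!file.exists(p)) stop("manifest not found: ", p, call. = FALSE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

require_file <- function(path, stage, subject) {
  if (!file.exists(path))
    stop("stage '", stage, "' failed for subject ", subject,
         ": missing file ", path, call. = FALSE)
  path
}

stage_calibrate <- function(config) {
  manifest <- read_manifest(config$output_dir)
  out_dir <- file.path(config$output_dir, "calibrated")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$calibrated <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    img <- read_image_png(require_file(manifest$image[i], "calibrate", id))
    card <- read_card_geometry_json(require_file(manifest$card[i], "calibrate", id))
    out <- file.path(out_dir, paste0(id, ".png"))
    write_image_png(calibrate_image(img, card), out)
    manifest$calibrated[i] <- out
  }
  utils::write.csv(manifest, manifest_path(config$output_dir), row.names = FALSE)
  log_msg("INFO", "calibrate: wrote ", nrow(manifest), " images")
  manifest
}

stage_segment <- function(config) {
  manifest <- read_manifest(config$output_dir)
  out_dir <- file.path(config$output_dir, "masks")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    lms <- read_landmarks_json(require_file(manifest$landmarks[i], "segment", id))
    rois <- tryCatch(segment_rois(lms), error = function(e)
      stop("stage 'segment' failed for subject ", id, ": ", conditionMessage(e),
           call. = FALSE))
    for (nm in names(rois))
      png::writePNG(rois[[nm]]$mask * 1, file.path(out_dir, paste0(id, "_", nm, ".png")))
  }
  log_msg("INFO", "segment: wrote masks for ", nrow(manifest), " subjects")
  invisible(NULL)
}

stage_featurize <- function(config) {
  manifest <- read_manifest(config$output_dir)
  if (is.null(manifest$calibrated))
    stop("featurize requires the calibrate stage to have run", call. = FALSE)
  out <- list()
  for (fs in config$feature_sets) {
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      id <- manifest$subject_id[i]
      img <- read_image_png(require_file(manifest$calibrated[i], "featurize", id))
      lms <- read_landmarks_json(require_file(manifest$landmarks[i], "featurize", id))
      skin12 <- left12 <- right12 <- NULL
      if (fs %in% c("skin", "fusion")) skin12 <- roi_color_means(img, forehead_roi(lms))
      if (fs %in% c("eye", "fusion")) {
        left12 <- roi_color_means(img, sclera_roi(lms, "left"))
        right12 <- roi_color_means(img, sclera_roi(lms, "right"))
      }
      fv <- assemble_features(skin12, left12, right12, fs)
      cbind(data.frame(subject_id = id, label = manifest$label[i]),
            as.data.frame(as.list(fv)))
    })
    df <- do.call(rbind, rows)
    path <- file.path(config$output_dir, paste0("features_", fs, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    out[[fs]] <- df
    log_msg("INFO", "featurize: wrote ", path)
  }
  out
}

stage_evaluate <- function(config) {
  features_by_set <- stats::setNames(lapply(config$feature_sets, function(fs) {
    path <- file.path(config$output_dir, paste0("features_", fs, ".csv"))
    if (!file.exists(path))
      stop("evaluate requires the featurize stage output: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$label <- as_label_factor(df$label)
    df
  }), config$feature_sets)
  configs <- stats::setNames(lapply(seq_along(config$models), function(i)
    model_config(config$models[i], seed = derive_seed(config$seed, 7000L + i))),
    config$models)
  report <- run_experiment(features_by_set, configs, k = config$k,
                           seed = config$seed, alpha = config$alpha)
  utils::write.csv(report$means, file.path(config$output_dir, "report_means.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_fold, file.path(config$output_dir, "report_per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(config$output_dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  log_msg("INFO", "evaluate: wrote report CSVs")
  report
}

#' Run the configured pipeline
#'
#' Executes the toggled stages in order
#' simulate -> calibrate -> segment -> featurize -> evaluate, writing every
#' artifact (scene PNGs and landmark/card JSON, calibrated PNGs, mask PNGs,
#' feature CSVs, report CSVs) under the output directory together with a run
#' manifest recording the seed and package version. Stage failures abort
#' with the stage name and subject id; artifacts written so far are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @return The `comparison_report` when the evaluate stage runs, otherwise
#'   `NULL`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  old <- options(neojaundice.log_level = config$log_level)
  on.exit(options(old))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- NULL
  if ("simulate" %in% config$stages) stage_simulate(config)
  if ("calibrate" %in% config$stages) stage_calibrate(config)
  if ("segment" %in% config$stages) stage_segment(config)
  if ("featurize" %in% config$stages) stage_featurize(config)
  if ("evaluate" %in% config$stages) report <- stage_evaluate(config)
  jsonlite::write_json(
    list(seed = config$seed, n = config$n,
         jaundiced_fraction = config$jaundiced_fraction,
         noise_sigma = config$noise_sigma, stages = config$stages,
         feature_sets = config$feature_sets, models = config$models,
         k = config$k, alpha = config$alpha,
         package_version = as.character(utils::packageVersion("neojaundice"))),
    file.path(config$output_dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(report)
}
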