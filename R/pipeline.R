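#' Grade one slide image with the two-stage pipeline
#'
#' Tiles the image, extracts stage-1 features, assembles the feature map on
#' the stage-2 canvas and returns the grade-group prediction.
#'
#' @param stage1,stage2 Trained models.
#' @param image `H x W x 3` array (or `synthetic_slide`).
#' @param patch_size Patch edge length in pixels.
#' @return A `grade_prediction`.
#' @export
grade_slide_image <- function(stage1, stage2, image, patch_size = 64) {
  pg <- extract_patches(image, patch_size)
  feats <- extract_features(stage1, pg$patches)
  fmap <- assemble_feature_map(feats, pg, canvas = stage2$config$canvas)
  predict_grade_group(stage2, fmap)
}

#' Grade every slide of a dataset
#'
#' @param stage1,stage2 Trained models.
#' @param dataset A `slide_dataset`.
#' @param split Optional split filter (e.g. `"validate"`).
#' @return Tibble: slide_id, split, reference, predicted, prob_benign,
#'   prob_gg1..prob_gg5.
#' @export
grade_slides <- function(stage1, stage2, dataset, split = NULL) {
  fdata <- featurize_dataset(stage1, dataset)
  idx <- seq_len(nrow(fdata$manifest))
  if (!is.null(split)) idx <- which(fdata$manifest$split %in% split)
  pred <- predict_feature_dataset(stage2, fdata, idx)
  probs <- do.call(rbind, pred$probs)
  colnames(probs) <- paste0("prob_", c("benign", paste0("gg", 1:5)))
  dplyr::bind_cols(
    tibble::tibble(slide_id = pred$slide_id,
                   split = fdata$manifest$split[idx],
                   reference = pred$reference,
                   predicted = pred$predicted),
    tibble::as_tibble(probs))
}

#' Run configuration for the end-to-end pipeline
#'
#' One auditable home for every knob: the synthetic-data section, both
#' training configurations, evaluation and mechanism settings, and the
#' global seed from which every stage derives its own seed via
#' [derive_seed()]. Serializable to/from YAML for the command-line
#' interface.
#'
#' @param seed Global integer seed.
#' @param n_slides,class_mix,grid,patch_size,separability Synthetic-data
#'   section.
#' @param stage1,stage2 Stage configurations; the global seed overrides
#'   their `seed` fields.
#' @param n_pairs,embed_n_per_class,embed_perplexity,embed_iterations
#'   Mechanism section.
#' @param out_dir Output directory for artifacts (NULL keeps everything in
#'   memory).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 0, n_slides = 160, class_mix = rep(1, 6),
                       grid = c(4, 8), patch_size = 64, separability = 1,
                       stage1 = desk_stage1_config(),
                       stage2 = desk_stage2_config(),
                       n_pairs = 5, embed_n_per_class = 200,
                       embed_perplexity = 50, embed_iterations = 1000,
                       out_dir = NULL) {
  stage1$seed <- derive_seed(seed, "stage1")
  stage2$seed <- derive_seed(seed, "stage2")
  structure(list(seed = as.integer(seed), n_slides = as.integer(n_slides),
                 class_mix = class_mix, grid = as.integer(grid),
                 patch_size = as.integer(patch_size),
                 separability = separability,
                 stage1 = stage1, stage2 = stage2,
                 n_pairs = as.integer(n_pairs),
                 embed_n_per_class = as.integer(embed_n_per_class),
                 embed_perplexity = embed_perplexity,
                 embed_iterations = as.integer(embed_iterations),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full desk-scale pipeline
#'
#' Generates the synthetic dataset, trains both stages, grades the
#' validation split and evaluates agreement. Optionally runs the two
#' mechanism analyses.
#'
#' @param config A [run_config()].
#' @param mechanism Also run the embedding and ratio-concatenation
#'   analyses.
#' @param verbose Print progress.
#' @return A `pipeline_result`: list with `dataset`, `stage1`, `stage2`,
#'   `predictions`, `evaluation`, and optionally `embedding`,
#'   `embedding_untrained`, `ratio_series`.
#' @export
run_pipeline <- function(config = run_config(), mechanism = FALSE,
                         verbose = FALSE) {
  dataset <- make_dataset(config$n_slides, config$class_mix, config$grid,
                          config$patch_size,
                          texture_params(config$separability),
                          seed = derive_seed(config$seed, "data"),
                          dir = if (!is.null(config$out_dir))
                            file.path(config$out_dir, "slides"))
  if (verbose) message("dataset: ", nrow(dataset$manifest), " slides")
  stage1 <- train_stage1(dataset, config$stage1, verbose = verbose)
  fdata <- featurize_dataset(stage1, dataset, verbose = verbose)
  stage2 <- train_stage2(fdata, config$stage2, verbose = verbose)
  idx <- which(dataset$manifest$split == "validate")
  pred <- predict_feature_dataset(stage2, fdata, idx)
  probs <- do.call(rbind, pred$probs)
  colnames(probs) <- paste0("prob_", c("benign", paste0("gg", 1:5)))
  predictions <- dplyr::bind_cols(
    tibble::tibble(slide_id = pred$slide_id, split = "validate",
                   reference = pred$reference, predicted = pred$predicted),
    tibble::as_tibble(probs))
  evaluation <- evaluate_predictions(predictions)
  out <- list(dataset = dataset, stage1 = stage1, stage2 = stage2,
              predictions = predictions, evaluation = evaluation,
              config = config)
  if (mechanism) {
    out$embedding <- embed_pattern_features(
      stage1, dataset, config$embed_n_per_class, config$embed_perplexity,
      config$embed_iterations, seed = derive_seed(config$seed, "embed"))
    untrained <- stage1
    untrained$layers <- with_seed(derive_seed(config$seed, "untrained"),
                                  build_stage1_layers(config$stage1))
    out$embedding_untrained <- embed_pattern_features(
      untrained, dataset, config$embed_n_per_class, config$embed_perplexity,
      config$embed_iterations, seed = derive_seed(config$seed, "embed"))
    out$ratio_series <- ratio_concatenation_experiment(
      stage1, stage2, dataset, config$n_pairs,
      seed = derive_seed(config$seed, "ratio"))
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$config$seed, "\n", sep = "")
  print(x$evaluation)
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The weights go into an RDS checkpoint; the configuration is additionally
#' embedded as human-readable JSON next to it (`<path>.json`).
#'
#' @param model A `stage1_model` or `stage2_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  cfg$augment <- NULL
  jsonlite::write_json(c(list(class = class(model)), unclass(cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
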