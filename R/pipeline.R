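#' Validate and normalize a pipeline configuration
#'
#' A pipeline configuration is a nested list (or JSON file) with optional
#' sections `synth`, `cohort`, `fusion`, `annotation`, `ensemble`, `eval`,
#' `temporal` and top-level `seed` and `out_dir`. Missing fields are filled
#' with defaults; unknown keys raise an error naming the field. The master
#' `seed` deterministically derives every stage's seed.
#'
#' @param config A named list, or a path to a JSON file.
#' @return A normalized list of class `pipeline_config`.
#' @export
#' @examples
#' validate_config(list())$ensemble$epochs  # 40
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file `%s` not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("`config` must be a list or a JSON file path")
  known <- c("synth", "cohort", "fusion", "annotation", "ensemble", "eval",
             "temporal", "seed", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stopf("unknown config key `%s`", bad[1])
  seed <- as.integer(config$seed %||% 1L)

  check_keys <- function(x, fn, section) {
    allowed <- names(formals(fn))
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stopf("unknown key `%s` in config section `%s`", bad[1], section)
    x
  }
  synth_args <- check_keys(config$synth %||% list(), synth_config, "synth")
  cohort <- config$cohort %||% list()
  bad <- setdiff(names(cohort), c("n_train", "n_test", "min_lag"))
  if (length(bad)) stopf("unknown key `%s` in config section `cohort`", bad[1])
  temporal <- config$temporal %||% list()
  bad <- setdiff(names(temporal), "window")
  if (length(bad)) stopf("unknown key `%s` in config section `temporal`", bad[1])
  window <- temporal$window %||% 3L
  if (window %% 2 == 0 || window < 3) stopf("`window` must be odd and >= 3")

  fusion_args <- check_keys(config$fusion %||% list(), fusion_config, "fusion")
  ann_args <- check_keys(config$annotation %||% list(), annotation_config, "annotation")
  ens_args <- check_keys(config$ensemble %||% list(), ensemble_config, "ensemble")
  eval_args <- check_keys(config$eval %||% list(), eval_config, "eval")

  ens_args$seed <- ens_args$seed %||% derive_seed(seed, "train")
  eval_args$seed <- eval_args$seed %||% derive_seed(seed, "evaluate")

  structure(list(
    synth = do.call(synth_config, synth_args),
    cohort = list(n_train = as.integer(cohort$n_train %||% 40L),
                  n_test = as.integer(cohort$n_test %||% 10L),
                  min_lag = as.integer(cohort$min_lag %||% 3L)),
    fusion = do.call(fusion_config, fusion_args),
    annotation = do.call(annotation_config, ann_args),
    ensemble = do.call(ensemble_config, ens_args),
    eval = do.call(eval_config, eval_args),
    temporal = list(window = as.integer(window)),
    seed = seed,
    out_dir = config$out_dir
  ), class = "pipeline_config")
}

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates simulate, fuse, annotate, split, train, predict, smooth,
#' call-onset and evaluate in one deterministic pass: a synthetic cohort is
#' generated and compressed embryo by embryo (each 5-D tensor is released
#' after fusion), frame labels are derived from the fluorescence cap series
#' through the annotation rules, an embryo-level split separates train and
#' test cohorts, the CNN ensemble is trained on the fused DIC frames,
#' per-frame test predictions are temporally smoothed and turned into onset
#' calls, and the frame-level and onset-timing reports are assembled.
#' Identical master seeds give identical reports.
#'
#' @param config A [validate_config()] result, raw list, or JSON path.
#' @param quiet Suppress per-stage progress lines (default `FALSE`).
#' @return A list with `frame_report` (class `eval_report`), `onset_report`
#'   (class `onset_report`), `predictions` (per-frame tibble), `onsets`
#'   (per-embryo tibble), `split` and `config`; artifacts are also written
#'   to `config$out_dir` when set.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  n_embryos <- cfg$cohort$n_train + cfg$cohort$n_test

  say("simulate+fuse", "generating and fusing %d synthetic embryos", n_embryos)
  cohort <- generate_cohort(
    n_embryos, template = cfg$synth, seed = derive_seed(cfg$seed, "simulate"),
    min_lag = cfg$cohort$min_lag,
    transform = function(e) {
      fused <- fuse_recording(e$recording, cfg$fusion)
      list(id = e$recording$id, fused = fused, truth = e$truth)
    }
  )
  ids <- vapply(cohort, `[[`, character(1), "id")

  say("annotate", "deriving frame labels from fluorescence cap fractions")
  labelled <- purrr::map(cohort, function(e) {
    onset <- annotate_polarization_onset(e$truth$cap_series, cfg$annotation)
    comp <- annotate_compaction(e$truth$angle_series, cfg$annotation)
    e$labels <- label_frames(onset, e$truth$n_frames)
    e$onset_idx <- onset
    e$compaction_idx <- comp
    e
  })

  split <- split_cohort(ids, counts = c(cfg$cohort$n_train, cfg$cohort$n_test),
                        seed = derive_seed(cfg$seed, "split"))
  say("split", "%d train / %d test embryos", length(split$train), length(split$test))

  gather <- function(which_ids) {
    sel <- labelled[ids %in% which_ids]
    list(frames = purrr::flatten(purrr::map(sel, ~ .x$fused$dic)),
         labels = unlist(purrr::map(sel, "labels")),
         embryos = sel)
  }
  train <- gather(split$train)
  test <- gather(split$test)

  say("train", "training %d members for %d epochs on %d frames",
      cfg$ensemble$n_members, cfg$ensemble$epochs, length(train$labels))
  ensemble <- train_ensemble(train$frames, train$labels, cfg$ensemble)

  say("predict", "predicting %d test frames", length(test$labels))
  preds <- ensemble_predict(ensemble, test$frames)
  predictions <- dplyr::bind_cols(
    tibble(
      recording_id = rep(vapply(test$embryos, `[[`, character(1), "id"),
                         vapply(test$embryos, function(e) e$truth$n_frames, integer(1))),
      frame_index = unlist(purrr::map(test$embryos,
                                      ~ seq_len(.x$truth$n_frames) - 1L)),
      truth = test$labels
    ),
    preds
  )

  say("smooth", "temporal smoothing (window %d) and onset calling",
      cfg$temporal$window)
  onsets <- purrr::map_dfr(test$embryos, function(e) {
    p <- predictions[predictions$recording_id == e$id, ]
    smoothed <- smooth_labels(p$label, cfg$temporal$window)
    tibble(
      id = e$id,
      pred_idx = call_onset(smoothed),
      proxy_idx = e$compaction_idx,
      true_idx = e$onset_idx,
      frame_interval_s = e$truth$frame_interval_s,
      n_frames = e$truth$n_frames
    )
  })

  say("evaluate", "frame metrics (B = %d bootstrap) and onset discrepancies",
      cfg$eval$n_bootstrap)
  frame_report <- evaluate_frames(predictions$label, predictions$truth,
                                  scores = predictions$p_after, cfg = cfg$eval)
  onset_report <- evaluate_onsets(onsets, cfg = cfg$eval)

  result <- list(frame_report = frame_report, onset_report = onset_report,
                 predictions = predictions, onsets = onsets, split = split,
                 config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(result, cfg$out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  readr::write_csv(result$onsets, file.path(out_dir, "onsets.csv"))
  labs <- dplyr::transmute(
    result$predictions,
    recording_id = .data$recording_id, frame_index = .data$frame_index,
    label = ifelse(.data$truth == 1, "after", "before"))
  write_labels(labs, file.path(out_dir, "labels.csv"))
  report <- list(
    n_frames = result$frame_report$n_frames,
    confusion = as.list(result$frame_report$confusion),
    metrics = result$frame_report$metrics,
    auc = result$frame_report$auc,
    onset = list(
      mae_model_s = result$onset_report$mae_model_s,
      mae_proxy_s = result$onset_report$mae_proxy_s,
      within_one_frame = result$onset_report$within_one_frame,
      wilcoxon = as.list(result$onset_report$wilcoxon),
      pearson_rho = result$onset_report$pearson_rho
    ),
    split = result$split,
    seed = result$config$seed
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
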