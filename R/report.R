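#' Frame-level evaluation report
#'
#' Computes the full frame-level protocol: confusion counts, accuracy,
#' sensitivity and specificity with percentile-bootstrap confidence
#' intervals (resampling frames, the analysis unit), and the ROC curve with
#' its AUC (bootstrap CI as well). The positive class is after-onset.
#'
#' @param pred 0/1 predicted labels.
#' @param truth 0/1 annotated labels.
#' @param scores Optional after-onset scores (ensemble mean probabilities)
#'   for the ROC; when `NULL` the ROC/AUC entries are omitted.
#' @param cfg An [eval_config()].
#' @return An object of class `eval_report`.
#' @export
evaluate_frames <- function(pred, truth, scores = NULL, cfg = eval_config()) {
  conf <- confusion_metrics(pred, truth)
  idx <- seq_along(pred)
  boot_metric <- function(stat_fn, stage) {
    bootstrap_ci(idx, statistic = stat_fn,
                 cfg = eval_config(cfg$n_bootstrap, cfg$level,
                                   derive_seed(cfg$seed, stage)))
  }
  acc_ci <- boot_metric(function(i) mean(pred[i] == truth[i]), "acc")
  sens_ci <- boot_metric(function(i) {
    p <- pred[i]; tr <- truth[i]
    if (!any(tr == 1)) return(NA_real_)
    mean(p[tr == 1] == 1)
  }, "sens")
  spec_ci <- boot_metric(function(i) {
    p <- pred[i]; tr <- truth[i]
    if (!any(tr == 0)) return(NA_real_)
    mean(p[tr == 0] == 0)
  }, "spec")
  metrics <- tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    value = c(conf$accuracy, conf$sensitivity, conf$specificity),
    ci_lower = c(acc_ci[1], sens_ci[1], spec_ci[1]),
    ci_upper = c(acc_ci[2], sens_ci[2], spec_ci[2])
  )
  roc <- NULL; auc <- NA_real_; auc_ci <- c(NA_real_, NA_real_)
  if (!is.null(scores)) {
    rr <- roc_auc(scores, truth)
    roc <- rr$curve; auc <- rr$auc
    auc_ci <- bootstrap_ci(idx, statistic = function(i) {
      tr <- truth[i]
      if (length(unique(tr)) < 2) return(NA_real_)
      roc_auc(scores[i], tr)$auc
    }, cfg = eval_config(cfg$n_bootstrap, cfg$level, derive_seed(cfg$seed, "auc")))
    metrics <- dplyr::bind_rows(metrics, tibble(
      metric = "auc", value = auc, ci_lower = auc_ci[1], ci_upper = auc_ci[2]
    ))
  }
  # consistency check, logged rather than fatal (percentile intervals can
  # rarely exclude the point estimate)
  bad <- with(metrics, which(is.finite(value) & (value < ci_lower | value > ci_upper)))
  if (length(bad)) {
    warn(sprintf("point estimate outside bootstrap interval for: %s",
                 paste(metrics$metric[bad], collapse = ", ")))
  }
  structure(
    list(confusion = conf, metrics = metrics, roc = roc, auc = auc,
         n_frames = conf$n, cfg = cfg),
    class = "eval_report"
  )
}

#' Onset-timing evaluation report
#'
#' Per-embryo signed time discrepancies for the model and for the
#' compaction proxy, the two-sided Wilcoxon matched-pairs signed-rank test
#' on their absolute values, and the Pearson correlation between the
#' model's predicted onset index and the compaction index.
#'
#' @param onsets A tibble with one row per test embryo and columns `id`,
#'   `pred_idx` (model onset, `NA` allowed), `proxy_idx` (compaction onset,
#'   `NA` allowed), `true_idx`, `frame_interval_s`, `n_frames`.
#' @param cfg An [eval_config()].
#' @return A list of class `onset_report` with `discrepancies` (per-embryo
#'   tibble), `wilcoxon`, `pearson_rho`, and mean absolute errors.
#' @export
evaluate_onsets <- function(onsets, cfg = eval_config()) {
  need <- c("id", "pred_idx", "proxy_idx", "true_idx",
            "frame_interval_s", "n_frames")
  if (!all(need %in% names(onsets))) {
    stopf("`onsets` must have columns %s", paste(need, collapse = ", "))
  }
  disc <- purrr::pmap_dfr(onsets, function(id, pred_idx, proxy_idx, true_idx,
                                           frame_interval_s, n_frames, ...) {
    tibble(
      id = id,
      model_s = time_discrepancy(pred_idx, true_idx, frame_interval_s, n_frames),
      proxy_s = time_discrepancy(proxy_idx, true_idx, frame_interval_s, n_frames),
      model_frames = (if (is.na(pred_idx)) n_frames else pred_idx) - true_idx,
      proxy_frames = (if (is.na(proxy_idx)) n_frames else proxy_idx) - true_idx
    )
  })
  d <- abs(disc$model_s) - abs(disc$proxy_s)
  wil <- if (any(d != 0)) wilcoxon_signed_rank(d) else
    tibble(w = NA_real_, p_value = NA_real_, n = 0L, method = "degenerate")
  eff_pred <- ifelse(is.na(onsets$pred_idx), onsets$n_frames, onsets$pred_idx)
  eff_proxy <- ifelse(is.na(onsets$proxy_idx), onsets$n_frames, onsets$proxy_idx)
  rho <- if (sd(eff_pred) > 0 && sd(eff_proxy) > 0) {
    pearson_corr(eff_pred, eff_proxy)
  } else NA_real_
  structure(
    list(discrepancies = disc, wilcoxon = wil, pearson_rho = rho,
         mae_model_s = mean(abs(disc$model_s)),
         mae_proxy_s = mean(abs(disc$proxy_s)),
         within_one_frame = mean(abs(disc$model_frames) <= 1),
         cfg = cfg),
    class = "onset_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d frames>\n", x$n_frames))
  print(x$metrics)
  invisible(x)
}

#' @export
print.onset_report <- function(x, ...) {
  cat(sprintf("<onset_report: %d embryos>\n", nrow(x$discrepancies)))
  cat(sprintf("  model MAE %.0f s | proxy MAE %.0f s | within +/-1 frame %.0f%%\n",
              x$mae_model_s, x$mae_proxy_s, 100 * x$within_one_frame))
  cat(sprintf("  Wilcoxon W = %s, p = %s | Pearson rho = %.3f\n",
              format(x$wilcoxon$w), format.pval(x$wilcoxon$p_value),
              x$pearson_rho))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The metrics tibble (`metric`, `value`, `ci_lower`, `ci_upper`).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble with accuracy, sensitivity, specificity, AUC
#'   and the frame count.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    accuracy = x$confusion$accuracy,
    sensitivity = x$confusion$sensitivity,
    specificity = x$confusion$specificity,
    auc = x$auc,
    n_frames = x$n_frames
  )
}

#' @method tidy onset_report
#' @export
tidy.onset_report <- function(x, ...) x$discrepancies

#' @method glance onset_report
#' @export
glance.onset_report <- function(x, ...) {
  tibble(mae_model_s = x$mae_model_s, mae_proxy_s = x$mae_proxy_s,
         within_one_frame = x$within_one_frame,
         wilcoxon_p = x$wilcoxon$p_value, pearson_rho = x$pearson_rho,
         n_embryos = nrow(x$discrepancies))
}

#' ROC curve plot for an evaluation report
#'
#' @param object An `eval_report` with an ROC component.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) stopf("report has no ROC component (no scores given)")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#d95f02", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Paired onset-discrepancy plot (model vs compaction proxy)
#'
#' @param object An `onset_report`.
#' @param ... Unused.
#' @return A ggplot object: paired absolute discrepancies per embryo.
#' @method autoplot onset_report
#' @export
autoplot.onset_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$discrepancies,
                              c("model_s", "proxy_s"),
                              names_to = "predictor", values_to = "disc_s")
  long$predictor <- ifelse(long$predictor == "model_s", "ensemble model",
                           "compaction proxy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predictor,
                                     y = abs(.data$disc_s) / 3600)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$id), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$predictor), size = 2) +
    ggplot2::labs(x = NULL, y = "|onset discrepancy| (h)",
                  title = sprintf("Wilcoxon p = %.3g",
                                  object$wilcoxon$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Class-activation-map overlay plot
#'
#' @param frame The input frame (matrix).
#' @param cam Output of [compute_cam()].
#' @param alpha Overlay opacity of the heat map (default 0.6).
#' @return A ggplot object with the frame in greyscale and the CAM overlaid.
#' @export
plot_cam <- function(frame, cam, alpha = 0.6) {
  df_img <- tidyr::expand_grid(y = seq_len(nrow(frame)), x = seq_len(ncol(frame)))
  df_img$intensity <- as.vector(frame)
  m <- cam$map
  df_cam <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df_cam$cam <- as.vector(m)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df_img,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_raster(data = df_cam,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      alpha = .data$cam),
                         fill = "red") +
    ggplot2::scale_alpha_continuous(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
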