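#' Ensemble training configuration
#'
#' The default protocol: six members, the first half
#' trained with SGD (momentum 0.9) and the second half with Adam, all for
#' the same number of epochs, ensembled by element-wise probability
#' averaging with a 0.5 decision threshold on the after-onset probability.
#' The desk-scale backbone is a small 3-block conv net trained from scratch
#' on 64x64 grayscale frames; `backbone`/`pretrained_init` are accepted for
#' interface compatibility but only the built-in backbone ships with the
#' package.
#'
#' @param n_members Number of CNN members (default 6).
#' @param epochs Training epochs per member (default 40).
#' @param threshold Decision threshold on the ensemble after-onset
#'   probability, in (0, 1) (default 0.5; ties go to before-onset).
#' @param ensemble_mode `"probability_average"` (default) or
#'   `"label_majority"` (majority of member labels, ties to before-onset).
#' @param input_size Square input side in pixels (default 64).
#' @param channels Feature maps of the three conv blocks.
#' @param lr_sgd,lr_adam Learning rates for the two optimizer families.
#' @param batch_size Minibatch size (default 8; small batches give
#'   the short training runs enough update steps).
#' @param clip_norm Global gradient-norm clip (default 5); stabilizes the
#'   SGD members over short training runs.
#' @param augment Apply flip/rotation augmentation during training (default
#'   `TRUE`; embryos have no canonical orientation).
#' @param backbone Backbone name; only `"smallconv"` is available.
#' @param pretrained_init Must be `FALSE`; pretrained initializations are
#'   not shipped.
#' @param seed Master seed; member seeds are derived from it.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 6, epochs = 40, threshold = 0.5,
                            ensemble_mode = c("probability_average", "label_majority"),
                            input_size = 64, channels = c(8, 16, 32),
                            lr_sgd = 0.05, lr_adam = 1e-3, batch_size = 8,
                            clip_norm = 5,
                            augment = TRUE, backbone = "smallconv",
                            pretrained_init = FALSE, seed = 1L) {
  check_scalar_number(n_members, "n_members", positive = TRUE)
  check_scalar_number(epochs, "epochs", positive = TRUE)
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must lie in (0, 1)")
  ensemble_mode <- match.arg(ensemble_mode)
  if (!identical(backbone, "smallconv")) {
    stopf("backbone `%s` is not available; only `smallconv` ships with this package", backbone)
  }
  if (isTRUE(pretrained_init)) {
    stopf("pretrained initializations are not shipped; set `pretrained_init = FALSE`")
  }
  structure(
    list(n_members = as.integer(n_members), epochs = as.integer(epochs),
         threshold = threshold, ensemble_mode = ensemble_mode,
         input_size = as.integer(input_size), channels = as.integer(channels),
         lr_sgd = lr_sgd, lr_adam = lr_adam,
         batch_size = as.integer(batch_size), clip_norm = clip_norm,
         augment = isTRUE(augment),
         backbone = backbone, pretrained_init = FALSE,
         seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Embryo-level train/test split
#'
#' Splits recording ids so that no embryo contributes frames to both
#' cohorts; grouping by embryo prevents the trivial leakage of near-identical
#' neighbouring frames across the split. Deterministic given `seed`.
#'
#' @param ids Character vector of recording ids (or a list of recordings
#'   with `$id` fields).
#' @param test_fraction Fraction of embryos assigned to the test cohort.
#' @param counts Optional integer pair `c(n_train, n_test)` overriding
#'   `test_fraction`; must sum to `length(ids)`.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
#' @examples
#' split_cohort(sprintf("e%02d", 1:10), test_fraction = 0.2, seed = 1)
split_cohort <- function(ids, test_fraction = 0.2, counts = NULL, seed = 1L) {
  if (is.list(ids)) {
    ids <- vapply(ids, function(r) {
      if (inherits(r, "recording5d") || !is.null(r$id)) as.character(r$id)
      else if (!is.null(r$recording)) as.character(r$recording$id)
      else stopf("cannot extract an id from `ids` elements")
    }, character(1))
  }
  n <- length(ids)
  if (n < 2) stopf("need at least 2 recordings to split")
  if (anyDuplicated(ids)) stopf("recording ids must be unique")
  if (!is.null(counts)) {
    if (length(counts) != 2 || sum(counts) != n) {
      stopf("`counts` must be two numbers summing to %d", n)
    }
    n_test <- as.integer(counts[2])
  } else {
    n_test <- round(n * test_fraction)
  }
  if (n_test < 1 || n_test >= n) stopf("split leaves an empty cohort")
  test <- withr::with_seed(seed, sample(ids, n_test))
  list(train = setdiff(ids, test), test = sort(test))
}

#' Train all ensemble members
#'
#' @param frames Training frames (3-D array `[h, w, n]` or list of matrices).
#' @param labels 0/1 labels, one per frame.
#' @param cfg An [ensemble_config()].
#' @return A list of class `polar_ensemble` containing `n_members` fitted
#'   `polar_cnn` models and the config.
#' @export
train_ensemble <- function(frames, labels, cfg = ensemble_config()) {
  members <- purrr::map(seq_len(cfg$n_members) - 1L, function(m) {
    train_member(frames, labels, member_index = m, cfg = cfg)
  })
  structure(list(members = members, cfg = cfg), class = "polar_ensemble")
}

#' Ensemble prediction for a batch of frames
#'
#' In `probability_average` mode the member probability vectors are averaged
#' element-wise and a frame is called after-onset iff the mean after-onset
#' probability strictly exceeds the threshold (a tie at the threshold is
#' conservatively called before-onset). In `label_majority` mode each member
#' votes with its own thresholded label and ties go to before-onset.
#'
#' @param models A `polar_ensemble`, or a list of `polar_cnn` models.
#' @param frames Frames (matrix, 3-D array or list of matrices).
#' @param cfg An [ensemble_config()]; defaults to the ensemble's own.
#' @return A tibble with one row per frame: `p_before`, `p_after`, `label`.
#' @export
ensemble_predict <- function(models, frames, cfg = NULL) {
  if (inherits(models, "polar_ensemble")) {
    cfg <- cfg %||% models$cfg
    models <- models$members
  }
  if (!length(models)) stopf("`models` must contain at least one model")
  cfg <- cfg %||% ensemble_config(n_members = length(models))
  probs <- purrr::map(models, predict_proba, frames = frames)
  mean_p <- Reduce(`+`, probs) / length(probs)
  if (cfg$ensemble_mode == "probability_average") {
    label <- as.integer(mean_p[, "p_after"] > cfg$threshold)
  } else {
    votes <- vapply(probs, function(p) as.integer(p[, "p_after"] > cfg$threshold),
                    integer(nrow(mean_p)))
    votes <- matrix(votes, nrow = nrow(mean_p))
    label <- as.integer(rowSums(votes) * 2 > length(models))
  }
  tibble(p_before = mean_p[, "p_before"], p_after = mean_p[, "p_after"],
         label = label)
}
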