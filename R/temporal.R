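#' Majority-vote temporal smoothing of a binary label series
#'
#' A sliding window of odd length (default 3) is applied over chronologically
#' ordered 0/1 labels in a single simultaneous pass: each strictly interior
#' position is replaced by the majority of the *raw* labels inside its
#' window, while the labels at both ends are kept untouched. Series of
#' length at most 2 are returned unchanged.
#'
#' @param labels Integer/numeric vector of 0/1 labels, chronological order.
#' @param window Odd window length, at least 3. Default 3.
#' @return Smoothed 0/1 integer vector of the same length.
#' @export
#' @examples
#' smooth_labels(c(0, 0, 1, 0, 1, 1, 1))  # 0 0 0 1 1 1 1
smooth_labels <- function(labels, window = 3) {
  check_binary(labels, "labels")
  check_scalar_number(window, "window")
  if (window < 3 || window %% 2 == 0) stopf("`window` must be odd and >= 3")
  n <- length(labels)
  out <- as.integer(labels)
  if (n <= 2) return(out)
  half <- (window - 1) / 2
  raw <- as.integer(labels)
  for (i in seq(2L, n - 1L)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- as.integer(sum(raw[lo:hi]) * 2 > (hi - lo + 1))
  }
  out
}

#' Call the polarization onset frame from smoothed labels
#'
#' The onset is the first (0-based) index predicted after-onset; `NA` when
#' every frame is predicted before-onset. Downstream relabelling uses
#' [label_frames()] on the returned index, so every frame from the called
#' onset onward is treated as polarized.
#'
#' @param labels Smoothed 0/1 label vector in chronological order.
#' @return 0-based onset index or `NA_integer_`.
#' @export
#' @examples
#' call_onset(c(0, 0, 0, 1, 1))  # 3
call_onset <- function(labels) {
  check_binary(labels, "labels")
  hit <- which(labels == 1)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Signed time discrepancy between predicted and annotated onset
#'
#' Computes `(effective_pred - true_idx) * frame_interval_s`, rounded to the
#' nearest second. When no onset was predicted within the recording, the
#' frame immediately after the final frame (`n_frames`, 0-based) is used as
#' the effective prediction, so a missed onset is penalized by the remaining
#' recording length.
#'
#' @param pred_idx Predicted 0-based onset index or `NA`.
#' @param true_idx Annotated 0-based onset index (required, `< n_frames`).
#' @param frame_interval_s Seconds per frame (positive).
#' @param n_frames Number of frames in the recording.
#' @return Signed discrepancy in seconds (integer-valued double).
#' @export
#' @examples
#' time_discrepancy(5, 3, 1200, 10)   # +2400
#' time_discrepancy(NA, 8, 1200, 10)  # +2400 (end-of-recording fallback)
time_discrepancy <- function(pred_idx, true_idx, frame_interval_s, n_frames) {
  if (is.na(true_idx)) stopf("`true_idx` is required")
  check_scalar_number(true_idx, "true_idx")
  check_scalar_number(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar_number(n_frames, "n_frames", positive = TRUE)
  if (true_idx >= n_frames) stopf("`true_idx` must be < n_frames")
  effective <- if (is.na(pred_idx)) n_frames else pred_idx
  round((effective - true_idx) * frame_interval_s)
}
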