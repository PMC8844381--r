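#' All-in-focus fusion configuration
#'
#' @param n_levels Wavelet decomposition depth (default 4, clamped to what
#'   the image size allows).
#' @param lowpass_rule How the coarse lowpass bands of the slices are fused:
#'   `"average"` (default) or `"max_local_energy"` (per pixel, take the slice
#'   whose lowpass band has the highest local variance in a 3x3
#'   neighborhood).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(n_levels = 4, lowpass_rule = c("average", "max_local_energy")) {
  check_scalar_number(n_levels, "n_levels", positive = TRUE)
  lowpass_rule <- match.arg(lowpass_rule)
  structure(list(n_levels = as.integer(n_levels), lowpass_rule = lowpass_rule),
            class = "fusion_config")
}

# Accept a z-stack as a list of matrices or a 3-D array [z, y, x].
as_slice_list <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    slices <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ])
  } else if (is.list(stack)) {
    slices <- stack
  } else if (is.matrix(stack)) {
    slices <- list(stack)
  } else stopf("`stack` must be a 3-D array [z, y, x] or a list of matrices")
  if (!length(slices)) stopf("`stack` must contain at least one slice")
  d1 <- dim(slices[[1]])
  for (s in slices) {
    if (!identical(dim(s), d1)) stopf("all slices must have the same shape")
    if (!all(is.finite(s))) stopf("slice values must be finite")
  }
  slices
}

# Symmetric padding of a matrix up to target dimensions.
pad_symmetric <- function(m, ty, tx) {
  py <- ty - nrow(m); px <- tx - ncol(m)
  if (py > 0) {
    top <- floor(py / 2); bot <- py - top
    ridx <- c(rev(seq_len(top)), seq_len(nrow(m)),
              nrow(m) + 1 - seq_len(bot))
    m <- m[ridx, , drop = FALSE]
  }
  if (px > 0) {
    left <- floor(px / 2); right <- px - left
    cidx <- c(rev(seq_len(left)), seq_len(ncol(m)),
              ncol(m) + 1 - seq_len(right))
    m <- m[, cidx, drop = FALSE]
  }
  m
}

# 3x3 local variance, used by the max_local_energy lowpass rule.
local_variance3 <- function(m) {
  box <- function(x) {
    xp <- rbind(x[1, , drop = FALSE], x, x[nrow(x), , drop = FALSE])
    xp <- cbind(xp[, 1, drop = FALSE], xp, xp[, ncol(xp), drop = FALSE])
    n <- nrow(x); p <- ncol(x)
    out <- matrix(0, n, p)
    for (di in 0:2) for (dj in 0:2) {
      out <- out + xp[di + seq_len(n), dj + seq_len(p)]
    }
    out / 9
  }
  box(m^2) - box(m)^2
}

#' Fuse a focus stack into one all-in-focus frame
#'
#' Each slice of the z-stack is decomposed with the dual-tree complex wavelet
#' transform; for every highpass coefficient the value is taken from the
#' slice with the largest coefficient magnitude (in-focus structure carries
#' the most high-frequency energy), ties going to the lowest z index; the
#' lowpass band is fused according to `cfg$lowpass_rule`; the inverse
#' transform yields the fused frame. Non-power-of-two shapes are padded
#' symmetrically and cropped back; the output is clamped to the intensity
#' range of the input stack.
#'
#' @param stack A 3-D array `[z, y, x]` or list of equally shaped matrices.
#' @param cfg A [fusion_config()].
#' @return A matrix of the input slice shape.
#' @export
fuse_aif_dtcwt <- function(stack, cfg = fusion_config()) {
  slices <- as_slice_list(stack)
  d <- dim(slices[[1]])
  nlev <- min(cfg$n_levels, floor(log2(min(d))))
  if (nlev < 1) {
    stopf("n_levels = %d too deep for image of size %dx%d",
          cfg$n_levels, d[1], d[2])
  }
  block <- 2^nlev
  ty <- ceiling(d[1] / block) * block; tx <- ceiling(d[2] / block) * block
  rng <- range(unlist(lapply(slices, range)))
  padded <- lapply(slices, function(s) pad_symmetric(s * 1.0, ty, tx))
  if (length(padded) == 1L) {
    fused_p <- dtcwt_inverse(dtcwt_forward(padded[[1]], nlev))
  } else {
    pyrs <- lapply(padded, dtcwt_forward, nlevels = nlev)
    fused <- pyrs[[1]]
    # highpass: per-coefficient max magnitude, lowest z wins ties
    for (lev in seq_len(nlev)) {
      for (s in names(fused$levels[[lev]])) {
        best <- pyrs[[1]]$levels[[lev]][[s]]
        best_mag <- Mod(best)
        for (z in seq_along(pyrs)[-1]) {
          cand <- pyrs[[z]]$levels[[lev]][[s]]
          cand_mag <- Mod(cand)
          upd <- cand_mag > best_mag     # strict: ties keep lower z
          best[upd] <- cand[upd]
          best_mag[upd] <- cand_mag[upd]
        }
        fused$levels[[lev]][[s]] <- best
      }
    }
    for (k in names(fused$lowpass)) {
      lls <- lapply(pyrs, function(p) p$lowpass[[k]])
      if (cfg$lowpass_rule == "average") {
        fused$lowpass[[k]] <- Reduce(`+`, lls) / length(lls)
      } else {
        en <- lapply(lls, local_variance3)
        pick <- lls[[1]]; pick_en <- en[[1]]
        for (z in seq_along(lls)[-1]) {
          upd <- en[[z]] > pick_en
          pick[upd] <- lls[[z]][upd]
          pick_en[upd] <- en[[z]][upd]
        }
        fused$lowpass[[k]] <- pick
      }
    }
    fused_p <- dtcwt_inverse(fused)
  }
  # crop padding back
  y0 <- floor((ty - d[1]) / 2); x0 <- floor((tx - d[2]) / 2)
  out <- fused_p[y0 + seq_len(d[1]), x0 + seq_len(d[2]), drop = FALSE]
  pmin(pmax(out, rng[1]), rng[2])
}

#' Maximum-intensity z-projection
#'
#' Element-wise maximum over the slices of a z-stack; the standard
#' compression for a sparse fluorescence channel.
#'
#' @inheritParams fuse_aif_dtcwt
#' @return A matrix of the input slice shape.
#' @export
#' @examples
#' max_intensity_projection(list(matrix(c(1, 2, 5, 0), 2), matrix(c(4, 0, 1, 3), 2)))
max_intensity_projection <- function(stack) {
  slices <- as_slice_list(stack)
  Reduce(pmax, slices)
}

#' Compress a 5-D recording to 2-D frame sequences
#'
#' For every time point, the DIC channel's z-stack is fused with
#' [fuse_aif_dtcwt()] and the fluorescence channel's with
#' [max_intensity_projection()]. Frame timing metadata is carried through.
#'
#' @param rec A [recording5d()].
#' @param cfg A [fusion_config()].
#' @return A `fused_sequence`: list with `id`, `dic` and `fluorescence`
#'   (lists of matrices, one per frame), `frame_interval_s`, `n_frames`.
#' @export
fuse_recording <- function(rec, cfg = fusion_config()) {
  stopifnot(inherits(rec, "recording5d"))
  roles <- rec$channel_roles
  if (!all(c("dic", "fluorescence") %in% names(roles))) {
    stopf("recording must declare both `dic` and `fluorescence` channel roles")
  }
  d <- dim(rec$tensor)
  n_t <- d[1]
  dic <- vector("list", n_t); fluo <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    dic_stack <- rec$tensor[t, , roles[["dic"]], , , drop = FALSE]
    dim(dic_stack) <- d[c(2, 4, 5)]
    fluo_stack <- rec$tensor[t, , roles[["fluorescence"]], , , drop = FALSE]
    dim(fluo_stack) <- d[c(2, 4, 5)]
    dic[[t]] <- fuse_aif_dtcwt(dic_stack, cfg)
    fluo[[t]] <- max_intensity_projection(fluo_stack)
  }
  structure(
    list(id = rec$id, dic = dic, fluorescence = fluo,
         frame_interval_s = rec$frame_interval_s, n_frames = n_t),
    class = "fused_sequence"
  )
}
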