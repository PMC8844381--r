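# Small convolutional network engine.
#
# A 3-block conv net (3x3 conv -> ReLU -> 2x2 maxpool, repeated) followed by
# global average pooling and a two-way dense softmax head. Convolutions are
# evaluated as im2col gathers followed by one BLAS matrix multiply per layer,
# which keeps desk-scale training (hundreds of 64x64 frames) in seconds per
# epoch. Everything is deterministic given the member seed.

# ---- low-level layers -------------------------------------------------------
# 3x3 same-padding convolution and 2x2 maxpool, implemented in C++ (src/conv.cpp).

conv3_forward <- function(x, kern, bias) {
  list(out = conv3_fwd_cpp(x, kern, bias), x = x)
}

conv3_backward <- function(dout, x, kern) {
  res <- conv3_bwd_cpp(dout, x, kern)
  list(dx = res$dx, dk = res$dk, db = res$db)
}

maxpool2_forward <- function(x) maxpool2_fwd_cpp(x)

maxpool2_backward <- function(dout, argmax, xdim) {
  maxpool2_bwd_cpp(dout, argmax, as.integer(xdim))
}

# ---- model ------------------------------------------------------------------

init_cnn <- function(input_size = 64L, channels = c(8L, 16L, 32L), seed = 1L) {
  withr::with_seed(seed, {
    he <- function(d) array(rnorm(prod(d), 0, sqrt(2 / prod(d[1:3]))), d)
    params <- list(
      k1 = he(c(3, 3, 1, channels[1])), b1 = numeric(channels[1]),
      k2 = he(c(3, 3, channels[1], channels[2])), b2 = numeric(channels[2]),
      k3 = he(c(3, 3, channels[2], channels[3])), b3 = numeric(channels[3]),
      wd = matrix(rnorm(2 * channels[3], 0, sqrt(1 / channels[3])), 2, channels[3]),
      bd = numeric(2)
    )
    structure(
      list(params = params, input_size = as.integer(input_size),
           channels = as.integer(channels), seed = as.integer(seed),
           class_order = c("before", "after"), optimizer = NA_character_,
           epochs_trained = 0L, train_accuracy = NA_real_),
      class = "polar_cnn"
    )
  })
}

# Per-image standardization; frames list/array -> [h, w, 1, n] batch array.
prep_frames <- function(frames, input_size) {
  if (is.list(frames)) {
    mats <- frames
  } else if (is.matrix(frames)) {
    mats <- list(frames)
  } else if (is.array(frames) && length(dim(frames)) == 3) {
    mats <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  } else stopf("`frames` must be a matrix, a 3-D array or a list of matrices")
  n <- length(mats)
  out <- array(0, c(input_size, input_size, 1L, n))
  for (i in seq_len(n)) {
    m <- bilinear_resize(mats[[i]], input_size, input_size)
    s <- sd(m)
    out[, , 1L, i] <- if (s > 0) (m - mean(m)) / s else m - mean(m)
  }
  out
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  c1 <- conv3_forward(x, params$k1, params$b1)
  r1 <- pmax(c1$out, 0)
  p1 <- maxpool2_forward(r1)
  c2 <- conv3_forward(p1$out, params$k2, params$b2)
  r2 <- pmax(c2$out, 0)
  p2 <- maxpool2_forward(r2)
  c3 <- conv3_forward(p2$out, params$k3, params$b3)
  r3 <- pmax(c3$out, 0)
  p3 <- maxpool2_forward(r3)
  d3 <- dim(p3$out)
  feat <- p3$out
  gmat <- matrix(feat, nrow = d3[1] * d3[2])   # (hw x f*n)
  g <- matrix(colMeans(gmat), d3[3], d3[4])    # (f x n)
  logits <- params$wd %*% g + params$bd        # (2 x n)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  res <- list(probs = probs, logits = logits, features = feat, g = g)
  if (keep_cache) res$cache <- list(x = x, c1 = c1, r1 = r1, p1 = p1,
                                    c2 = c2, r2 = r2, p2 = p2,
                                    c3 = c3, r3 = r3, p3 = p3)
  res
}

cnn_backward <- function(params, fwd, y_onehot) {
  ch <- fwd$cache
  n <- ncol(fwd$probs)
  dlogits <- (fwd$probs - y_onehot) / n
  grads <- list()
  grads$wd <- tcrossprod(dlogits, fwd$g)
  grads$bd <- rowSums(dlogits)
  dg <- crossprod(params$wd, dlogits)  # (f x n)
  d3 <- dim(ch$p3$out)
  dfeat <- array(rep(as.vector(dg), each = d3[1] * d3[2]) / (d3[1] * d3[2]), d3)
  dp3 <- maxpool2_backward(dfeat, ch$p3$argmax, dim(ch$r3))
  dr3 <- dp3 * (ch$r3 > 0)
  bw3 <- conv3_backward(dr3, ch$p2$out, params$k3)
  grads$k3 <- bw3$dk; grads$b3 <- bw3$db
  dp2 <- maxpool2_backward(bw3$dx, ch$p2$argmax, dim(ch$r2))
  dr2 <- dp2 * (ch$r2 > 0)
  bw2 <- conv3_backward(dr2, ch$p1$out, params$k2)
  grads$k2 <- bw2$dk; grads$b2 <- bw2$db
  dp1 <- maxpool2_backward(bw2$dx, ch$p1$argmax, dim(ch$r1))
  dr1 <- dp1 * (ch$r1 > 0)
  bw1 <- conv3_backward(dr1, ch$x, params$k1)
  grads$k1 <- bw1$dk; grads$b1 <- bw1$db
  grads
}

make_optimizer <- function(kind, params, lr) {
  state <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  t <- 0L
  if (kind == "sgd") {
    mom <- 0.9
    function(params, grads, scale = 1) {
      for (nm in names(params)) {
        state[[nm]]$m <<- mom * state[[nm]]$m + grads[[nm]]
        params[[nm]] <- params[[nm]] - scale * lr * state[[nm]]$m
      }
      params
    }
  } else if (kind == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(params, grads, scale = 1) {
      t <<- t + 1L
      for (nm in names(params)) {
        state[[nm]]$m <<- b1 * state[[nm]]$m + (1 - b1) * grads[[nm]]
        state[[nm]]$v <<- b2 * state[[nm]]$v + (1 - b2) * grads[[nm]]^2
        mhat <- state[[nm]]$m / (1 - b1^t)
        vhat <- state[[nm]]$v / (1 - b2^t)
        params[[nm]] <- params[[nm]] - scale * lr * mhat / (sqrt(vhat) + eps)
      }
      params
    }
  } else stopf("unknown optimizer `%s`", kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random flip / 90-degree rotation augmentation for one [h,w] matrix.
augment_frame <- function(m, draws) {
  if (draws[1] < 0.5) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (draws[2] < 0.5) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  k <- floor(draws[3] * 4) %% 4
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

#' Train one ensemble member
#'
#' Trains a small conv net (3x3 conv / ReLU / 2x2 maxpool, three blocks,
#' global average pooling, two-way dense softmax head) on labelled frames.
#' Under the default optimizer assignment the first half of the members use
#' SGD with momentum and the second half use Adam, so members differ in both
#' initialization and optimization trajectory. Deterministic given the
#' member seed derived from `cfg$seed` and `member_index`.
#'
#' @param frames Training frames: a 3-D array `[h, w, n]` or list of matrices.
#' @param labels 0/1 labels (1 = after-onset), one per frame.
#' @param member_index 0-based member index (selects optimizer and seed).
#' @param cfg An [ensemble_config()].
#' @return A fitted model of class `polar_cnn`.
#' @export
train_member <- function(frames, labels, member_index = 0L,
                         cfg = ensemble_config()) {
  check_binary(labels, "labels")
  if (length(unique(labels)) < 2) {
    stopf("training data contains a single class; both classes are required")
  }
  member_seed <- derive_seed(cfg$seed, paste0("member", member_index))
  model <- init_cnn(cfg$input_size, cfg$channels, seed = member_seed)
  half <- ceiling(cfg$n_members / 2)
  kind <- if (member_index < half) "sgd" else "adam"
  lr <- if (kind == "sgd") cfg$lr_sgd else cfg$lr_adam
  model$optimizer <- kind
  x_all <- prep_frames(frames, cfg$input_size)
  n <- dim(x_all)[4]
  if (length(labels) != n) stopf("`labels` length does not match frame count")
  y <- as.integer(labels)
  step <- make_optimizer(kind, model$params, lr)
  # step decay: halve the rate twice in the last 40% of training
  lr_scale <- rep(1, cfg$epochs)
  if (cfg$epochs >= 3) {
    lr_scale[seq(ceiling(0.6 * cfg$epochs) + 1, cfg$epochs)] <- 0.5
    lr_scale[seq(ceiling(0.85 * cfg$epochs) + 1, length.out =
                   max(0, cfg$epochs - ceiling(0.85 * cfg$epochs)))] <- 0.25
  }
  params <- model$params
  bs <- cfg$batch_size
  withr::with_seed(member_seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        xb <- x_all[, , , take, drop = FALSE]
        if (cfg$augment) {
          for (i in seq_along(take)) {
            xb[, , 1L, i] <- augment_frame(xb[, , 1L, i], runif(3))
          }
        }
        yb <- y[take]
        onehot <- rbind(1 - yb, yb)
        fwd <- cnn_forward(params, xb, keep_cache = TRUE)
        if (any(!is.finite(fwd$probs))) {
          stopf("training diverged (non-finite probabilities) at epoch %d", epoch)
        }
        grads <- cnn_backward(params, fwd, onehot)
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > cfg$clip_norm) {
          grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
        }
        params <- step(params, grads, lr_scale[epoch])
      }
    }
  })
  model$params <- params
  model$epochs_trained <- cfg$epochs
  fwd <- cnn_forward(params, x_all)
  model$train_accuracy <- mean((fwd$probs[2, ] > 0.5) == (y == 1))
  model
}

#' Per-frame class probabilities from a single model
#'
#' @param model A fitted `polar_cnn`.
#' @param frames Frames as in [train_member()].
#' @return Matrix `n x 2` with columns `p_before`, `p_after`; rows on the
#'   probability simplex.
#' @export
predict_proba <- function(model, frames) {
  x <- prep_frames(frames, model$input_size)
  out <- t(cnn_forward(model$params, x)$probs)
  colnames(out) <- c("p_before", "p_after")
  out
}

#' Class activation map for one frame
#'
#' The raw map is the weighted sum of the feature maps entering the global
#' average pooling stage, weighted by the dense-head weights of the requested
#' class: `sum_f w[class, f] * featuremap_f`. Because GAP is a spatial mean,
#' the spatial mean of the raw map equals the class logit minus the class
#' bias exactly; this identity is the correctness check for the map. The
#' returned heat map is the raw map bilinearly rescaled to input resolution.
#'
#' @param model A fitted `polar_cnn`.
#' @param frame One frame (matrix).
#' @param class_index 0 = before-onset, 1 = after-onset.
#' @return A list with `map` (input-resolution heat map), `raw` (pre-GAP
#'   resolution map), `logit` and `bias` for the requested class.
#' @export
compute_cam <- function(model, frame, class_index = 1L) {
  if (!class_index %in% c(0L, 1L)) stopf("`class_index` must be 0 or 1")
  x <- prep_frames(frame, model$input_size)
  fwd <- cnn_forward(model$params, x)
  feat <- fwd$features[, , , 1, drop = FALSE]      # [h, w, f, 1]
  w <- model$params$wd[class_index + 1L, ]
  raw <- matrix(0, dim(feat)[1], dim(feat)[2])
  for (f in seq_along(w)) raw <- raw + w[f] * feat[, , f, 1]
  list(map = bilinear_resize(raw, model$input_size, model$input_size),
       raw = raw,
       logit = fwd$logits[class_index + 1L, 1],
       bias = model$params$bd[class_index + 1L])
}
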