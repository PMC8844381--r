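# Internal helpers shared across modules.

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  invisible(x)
}

check_binary <- function(x, name) {
  if (length(x) && !all(x %in% c(0, 1))) {
    stopf("`%s` must contain only 0/1 values", name)
  }
  invisible(x)
}

#' Derive a stage seed from a master seed
#'
#' Mixes a master seed with a stage name so that every pipeline stage draws
#' from an independent, reproducible stream and adding a stage never perturbs
#' the randomness of earlier stages.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(master_seed, stage) {
  check_scalar_number(master_seed, "master_seed")
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Bilinear rescale of a matrix to (ny, nx); used for CAM upsampling.
# Corner-aligned sampling so the map's extremes land on the image border.
bilinear_resize <- function(m, ny, nx) {
  sy <- nrow(m); sx <- ncol(m)
  if (sy == ny && sx == nx) return(m)
  yi <- seq(1, sy, length.out = ny)
  xi <- seq(1, sx, length.out = nx)
  y0 <- if (sy == 1L) rep(1L, ny) else pmin(floor(yi), sy - 1L)
  x0 <- if (sx == 1L) rep(1L, nx) else pmin(floor(xi), sx - 1L)
  fy <- yi - y0; fx <- xi - x0
  y1 <- pmin(y0 + 1L, sy); x1 <- pmin(x0 + 1L, sx)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, ny, nx); wx <- matrix(fx, ny, nx, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

# Local gradient energy (mean squared forward difference), a simple
# sharpness score used to compare fused frames with single slices.
gradient_energy <- function(m) {
  dy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  dx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  (sum(dy^2) + sum(dx^2)) / length(m)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
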