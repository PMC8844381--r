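#' Annotation thresholds
#'
#' Configuration for rule-based annotation of polarization and compaction.
#' Polarization onset is the first frame whose largest closed apical-cap
#' surface fraction is at least `cap_fraction_threshold` (inclusive);
#' compaction is the first frame whose smallest inter-blastomere angle
#' strictly exceeds `angle_threshold_deg`.
#'
#' @param cap_fraction_threshold Surface fraction in (0, 1]; default 1/3.
#' @param angle_threshold_deg Angle in degrees in (0, 180); default 120.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(cap_fraction_threshold = 1 / 3,
                              angle_threshold_deg = 120) {
  check_scalar_number(cap_fraction_threshold, "cap_fraction_threshold")
  check_scalar_number(angle_threshold_deg, "angle_threshold_deg")
  if (cap_fraction_threshold <= 0 || cap_fraction_threshold > 1) {
    stopf("`cap_fraction_threshold` must lie in (0, 1]")
  }
  if (angle_threshold_deg <= 0 || angle_threshold_deg >= 180) {
    stopf("`angle_threshold_deg` must lie in (0, 180)")
  }
  structure(
    list(cap_fraction_threshold = cap_fraction_threshold,
         angle_threshold_deg = angle_threshold_deg),
    class = "annotation_config"
  )
}

#' Call polarization onset from a cap-fraction series
#'
#' Returns the first (0-based) frame index at which the per-frame maximum
#' closed-cap surface fraction reaches the threshold, mirroring expert
#' annotation of the fluorescence channel ("a closed apical ring or cap
#' covering at least 1/3 of the visible cell surface").
#'
#' @param cap_fractions Numeric vector of per-frame cap fractions in \[0, 1\].
#' @param cfg An [annotation_config()].
#' @return 0-based frame index, or `NA_integer_` if the threshold is never
#'   reached.
#' @export
#' @examples
#' annotate_polarization_onset(c(0.10, 0.20, 0.34, 0.40))  # 2
annotate_polarization_onset <- function(cap_fractions, cfg = annotation_config()) {
  if (!length(cap_fractions)) stopf("`cap_fractions` must be nonempty")
  if (any(!is.finite(cap_fractions)) ||
      any(cap_fractions < 0) || any(cap_fractions > 1)) {
    stopf("`cap_fractions` must lie in [0, 1]")
  }
  hit <- which(cap_fractions >= cfg$cap_fraction_threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Expand an onset index into per-frame binary labels
#'
#' Frames strictly before the onset are labelled 0 (before-onset); the onset
#' frame and every later frame are labelled 1 (after-onset). A missing onset
#' yields all zeros.
#'
#' @param onset_idx 0-based onset frame index, or `NA`.
#' @param n_frames Number of frames.
#' @return Integer vector of 0/1 labels of length `n_frames`.
#' @export
#' @examples
#' label_frames(2, 5)  # 0 0 1 1 1
label_frames <- function(onset_idx, n_frames) {
  check_scalar_number(n_frames, "n_frames")
  n_frames <- as.integer(n_frames)
  if (is.na(onset_idx)) return(integer(n_frames))
  check_scalar_number(onset_idx, "onset_idx")
  if (onset_idx < 0 || onset_idx > n_frames) {
    stopf("`onset_idx` must lie in [0, n_frames]")
  }
  as.integer(seq_len(n_frames) - 1L >= onset_idx)
}

#' Inter-blastomere angle of two contacting spherical blastomeres
#'
#' The exterior angle between the two membrane tangents at a contact point,
#' computed analytically from circle-overlap geometry: two circles of radii
#' `r1`, `r2` with center distance `d`. Fully separated cells give 0 degrees
#' (point contact limit); fully merged equal cells approach 180 degrees.
#' The compaction criterion is an angle strictly above 120 degrees.
#'
#' @param r1,r2 Circle radii (positive).
#' @param d Center distance with `abs(r1 - r2) < d < r1 + r2`.
#' @return Angle in degrees in (0, 180).
#' @export
#' @examples
#' measure_interblastomere_angle(1, 1, 1)  # exactly 120
measure_interblastomere_angle <- function(r1, r2, d) {
  check_scalar_number(r1, "r1", positive = TRUE)
  check_scalar_number(r2, "r2", positive = TRUE)
  check_scalar_number(d, "d", positive = TRUE)
  if (d >= r1 + r2) stopf("circles do not intersect (d >= r1 + r2)")
  if (d <= abs(r1 - r2)) stopf("one circle is nested in the other (d <= |r1 - r2|)")
  # Contact point P on both circles; the tangent of circle i at P is normal
  # to the radius vector from center i. The exterior angle between the two
  # tangents equals pi minus the angle between the two radius vectors.
  # Triangle with sides r1, r2, d at P: angle between radii via law of cosines.
  cos_at_p <- (r1^2 + r2^2 - d^2) / (2 * r1 * r2)
  cos_at_p <- min(1, max(-1, cos_at_p))
  angle_between_radii <- acos(cos_at_p)
  (pi - angle_between_radii) / pi * 180
}

#' Call compaction from an angle series
#'
#' Returns the first (0-based) frame index whose smallest inter-blastomere
#' angle strictly exceeds the threshold (120 degrees by default).
#'
#' @param angles Numeric vector of per-frame smallest inter-blastomere angles
#'   in degrees, each in (0, 180).
#' @param cfg An [annotation_config()].
#' @return 0-based frame index or `NA_integer_`.
#' @export
#' @examples
#' annotate_compaction(c(100, 115, 125, 130))  # 2
annotate_compaction <- function(angles, cfg = annotation_config()) {
  if (!length(angles)) stopf("`angles` must be nonempty")
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180)) {
    stopf("`angles` must lie in (0, 180) degrees")
  }
  hit <- which(angles > cfg$angle_threshold_deg)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Estimate the inter-blastomere angle from rasterized cell masks
#'
#' A contour-based alternative to the analytic
#' [measure_interblastomere_angle()]: for two overlapping cell masks, the
#' two contact endpoints are located where the mask boundaries meet, a local
#' tangent is fit to each cell's boundary over a short arc (PCA over the
#' nearest boundary pixels) at each endpoint, and the mean of the two
#' endpoint exterior angles is returned. Accuracy is limited by
#' rasterization; expect a few degrees of error at typical resolutions.
#'
#' @param mask1,mask2 Logical or 0/1 matrices of identical size, one per cell.
#' @param arc_px Number of boundary pixels on each side used for the tangent
#'   fit (default 5).
#' @return Estimated angle in degrees.
#' @export
estimate_angle_from_masks <- function(mask1, mask2, arc_px = 5) {
  mask1 <- mask1 != 0; mask2 <- mask2 != 0
  if (!identical(dim(mask1), dim(mask2))) stopf("masks must have identical size")
  if (!any(mask1 & mask2)) stopf("masks do not overlap; no contact to measure")
  boundary <- function(m) {
    inner <- m
    inner[-1, ] <- inner[-1, ] & m[-nrow(m), ]
    inner[-nrow(m), ] <- inner[-nrow(m), ] & m[-1, ]
    inner[, -1] <- inner[, -1] & m[, -ncol(m)]
    inner[, -ncol(m)] <- inner[, -ncol(m)] & m[, -1]
    which(m & !inner, arr.ind = TRUE)
  }
  b1 <- boundary(mask1); b2 <- boundary(mask2)
  union_b <- boundary(mask1 | mask2)
  # Contact endpoints: union-boundary pixels close to both cells' boundaries.
  d_to <- function(pts, b) {
    apply(pts, 1, function(p) min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
  }
  near_both <- d_to(union_b, b1) <= 1.5 & d_to(union_b, b2) <= 1.5
  cand <- union_b[near_both, , drop = FALSE]
  if (nrow(cand) < 2) stopf("could not locate two contact endpoints")
  # The two endpoints are the mutually farthest candidate pixels.
  dmat <- as.matrix(stats::dist(cand))
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  endpoints <- cand[ij, , drop = FALSE]
  tangent_dir <- function(b, p) {
    d <- sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)
    keep <- order(d)[seq_len(min(2 * arc_px + 1, nrow(b)))]
    pts <- b[keep, , drop = FALSE]
    pc <- prcomp(pts, center = TRUE, scale. = FALSE)
    pc$rotation[, 1]
  }
  angle_at <- function(p) {
    t1 <- tangent_dir(b1, p); t2 <- tangent_dir(b2, p)
    cosang <- abs(sum(t1 * t2))
    interior <- acos(min(1, max(-1, cosang))) / pi * 180
    180 - interior
  }
  mean(c(angle_at(endpoints[1, ]), angle_at(endpoints[2, ])))
}

#' @importFrom stats prcomp
NULL
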