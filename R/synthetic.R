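#' Synthetic embryo-movie configuration
#'
#' Defines one simulated 8-cell-stage recording. Inter-blastomere angles
#' follow a linear trajectory that first strictly exceeds 120 degrees at
#' `compaction_frame`; the fluorescence channel grows an apical cap on the
#' first polarized blastomere from `polarization_frame` on, with cap
#' fraction exactly 1/3 at onset; the DIC channel carries a fine
#' boundary-texture change of amplitude `dic_cue_strength` from the onset
#' frame (polarization is not assumed to alter DIC brightness, only texture).
#' Each z slice is defocused according to its distance from a blastomere's
#' focal plane: edges soften and fine texture is attenuated analytically,
#' the way Gaussian defocus suppresses high spatial frequencies.
#'
#' @param n_blastomeres Number of blastomeres (default 8; two rings of 4).
#' @param img_size Frame side in pixels (y = x, default 64).
#' @param n_z Number of z slices (default 5).
#' @param z_step_um Micrometers per z step (default 4).
#' @param radius_px Blastomere radius in pixels (default 9, scaled with
#'   `img_size`).
#' @param packing_jitter Relative jitter of blastomere placement (default 0.05).
#' @param angle_start_deg,angle_end_deg Endpoints of the smallest
#'   inter-blastomere angle trajectory (defaults 95 and 155 degrees).
#' @param compaction_frame 0-based frame at which the smallest angle first
#'   strictly exceeds 120 degrees (default 8).
#' @param polarization_frame 0-based frame at which the first apical cap
#'   reaches fraction 1/3 (default 13; must be >= `compaction_frame`).
#' @param cap_growth_per_frame Cap-fraction growth per frame after onset
#'   (default 0.06).
#' @param dic_cue_strength Amplitude of the polarization-coupled DIC
#'   boundary-texture cue, relative to membrane contrast (default 1; 0
#'   removes any DIC trace of polarization beyond compaction geometry).
#' @param defocus_sigma_per_um Defocus blur scale in px per micrometer of
#'   distance from the focal plane (default 0.35).
#' @param noise_sd Additive Gaussian noise sd, relative to unit intensity
#'   (default 0.02).
#' @param n_frames Number of time points (default 24, a typical 8-cell-stage
#'   window at half-hour frame intervals).
#' @param frame_interval_s Seconds per frame; `NULL` (default) samples
#'   uniformly from \[1200, 2400\] as in confocal embryo time-lapse practice.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_blastomeres = 8, img_size = 64, n_z = 5,
                         z_step_um = 4, radius_px = 9 * img_size / 64,
                         packing_jitter = 0.05,
                         angle_start_deg = 95, angle_end_deg = 155,
                         compaction_frame = 8, polarization_frame = 13,
                         cap_growth_per_frame = 0.06,
                         dic_cue_strength = 1, defocus_sigma_per_um = 0.35,
                         noise_sd = 0.02, n_frames = 24,
                         frame_interval_s = NULL, seed = 1L) {
  cfg <- list(n_blastomeres = as.integer(n_blastomeres),
              img_size = as.integer(img_size), n_z = as.integer(n_z),
              z_step_um = z_step_um, radius_px = radius_px,
              packing_jitter = packing_jitter,
              angle_start_deg = angle_start_deg, angle_end_deg = angle_end_deg,
              compaction_frame = as.integer(compaction_frame),
              polarization_frame = as.integer(polarization_frame),
              cap_growth_per_frame = cap_growth_per_frame,
              dic_cue_strength = dic_cue_strength,
              defocus_sigma_per_um = defocus_sigma_per_um,
              noise_sd = noise_sd, n_frames = as.integer(n_frames),
              frame_interval_s = frame_interval_s, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$compaction_frame < 0 ||
      cfg$compaction_frame > cfg$polarization_frame ||
      cfg$polarization_frame >= cfg$n_frames) {
    stopf("need 0 <= compaction_frame <= polarization_frame < n_frames")
  }
  for (f in c("z_step_um", "radius_px", "defocus_sigma_per_um",
              "cap_growth_per_frame")) {
    check_scalar_number(cfg[[f]], f, positive = TRUE)
  }
  if (cfg$noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (cfg$dic_cue_strength < 0) stopf("`dic_cue_strength` must be >= 0")
  if (!is.null(cfg$frame_interval_s)) {
    check_scalar_number(cfg$frame_interval_s, "frame_interval_s", positive = TRUE)
  }
  if (cfg$angle_start_deg <= 0 || cfg$angle_end_deg >= 180 ||
      cfg$angle_start_deg >= cfg$angle_end_deg) {
    stopf("need 0 < angle_start_deg < angle_end_deg < 180")
  }
  invisible(cfg)
}

# center distance of two equal circles of radius r meeting at exterior
# angle `alpha` degrees (inverse of measure_interblastomere_angle)
angle_to_distance <- function(alpha_deg, r) 2 * r * cos(alpha_deg / 2 * pi / 180)

#' Generate one synthetic 5-D embryo recording with ground truth
#'
#' Deterministic given `cfg$seed`. Blastomeres are spheres rendered as
#' soft-edged circles in projection; compaction moves their centers together
#' so that the smallest contact angle follows the configured trajectory
#' exactly (the critical contacting pair's geometry is recorded per frame,
#' so the angle series can be re-measured from geometry). The fluorescence
#' channel shows a membrane outline plus, from `polarization_frame` on, a
#' bright apical arc covering the ground-truth cap fraction of the first
#' polarized blastomere's outward surface.
#'
#' @param cfg A [synth_config()].
#' @return A list with `recording` (a [recording5d()]) and `truth`, where
#'   `truth` holds `polarization_onset_idx`, `compaction_idx` (0-based),
#'   `angle_series` (deg), `cap_series`, `labels` (0/1 per frame),
#'   `critical_pair` (per-frame tibble of `r` and `d` for the smallest-angle
#'   contacting pair) and `frame_interval_s`; `cfg` echoes the realized
#'   configuration, so any embryo can be regenerated exactly.
#' @export
generate_recording <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  withr::with_seed(cfg$seed, generate_recording_impl(cfg))
}

generate_recording_impl <- function(cfg) {
  n <- cfg$img_size; nf <- cfg$n_frames; nz <- cfg$n_z
  nb <- cfg$n_blastomeres
  r <- cfg$radius_px * runif(1, 1 - cfg$packing_jitter, 1 + cfg$packing_jitter)
  interval <- cfg$frame_interval_s %||% runif(1, 1200, 2400)

  # --- ground-truth series -------------------------------------------------
  slope <- (cfg$angle_end_deg - cfg$angle_start_deg) / max(1, nf - 1)
  t_idx <- seq_len(nf) - 1L
  angle_series <- 120 + slope * (t_idx - cfg$compaction_frame + 0.5)
  angle_series <- pmin(pmax(angle_series, 5), 175)
  cap_series <- ifelse(
    t_idx < cfg$polarization_frame, 0,
    pmin(1, 1 / 3 + cfg$cap_growth_per_frame * (t_idx - cfg$polarization_frame))
  )
  labels <- as.integer(t_idx >= cfg$polarization_frame)

  # --- base layout: two rings of ceil(nb/2) and floor(nb/2) cells ----------
  n_top <- ceiling(nb / 2); n_bot <- nb - n_top
  ang_top <- 2 * pi * (seq_len(n_top) - 1) / n_top + pi / n_top
  ang_bot <- if (n_bot) 2 * pi * (seq_len(n_bot) - 1) / max(1, n_bot) else numeric()
  rho <- 1                                  # base ring radius, rescaled per frame
  base <- rbind(
    cbind(rho * cos(ang_top), rho * sin(ang_top)),
    if (n_bot) cbind(rho * cos(ang_bot), rho * sin(ang_bot))
  )
  base <- base * (1 + matrix(runif(2 * nb, -cfg$packing_jitter,
                                   cfg$packing_jitter), nb, 2))
  layer <- c(rep(1L, n_top), rep(2L, n_bot))   # z layer per blastomere
  # contact graph: ring neighbours plus nearest inter-ring pairs
  pairs <- NULL
  if (n_top > 1) pairs <- cbind(seq_len(n_top), c(seq_len(n_top)[-1], 1L))
  if (n_bot > 1) {
    pb <- cbind(n_top + seq_len(n_bot), n_top + c(seq_len(n_bot)[-1], 1L))
    pairs <- rbind(pairs, pb)
  }
  if (n_bot) {
    for (i in seq_len(n_bot)) {
      dists <- sqrt(rowSums((base[seq_len(n_top), , drop = FALSE] -
                               matrix(base[n_top + i, ], n_top, 2,
                                      byrow = TRUE))^2))
      pairs <- rbind(pairs, c(which.min(dists), n_top + i))
    }
  }
  pair_d0 <- sqrt(rowSums((base[pairs[, 1], , drop = FALSE] -
                             base[pairs[, 2], , drop = FALSE])^2))
  d0_max <- max(pair_d0)   # critical (smallest-angle) contacting pair

  # --- per-frame geometry: scale so the critical pair realizes the angle ---
  d_crit <- angle_to_distance(angle_series, r)
  scales <- d_crit / d0_max
  center <- (n + 1) / 2

  yy <- matrix(seq_len(n), n, n)       # row = y
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  focal <- ifelse(layer == 1L, (nz + 1) / 2 - 1, (nz + 1) / 2 + 1)
  tex_phase <- runif(nb, 0, 2 * pi)
  cue_phase <- runif(nb, 0, 2 * pi)
  cap_dir <- atan2(base[1, 2], base[1, 1])   # outward direction of cell 1

  tensor <- array(0, c(nf, nz, 2L, n, n))
  edge_w0 <- 1.1            # in-focus membrane edge width (px)
  lam_tex <- 4.5            # interior texture wavelength (px)
  lam_cue <- 5.0            # polarization cue wavelength along the membrane (px)

  for (t in seq_len(nf)) {
    pos <- base * scales[t]
    cx <- center + pos[, 1] * 1.0
    cy <- center + pos[, 2] * 1.0
    polarized <- labels[t] == 1L
    for (z in seq_len(nz)) {
      dic <- matrix(0, n, n); fluo <- matrix(0, n, n)
      for (b in seq_len(nb)) {
        dz_um <- abs(z - focal[b]) * cfg$z_step_um
        sig <- sqrt(edge_w0^2 + (cfg$defocus_sigma_per_um * dz_um)^2)
        dist <- sqrt((yy - cy[b])^2 + (xx - cx[b])^2)
        inside <- 1 / (1 + exp((dist - r) / (sig / 2)))
        ring <- exp(-(dist - r)^2 / (2 * sig^2)) * (edge_w0 / sig)
        att_tex <- exp(-0.5 * (sig * 2 * pi / lam_tex)^2)
        tex <- sin(2 * pi * dist / lam_tex + tex_phase[b]) * inside * att_tex
        cell <- 0.35 * inside + 0.45 * ring + 0.12 * tex
        if (polarized && cfg$dic_cue_strength > 0) {
          # fine texture along the membrane, switched on at onset
          arc <- atan2(yy - cy[b], xx - cx[b])
          att_cue <- exp(-0.5 * (sig * 2 * pi / lam_cue)^2)
          cue <- sin(arc * round(2 * pi * r / lam_cue) + cue_phase[b]) *
            exp(-(dist - r)^2 / (2 * sig^2)) * att_cue
          cell <- cell + 0.45 * cfg$dic_cue_strength * cue
        }
        dic <- pmax(dic, cell)
        # fluorescence: faint membrane everywhere
        fluo <- pmax(fluo, 0.15 * ring)
        if (b == 1L && cap_series[t] > 0) {
          arc <- atan2(yy - cy[b], xx - cx[b])
          darc <- abs(((arc - cap_dir + pi) %% (2 * pi)) - pi)
          in_cap <- 1 / (1 + exp((darc - cap_series[t] * pi) / 0.05))
          fluo <- pmax(fluo, ring * in_cap)
        }
      }
      dic <- dic + 0.05 + rnorm(n * n, 0, cfg$noise_sd)
      fluo <- fluo + 0.02 + rnorm(n * n, 0, cfg$noise_sd / 2)
      tensor[t, z, 1L, , ] <- dic
      tensor[t, z, 2L, , ] <- fluo
    }
  }
  tensor <- round(pmin(pmax(tensor, 0), 2) * 20000)

  truth <- list(
    polarization_onset_idx = cfg$polarization_frame,
    compaction_idx = cfg$compaction_frame,
    angle_series = angle_series,
    cap_series = cap_series,
    labels = labels,
    critical_pair = tibble(frame = t_idx, r = r, d = d_crit),
    frame_interval_s = interval,
    n_frames = nf
  )
  rec <- recording5d(tensor, id = sprintf("synth%04d", cfg$seed),
                     frame_interval_s = interval, z_step_um = cfg$z_step_um,
                     channel_roles = c(dic = 1, fluorescence = 2))
  list(recording = rec, truth = truth, cfg = cfg)
}

#' Generate a cohort of synthetic embryos
#'
#' Draws per-embryo parameters (onset frames, recording length, frame
#' interval, geometry jitter) from ranges around the template configuration,
#' with every embryo's seed derived deterministically from the master seed,
#' so cohorts are reproducible and embryos mutually independent.
#'
#' @param n_embryos Number of recordings (>= 1).
#' @param template A [synth_config()] used as the center of the jitter
#'   ranges.
#' @param seed Master seed.
#' @param min_lag Minimum number of frames between compaction and
#'   polarization onset (default 3; compaction typically precedes
#'   polarization).
#' @param transform Optional function applied to each embryo's
#'   `list(recording, truth)` before it is stored; lets callers compress a
#'   recording (e.g. [fuse_recording()]) and release the 5-D tensor
#'   immediately, keeping cohort generation memory-flat.
#' @return A list of `n_embryos` elements, each as returned by
#'   [generate_recording()] (or by `transform`).
#' @export
generate_cohort <- function(n_embryos, template = synth_config(), seed = 1L,
                            min_lag = 3L, transform = NULL) {
  check_scalar_number(n_embryos, "n_embryos")
  if (n_embryos < 1) stopf("`n_embryos` must be >= 1")
  purrr::map(seq_len(n_embryos), function(i) {
    eseed <- derive_seed(seed, paste0("embryo", i))
    withr::with_seed(eseed, {
      nf <- max(template$n_frames + sample(-4:4, 1), min_lag + 6L)
      comp <- template$compaction_frame + sample(-2:2, 1)
      lag <- max(min_lag, round(template$polarization_frame -
                                  template$compaction_frame) + sample(-1:2, 1))
      pol <- max(min_lag, min(comp + lag, nf - 5L))
      comp <- max(0L, pol - lag)
      cfg <- modifyList(unclass(template), list(
        n_frames = as.integer(nf),
        compaction_frame = as.integer(comp),
        polarization_frame = as.integer(pol),
        seed = derive_seed(eseed, "render")
      ))
      class(cfg) <- "synth_config"
      out <- generate_recording(cfg)
      out$recording$id <- sprintf("embryo%03d", i)
      if (!is.null(transform)) out <- transform(out)
      out
    })
  })
}
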