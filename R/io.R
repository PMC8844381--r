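#' Construct and validate a 5-D recording
#'
#' The canonical in-memory form of one embryo time-lapse: a nonnegative
#' intensity tensor with axes (t, z, c, y, x), a mapping of channel indices
#' to roles, and the timing/z metadata needed to convert frame indices to
#' seconds and slice indices to micrometers. Intensities are kept in their
#' native integer range (16-bit microscope counts by default) until fusion
#' promotes them to double.
#'
#' @param tensor 5-D numeric array, axes (t, z, c, y, x), finite and >= 0.
#' @param id Recording identifier string.
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @param z_step_um Micrometers between consecutive z slices (> 0).
#' @param channel_roles Named integer vector mapping roles to channel
#'   indices, e.g. `c(dic = 1, fluorescence = 2)`; exactly one channel per
#'   declared role.
#' @return An object of class `recording5d`.
#' @export
recording5d <- function(tensor, id = "rec",
                        frame_interval_s, z_step_um,
                        channel_roles = c(dic = 1, fluorescence = 2)) {
  if (!is.array(tensor) || length(dim(tensor)) != 5) {
    stopf("`tensor` must be a 5-D array with axes (t, z, c, y, x)")
  }
  if (any(dim(tensor) < 1)) stopf("all five axis lengths must be >= 1")
  if (!all(is.finite(tensor))) stopf("`tensor` values must be finite")
  if (any(tensor < 0)) stopf("`tensor` values must be >= 0")
  check_scalar_number(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar_number(z_step_um, "z_step_um", positive = TRUE)
  if (is.null(names(channel_roles)) || anyDuplicated(names(channel_roles)) ||
      anyDuplicated(channel_roles)) {
    stopf("`channel_roles` must map each role to exactly one distinct channel")
  }
  bad <- setdiff(names(channel_roles), c("dic", "fluorescence"))
  if (length(bad)) stopf("unknown channel role `%s`", bad[1])
  if (any(channel_roles < 1 | channel_roles > dim(tensor)[3])) {
    stopf("`channel_roles` indices must lie in 1..%d", dim(tensor)[3])
  }
  structure(
    list(id = as.character(id), tensor = tensor,
         frame_interval_s = frame_interval_s, z_step_um = z_step_um,
         channel_roles = channel_roles),
    class = "recording5d"
  )
}

#' @export
print.recording5d <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<recording5d `%s`: %d frames x %d z x %d channels x %dx%d px, dt = %gs, dz = %g um>\n",
              x$id, d[1], d[2], d[3], d[4], d[5],
              x$frame_interval_s, x$z_step_um))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a recording to a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written in t-major (t, z, c) order as 16-bit grayscale; axis
#' lengths, channel roles and timing metadata go to `<path>.json`. A tensor
#' whose values are 16-bit integers round-trips bit-for-bit through
#' [read_recording()].
#'
#' @param rec A [recording5d()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording5d"))
  d <- dim(rec$tensor)
  if (max(rec$tensor) > 65535 || any(rec$tensor != round(rec$tensor))) {
    stopf("tensor must hold 16-bit integer intensities (0..65535) for exact storage")
  }
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (cc in seq_len(d[3])) {
    m <- rec$tensor[t, z, cc, , ]
    dim(m) <- d[4:5]
    pages[[k]] <- m / 65535
    k <- k + 1L
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stopf("failed to write `%s`: %s", path,
                                           conditionMessage(e)))
  jsonlite::write_json(
    list(id = rec$id, axes = "tzcyx", dim = d,
         frame_interval_s = rec$frame_interval_s, z_step_um = rec$z_step_um,
         channel_roles = as.list(rec$channel_roles)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

parse_axis_order <- function(axis_order) {
  ax <- strsplit(axis_order, "")[[1]]
  bad <- setdiff(ax, c("t", "z", "c", "y", "x"))
  if (length(bad)) stopf("unknown axis `%s` in axis_order `%s`", bad[1], axis_order)
  if (anyDuplicated(ax)) stopf("duplicated axis in axis_order `%s`", axis_order)
  if (!all(c("y", "x") %in% ax)) stopf("axis_order must contain `y` and `x`")
  if (!identical(tail(ax, 2), c("y", "x"))) {
    stopf("axis_order must end in `yx` (pages are y-by-x planes)")
  }
  ax
}

#' Read a recording from TIFF (+ sidecar) back into a `recording5d`
#'
#' Inverts [write_recording()] exactly for 16-bit data. If no JSON sidecar is
#' present, `axis_order` and `metadata` must describe the file: pages span
#' the leading axes of `axis_order` (slowest first), missing axes of length 1
#' are inserted, and the internal order is always (t, z, c, y, x). A
#' directory path is read as a fallback directory-of-2-D-TIFFs layout with
#' files named `t###_z###_c###.tif`.
#'
#' @param path TIFF file (or directory of 2-D TIFFs).
#' @param axis_order On-disk axis order string, a subset/permutation of
#'   `"tzcyx"` ending in `"yx"`. Ignored when a sidecar is present.
#' @param metadata Named list of overrides: `frame_interval_s`, `z_step_um`,
#'   `channel_roles`, `id`, and (sidecar-less files) axis lengths `n_t`,
#'   `n_z`, `n_c`.
#' @return A [recording5d()].
#' @export
read_recording <- function(path, axis_order = "tzcyx", metadata = list()) {
  if (dir.exists(path)) return(read_recording_dir(path, metadata))
  if (!file.exists(path)) stopf("cannot read `%s`: no such file", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stopf("failed to read `%s`: %s", path,
                                              conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  side <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    axis_order <- side$axes
  }
  ax <- parse_axis_order(axis_order)
  lead <- setdiff(ax, c("y", "x"))
  if (!is.null(side)) {
    d5 <- setNames(as.integer(side$dim), c("t", "z", "c", "y", "x"))
  } else {
    d5 <- c(t = 1L, z = 1L, c = 1L,
            y = nrow(pages[[1]]), x = ncol(pages[[1]]))
    for (a in c("t", "z", "c")) {
      key <- paste0("n_", a)
      if (!is.null(metadata[[key]])) d5[a] <- as.integer(metadata[[key]])
    }
    # any single unspecified leading axis absorbs the page count
    unspec <- lead[!paste0("n_", lead) %in% names(metadata)]
    if (length(unspec) == 1 && prod(d5[lead]) != length(pages)) {
      d5[unspec] <- length(pages) / prod(d5[setdiff(lead, unspec)])
    }
  }
  if (prod(d5[c("t", "z", "c")]) != length(pages)) {
    stopf("page count %d does not match axis lengths t*z*c = %d",
          length(pages), prod(d5[c("t", "z", "c")]))
  }
  # assemble: page index spans `lead` axes, leftmost slowest
  tensor <- array(0, unname(d5[c("t", "z", "c", "y", "x")]))
  n_lead <- d5[lead]
  idx <- matrix(1L, length(pages), 3,
                dimnames = list(NULL, c("t", "z", "c")))
  if (length(lead)) {
    grid <- do.call(expand.grid, rev(lapply(n_lead, seq_len)))  # rightmost fastest
    grid <- grid[, rev(seq_along(lead)), drop = FALSE]
    colnames(grid) <- lead
    for (a in lead) idx[, a] <- grid[[a]]
  }
  for (k in seq_along(pages)) {
    tensor[idx[k, "t"], idx[k, "z"], idx[k, "c"], , ] <- pages[[k]]
  }
  meta <- list(
    id = metadata$id %||% side$id %||% sub("\\.tiff?$", "", basename(path)),
    frame_interval_s = metadata$frame_interval_s %||% side$frame_interval_s,
    z_step_um = metadata$z_step_um %||% side$z_step_um,
    channel_roles = metadata$channel_roles %||%
      (if (!is.null(side)) unlist(side$channel_roles) else
         if (d5["c"] == 2) c(dic = 1, fluorescence = 2) else c(dic = 1))
  )
  if (is.null(meta$frame_interval_s)) stopf("`frame_interval_s` missing: not in sidecar or metadata")
  if (is.null(meta$z_step_um)) stopf("`z_step_um` missing: not in sidecar or metadata")
  recording5d(tensor, id = meta$id,
              frame_interval_s = meta$frame_interval_s,
              z_step_um = meta$z_step_um,
              channel_roles = meta$channel_roles)
}

read_recording_dir <- function(path, metadata = list()) {
  files <- list.files(path, pattern = "^t\\d+_z\\d+_c\\d+\\.tiff?$",
                      full.names = TRUE)
  if (!length(files)) stopf("no t###_z###_c###.tif files found in `%s`", path)
  parse1 <- function(f) {
    as.integer(regmatches(basename(f),
                          gregexpr("\\d+", basename(f)))[[1]][1:3])
  }
  coords <- t(vapply(files, parse1, integer(3)))
  d5 <- c(max(coords[, 1]), max(coords[, 2]), max(coords[, 3]))
  first <- tiff::readTIFF(files[1], as.is = TRUE)
  tensor <- array(0, c(d5, nrow(first), ncol(first)))
  for (i in seq_along(files)) {
    tensor[coords[i, 1], coords[i, 2], coords[i, 3], , ] <-
      tiff::readTIFF(files[i], as.is = TRUE)
  }
  side <- NULL
  sc <- file.path(path, "recording.json")
  if (file.exists(sc)) side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  recording5d(
    tensor, id = metadata$id %||% side$id %||% basename(path),
    frame_interval_s = metadata$frame_interval_s %||% side$frame_interval_s,
    z_step_um = metadata$z_step_um %||% side$z_step_um,
    channel_roles = metadata$channel_roles %||%
      (if (!is.null(side)) unlist(side$channel_roles)
       else c(dic = 1, fluorescence = 2))
  )
}

#' Read / write frame label tables
#'
#' A label table is a tibble with columns `recording_id`, `frame_index`
#' (0-based) and `label` (`"before"` or `"after"`); frame indices are unique
#' per recording.
#'
#' @param path CSV path.
#' @return `read_labels()` returns the validated tibble; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    recording_id = readr::col_character(),
    frame_index = readr::col_integer(),
    label = readr::col_character()
  ))
  validate_labels(tab)
}

#' @rdname read_labels
#' @param table A label table (data frame with the three columns above).
#' @export
write_labels <- function(table, path) {
  table <- validate_labels(table)
  readr::write_csv(table, path)
  invisible(path)
}

validate_labels <- function(tab) {
  need <- c("recording_id", "frame_index", "label")
  if (!all(need %in% names(tab))) {
    stopf("label table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(tab)) {
    if (!all(tab$label %in% c("before", "after"))) {
      stopf("labels must be `before` or `after`")
    }
    if (any(tab$frame_index < 0) || any(tab$frame_index != round(tab$frame_index))) {
      stopf("frame_index must be nonnegative integers (0-based)")
    }
    if (anyDuplicated(tab[, c("recording_id", "frame_index")])) {
      stopf("duplicate (recording_id, frame_index) rows")
    }
  }
  as_tibble(tab[, need])
}
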