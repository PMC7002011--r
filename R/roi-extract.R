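# Convert a 0-based half-open pixel box to 1-based inclusive row/col ranges,
# with bounds checking against the stack.
box_indices <- function(roi, H, W) {
  rows <- (roi$y0 + 1L):roi$y1
  cols <- (roi$x0 + 1L):roi$x1
  if (roi$y0 < 0 || roi$x0 < 0 || roi$y1 > H || roi$x1 > W ||
      roi$y1 <= roi$y0 || roi$x1 <= roi$x0) {
    abort(sprintf("ROI '%s' box [%d,%d)x[%d,%d) is outside the %d x %d image.",
                  roi$roi_id, roi$x0, roi$x1, roi$y0, roi$y1, W, H))
  }
  list(rows = rows, cols = cols)
}

#' Extract the mean-intensity trace of one ROI
#'
#' Averages the pixels of the ROI box at every frame of the requested channel.
#'
#' @param stack A [channel_stack()].
#' @param roi One ROI record (a one-row data frame or list with `roi_id`,
#'   `x0`, `y0`, `x1`, `y1` as a 0-based half-open pixel box).
#' @param channel Channel name.
#' @return Raw trace tibble (`state = "raw"`).
#' @export
extract_roi_trace <- function(stack, roi, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack)
  ix <- box_indices(roi, d[2], d[3])
  arr <- stack$frames[[channel]]
  if (is.null(arr)) abort(sprintf("Channel '%s' not in stack.", channel))
  vals <- vapply(seq_len(d[1]), function(f) mean(arr[f, ix$rows, ix$cols]), numeric(1))
  tibble(
    roi_id = roi$roi_id,
    cell_id = roi$cell_id %||% NA_character_,
    population = roi$population %||% NA_character_,
    kind = roi$kind %||% NA_character_,
    channel = channel, frame = seq_len(d[1]),
    time_s = stack$frame_times_s, value = vals, state = "raw"
  )
}

#' Extract raw traces for every ROI of an annotation table
#'
#' @param stack A [channel_stack()].
#' @param roi_table ROI tibble with box geometry columns.
#' @param channels Channels to extract (default: all channels of the stack).
#' @return Long raw trace tibble across all ROIs and channels.
#' @export
extract_roi_traces <- function(stack, roi_table, channels = NULL) {
  channels <- channels %||% stack$channel_names
  purrr::map_dfr(seq_len(nrow(roi_table)), function(i) {
    roi <- as.list(roi_table[i, ])
    purrr::map_dfr(channels, function(ch) extract_roi_trace(stack, roi, ch))
  })
}

#' Membrane intensity profiles over time from a perpendicular ROI
#'
#' The membrane-recruitment protocol records a 15-position profile per frame
#' from a box drawn perpendicular to the plasma membrane, ordered from outside
#' the cell toward the cytosol; each position is the mean across the 36-px
#' width of the box.
#'
#' @param stack A [channel_stack()].
#' @param roi ROI record of kind `membrane_perpendicular`; one box axis must
#'   be 15 px long (the probe axis), the other is the averaging width.
#' @param channel Channel name.
#' @return Profile tibble: `roi_id`, `channel`, `frame`, `time_s`, `position`
#'   (1 = extracellular end), `value`.
#' @export
extract_membrane_profile <- function(stack, roi, channel) {
  if (!is.null(roi$kind) && !is.na(roi$kind) && roi$kind != "membrane_perpendicular") {
    abort(sprintf("ROI '%s' has kind '%s'; expected 'membrane_perpendicular'.",
                  roi$roi_id, roi$kind))
  }
  d <- dim(stack)
  ix <- box_indices(roi, d[2], d[3])
  n_rows <- length(ix$rows); n_cols <- length(ix$cols)
  along_rows <- n_rows == 15L
  if (!along_rows && n_cols != 15L) {
    abort(sprintf("ROI '%s' is %d x %d px; the probe axis must be 15 px.",
                  roi$roi_id, n_cols, n_rows))
  }
  arr <- stack$frames[[channel]]
  purrr::map_dfr(seq_len(d[1]), function(f) {
    sub <- arr[f, ix$rows, ix$cols, drop = TRUE]
    prof <- if (along_rows) rowMeans(sub) else colMeans(sub)
    tibble(roi_id = roi$roi_id, channel = channel, frame = f,
           time_s = stack$frame_times_s[f],
           position = seq_len(15L), value = as.numeric(prof))
  })
}

#' Locate the membrane peak of a profile series
#'
#' The plasma-membrane position is defined on the final frame of the time
#' lapse: the position of maximum intensity, with ties broken toward the
#' extracellular side (smaller index). A peak at either end of the profile
#' triggers a warning because the peak +/- 1 averaging window truncates there.
#'
#' @param profiles Profile tibble from [extract_membrane_profile()].
#' @return Integer peak position.
#' @export
locate_membrane_peak <- function(profiles) {
  stopifnot(all(c("frame", "position", "value") %in% names(profiles)))
  last <- profiles %>%
    dplyr::filter(.data$frame == max(.data$frame)) %>%
    arrange(.data$position)
  if (nrow(last) == 0) abort("Profile series has no frames.")
  peak <- last$position[which.max(last$value)]
  if (peak == min(last$position) || peak == max(last$position)) {
    warn(sprintf("Membrane peak at boundary position %d; the peak +/- 1 window will truncate.", peak))
  }
  as.integer(peak)
}

# Sample a polyline at 1-px arc-length steps; returns per-sample position,
# unit tangent and cumulative arc length. Vertices are (x, y) pixel centers.
sample_polyline <- function(path, step = 1) {
  stopifnot(is.matrix(path), ncol(path) == 2, nrow(path) >= 2)
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) abort("Polyline has zero-length segments.")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(path)] <- nrow(path) - 1L
  frac <- (s - cum[idx]) / seg_len[idx]
  pts <- path[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seg_len[idx]
  list(s = s, x = pts[, 1], y = pts[, 2], tx = tang[, 1], ty = tang[, 2])
}

# Width-averaged intensity along a sampled polyline on one image (matrix).
# Width offsets are taken perpendicular to the local tangent; samples use
# nearest-pixel lookup. Errors if any sample falls outside the image.
profile_along_path <- function(img, sp, width_px) {
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  H <- nrow(img); W <- ncol(img)
  vapply(seq_along(sp$s), function(i) {
    px <- sp$x[i] - offs * sp$ty[i]
    py <- sp$y[i] + offs * sp$tx[i]
    ri <- round(py); ci <- round(px)
    if (any(ri < 1 | ri > H | ci < 1 | ci > W)) {
      abort("Sampling path exits the image bounds.")
    }
    mean(img[cbind(ri, ci)])
  }, numeric(1))
}

#' Build a kymograph along a polyline
#'
#' Samples the path at 1-px arc-length steps on every frame, averaging across
#' `width_px` perpendicular to the local tangent (the cortical kymographs of
#' the side-relocalization experiments use a 2-px-wide path averaged to a
#' 1-px line).
#'
#' @param stack A [channel_stack()].
#' @param path Two-column matrix of (x, y) polyline vertices in pixel units.
#' @param width_px Averaging width in pixels (>= 1).
#' @param channel Channel name.
#' @return Numeric matrix, rows = time, columns = arc-length position.
#' @export
build_kymograph <- function(stack, path, width_px = 1, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  if (width_px < 1) abort("`width_px` must be >= 1.")
  sp <- sample_polyline(path)
  d <- dim(stack)
  out <- t(vapply(seq_len(d[1]), function(f) {
    profile_along_path(stack_frame(stack, channel, f), sp, width_px)
  }, numeric(length(sp$s))))
  dimnames(out) <- list(frame = NULL, arc_px = NULL)
  out
}

#' Sum projection of consecutive frames
#'
#' Pixel-wise sum of `n_frames` consecutive single-plane images (5 by
#' default, the standard display projection for cortical tip quantification).
#'
#' @param stack A [channel_stack()].
#' @param channel Channel name.
#' @param start_frame First frame of the window.
#' @param n_frames Window length (default 5).
#' @return Numeric matrix (rows x cols).
#' @export
sum_project <- function(stack, channel, start_frame = 1L, n_frames = 5L) {
  d <- dim(stack)
  if (start_frame < 1 || start_frame + n_frames - 1 > d[1]) {
    abort(sprintf("Projection window [%d, %d] exceeds the %d-frame stack.",
                  start_frame, start_frame + n_frames - 1, d[1]))
  }
  frames <- start_frame:(start_frame + n_frames - 1L)
  Reduce(`+`, lapply(frames, function(f) stack_frame(stack, channel, f)))
}

#' Cortical tip profile from a segmented line
#'
#' Collects the width-averaged intensity of a segmented line drawn along the
#' cell tip (3 px wide by default), subtracts the camera background, and
#' parameterizes positions by signed arc-length distance (in micrometers)
#' from the geometric center of the tip, which must lie on the line.
#'
#' @param image 2-D intensity matrix (e.g. a [sum_project()] output).
#' @param tip_line Two-column matrix of (x, y) polyline vertices.
#' @param width_px Averaging width (default 3).
#' @param background Scalar camera background to subtract.
#' @param center Length-2 (x, y) geometric tip center; must lie on the line
#'   (within half a pixel).
#' @param pixel_size_um Pixel size for the position axis (default 0.083).
#' @return Tip profile tibble: `position_um` (0 at the center), `value`.
#' @export
extract_tip_profile <- function(image, tip_line, width_px = 3, background = 0,
                                center, pixel_size_um = 0.083) {
  sp <- sample_polyline(tip_line)
  # signed arc position of the center: nearest path sample
  d2 <- (sp$x - center[1])^2 + (sp$y - center[2])^2
  i0 <- which.min(d2)
  if (sqrt(d2[i0]) > 0.5 + 1e-9) {
    abort("`center` does not lie on the tip line.")
  }
  vals <- profile_along_path(image, sp, width_px)
  tibble(position_um = (sp$s - sp$s[i0]) * pixel_size_um,
         value = vals - background)
}

#' Central tip intensity: mean of 5 pixels around the geometric center
#'
#' @param profile Tip profile tibble from [extract_tip_profile()].
#' @param n_px Number of central samples to average (default 5).
#' @return Scalar mean of the `n_px` samples centered on position 0.
#' @export
tip_center_value <- function(profile, n_px = 5L) {
  stopifnot(all(c("position_um", "value") %in% names(profile)))
  n <- nrow(profile)
  if (n < n_px) abort(sprintf("Profile has %d positions; need at least %d.", n, n_px))
  ord <- order(profile$position_um)
  pos <- profile$position_um[ord]
  i0 <- which.min(abs(pos))
  h <- (n_px - 1L) %/% 2L
  if (i0 - h < 1L || i0 + h > n) {
    abort("Profile does not span the center widely enough for the averaging window.")
  }
  mean(profile$value[ord][(i0 - h):(i0 + h)])
}
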