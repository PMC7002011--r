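#' Multi-channel time-lapse stack
#'
#' A light container for a registered multi-channel time lapse: one numeric
#' array per channel with dimensions (time, rows, cols), shared frame times in
#' seconds and the pixel size in micrometers.
#'
#' @param frames Named list of 3-D arrays (time x rows x cols), one per
#'   channel; all channels must share dimensions.
#' @param frame_times_s Strictly increasing frame times (seconds).
#' @param pixel_size_um Pixel size (micrometers per pixel), default 0.083.
#' @return A `channel_stack`.
#' @export
channel_stack <- function(frames, frame_times_s, pixel_size_um = 0.083) {
  if (!is.list(frames) || is.null(names(frames)) || any(names(frames) == "")) {
    abort("`frames` must be a named list of 3-D arrays, one per channel.")
  }
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 1L) != 3L)) abort("Each channel must be a 3-D array (time x rows x cols).")
  if (length(unique(lapply(dims, identity))) != 1L) abort("All channels must share the same dimensions.")
  if (dims[[1]][1] != length(frame_times_s)) {
    abort("`frame_times_s` length must equal the number of frames.")
  }
  if (length(frame_times_s) > 1 && any(diff(frame_times_s) <= 0)) {
    abort("`frame_times_s` must be strictly increasing.")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames,
                 frame_times_s = as.numeric(frame_times_s),
                 pixel_size_um = pixel_size_um,
                 channel_names = names(frames)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<channel_stack> %s | %d frames of %d x %d px | %.3f um/px\n",
              paste(x$channel_names, collapse = "+"), d[1], d[2], d[3],
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$frames[[1]])

stack_frame <- function(stack, channel, frame) {
  if (!channel %in% stack$channel_names) {
    abort(sprintf("Channel '%s' not in stack (%s).", channel,
                  paste(stack$channel_names, collapse = ", ")))
  }
  stack$frames[[channel]][frame, , , drop = TRUE]
}

#' Write / read a stack as multi-page TIFF
#'
#' Pages are interleaved in acquisition order — for each frame the RFP channel
#' precedes the GFP channel. Intensities are stored as 16-bit samples scaled
#' by `scale` (counts per unit), so round-tripping quantizes values to
#' 1/`scale` of a count; write at full precision requires CSV export instead.
#'
#' @param stack A `channel_stack`.
#' @param path TIFF file path.
#' @param scale Counts full-scale; default 65535 (one camera count per level).
#' @return `write_stack_tiff()`: `path`, invisibly. `read_stack_tiff()`: a
#'   `channel_stack`.
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  stopifnot(inherits(stack, "channel_stack"))
  n_t <- dim(stack)[1]
  pages <- list()
  for (f in seq_len(n_t)) {
    for (ch in stack$channel_names) {
      pages[[length(pages) + 1L]] <- pmin(pmax(stack_frame(stack, ch, f) / scale, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param channel_names Channel names in per-frame page order.
#' @param frame_times_s Frame times of the recording.
#' @param pixel_size_um Pixel size (micrometers).
#' @export
read_stack_tiff <- function(path, frame_times_s,
                            channel_names = c("RFP", "GFP"),
                            pixel_size_um = 0.083, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(channel_names)
  if (length(pages) %% n_ch != 0L) {
    abort("Page count is not a multiple of the number of channels.")
  }
  n_t <- length(pages) %/% n_ch
  d <- dim(pages[[1]])
  frames <- lapply(seq_len(n_ch), function(ci) {
    arr <- array(0, dim = c(n_t, d[1], d[2]))
    for (f in seq_len(n_t)) arr[f, , ] <- pages[[(f - 1L) * n_ch + ci]] * scale
    arr
  })
  names(frames) <- channel_names
  channel_stack(frames, frame_times_s, pixel_size_um)
}

#' Write / read an ROI annotation table as CSV
#'
#' Columns: `roi_id`, `cell_id`, `population`, `kind`, and the 0-based
#' half-open pixel box `x0, y0, x1, y1`.
#'
#' @param roi_table ROI tibble.
#' @param path CSV path.
#' @export
write_roi_csv <- function(roi_table, path) {
  utils::write.csv(roi_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bleach-corrected difference stack relative to the first frame
#'
#' Reproduces the display pipeline used for relocalization snapshots: the
#' whole-field mean intensity `m(t)` is fitted to a mono-exponential decay
#' `c e^(-lambda t) + d`; each frame is divided by the fitted decay
#' (normalized to 1 at the first frame); the corrected first frame is then
#' subtracted from every corrected frame, so gains over the initial state show
#' as positive signal. The first output frame is identically zero.
#'
#' @param stack A `channel_stack` with at least 3 frames.
#' @param channel Channel to process.
#' @return A single-channel `channel_stack` of difference images.
#' @export
make_difference_stack <- function(stack, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  n_t <- dim(stack)[1]
  if (n_t < 3L) abort("Need at least 3 frames to fit the exponential bleach model.")
  tt <- stack$frame_times_s
  m <- vapply(seq_len(n_t), function(f) mean(stack_frame(stack, channel, f)), numeric(1))
  span <- max(tt) - min(tt)
  if (diff(range(m)) <= 1e-9 * max(abs(m), 1)) {
    # no measurable decay: skip the fit, subtract the first frame directly
    decay <- rep(1, n_t)
    return(subtract_first(stack, channel, decay))
  }
  # nls.lm rather than nlsLM: over short windows the decay is nearly linear
  # and (c, lambda, d) are poorly identified; LM damping still yields the
  # fitted decay curve, which is all the correction needs
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(cc = max(m[1] - m[n_t], 1e-6),
                 lambda = 1 / max(span, 1e-6), d = min(m)),
      fn = function(p) m - (p$cc * exp(-p$lambda * tt) + p$d),
      lower = c(0, 0, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    abort(sprintf(
      "Exponential bleach fit did not converge (field means range %.4g-%.4g).",
      min(m), max(m)))
  }
  p <- fit$par
  decay <- p$cc * exp(-p$lambda * tt) + p$d
  decay <- decay / decay[1]
  if (any(decay <= 0)) abort("Fitted bleach decay is non-positive; cannot correct.")
  subtract_first(stack, channel, decay)
}

subtract_first <- function(stack, channel, decay) {
  n_t <- dim(stack)[1]
  corrected <- sweep(stack$frames[[channel]], 1, decay, "/")
  first <- corrected[1, , , drop = TRUE]
  for (f in seq_len(n_t)) corrected[f, , ] <- corrected[f, , ] - first
  out <- list(corrected)
  names(out) <- channel
  channel_stack(out, stack$frame_times_s, stack$pixel_size_um)
}
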