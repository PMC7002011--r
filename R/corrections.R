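#' Estimate the camera/background series from control regions
#'
#' Averages, per channel and frame, the raw traces of either tag-free cells
#' (the whole-cell recruitment protocol measures background from untagged
#' cells mixed into the population) or cell-free regions (the cortex-side and
#' tip protocols measure camera background from five cell-free regions).
#'
#' @param traces Long trace table. If a `population` column is present, rows
#'   are restricted to the population matching `source`; otherwise every ROI
#'   in the table is treated as a background source.
#' @param source `"cell_free"` or `"tag_free"`.
#' @return A background tibble: `channel`, `frame`, `time_s`, `background`,
#'   `source`, `n_sources`.
#' @export
estimate_background <- function(traces, source = c("cell_free", "tag_free")) {
  source <- match.arg(source)
  assert_trace_table(traces)
  if ("population" %in% names(traces)) {
    wanted <- if (source == "cell_free") "cell_free" else "tag_free"
    sub <- dplyr::filter(traces, .data$population == wanted)
    other <- setdiff(intersect(unique(traces$population), c("cell_free", "tag_free")),
                     wanted)
    if (nrow(sub) == 0 && length(other) > 0) {
      abort(sprintf(
        "No '%s' traces found, but the table contains '%s' traces; background sources must not be mixed across protocols.",
        wanted, paste(other, collapse = "', '")))
    }
  } else {
    sub <- traces
  }
  if (nrow(sub) == 0) abort(sprintf("No traces available for background source '%s'.", source))

  lens <- sub %>% group_by(.data$roi_id, .data$channel) %>% summarise(n = n(), .groups = "drop")
  if (n_distinct(lens$n) != 1L) abort("Background source traces must all have the same length.")

  sub %>%
    group_by(.data$channel, .data$frame) %>%
    summarise(time_s = .data$time_s[1], background = mean(.data$value),
              n_sources = n_distinct(.data$roi_id), .groups = "drop") %>%
    mutate(source = source) %>%
    select("channel", "frame", "time_s", "background", "source", "n_sources")
}

#' Photobleaching correction coefficients from control cells
#'
#' For each control cell i, the per-frame bleaching coefficient is the
#' background-subtracted signal normalized to its initial value,
#' `D_i(t) = (F_i(t) - B(t)) / (F_i(0) - B(0))`; it equals 1 at the first
#' frame by construction. Each per-cell series is smoothed with a centered
#' moving average (window 5 by default), and the smoothed series are then
#' averaged across control cells.
#'
#' Controls are measured in their own channel: RFP-control cells provide the
#' RFP coefficient, GFP-control cells the GFP coefficient.
#'
#' @param traces Long trace table containing the control cells (a
#'   `population` column is used to select them when present).
#' @param background Background tibble from [estimate_background()].
#' @param population `"rfp_control"` or `"gfp_control"`.
#' @param window Odd moving-average window (default 5).
#' @param exclude Optional ROI ids to hold out (e.g. for leave-one-out
#'   control-flatness checks).
#' @param context Free-text label recording which protocol the series serves
#'   (e.g. `"whole_cell_rfp"`, `"side_gfp"`, `"tip_gfp"`).
#' @return A bleach tibble: `channel`, `frame`, `coefficient`, with
#'   attributes `smoothing_window`, `n_control_cells`, `context`.
#' @export
bleach_series <- function(traces, background,
                          population = c("rfp_control", "gfp_control"),
                          window = 5L, exclude = NULL, context = NULL) {
  population <- match.arg(population)
  assert_trace_table(traces)
  ch <- if (population == "rfp_control") "RFP" else "GFP"
  sub <- traces
  if ("population" %in% names(sub)) {
    sub <- dplyr::filter(sub, .data$population == !!population)
  }
  sub <- dplyr::filter(sub, .data$channel == ch, !.data$roi_id %in% exclude)
  if (nrow(sub) == 0) abort(sprintf("No %s traces available to estimate bleaching.", population))

  bg <- dplyr::filter(background, .data$channel == ch)
  if (nrow(bg) == 0) abort(sprintf("Background series has no %s channel.", ch))

  per_cell <- sub %>%
    left_join(select(bg, "frame", "background"), by = "frame") %>%
    arrange(.data$roi_id, .data$frame) %>%
    group_by(.data$roi_id)
  # validate the t0 normalizer per cell before dividing
  t0 <- per_cell %>% summarise(d0 = .data$value[1] - .data$background[1], .groups = "drop")
  bad <- t0$roi_id[t0$d0 <= 0]
  if (length(bad) > 0) {
    abort(sprintf(
      "Control cell(s) %s have non-positive background-subtracted signal at t0; bleaching coefficients are undefined.",
      paste(bad, collapse = ", ")))
  }
  smoothed <- per_cell %>%
    mutate(coef = (.data$value - .data$background) /
             (.data$value[1] - .data$background[1])) %>%
    mutate(coef = moving_average(.data$coef, window)) %>%
    ungroup()

  out <- smoothed %>%
    group_by(.data$frame) %>%
    summarise(coefficient = mean(.data$coef), .groups = "drop") %>%
    mutate(channel = ch) %>%
    select("channel", "frame", "coefficient")
  attr(out, "smoothing_window") <- as.integer(window)
  attr(out, "n_control_cells") <- n_distinct(sub$roi_id)
  attr(out, "context") <- context %||% NA_character_
  out
}

#' Background-subtract and bleach-correct raw traces
#'
#' Applies `S(t) = (Raw(t) - B(t)) / D(t)` per ROI, where `B` is the
#' background series and `D` the (smoothed, cell-averaged) bleaching
#' coefficient for the trace's channel. Only channels present in `bleach` are
#' corrected and returned. Negative corrected values are kept — clipping
#' would bias weak near-zero signals.
#'
#' @param traces Long raw trace table.
#' @param background Background tibble from [estimate_background()].
#' @param bleach Bleach tibble from [bleach_series()] (bind rows of two
#'   series to correct both channels at once).
#' @return Corrected trace tibble (`state = "corrected"`).
#' @export
correct_traces <- function(traces, background, bleach) {
  assert_trace_table(traces)
  if (any(bleach$coefficient <= 0)) {
    abort("Bleaching coefficient is non-positive at some frame; correction is undefined.")
  }
  channels <- unique(bleach$channel)
  sub <- dplyr::filter(traces, .data$channel %in% channels)
  out <- sub %>%
    left_join(select(background, "channel", "frame", "background"),
              by = c("channel", "frame")) %>%
    left_join(select(bleach, "channel", "frame", "coefficient"),
              by = c("channel", "frame"))
  if (anyNA(out$background) || anyNA(out$coefficient)) {
    abort("Background/bleach series do not cover every frame of the traces.")
  }
  out %>%
    mutate(value = (.data$value - .data$background) / .data$coefficient,
           state = "corrected") %>%
    select(-"background", -"coefficient")
}

#' Net signal: subtract each trace's initial value
#'
#' `N(t) = S(t) - S(0)`, so every net trace is exactly 0 at the first frame.
#' Expects bleach-corrected input.
#'
#' @param traces Corrected trace tibble.
#' @return Net trace tibble (`state = "net"`).
#' @export
net_traces <- function(traces) {
  assert_trace_table(traces)
  if ("state" %in% names(traces) && !all(traces$state == "corrected")) {
    abort("net_traces() expects corrected traces (state = \"corrected\").")
  }
  traces %>%
    group_by(.data$roi_id, .data$channel) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(value = .data$value - .data$value[1]) %>%
    ungroup() %>%
    mutate(state = "net")
}

#' Normalize each trace to its initial value
#'
#' `S(t) / S(0)`, so every normalized trace is exactly 1 at the first frame.
#' Used for tip time courses, where depletion reads out as a decay below 1.
#'
#' @param traces Corrected trace tibble; the initial value of every trace must
#'   be positive.
#' @return Normalized trace tibble (`state = "normalized"`).
#' @export
normalize_traces <- function(traces) {
  assert_trace_table(traces)
  if ("state" %in% names(traces) && !all(traces$state == "corrected")) {
    abort("normalize_traces() expects corrected traces (state = \"corrected\").")
  }
  grouped <- traces %>%
    group_by(.data$roi_id, .data$channel) %>%
    arrange(.data$frame, .by_group = TRUE)
  t0 <- grouped %>% summarise(v0 = .data$value[1], .groups = "drop")
  bad <- t0$roi_id[t0$v0 <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Trace(s) %s have non-positive initial value; cannot normalize.",
                  paste(unique(bad), collapse = ", ")))
  }
  grouped %>%
    mutate(value = .data$value / .data$value[1]) %>%
    ungroup() %>%
    mutate(state = "normalized")
}

#' Average the membrane-peak region of profile series over time
#'
#' Given a time series of 15-position membrane profiles and the peak position,
#' averages positions `peak - 1 .. peak + 1` at each frame. If the peak sits
#' at the first or last position, the two available positions are averaged and
#' a warning is emitted.
#'
#' @param profiles Profile tibble (`roi_id`, `channel`, `frame`, `time_s`,
#'   `position`, `value`), typically bleach-corrected.
#' @param peak Integer peak position from [locate_membrane_peak()].
#' @return A trace tibble (one value per frame).
#' @export
peak_value_series <- function(profiles, peak) {
  stopifnot(all(c("frame", "position", "value") %in% names(profiles)))
  if (!"time_s" %in% names(profiles)) profiles$time_s <- NA_real_
  positions <- sort(unique(profiles$position))
  if (!peak %in% positions) abort("`peak` is not a position of the profile series.")
  window <- intersect((peak - 1L):(peak + 1L), positions)
  if (length(window) < 3L) {
    warn(sprintf(
      "Peak at boundary position %d: averaging the %d available positions.",
      peak, length(window)))
  }
  out <- profiles %>%
    dplyr::filter(.data$position %in% window) %>%
    group_by(dplyr::across(dplyr::any_of(c("roi_id", "cell_id", "population",
                                           "channel", "state"))),
             .data$frame) %>%
    summarise(time_s = .data$time_s[1], value = mean(.data$value), .groups = "drop")
  out$peak_position <- peak
  out
}
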