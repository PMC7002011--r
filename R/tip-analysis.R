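#' Normalized tip-signal time courses
#'
#' Full tip protocol: the GFP bleaching coefficient is estimated at the tips
#' of GFP-control cells (background from cell-free regions), sample tip traces
#' are background- and bleach-corrected, then each cell is normalized to its
#' own initial value, so depletion reads out as a decay below 1. Sparse
#' sampling (e.g. 4 time points instead of 30) is supported as long as control
#' and sample traces share the time axis.
#'
#' @param traces Long raw trace table containing sample tip traces
#'   (`population == "sample"`, `kind == "tip_patch"`), GFP-control tip traces
#'   and cell-free regions, all in the GFP channel.
#' @param window Moving-average window for the bleaching coefficient.
#' @param holdout_controls If `TRUE`, each GFP-control cell is corrected with
#'   a bleaching series estimated from the other controls (leave-one-out);
#'   used to validate control flatness without self-correction.
#' @return A `tip_timecourse`: list with `cells` (per-cell normalized traces),
#'   `summary` (per-frame group mean, sd, n) and `bleach` (the coefficient
#'   series used).
#' @export
tip_timecourse <- function(traces, window = 5L, holdout_controls = FALSE) {
  assert_trace_table(traces)
  gfp <- dplyr::filter(traces, .data$channel == "GFP")
  background <- estimate_background(gfp, source = "cell_free")
  ctl_tips <- dplyr::filter(gfp, .data$population == "gfp_control",
                            .data$kind == "tip_patch")
  if (nrow(ctl_tips) == 0) abort("No GFP-control tip traces to estimate bleaching from.")
  samp_tips <- dplyr::filter(gfp, .data$population == "sample",
                             .data$kind == "tip_patch")
  if (nrow(samp_tips) == 0) abort("No sample tip traces found.")

  bleach <- bleach_series(ctl_tips, background, population = "gfp_control",
                          window = window, context = "tip_gfp")
  cells <- samp_tips %>%
    correct_traces(background, bleach) %>%
    normalize_traces()

  if (holdout_controls) {
    ids <- unique(ctl_tips$roi_id)
    held <- purrr::map_dfr(ids, function(id) {
      bl <- bleach_series(ctl_tips, background, population = "gfp_control",
                          window = window, exclude = id, context = "tip_gfp")
      ctl_tips %>%
        dplyr::filter(.data$roi_id == id) %>%
        correct_traces(background, bl) %>%
        normalize_traces()
    })
    cells <- bind_rows(cells, held)
  }

  summary <- cells %>%
    group_by(.data$population, .data$frame) %>%
    summarise(time_s = .data$time_s[1], mean = mean(.data$value),
              sd = sd(.data$value), n_cells = n_distinct(.data$roi_id),
              .groups = "drop")
  structure(list(cells = cells, summary = summary, bleach = bleach),
            class = "tip_timecourse")
}

#' @export
print.tip_timecourse <- function(x, ...) {
  samp <- dplyr::filter(x$summary, .data$population == "sample")
  cat(sprintf("<tip_timecourse> %d sample cells, %d frames; final mean = %.3f\n",
              samp$n_cells[1], nrow(samp), samp$mean[nrow(samp)]))
  invisible(x)
}

#' @export
autoplot.tip_timecourse <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$time_s, y = .data$mean,
                               color = .data$population, fill = .data$population)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "time (s)", y = "normalized tip signal",
                  title = "Tip signal relative to t0 (mean +/- sd)") +
    ggplot2::theme_minimal()
}

#' Per-cell ratio of two channels at the cell tip
#'
#' Computes per-cell ratios A/B of paired tip intensities (e.g. Cdc42-GTP
#' reporter over GEF fluorescence from each channel's sum projection). Cells
#' with non-positive denominator are excluded and counted. Because the
#' per-cell mean of ratios and the ratio of group means generally differ,
#' both summaries are reported.
#'
#' @param values_a,values_b Paired per-cell scalars (numerator, denominator).
#' @param cell_id Optional cell identifiers.
#' @return A list: `ratios` (tibble `cell_id`, `value_a`, `value_b`, `ratio`),
#'   `n_excluded`, and `summary` (mean/sd of per-cell ratios and the ratio of
#'   group means).
#' @export
channel_ratio <- function(values_a, values_b, cell_id = NULL) {
  if (length(values_a) != length(values_b)) abort("`values_a` and `values_b` lengths differ.")
  cell_id <- cell_id %||% sprintf("cell%03d", seq_along(values_a))
  keep <- values_b > 0
  n_excluded <- sum(!keep)
  ratios <- tibble(cell_id = cell_id[keep],
                   value_a = values_a[keep], value_b = values_b[keep],
                   ratio = values_a[keep] / values_b[keep])
  list(
    ratios = ratios,
    n_excluded = n_excluded,
    summary = tibble(
      n_cells = nrow(ratios),
      ratio_mean = mean(ratios$ratio),
      ratio_sd = sd(ratios$ratio),
      ratio_of_means = mean(ratios$value_a) / mean(ratios$value_b)
    )
  )
}

#' Pointwise mean and sd of aligned cortical tip profiles
#'
#' Averages center-aligned tip profiles across cells on their common position
#' grid (thick line = mean, shaded band = sd in the standard display).
#'
#' @param profiles Tibble with `cell_id`, `position_um`, `value`; every cell
#'   must be sampled on the same position grid.
#' @return Tibble: `position_um`, `mean`, `sd`, `n_cells`.
#' @export
tip_profile_summary <- function(profiles) {
  stopifnot(all(c("cell_id", "position_um", "value") %in% names(profiles)))
  grids <- profiles %>%
    group_by(.data$cell_id) %>%
    summarise(key = paste(round(.data$position_um, 9), collapse = ","),
              .groups = "drop")
  if (n_distinct(grids$key) != 1L) {
    abort("Tip profiles are not on a common position grid; align them before summarizing.")
  }
  profiles %>%
    group_by(.data$position_um) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_cells = n_distinct(.data$cell_id), .groups = "drop") %>%
    arrange(.data$position_um)
}

#' Mean-and-band plot of a tip profile summary
#'
#' @param summary Output of [tip_profile_summary()].
#' @return A ggplot.
#' @export
plot_tip_profile <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$position_um, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(linewidth = 0.9, color = "#1b9e77") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "distance from tip center (um)",
                  y = "background-corrected intensity (a.u.)") +
    ggplot2::theme_minimal()
}
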