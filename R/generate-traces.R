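#' Saturating-exponential recruitment signal
#'
#' Closed form of the first-order recruitment model: `a * (1 - exp(-b * t))`.
#' Reaches half its plateau `a` at `t = ln(2) / b`.
#'
#' @param t Time in seconds (vector).
#' @param a Plateau (intensity units).
#' @param b Rate constant per second.
#' @return Numeric vector.
#' @export
sat_exp <- function(t, a, b) a * (1 - exp(-b * t))

# Noise-free fluorophore signal (before bleaching/background) of one ROI in
# one channel, per frame. `a` is the per-cell plateau for sample cells.
# Populations: sample cells carry the recruitment signal in the scenario's
# signal channel and autofluorescence elsewhere; control cells carry a
# constant fluorophore signal in their own channel; tag-free cells carry
# autofluorescence only; cell-free regions carry nothing.
true_signal <- function(cfg, population, kind, channel, tau, a = NA_real_) {
  sig_ch <- signal_channel(cfg)
  auto <- cfg$autofluorescence_level
  b <- log(2) / cfg$t_half_true_s
  if (population == "cell_free") return(rep(0, length(tau)))
  if (population == "tag_free") return(rep(auto, length(tau)))
  if (population == "sample") {
    if (channel != sig_ch) return(rep(auto, length(tau)))
    if (kind == "tip_patch") {
      # the whole tip trace decays from its initial level toward
      # (1 - depletion) of it, with the same first-order rate as the side
      # recruitment, so the normalized readout plateaus at exactly 1 - depletion
      t0_level <- auto + cfg$control_level
      return(t0_level * (1 - cfg$tip_depletion_fraction * (1 - exp(-b * tau))))
    }
    return(auto + sat_exp(tau, a, b))
  }
  # bleaching controls: constant fluorophore signal in their own channel
  own <- switch(population, rfp_control = "RFP", gfp_control = "GFP",
                abort(sprintf("Unknown population '%s'.", population)))
  if (channel == own) rep(auto + cfg$control_level, length(tau)) else rep(auto, length(tau))
}

# Apply acquisition: per-exposure bleaching, camera background, additive noise.
record_trace <- function(cfg, signal, channel, frames) {
  rate <- if (channel == "RFP") cfg$bleach_rate_rfp else cfg$bleach_rate_gfp
  bleach <- (1 - rate)^(frames - 1)
  signal * bleach + cfg$background_level + rnorm(length(signal), 0, cfg$noise_sd)
}

#' Generate synthetic per-ROI intensity traces with known ground truth
#'
#' Simulates the trace-level output of a mixed-population time-lapse: for each
#' sample cell a membrane-recruitment trace following
#' `(auto + a_i (1 - e^(-b tau))) (1 - k)^t + background + noise`, with
#' `b = ln(2) / t_half_true_s` and per-cell plateau `a_i` drawn log-normally
#' (mean `plateau_mean`, CV `plateau_cv`); constant-signal traces for RFP and
#' GFP bleaching-control cells under the same bleaching, background and noise;
#' autofluorescence-only traces for tag-free cells; and background-only traces
#' for cell-free regions. Relocalization scenarios (signal channel GFP)
#' additionally emit tip-patch traces for sample and GFP-control cells, with
#' sample tips decaying toward `(1 - tip_depletion_fraction)` of their initial
#' level at the same rate `b`.
#'
#' All randomness is fixed by `cfg$seed`: two calls with the same configuration
#' return identical datasets.
#'
#' @param cfg A [scenario_config()].
#' @return A `synthetic_dataset`: list with `traces` (long tibble: `roi_id`,
#'   `cell_id`, `population`, `kind`, `channel`, `frame`, `time_s`, `value`,
#'   `state = "raw"`), `roi_table` (one row per ROI), `truth` (per sample
#'   cell: `roi_id`, `a_true`, `b_true`, `t_half_true`) and `config`.
#' @examples
#' d <- generate_traces(scenario_preset("opto_50ms", n_sample_cells = 3,
#'                                      n_rfp_controls = 2, n_gfp_controls = 2))
#' dplyr::count(d$traces, population, kind, channel)
#' @export
generate_traces <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  frames <- seq_len(cfg$n_frames)
  tau <- (frames - 1) * cfg$cycle_period_s
  sig_ch <- signal_channel(cfg)
  with_tips <- sig_ch == "GFP"

  # per-cell plateaus, log-normal with the requested mean and CV
  a_i <- draw_plateaus(cfg$n_sample_cells, cfg$plateau_mean, cfg$plateau_cv)

  rois <- roi_plan(cfg, with_tips)
  truth <- tibble(
    roi_id = rois$roi_id[rois$population == "sample" & rois$kind != "tip_patch"],
    cell_id = rois$cell_id[rois$population == "sample" & rois$kind != "tip_patch"],
    a_true = a_i,
    b_true = log(2) / cfg$t_half_true_s,
    t_half_true = cfg$t_half_true_s
  )

  traces <- purrr::pmap_dfr(rois, function(roi_id, cell_id, population, kind) {
    a <- if (population == "sample" && kind != "tip_patch") {
      a_i[match(cell_id, truth$cell_id)]
    } else NA_real_
    purrr::map_dfr(c("RFP", "GFP"), function(ch) {
      sig <- true_signal(cfg, population, kind, ch, tau, a)
      vals <- if (population == "cell_free") {
        cfg$background_level + rnorm(length(sig), 0, cfg$noise_sd)
      } else {
        record_trace(cfg, sig, ch, frames)
      }
      tibble(
        roi_id = roi_id, cell_id = cell_id, population = population,
        kind = kind, channel = ch, frame = frames, time_s = tau,
        value = vals, state = "raw"
      )
    })
  })

  structure(list(traces = traces, roi_table = as_tibble(rois),
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

draw_plateaus <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

# ROI bookkeeping shared by the trace- and image-level generators.
roi_plan <- function(cfg, with_tips) {
  sample_kind <- if (signal_channel(cfg) == "GFP") "cortex_side" else "membrane_perpendicular"
  control_kind <- if (signal_channel(cfg) == "GFP") "cortex_side" else "whole_cell"
  rows <- list()
  add <- function(roi_id, cell_id, population, kind) {
    rows[[length(rows) + 1L]] <<- tibble(roi_id = roi_id, cell_id = cell_id,
                                         population = population, kind = kind)
  }
  for (i in seq_len(cfg$n_sample_cells)) {
    add(sprintf("samp%02d_mem", i), sprintf("cell_samp%02d", i), "sample", sample_kind)
    if (with_tips) add(sprintf("samp%02d_tip", i), sprintf("cell_samp%02d", i),
                       "sample", "tip_patch")
  }
  for (i in seq_len(cfg$n_rfp_controls)) {
    add(sprintf("rctl%02d", i), sprintf("cell_rctl%02d", i), "rfp_control", control_kind)
  }
  for (i in seq_len(cfg$n_gfp_controls)) {
    add(sprintf("gctl%02d", i), sprintf("cell_gctl%02d", i), "gfp_control", control_kind)
    if (with_tips) add(sprintf("gctl%02d_tip", i), sprintf("cell_gctl%02d", i),
                       "gfp_control", "tip_patch")
  }
  for (i in seq_len(cfg$n_tagfree_cells)) {
    add(sprintf("free%02d", i), sprintf("cell_free%02d", i), "tag_free", "whole_cell")
  }
  for (i in seq_len(cfg$n_cellfree_regions)) {
    add(sprintf("bkg%02d", i), NA_character_, "cell_free", "cell_free")
  }
  dplyr::bind_rows(rows)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %s>\n", x$config$name))
  cat(sprintf("  %d ROIs, %d frames, %d trace rows%s\n",
              nrow(x$roi_table), x$config$n_frames, nrow(x$traces),
              if (!is.null(x$stack)) ", with rendered stack" else ""))
  cat(sprintf("  truth: %d sample cells, t_half = %.3g s\n",
              nrow(x$truth), x$config$t_half_true_s))
  invisible(x)
}

#' Write a synthetic dataset's tables to CSV
#'
#' Writes `traces.csv` (long format), `roi_table.csv` and `truth.csv` into
#' `dir`, at full floating-point precision.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_full(dataset$traces, file.path(dir, "traces.csv"))
  write_csv_full(dataset$roi_table, file.path(dir, "roi_table.csv"))
  write_csv_full(dataset$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
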