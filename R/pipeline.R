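#' Membrane-recruitment protocol on trace tables
#'
#' Whole-cell protocol of the optogenetic recruitment assay: camera/cell
#' background is estimated from tag-free cells, the RFP bleaching coefficient
#' from RFP-control cells (per-cell normalization to t0, moving-average
#' smoothing, cell averaging), sample traces are corrected and
#' zero-referenced, and each cell's net trace is fitted to
#' `a (1 - e^(-b t))` to yield per-cell half-times.
#'
#' @param traces Long raw trace table containing `sample`, `rfp_control` and
#'   `tag_free` populations.
#' @param channel Signal channel (default `"RFP"`).
#' @param background_source `"tag_free"` (whole-cell protocol) or
#'   `"cell_free"` (cortex-side protocol).
#' @param window Moving-average window for the bleaching coefficients.
#' @param fit_window_s Optional fit window in seconds.
#' @return List: `background`, `bleach`, `corrected`, `net`, `fits`,
#'   `summary`.
#' @export
run_membrane_recruitment <- function(traces, channel = "RFP",
                                     background_source = "tag_free",
                                     window = 5L, fit_window_s = NULL) {
  assert_trace_table(traces)
  require_populations(traces, c("sample",
                                if (channel == "RFP") "rfp_control" else "gfp_control",
                                if (background_source == "tag_free") "tag_free" else "cell_free"),
                      "membrane_recruitment")
  background <- estimate_background(traces, source = background_source)
  ctl_pop <- if (channel == "RFP") "rfp_control" else "gfp_control"
  bleach <- bleach_series(traces, background, population = ctl_pop,
                          window = window,
                          context = paste0("whole_cell_", tolower(channel)))
  samp <- dplyr::filter(traces, .data$population == "sample",
                        .data$channel == !!channel,
                        .data$kind != "tip_patch" | is.na(.data$kind))
  corrected <- correct_traces(samp, background, bleach)
  net <- net_traces(corrected)
  fits <- single_cell_half_times(net, window_s = fit_window_s)
  list(background = background, bleach = bleach, corrected = corrected,
       net = net, fits = fits, summary = fit_summary(fits))
}

#' Side-relocalization protocol on trace tables
#'
#' Cortex-side protocol: camera background from cell-free regions; RFP and
#' GFP bleaching coefficients from the cell sides of the respective control
#' strains; both channels of the sample cells corrected and zero-referenced.
#' The RFP traces (optogenetic construct) are fitted per cell; the weaker GFP
#' traces are averaged across cells and the initial `fit_window_s` seconds of
#' the average are fitted once. Per-cell cumulative GFP signals of sample and
#' GFP-control cells are returned together with a rank-based group comparison
#' (delegated to [stats::kruskal.test()]).
#'
#' @param traces Long raw trace table with `sample`, `rfp_control`,
#'   `gfp_control` and `cell_free` populations (cortex-side ROIs).
#' @param window Moving-average window for the bleaching coefficients.
#' @param fit_window_s Fit window for the averaged GFP profile (default 45 s).
#' @return List: `background`, `bleach`, `net_rfp`, `net_gfp`, `rfp_fits`,
#'   `rfp_summary`, `gfp_fit`, `cumulative`, `group_test`.
#' @export
run_side_relocalization <- function(traces, window = 5L, fit_window_s = 45) {
  assert_trace_table(traces)
  require_populations(traces, c("sample", "rfp_control", "gfp_control", "cell_free"),
                      "side_relocalization")
  side <- dplyr::filter(traces, .data$kind != "tip_patch" | is.na(.data$kind))
  background <- estimate_background(side, source = "cell_free")
  bl_rfp <- bleach_series(side, background, population = "rfp_control",
                          window = window, context = "side_rfp")
  bl_gfp <- bleach_series(side, background, population = "gfp_control",
                          window = window, context = "side_gfp")
  bleach <- bind_rows(bl_rfp, bl_gfp)

  samp <- dplyr::filter(side, .data$population == "sample")
  net <- samp %>% correct_traces(background, bleach) %>% net_traces()
  net_rfp <- dplyr::filter(net, .data$channel == "RFP")
  net_gfp <- dplyr::filter(net, .data$channel == "GFP")

  rfp_fits <- if (nrow(net_rfp) > 0) single_cell_half_times(net_rfp) else NULL
  gfp_fit <- if (n_distinct(net_gfp$roi_id) >= 2) {
    average_profile_half_time(net_gfp, window_s = fit_window_s)
  } else NULL

  # cumulative GFP statistic: sample vs GFP-control cells, same correction
  ctl_gfp <- dplyr::filter(side, .data$population == "gfp_control",
                           .data$channel == "GFP")
  ctl_net <- ctl_gfp %>% correct_traces(background, bl_gfp) %>% net_traces()
  cumulative <- bind_rows(cumulative_signal(net_gfp), cumulative_signal(ctl_net))
  group_test <- if (n_distinct(cumulative$population) == 2) {
    stats::kruskal.test(cumulative ~ population, data = cumulative)
  } else NULL

  list(background = background, bleach = bleach,
       net_rfp = net_rfp, net_gfp = net_gfp,
       rfp_fits = rfp_fits,
       rfp_summary = if (!is.null(rfp_fits)) fit_summary(rfp_fits) else NULL,
       gfp_fit = gfp_fit, cumulative = cumulative, group_test = group_test)
}

#' Membrane-recruitment protocol from a rendered stack
#'
#' Image-mode version of [run_membrane_recruitment()]: for each sample cell a
#' 15-position membrane profile is extracted from its perpendicular ROI and
#' corrected position-by-position (background from tag-free whole-cell ROIs,
#' bleaching from RFP-control whole-cell ROIs); the membrane peak is located
#' on the final frame, the peak +/- 1 positions are averaged into a trace,
#' zero-referenced and fitted per cell.
#'
#' @param stack A [channel_stack()].
#' @param roi_table ROI tibble with box geometries and populations.
#' @param channel Signal channel (default `"RFP"`).
#' @param window Moving-average window.
#' @return List: `background`, `bleach`, `peaks`, `net`, `fits`, `summary`.
#' @export
run_membrane_recruitment_stack <- function(stack, roi_table, channel = "RFP",
                                           window = 5L) {
  require_populations(roi_table, c("sample", "rfp_control", "tag_free"),
                      "membrane_recruitment")
  aux <- dplyr::filter(roi_table, .data$population %in% c("rfp_control", "tag_free"))
  aux_traces <- extract_roi_traces(stack, aux, channels = channel)
  background <- estimate_background(aux_traces, source = "tag_free")
  bleach <- bleach_series(aux_traces, background,
                          population = if (channel == "RFP") "rfp_control" else "gfp_control",
                          window = window, context = "whole_cell_rfp")

  samp <- dplyr::filter(roi_table, .data$population == "sample",
                        .data$kind == "membrane_perpendicular")
  if (nrow(samp) == 0) abort("No sample membrane_perpendicular ROIs in the table.")
  bg_join <- select(background, "frame", "background")
  bl_join <- select(bleach, "frame", "coefficient")

  results <- purrr::map(seq_len(nrow(samp)), function(i) {
    roi <- as.list(samp[i, ])
    prof <- extract_membrane_profile(stack, roi, channel) %>%
      left_join(bg_join, by = "frame") %>%
      left_join(bl_join, by = "frame") %>%
      mutate(value = (.data$value - .data$background) / .data$coefficient) %>%
      select(-"background", -"coefficient")
    peak <- locate_membrane_peak(prof)
    trace <- peak_value_series(prof, peak) %>%
      mutate(state = "corrected", channel = channel)
    list(peak = tibble(roi_id = roi$roi_id, peak_position = peak), trace = trace)
  })
  peaks <- purrr::map_dfr(results, "peak")
  corrected <- purrr::map_dfr(results, "trace")
  net <- net_traces(corrected)
  fits <- single_cell_half_times(net)
  list(background = background, bleach = bleach, peaks = peaks,
       net = net, fits = fits, summary = fit_summary(fits))
}

require_populations <- function(tbl, needed, protocol) {
  if (!"population" %in% names(tbl)) {
    abort(sprintf("The %s protocol needs a `population` column.", protocol))
  }
  missing <- setdiff(needed, unique(tbl$population))
  if (length(missing) > 0) {
    abort(sprintf(
      "The %s protocol requires co-imaged population(s) %s, absent from the input.",
      protocol, paste0("'", missing, "'", collapse = ", ")))
  }
  invisible(tbl)
}

#' Validate a trace table or stack/ROI pair before analysis
#'
#' Report-only checks: required columns, strictly increasing times, equal
#' trace lengths, ROI boxes inside image bounds, populations present.
#'
#' @param traces Optional long trace table.
#' @param stack Optional [channel_stack()].
#' @param roi_table Optional ROI tibble (checked against `stack` if given).
#' @return Tibble: `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(traces = NULL, stack = NULL, roi_table = NULL) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, pass = pass,
                                             detail = detail)
  }
  if (!is.null(traces)) {
    missing <- setdiff(trace_cols, names(traces))
    add("trace columns", length(missing) == 0,
        if (length(missing)) paste("missing:", paste(missing, collapse = ", ")) else "")
    if (length(missing) == 0) {
      bad_time <- traces %>%
        group_by(.data$roi_id, .data$channel) %>%
        arrange(.data$frame, .by_group = TRUE) %>%
        summarise(ok = all(diff(.data$time_s) > 0) || n() == 1L, .groups = "drop") %>%
        dplyr::filter(!.data$ok)
      add("monotone frame times", nrow(bad_time) == 0,
          if (nrow(bad_time)) paste("non-monotone:", paste(bad_time$roi_id, collapse = ", ")) else "")
      lens <- traces %>% group_by(.data$roi_id, .data$channel) %>%
        summarise(n = n(), .groups = "drop")
      add("equal trace lengths", n_distinct(lens$n) == 1L,
          sprintf("lengths: %s", paste(sort(unique(lens$n)), collapse = ", ")))
      if ("population" %in% names(traces)) {
        add("control populations present",
            all(c("sample") %in% traces$population),
            paste("present:", paste(sort(unique(traces$population)), collapse = ", ")))
      }
    }
  }
  if (!is.null(stack) && !is.null(roi_table)) {
    d <- dim(stack)
    oob <- purrr::map_lgl(seq_len(nrow(roi_table)), function(i) {
      roi <- as.list(roi_table[i, ])
      tryCatch({ box_indices(roi, d[2], d[3]); FALSE }, error = function(e) TRUE)
    })
    add("ROIs inside image bounds", !any(oob),
        if (any(oob)) paste("out of bounds:", paste(roi_table$roi_id[oob], collapse = ", ")) else "")
    add("frame times match stack", TRUE,
        sprintf("%d frames, %.3g-%.3g s", d[1], min(stack$frame_times_s),
                max(stack$frame_times_s)))
  }
  bind_rows(checks)
}

#' Run a complete protocol from a configuration and write a report bundle
#'
#' Orchestrates one analysis run: validates inputs, executes the protocol's
#' stage sequence, and writes all result tables as CSV plus a JSON manifest
#' (protocol, parameters, seed, package version) and a plain-text log into
#' `output_dir`. Reruns with identical configuration and inputs produce
#' identical tables.
#'
#' @param config A named list (or path to a YAML file) with at least
#'   `protocol` (one of `"membrane_recruitment"`, `"side_relocalization"`,
#'   `"tip_timecourse"`, `"synthetic_validation"`) and the protocol's inputs:
#'   either `preset` (a [scenario_preset()] name, for synthetic runs) or
#'   `traces_csv` (a long trace table). Optional: `seed`, `window`,
#'   `fit_window_s`, `output_dir`.
#' @return The protocol's result list, invisibly; side effect: the report
#'   bundle under `output_dir` (if given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  protocol <- config$protocol %||% abort("`config$protocol` is required.")
  window <- config$window %||% 5L
  fit_window_s <- config$fit_window_s %||% 45

  traces <- NULL
  dataset <- NULL
  if (!is.null(config$preset)) {
    dataset <- generate_traces(scenario_preset(config$preset,
                                               seed = config$seed %||% scenario_preset(config$preset)$seed))
    traces <- dataset$traces
  } else if (!is.null(config$traces_csv)) {
    traces <- as_tibble(utils::read.csv(config$traces_csv, stringsAsFactors = FALSE))
  }
  if (is.null(traces)) abort("Provide either `preset` or `traces_csv` in the config.")
  assert_trace_table(traces)

  result <- switch(protocol,
    membrane_recruitment = run_membrane_recruitment(
      traces, background_source = config$background_source %||% "tag_free",
      window = window),
    side_relocalization = run_side_relocalization(traces, window = window,
                                                  fit_window_s = fit_window_s),
    tip_timecourse = tip_timecourse(traces, window = window),
    synthetic_validation = {
      if (is.null(dataset)) abort("synthetic_validation needs a `preset`.")
      res <- if (signal_channel(dataset$config) == "RFP") {
        run_membrane_recruitment(traces)
      } else {
        run_side_relocalization(traces, window = window, fit_window_s = fit_window_s)
      }
      res$recovery <- recovery_table(res, dataset)
      res
    },
    abort(sprintf("Unknown protocol '%s'.", protocol)))

  if (!is.null(config$output_dir)) {
    write_bundle(result, config, protocol)
  }
  invisible(result)
}

recovery_table <- function(result, dataset) {
  truth <- dataset$truth
  if (!is.null(result$fits)) {
    left_join(result$fits, truth, by = "roi_id") %>%
      mutate(t_half_error = .data$t_half - .data$t_half_true)
  } else {
    tibble(t_half_true = truth$t_half_true[1],
           t_half_recovered = result$gfp_fit$t_half)
  }
}

write_bundle <- function(result, config, protocol) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("protocol: %s", protocol),
           sprintf("run at: (deterministic; timestamps omitted)"))
  for (nm in names(result)) {
    obj <- result[[nm]]
    if (is.data.frame(obj)) {
      write_csv_full(obj, file.path(dir, paste0(nm, ".csv")))
      log <- c(log, sprintf("wrote %s.csv (%d rows)", nm, nrow(obj)))
    }
  }
  manifest <- list(protocol = protocol,
                   package_version = as.character(utils::packageVersion("cortiquant")),
                   config = config[setdiff(names(config), "output_dir")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Heatmap display of a kymograph matrix
#'
#' @param kymo Matrix from [build_kymograph()] (rows = time).
#' @return A ggplot.
#' @export
plot_kymograph <- function(kymo) {
  df <- tidyr::expand_grid(frame = seq_len(nrow(kymo)),
                           arc_px = seq_len(ncol(kymo)))
  df$value <- kymo[cbind(df$frame, df$arc_px)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc_px, y = .data$frame,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "arc length (px)", y = "frame") +
    ggplot2::theme_minimal()
}
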