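# Small deterministic configurations used across tests.

# Idealized acquisition: no noise, no bleaching, no background, no
# autofluorescence, identical plateaus — the closed form is exact.
ideal_cfg <- function(...) {
  scenario_config(noise_sd = 0, bleach_rate_rfp = 0, bleach_rate_gfp = 0,
                  background_level = 0, autofluorescence_level = 0,
                  plateau_cv = 0, ...)
}

# Scaled-down mixture for fast full-pipeline runs.
small_cfg <- function(...) {
  scenario_config(n_sample_cells = 6L, n_rfp_controls = 4L,
                  n_gfp_controls = 4L, n_tagfree_cells = 3L,
                  n_cellfree_regions = 3L, ...)
}

# Minimal single-channel stack from a 3-D array.
array_stack <- function(arr, channel = "RFP", period = 0.5) {
  channel_stack(setNames(list(arr), channel),
                frame_times_s = (seq_len(dim(arr)[1]) - 1) * period)
}

const_stack <- function(value, n_frames = 3, H = 8, W = 10, channel = "RFP") {
  array_stack(array(value, dim = c(n_frames, H, W)), channel = channel)
}

roi_box <- function(roi_id, x0, y0, x1, y1, kind = NA_character_,
                    population = NA_character_) {
  list(roi_id = roi_id, cell_id = NA_character_, population = population,
       kind = kind, x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

# One raw trace as a long tibble.
trace_tbl <- function(values, roi_id = "roi1", channel = "RFP",
                      period = 0.5, population = NA_character_,
                      kind = NA_character_, state = "raw") {
  tibble::tibble(
    roi_id = roi_id, cell_id = NA_character_, population = population,
    kind = kind, channel = channel, frame = seq_along(values),
    time_s = (seq_along(values) - 1) * period, value = values, state = state
  )
}

as_corrected <- function(tbl) dplyr::mutate(tbl, state = "corrected")
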