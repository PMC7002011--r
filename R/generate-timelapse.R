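# Renderer geometry. Cells are 2-D capsules ("rods"): a straight spine of
# half-length CAP_L with a circular cap of radius CAP_R, giving a footprint of
# (2*CAP_L + 2*CAP_R + 1) x (2*CAP_R + 1) = 51 x 15 px. The membrane is the
# outer 3-px band of the capsule; the straight side is 37 px long so the
# canonical 36-px-wide membrane ROIs fit without touching the curved caps.
CAP_L <- 18L   # spine half-length (px)
CAP_R <- 7L    # capsule radius (px)
SLOT_W <- 61L  # placement grid slot (px)
SLOT_H <- 31L

# squared distance from pixel (x, y) to the spine segment of a cell at (cx, cy)
capsule_dist2 <- function(x, y, cx, cy) {
  dx <- pmax(abs(x - cx) - CAP_L, 0)
  dx^2 + (y - cy)^2
}

cell_masks <- function(cx, cy, H, W) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  d2 <- capsule_dist2(xs, ys, cx, cy)
  inside <- d2 <= CAP_R^2
  membrane <- inside & d2 >= (CAP_R - 2L)^2
  side_band <- membrane & abs(xs - cx) <= CAP_L          # straight-side membrane
  cap_band <- membrane & !side_band                      # curved tip membrane
  list(cell = which(inside), membrane = which(membrane),
       side = which(side_band), caps = which(cap_band))
}

# 0-based half-open pixel box helper (stored convention for ROI CSVs)
box <- function(col_lo, col_hi, row_lo, row_hi) {
  c(x0 = col_lo - 1L, y0 = row_lo - 1L, x1 = col_hi, y1 = row_hi)
}

#' Render a synthetic multi-channel time lapse with matching ROI annotations
#'
#' Draws non-overlapping capsule-shaped cells on a uniform camera background
#' and renders, per pixel and frame, the same generative model as
#' [generate_traces()]: recruitment kinetics on the membrane band of sample
#' cells, constant cytosolic signal in control cells, constant per-cell
#' autofluorescence, per-frame multiplicative bleaching, and additive
#' per-pixel Gaussian noise. Emits the matching ROI table (perpendicular
#' membrane ROIs 36 x 15 px, cortex-side ROIs 36 x 3 px, tip patches 3 x 9 px,
#' whole-cell boxes and cell-free regions; 0-based half-open boxes) so the
#' full image pipeline can run end-to-end. Pixel size is recorded as
#' 0.083 micrometers.
#'
#' @param cfg A [scenario_config()]. `cfg$noise_sd` is applied per pixel.
#' @param field_dim Optional c(rows, cols) of the field; errors if too small
#'   to place all requested cells without overlap. By default the field is
#'   sized to fit.
#' @return A `synthetic_dataset` whose `stack` is a [channel_stack()] and
#'   whose `traces` are the raw ROI-mean traces extracted from the rendered
#'   stack.
#' @export
generate_timelapse <- function(cfg, field_dim = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n_cells <- cfg$n_sample_cells + cfg$n_rfp_controls + cfg$n_gfp_controls +
    cfg$n_tagfree_cells
  n_slots <- n_cells + cfg$n_cellfree_regions
  ncol_s <- max(1L, ceiling(sqrt(n_slots)))
  nrow_s <- ceiling(n_slots / ncol_s)
  H_need <- nrow_s * SLOT_H + 2L
  W_need <- ncol_s * SLOT_W + 2L
  if (is.null(field_dim)) {
    H <- H_need; W <- W_need
  } else {
    H <- field_dim[1]; W <- field_dim[2]
    if (H < H_need || W < W_need) {
      abort(sprintf(
        "Field %d x %d px is too small to place %d cells and %d cell-free regions without overlap (need %d x %d).",
        H, W, n_cells, cfg$n_cellfree_regions, H_need, W_need))
    }
    nrow_s <- (H - 2L) %/% SLOT_H
    ncol_s <- (W - 2L) %/% SLOT_W
  }

  frames <- seq_len(cfg$n_frames)
  tau <- (frames - 1) * cfg$cycle_period_s
  b <- log(2) / cfg$t_half_true_s
  sig_ch <- signal_channel(cfg)
  with_tips <- sig_ch == "GFP"
  a_i <- draw_plateaus(cfg$n_sample_cells, cfg$plateau_mean, cfg$plateau_cv)

  plan <- roi_plan(cfg, with_tips)
  # one slot (placement site) per cell / cell-free region, in plan order
  cells <- unique(plan$cell_id[!is.na(plan$cell_id)])
  sites <- c(cells, plan$roi_id[plan$population == "cell_free"])
  centers <- lapply(seq_along(sites), function(k) {
    sr <- (k - 1L) %/% ncol_s
    sc <- (k - 1L) %% ncol_s
    c(cy = sr * SLOT_H + 1L + SLOT_H %/% 2L + 1L,
      cx = sc * SLOT_W + 1L + SLOT_W %/% 2L + 1L)
  })
  names(centers) <- sites

  # per-cell pixel masks and population
  cell_pop <- plan %>%
    dplyr::filter(!is.na(.data$cell_id)) %>%
    dplyr::distinct(.data$cell_id, .data$population)
  masks <- lapply(cell_pop$cell_id, function(id) {
    ctr <- centers[[id]]
    cell_masks(ctr["cx"], ctr["cy"], H, W)
  })
  names(masks) <- cell_pop$cell_id

  render_channel <- function(ch) {
    rate <- if (ch == "RFP") cfg$bleach_rate_rfp else cfg$bleach_rate_gfp
    bleach <- (1 - rate)^(frames - 1)
    arr <- array(cfg$background_level, dim = c(cfg$n_frames, H, W))
    for (ci in seq_len(nrow(cell_pop))) {
      id <- cell_pop$cell_id[ci]
      pop <- cell_pop$population[ci]
      mk <- masks[[id]]
      plane <- matrix(0, H, W)
      plane[mk$cell] <- cfg$autofluorescence_level
      if (pop %in% c("rfp_control", "gfp_control")) {
        own <- if (pop == "rfp_control") "RFP" else "GFP"
        if (ch == own) plane[mk$cell] <- plane[mk$cell] + cfg$control_level
      }
      for (f in frames) {
        extra <- matrix(0, H, W)
        if (pop == "sample" && ch == sig_ch) {
          i <- match(id, cells[seq_len(cfg$n_sample_cells)])
          extra[mk$side] <- sat_exp(tau[f], a_i[i], b)
          if (with_tips) {
            dep <- 1 - cfg$tip_depletion_fraction * (1 - exp(-b * tau[f]))
            extra[mk$caps] <- (cfg$autofluorescence_level + cfg$control_level) *
              dep - cfg$autofluorescence_level
          } else {
            extra[mk$caps] <- sat_exp(tau[f], a_i[i], b)
          }
        }
        idx <- c(mk$cell)
        arr[f, , ][idx] <- arr[f, , ][idx] + (plane[idx] + extra[idx]) * bleach[f]
      }
    }
    if (cfg$noise_sd > 0) {
      arr <- arr + array(rnorm(length(arr), 0, cfg$noise_sd), dim = dim(arr))
    }
    arr
  }
  stack <- channel_stack(list(RFP = render_channel("RFP"),
                              GFP = render_channel("GFP")),
                         frame_times_s = tau, pixel_size_um = 0.083)

  # ROI geometries in plan order
  geo <- purrr::pmap_dfr(plan, function(roi_id, cell_id, population, kind) {
    ctr <- centers[[if (is.na(cell_id)) roi_id else cell_id]]
    cx <- ctr[["cx"]]; cy <- ctr[["cy"]]
    bx <- switch(kind,
      membrane_perpendicular = box(cx - 17L, cx + 18L, cy - 12L, cy + 2L),
      cortex_side            = box(cx - 17L, cx + 18L, cy - 7L, cy - 5L),
      tip_patch              = box(cx + 23L, cx + 25L, cy - 4L, cy + 4L),
      whole_cell             = box(cx - 25L, cx + 25L, cy - 7L, cy + 7L),
      cell_free              = box(cx - 5L, cx + 5L, cy - 5L, cy + 5L),
      abort(sprintf("Unhandled ROI kind '%s'.", kind)))
    tibble(roi_id = roi_id, cell_id = cell_id, population = population,
           kind = kind, x0 = bx[["x0"]], y0 = bx[["y0"]],
           x1 = bx[["x1"]], y1 = bx[["y1"]])
  })

  truth <- tibble(
    roi_id = plan$roi_id[plan$population == "sample" & plan$kind != "tip_patch"],
    cell_id = plan$cell_id[plan$population == "sample" & plan$kind != "tip_patch"],
    a_true = a_i, b_true = b, t_half_true = cfg$t_half_true_s
  )

  traces <- extract_roi_traces(stack, geo)
  structure(list(traces = traces, roi_table = geo, truth = truth,
                 config = cfg, stack = stack),
            class = "synthetic_dataset")
}
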