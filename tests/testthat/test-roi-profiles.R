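test_that("ROI traces are pixel means: constants, small arithmetic, brute force", {
  st <- const_stack(7, n_frames = 4)
  tr <- extract_roi_trace(st, roi_box("r", 2, 3, 6, 7), "RFP")
  expect_equal(tr$value, rep(7, 4))
  expect_identical(tr$state, rep("raw", 4))

  # 2x2 ROI over pixels {1,2,3,4}
  arr <- array(0, dim = c(2, 4, 4))
  arr[, 1:2, 1:2] <- rep(matrix(c(1, 3, 2, 4), 2, 2), each = 2)
  st2 <- array_stack(arr)
  expect_equal(extract_roi_trace(st2, roi_box("q", 0, 0, 2, 2), "RFP")$value,
               c(2.5, 2.5))

  # brute-force per-pixel oracle on a random stack
  set.seed(11)
  arr3 <- array(rnorm(3 * 9 * 12), dim = c(3, 9, 12))
  st3 <- array_stack(arr3)
  roi <- roi_box("z", 2, 1, 8, 6)   # cols 3..8, rows 2..6 (1-based)
  got <- extract_roi_trace(st3, roi, "RFP")$value
  oracle <- numeric(3)
  for (f in 1:3) {
    acc <- 0; n <- 0
    for (r in 2:6) for (cc in 3:8) { acc <- acc + arr3[f, r, cc]; n <- n + 1 }
    oracle[f] <- acc / n
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("out-of-bounds ROIs raise an error naming the ROI", {
  st <- const_stack(1)
  expect_error(extract_roi_trace(st, roi_box("bad_roi", 5, 5, 20, 9), "RFP"),
               "bad_roi")
})

test_that("membrane profiles average across the ROI width and keep 15 positions", {
  arr <- array(1, dim = c(2, 20, 40))
  arr[, 8, ] <- 9   # one bright row crossing the ROI
  st <- array_stack(arr)
  roi <- roi_box("m", 2, 3, 38, 18, kind = "membrane_perpendicular")
  prof <- extract_membrane_profile(st, roi, "RFP")
  expect_equal(nrow(prof), 2 * 15)
  expect_equal(sort(unique(prof$position)), 1:15)
  p1 <- dplyr::filter(prof, frame == 1)
  expect_equal(sum(p1$value == 9), 1)       # single-position peak
  expect_equal(p1$value[p1$position != 5], rep(1, 14))
  expect_equal(locate_membrane_peak(prof), 5L)

  # uniform image -> flat profile
  flat <- extract_membrane_profile(const_stack(3, H = 20, W = 40), roi, "RFP")
  expect_equal(unique(flat$value), 3)
})

test_that("peak location uses the final frame, breaks ties outward, warns at edges", {
  prof <- tidyr::expand_grid(frame = 1:2, position = 1:15)
  prof$value <- 0
  prof$value[prof$frame == 2 & prof$position %in% c(4, 9)] <- 5
  prof$value[prof$frame == 1 & prof$position == 12] <- 99  # earlier frames ignored
  expect_equal(locate_membrane_peak(prof), 4L)

  edge <- tidyr::expand_grid(frame = 1, position = 1:15)
  edge$value <- rev(seq_len(15))
  expect_warning(p <- locate_membrane_peak(edge), "boundary")
  expect_equal(p, 1L)
})

test_that("kymographs sample the path per frame with the declared shape", {
  st <- const_stack(4, n_frames = 3, H = 10, W = 20)
  path <- cbind(x = c(3, 17), y = c(5, 5))
  k <- build_kymograph(st, path, width_px = 1, channel = "RFP")
  expect_equal(dim(k), c(3, 15))
  expect_true(all(k == 4))

  arr <- array(0, dim = c(3, 10, 20))
  arr[2, 5, 9] <- 50
  k2 <- build_kymograph(array_stack(arr), path, width_px = 1, channel = "RFP")
  hot <- which(k2 != 0, arr.ind = TRUE)
  expect_equal(nrow(hot), 1L)
  expect_equal(unname(hot[1, 1]), 2)   # row = frame of the bright pixel
  expect_error(build_kymograph(st, cbind(c(3, 40), c(5, 5)), 1, "RFP"), "bounds")
})

test_that("sum projections add consecutive frames and are linear", {
  st <- const_stack(2, n_frames = 6)
  expect_true(all(sum_project(st, "RFP", 1, 5) == 10))

  arr <- array(rep(1:5, each = 1), dim = c(5, 3, 3))
  for (f in 1:5) arr[f, , ] <- f
  expect_true(all(sum_project(array_stack(arr), "RFP", 1, 5) == 15))

  set.seed(3)
  A <- array(rnorm(5 * 4 * 4), dim = c(5, 4, 4))
  B <- array(rnorm(5 * 4 * 4), dim = c(5, 4, 4))
  expect_equal(sum_project(array_stack(A + B), "RFP", 1, 5),
               sum_project(array_stack(A), "RFP", 1, 5) +
                 sum_project(array_stack(B), "RFP", 1, 5))
  expect_error(sum_project(st, "RFP", 4, 5), "window")
})

test_that("tip profiles are width-averaged, background-subtracted and centered", {
  img <- matrix(8, 15, 25)
  line <- cbind(x = c(5, 21), y = c(8, 8))
  prof <- extract_tip_profile(img, line, width_px = 3, background = 3,
                              center = c(13, 8))
  expect_true(all(abs(prof$value - 5) < 1e-12))
  expect_equal(min(abs(prof$position_um)), 0)
  expect_error(extract_tip_profile(img, line, center = c(13, 12)), "center")

  zero <- extract_tip_profile(img, line, background = 8, center = c(13, 8))
  expect_true(all(zero$value == 0))
})

test_that("tip center value averages the 5 central samples", {
  flat <- tibble::tibble(position_um = (-4:4) * 0.083, value = 6)
  expect_equal(tip_center_value(flat), 6)
  ramp <- tibble::tibble(position_um = (-2:2) * 0.083, value = 1:5)
  expect_equal(tip_center_value(ramp), 3)
  expect_error(tip_center_value(ramp[1:3, ]), "at least 5")

  set.seed(5)
  for (i in 1:20) {
    n <- sample(7:15, 1)
    half <- (n - 1) %/% 2
    pos <- (seq_len(n) - half - 1) * 0.083
    v <- rnorm(n)
    ord <- sample(n)   # order must not matter
    prof <- tibble::tibble(position_um = pos[ord], value = v[ord])
    i0 <- which(pos == 0)
    expect_equal(tip_center_value(prof), mean(v[(i0 - 2):(i0 + 2)]))
  }
})
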