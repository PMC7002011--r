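test_that("background estimation averages sources per frame and validates mixing", {
  t1 <- trace_tbl(rep(10, 4), "b1", population = "cell_free")
  t2 <- trace_tbl(rep(20, 4), "b2", population = "cell_free")
  bg <- estimate_background(dplyr::bind_rows(t1, t2), "cell_free")
  expect_equal(bg$background, rep(15, 4))
  expect_equal(unique(bg$n_sources), 2L)

  one <- estimate_background(t1, "cell_free")
  expect_equal(one$background, t1$value)

  tf <- trace_tbl(rep(30, 4), "f1", population = "tag_free")
  expect_error(estimate_background(tf, "cell_free"), "mixed")

  # 5 noisy constant sources: mean within 3 sigma / sqrt(5)
  set.seed(2)
  noisy <- purrr::map_dfr(1:5, function(i) {
    trace_tbl(100 + rnorm(30, 0, 4), sprintf("b%d", i), population = "cell_free")
  })
  bgn <- estimate_background(noisy, "cell_free")
  expect_true(mean(abs(bgn$background - 100) < 3 * 4 / sqrt(5)) > 0.95)
})

test_that("moving average preserves constants, centers interior windows, shrinks at edges", {
  expect_equal(moving_average(rep(4, 9)), rep(4, 9))
  expect_equal(moving_average(1:7, 5)[3], 3)
  expect_equal(moving_average(1:5, 5)[1], 1)   # window shrinks to a single point
  expect_equal(moving_average(1:5, 5)[2], 2)   # and to 3 points one step in
  expect_error(moving_average(1:5, 4), "odd")
  # linear series are fixed points of a centered mean
  expect_equal(moving_average(seq(0, 10, by = 0.5), 5), seq(0, 10, by = 0.5))
})

test_that("bleaching coefficients invert the control algebra exactly", {
  k <- 0.02; S0 <- 400; B <- 100
  f <- (1 - k)^(0:19)
  ctl <- trace_tbl(B + S0 * f, "ctl1", population = "rfp_control")
  bg <- estimate_background(trace_tbl(rep(B, 20), "b1", population = "cell_free"),
                            "cell_free")
  bl <- bleach_series(ctl, bg, "rfp_control", window = 1)  # unsmoothed
  expect_equal(bl$coefficient, f, tolerance = 1e-12)
  expect_equal(bl$coefficient[1], 1)

  # no bleaching -> all ones
  flat <- trace_tbl(rep(B + S0, 20), "ctl1", population = "rfp_control")
  expect_equal(bleach_series(flat, bg, "rfp_control")$coefficient, rep(1, 20))

  bad <- trace_tbl(c(B - 5, rep(B + 10, 19)), "ctl_dim", population = "rfp_control")
  expect_error(bleach_series(bad, bg, "rfp_control"), "ctl_dim")
})

test_that("smoothing reduces the deviation of noisy bleaching coefficients", {
  set.seed(9)
  k <- 0.01; S0 <- 500; B <- 100
  f <- (1 - k)^(0:29)
  ctls <- purrr::map_dfr(1:10, function(i) {
    trace_tbl(B + S0 * f + rnorm(30, 0, 8), sprintf("c%02d", i),
              population = "rfp_control")
  })
  bg <- estimate_background(trace_tbl(rep(B, 30), "b", population = "cell_free"),
                            "cell_free")
  raw <- bleach_series(ctls, bg, "rfp_control", window = 1)
  smo <- bleach_series(ctls, bg, "rfp_control", window = 5)
  expect_lt(mean(abs(smo$coefficient[-1] - f[-1])),
            mean(abs(raw$coefficient[-1] - f[-1])))
  expect_equal(attr(smo, "smoothing_window"), 5L)
  expect_equal(attr(smo, "n_control_cells"), 10L)
})

test_that("trace correction divides out background and bleaching exactly", {
  n <- 10
  bg <- estimate_background(trace_tbl(rep(0, n), "b", population = "cell_free"),
                            "cell_free")
  bl <- tibble::tibble(channel = "RFP", frame = 1:n, coefficient = rep(1, n))
  raw <- trace_tbl(seq(5, 50, by = 5), "s1")
  out <- correct_traces(raw, bg, bl)
  expect_equal(out$value, raw$value)       # identity when D = 1, B = 0
  expect_identical(unique(out$state), "corrected")

  # raw(t) = B(t) + s(t) * D(t) inverts to s(t)
  B <- 100 + sin(1:n); D <- (1 - 0.03)^(0:(n - 1)); s <- c(0, cumsum(runif(n - 1)))
  bg2 <- estimate_background(trace_tbl(B, "b", population = "cell_free"), "cell_free")
  bl2 <- tibble::tibble(channel = "RFP", frame = 1:n, coefficient = D)
  out2 <- correct_traces(trace_tbl(B + s * D, "s1"), bg2, bl2)
  expect_equal(out2$value, s, tolerance = 1e-12)

  bl_bad <- tibble::tibble(channel = "RFP", frame = 1:n,
                           coefficient = c(rep(1, n - 1), 0))
  expect_error(correct_traces(raw, bg, bl_bad), "non-positive")
  expect_error(correct_traces(raw, bg, bl2[1:3, ]), "every frame")
})

test_that("net traces are zero-referenced and normalization is ratio-to-t0", {
  tr <- as_corrected(trace_tbl(c(5, 8, 11)))
  expect_equal(net_traces(tr)$value, c(0, 3, 6))
  expect_equal(net_traces(as_corrected(trace_tbl(rep(7, 5))))$value, rep(0, 5))
  expect_error(net_traces(trace_tbl(1:3)), "corrected")

  expect_equal(normalize_traces(as_corrected(trace_tbl(c(4, 2, 1))))$value,
               c(1, 0.5, 0.25))
  expect_equal(normalize_traces(as_corrected(trace_tbl(rep(3, 4))))$value,
               rep(1, 4))
  expect_error(normalize_traces(as_corrected(trace_tbl(c(0, 1, 2), "dark1"))),
               "dark1")
})

test_that("peak +/- 1 averaging matches hand arithmetic and warns at boundaries", {
  prof <- tidyr::expand_grid(frame = 1:2, position = 1:15)
  prof$value <- rep(c(0, 1, 2, 3, 2, 1, rep(0, 9)), times = 2)
  pv <- peak_value_series(prof, 4L)
  expect_equal(pv$value, rep((2 + 3 + 2) / 3, 2))

  flat <- tidyr::expand_grid(frame = 1:3, position = 1:15)
  flat$value <- 4
  expect_equal(peak_value_series(flat, 8L)$value, rep(4, 3))

  expect_warning(edge <- peak_value_series(prof, 1L), "boundary")
  expect_equal(edge$value, rep((0 + 1) / 2, 2))
})

test_that("peak +/- 1 averaging equals a brute-force oracle on random profiles", {
  set.seed(21)
  for (i in 1:50) {
    vals <- matrix(rnorm(15 * 4), nrow = 4)     # 4 frames x 15 positions
    prof <- tidyr::expand_grid(frame = 1:4, position = 1:15)
    prof$value <- as.vector(t(vals))
    peak <- sample(2:14, 1)
    got <- peak_value_series(prof, peak)$value
    oracle <- rowMeans(vals[, (peak - 1):(peak + 1)])
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("difference stacks invert bleaching and zero the first frame", {
  set.seed(4)
  scene <- matrix(runif(12 * 15, 100, 200), 12, 15)
  # static scene, no bleaching
  arr <- array(0, dim = c(6, 12, 15))
  for (f in 1:6) arr[f, , ] <- scene
  d0 <- make_difference_stack(array_stack(arr), "RFP")
  expect_lt(max(abs(d0$frames$RFP)), 1e-6)

  # static scene under known exponential bleaching
  lam <- 0.08
  tt <- (0:5) * 0.5
  arr2 <- array(0, dim = c(6, 12, 15))
  for (f in 1:6) arr2[f, , ] <- scene * exp(-lam * tt[f])
  d1 <- make_difference_stack(array_stack(arr2), "RFP")
  expect_lt(max(abs(d1$frames$RFP)) / mean(scene), 1e-3)
  expect_true(all(d1$frames$RFP[1, , ] == 0))
  expect_error(make_difference_stack(array_stack(arr2[1:2, , , drop = FALSE]), "RFP"),
               "3 frames")
})
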