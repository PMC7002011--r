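test_that("noise-free saturating-exponential data are recovered to 1e-6", {
  tt <- (0:29) * 0.5
  y <- sat_exp(tt, 100, 0.8)
  fit <- fit_saturating_exponential(tt, y)
  expect_true(fit$converged)
  expect_equal(fit$a, 100, tolerance = 1e-6)
  expect_equal(fit$b, 0.8, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.8, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / fit$b)   # identity to machine precision
})

test_that("degenerate inputs return a non-converged fit without crashing", {
  tt <- (0:9) * 0.5
  fit <- fit_saturating_exponential(tt, rep(0, 10))
  expect_false(fit$converged)
  expect_true(is.na(fit$t_half))
  expect_error(fit_saturating_exponential(tt[1:3], rep(1, 3)), "4 points")
  expect_error(fit_saturating_exponential(tt + 1, sat_exp(tt + 1, 1, 1)), "start at 0")
})

test_that("half_time implements ln(2)/b with its scaling law", {
  expect_equal(half_time(log(2)), 1)
  expect_equal(half_time(log(2) / 0.85), 0.85)
  expect_equal(half_time(2 * 0.4), half_time(0.4) / 2)
  expect_error(half_time(0), "positive")
  expect_error(half_time(-1), "positive")
})

test_that("normalization rescales the plateau but leaves b and t_half unchanged", {
  tt <- (0:24) * 0.5
  y <- sat_exp(tt, 73, 1.1)
  f0 <- fit_saturating_exponential(tt, y, normalize = FALSE)
  f1 <- fit_saturating_exponential(tt, y, normalize = TRUE)
  expect_equal(f1$b, f0$b, tolerance = 1e-8)
  expect_equal(f1$t_half, f0$t_half, tolerance = 1e-8)
  expect_equal(f1$a * mean(tail(y, 5)), f0$a, tolerance = 1e-6)
})

test_that("the optimizer beats a coarse grid-search oracle on small problems", {
  set.seed(14)
  tt <- (0:19) * 0.5
  for (i in 1:5) {
    y <- sat_exp(tt, runif(1, 50, 150), runif(1, 0.3, 1.5)) + rnorm(20, 0, 3)
    fit <- fit_saturating_exponential(tt, y)
    grid <- tidyr::expand_grid(a = seq(20, 200, by = 5),
                               b = seq(0.05, 2.5, by = 0.05))
    grid_rss <- purrr::map2_dbl(grid$a, grid$b,
                                function(a, b) sum((y - sat_exp(tt, a, b))^2))
    expect_lte(fit$rss, min(grid_rss))
  }
})

test_that("tidy and glance expose the fitted parameters", {
  tt <- (0:9) * 1
  fit <- fit_saturating_exponential(tt, sat_exp(tt, 10, 0.5))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "b"], 0.5, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_points, 10L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("identical cells give identical single-cell fits; empty input errors", {
  tt <- (0:29) * 0.5
  y <- sat_exp(tt, 50, log(2) / 0.85)
  traces <- purrr::map_dfr(1:30, function(i) {
    trace_tbl(y, sprintf("c%02d", i), state = "net")
  })
  fits <- single_cell_half_times(traces)
  expect_equal(nrow(fits), 30)
  expect_equal(length(unique(round(fits$t_half, 10))), 1L)
  expect_equal(fits$t_half[1], 0.85, tolerance = 1e-6)
  expect_error(single_cell_half_times(traces[0, ]), "No traces")
})

test_that("median recovery from noisy single-cell fits is within 5% over 200 replicates", {
  set.seed(31)
  tt <- (0:29) * 0.5
  a <- 100; b <- log(2) / 0.85
  t_halves <- replicate(200, {
    y <- sat_exp(tt, a, b) + rnorm(30, 0, 0.05 * a)
    f <- fit_saturating_exponential(tt, y, normalize = TRUE)
    if (f$converged) f$t_half else NA_real_
  })
  expect_lt(mean(is.na(t_halves)), 0.05)
  expect_equal(median(t_halves, na.rm = TRUE), 0.85, tolerance = 0.05)
})

test_that("averaged-profile fitting equals the single fit for identical cells", {
  tt <- (0:30) * 3
  y <- sat_exp(tt, 40, log(2) / 5.4)
  traces <- purrr::map_dfr(1:4, function(i) {
    trace_tbl(y, sprintf("c%d", i), period = 3, state = "net")
  })
  avg_fit <- average_profile_half_time(traces, window_s = 45)
  single <- fit_saturating_exponential(tt, y, normalize = TRUE, window_s = 45)
  expect_equal(avg_fit$t_half, single$t_half, tolerance = 1e-9)
  expect_lte(max(avg_fit$data$time_s), 45)

  expect_error(average_profile_half_time(traces, window_s = 500), "window")
  expect_error(average_profile_half_time(traces[traces$roi_id == "c1", ]),
               "at least 2")
})

test_that("pointwise averaging of traces is linear", {
  set.seed(8)
  tt <- (0:20) * 1
  m <- matrix(rnorm(21 * 5), nrow = 5)
  traces <- purrr::map_dfr(1:5, function(i) {
    trace_tbl(m[i, ], sprintf("c%d", i), period = 1, state = "net")
  })
  avg <- traces %>%
    dplyr::group_by(frame) %>%
    dplyr::summarise(value = mean(value))
  expect_equal(avg$value, colMeans(m))
})

test_that("cumulative signal sums net traces and separates responders from controls", {
  expect_equal(cumulative_signal(trace_tbl(rep(0, 4), state = "net"))$cumulative, 0)
  expect_equal(cumulative_signal(trace_tbl(c(0, 1, 2, 3), state = "net"))$cumulative, 6)
  expect_error(cumulative_signal(trace_tbl(1:3, state = "raw")), "net")

  set.seed(12)
  tt <- (0:29) * 0.5
  resp <- purrr::map_dfr(1:15, function(i) {
    trace_tbl(sat_exp(tt, 50, 0.8) + rnorm(30, 0, 10),
              sprintf("s%02d", i), population = "sample", state = "net")
  })
  ctls <- purrr::map_dfr(1:15, function(i) {
    trace_tbl(rnorm(30, 0, 10), sprintf("k%02d", i),
              population = "gfp_control", state = "net")
  })
  cum <- cumulative_signal(dplyr::bind_rows(resp, ctls))
  w <- stats::wilcox.test(cumulative ~ population, data = cum)
  # responders stochastically dominate flat controls
  expect_lt(w$p.value, 1e-4)
  expect_true(min(cum$cumulative[cum$population == "sample"]) >
                max(cum$cumulative[cum$population == "gfp_control"]))
})
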